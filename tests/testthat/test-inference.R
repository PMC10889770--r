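# spelled-out between/within variance oracle for the Gelman-Rubin factor
psrf_oracle <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  means <- sapply(chains, mean)
  vars <- sapply(chains, var)
  W <- sum(vars) / m
  B_over_n <- sum((means - mean(means))^2) / (m - 1)
  var_plus <- (n - 1) / n * W + B_over_n
  sqrt(var_plus / W)
}

test_that("psrf matches the spelled-out between/within variance formula", {
  chains <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(psrf(chains), psrf_oracle(chains), tolerance = 1e-12)

  set.seed(101)
  for (rep in 1:5) {
    chains <- list(rnorm(10, 0, 1), rnorm(10, 0.3, 1.2), rnorm(10, -0.2, 0.8))
    expect_equal(psrf(chains), psrf_oracle(chains), tolerance = 1e-12)
  }
})

test_that("psrf detects mixing and non-mixing chains", {
  set.seed(102)
  iid <- list(rnorm(20000), rnorm(20000))
  expect_gt(psrf(iid), 0.99)
  expect_lt(psrf(iid), 1.01)
  separated <- list(rnorm(200, 0, 1), rnorm(200, 10, 1))
  expect_gt(psrf(separated), 1.05)
  # zero total variance: 1 by convention
  expect_identical(psrf(list(rep(2, 5), rep(2, 5))), 1.0)
  expect_error(psrf(list(c(1, 2, 3, 4))), "at least 2 chains")
  expect_error(psrf(list(c(1, 2), c(1, 2))), "insufficient draws")
})

test_that("a single-person posterior matches a quadrature oracle", {
  # one person, one item, y = 1, easiness and gamma frozen at 0, all scales
  # fixed: the only free block beyond positions is theta with a N(0,1) prior,
  # so the posterior is proportional to plogis(theta) * dnorm(theta)
  ds <- load_long_table(long_rows("p1", "i1", 1, 10))
  labels <- data.frame(person_id = "p1", item_id = "i1", residual = 0.1,
                       label = "slow", stringsAsFactors = FALSE)
  class(labels) <- c("speed_labels", "data.frame")
  expanded <- build_expanded(ds, labels)
  fit <- run_mcmc(expanded, lsirt_spec(constrained = TRUE),
                  n_chains = 2, n_iter = 4000, seed = 31,
                  fix = list(easiness = 0, gamma = 0, sigma_theta = 1,
                             mu_c = 0, sigma_c = 1,
                             person_pos = matrix(0, 1, 2),
                             item_pos = matrix(0, 2, 2)))
  num <- integrate(function(t) t * plogis(t) * dnorm(t), -Inf, Inf)$value
  den <- integrate(function(t) plogis(t) * dnorm(t), -Inf, Inf)$value
  theta_draws <- unlist(lapply(fit$draws, function(d) d[, "theta[1]"]))
  expect_equal(mean(theta_draws), num / den, tolerance = 0.06)
})

test_that("sampling is reproducible for a fixed seed", {
  expanded <- tiny_expanded(12, 4, seed = 111)
  spec <- lsirt_spec(constrained = TRUE)
  fit1 <- run_mcmc(expanded, spec, n_chains = 2, n_iter = 300, seed = 7)
  fit2 <- run_mcmc(expanded, spec, n_chains = 2, n_iter = 300, seed = 7)
  expect_identical(fit1$draws, fit2$draws)
  expect_identical(fit1$log_post, fit2$log_post)
  expect_error(run_mcmc(expanded, spec, n_chains = 2, n_iter = 300),
               "seed")
})

test_that("stored log posteriors match the reference density on extracted draws", {
  sf <- small_synthetic_fit()
  spec <- sf$fit$spec
  for (i in c(1, 50)) {
    params <- extract_draw(sf$fit, 1, i)
    expect_equal(sf$fit$log_post[[1]][i],
                 log_posterior(params, sf$expanded, spec), tolerance = 1e-8)
  }
})

test_that("data simulated without distance effects yield a near-zero gamma posterior", {
  cfg <- synthetic_config(P = 200, I = 20, gamma = 0, seed = 121)
  g <- generate_dataset(cfg)
  expanded <- build_expanded(g$data, classify_responses(g$data)$labels)
  fit <- run_mcmc(expanded, lsirt_spec(constrained = TRUE),
                  n_chains = 2, n_iter = 1200, seed = 122)
  gamma_draws <- unlist(lapply(fit$draws, function(d) d[, "gamma"]))
  expect_lt(median(gamma_draws), 0.4)
})

test_that("procrustes alignment recovers exact isometric copies and is idempotent", {
  sf <- small_synthetic_fit()
  fit <- sf$fit
  L <- fit$layout

  aligned <- procrustes_align(fit)
  ref <- lsirtmap:::stacked_config(
    aligned$draws[[aligned$reference$chain]][aligned$reference$draw, ], L)

  # an exact rotated + translated + reflected copy of the reference maps back
  Q <- rotation2(0.7) %*% diag(c(1, -1))
  copy <- sweep(ref %*% Q, 2, c(3, -2), "+")
  mapped <- lsirtmap:::procrustes_onto(copy, sweep(ref, 2, colMeans(ref)),
                                       colMeans(ref))
  expect_lt(max(abs(mapped - ref)), 1e-9)

  # idempotence
  again <- procrustes_align(aligned)
  expect_equal(again$draws, aligned$draws, tolerance = 1e-9)
})

test_that("procrustes alignment preserves within-draw distances and the likelihood", {
  sf <- small_synthetic_fit()
  fit <- sf$fit
  aligned <- procrustes_align(fit)
  idx <- c(1, 25, 100)
  for (i in idx) {
    p0 <- extract_draw(fit, 2, i)
    p1 <- extract_draw(aligned, 2, i)
    D0 <- lsirtmap:::distance_matrix(p0$person_pos, p0$item_pos)
    D1 <- lsirtmap:::distance_matrix(p1$person_pos, p1$item_pos)
    expect_lt(max(abs(D0 - D1)), 1e-9)
    expect_equal(log_likelihood(p1, sf$expanded, fit$spec),
                 log_likelihood(p0, sf$expanded, fit$spec), tolerance = 1e-9)
  }
  expect_identical(aligned$log_post, fit$log_post)
})

test_that("procrustes alignment error attains the singular-value optimum", {
  set.seed(131)
  for (rep in 1:5) {
    Y <- matrix(rnorm(10), 5, 2)  # reference configuration
    X <- matrix(rnorm(10), 5, 2)
    Yc <- sweep(Y, 2, colMeans(Y))
    mapped <- lsirtmap:::procrustes_onto(X, Yc, colMeans(Y))
    achieved <- sum((mapped - Y)^2)
    # orthogonal-Procrustes optimum via singular values
    Xc <- sweep(X, 2, colMeans(X))
    optimum <- sum(Xc^2) + sum(Yc^2) - 2 * sum(svd(crossprod(Xc, Yc))$d)
    expect_equal(achieved, optimum, tolerance = 1e-9)
  }
})

test_that("distance convergence diagnostics are alignment-free", {
  sf <- small_synthetic_fit()
  before <- convergence_on_distances(sf$fit)
  after <- convergence_on_distances(procrustes_align(sf$fit))
  expect_equal(before$psrf_by_quantity$psrf, after$psrf_by_quantity$psrf,
               tolerance = 1e-9)
  expect_identical(before$passed, after$passed)
})

test_that("degenerate short chains are rejected by the diagnostics", {
  sf <- small_synthetic_fit()
  short <- sf$fit
  short$draws <- lapply(short$draws, function(d) d[1, , drop = FALSE])
  expect_error(convergence_on_distances(short), "insufficient draws")
})

test_that("posterior predictive checks saturate, calibrate, and reject n_rep = 0", {
  sf <- small_synthetic_fit()
  expect_error(posterior_predictive_check(sf$fit, sf$expanded, n_rep = 0),
               "positive")

  # calibration: data generated from the model family, so observed item
  # proportions should fall inside their predictive intervals
  ppc <- posterior_predictive_check(sf$fit, sf$expanded, n_rep = 150, seed = 9)
  expect_gte(ppc$item_coverage, 0.9)
  expect_true(all(ppc$item_table$predictive_mean >= ppc$item_table$lower &
                  ppc$item_table$predictive_mean <= ppc$item_table$upper))

  # a posterior concentrated at a huge linear predictor predicts all-correct
  expanded <- tiny_expanded(4, 2, seed = 141)
  sat <- run_mcmc(expanded, lsirt_spec(constrained = TRUE),
                  n_chains = 2, n_iter = 200, seed = 13,
                  fix = list(theta = 35, easiness = 0, gamma = 0,
                             sigma_theta = 1, mu_c = 0, sigma_c = 1))
  ppc_sat <- posterior_predictive_check(sat, expanded, n_rep = 50, seed = 14)
  expect_true(all(ppc_sat$item_table$predictive_mean > 0.999))
})
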