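# a hand-built map avoids needing an MCMC fit for the geometry summaries
manual_map <- function(person_pos, item_pos, theta = NULL, easiness = NULL,
                       constrained = TRUE) {
  P <- nrow(person_pos)
  I <- nrow(item_pos) / 2
  structure(
    list(person_pos_hat = person_pos, item_pos_hat = item_pos,
         theta_hat = theta %||% rep(0, P),
         easiness_hat = easiness %||% rep(0, if (constrained) I else 2 * I),
         gamma_hat = 1, gamma_ci = c(0.8, 1.2),
         condition = rep(c("slow", "fast"), each = I),
         item_of = rep(seq_len(I), 2),
         person_ids = sprintf("p%02d", seq_len(P)),
         item_ids = sprintf("i%02d", seq_len(I)),
         pseudo_item_ids = c(sprintf("i%02d_slow", seq_len(I)),
                             sprintf("i%02d_fast", seq_len(I))),
         k = 2, constrained = constrained),
    class = "interaction_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("mean item distance averages over all persons", {
  # all persons at the item's position
  m <- manual_map(matrix(0, 4, 2), rbind(c(0, 0), c(1, 1)))
  expect_identical(mean_item_distance(m, 1), 0)
  # two persons at distances 1 and 3
  m2 <- manual_map(rbind(c(1, 0), c(3, 0)), rbind(c(0, 0), c(5, 5)))
  expect_identical(mean_item_distance(m2, 1), 2)
  # brute-force oracle on a random configuration
  set.seed(151)
  pp <- matrix(rnorm(20), 10, 2)
  ip <- matrix(rnorm(8), 4, 2)
  m3 <- manual_map(pp, ip)
  for (j in 1:4) {
    oracle <- mean(sapply(1:10, function(p) euclidean_distance(pp[p, ], ip[j, ])))
    expect_equal(mean_item_distance(m3, j), oracle, tolerance = 1e-12)
  }
})

test_that("mean item distance is invariant to person permutation", {
  set.seed(152)
  pp <- matrix(rnorm(16), 8, 2)
  ip <- matrix(rnorm(8), 4, 2)
  m <- manual_map(pp, ip)
  mp <- manual_map(pp[sample(8), ], ip)
  for (j in 1:4) {
    expect_equal(mean_item_distance(m, j), mean_item_distance(mp, j),
                 tolerance = 1e-12)
  }
})

test_that("slow-fast separation is the distance between an item's two positions", {
  m <- manual_map(matrix(0, 2, 2), rbind(c(1, 1), c(2, 2), c(1, 1), c(5, 6)))
  expect_identical(slow_fast_separation(m, 1), 0)
  expect_identical(slow_fast_separation(m, 2), 5)
  set.seed(153)
  ip <- matrix(rnorm(12), 6, 2)
  m2 <- manual_map(matrix(0, 2, 2), ip)
  for (i in 1:3) {
    expect_equal(slow_fast_separation(m2, i),
                 euclidean_distance(ip[i, ], ip[3 + i, ]), tolerance = 1e-12)
  }
})

test_that("distance summaries are invariant under a global isometry of the map", {
  set.seed(154)
  pp <- matrix(rnorm(12), 6, 2)
  ip <- matrix(rnorm(12), 6, 2)
  m <- manual_map(pp, ip)
  Q <- rotation2(1.1) %*% diag(c(-1, 1))
  shift <- c(2, -3)
  mt <- manual_map(sweep(pp %*% Q, 2, shift, "+"), sweep(ip %*% Q, 2, shift, "+"))
  for (j in 1:6) {
    expect_equal(mean_item_distance(mt, j), mean_item_distance(m, j),
                 tolerance = 1e-12)
  }
  for (i in 1:3) {
    expect_equal(slow_fast_separation(mt, i), slow_fast_separation(m, i),
                 tolerance = 1e-12)
  }
})

test_that("ability grouping uses -0.5 and 0.5 with an inclusive middle band", {
  g <- ability_grouping(c(-0.6, -0.5, 0, 0.5, 0.51))
  expect_identical(as.character(g), c("low", "medium", "medium", "medium", "high"))
})

test_that("easiness-distance table pairs the two model fits item by item", {
  # identical slow/fast easiness and symmetric positions: both columns zero
  set.seed(161)
  base_pos <- matrix(rnorm(6), 3, 2)
  con <- manual_map(matrix(rnorm(10), 5, 2), rbind(base_pos, base_pos),
                    constrained = TRUE)
  uncon <- manual_map(con$person_pos_hat, con$item_pos_hat,
                      easiness = rep(c(0.3, -0.2, 0.5), 2), constrained = FALSE)
  tab <- easiness_distance_table(con, uncon)
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$relative_easiness == 0))
  expect_true(all(abs(tab$distance_diff) < 1e-12))
  expect_true(is.na(attr(tab, "correlation")))
})

test_that("difficulty-separation correlation handles degeneracy and permutation", {
  set.seed(162)
  ds <- tiny_dataset(10, 4, seed = 162)
  # constant separations: undefined with a warning
  ip_same <- rbind(matrix(rnorm(8), 4, 2), matrix(rnorm(8), 4, 2))
  ip_same[5:8, ] <- ip_same[1:4, ] + 1 / sqrt(2)  # equal separations of 1
  m <- manual_map(matrix(rnorm(20), 10, 2), ip_same)
  expect_warning(r <- difficulty_separation_correlation(m, ds), "undefined")
  expect_true(is.na(r))

  # permutation of item labels leaves the value unchanged
  ip <- rbind(matrix(rnorm(8), 4, 2), matrix(rnorm(8), 4, 2))
  m2 <- manual_map(matrix(rnorm(20), 10, 2), ip)
  r2 <- difficulty_separation_correlation(m2, ds)
  perm <- c(3, 1, 4, 2)
  ds_perm <- ds
  ds_perm$responses <- ds$responses[, perm]
  ds_perm$rt_seconds <- ds$rt_seconds[, perm]
  ds_perm$observed <- ds$observed[, perm]
  ds_perm$item_ids <- ds$item_ids[perm]
  m_perm <- manual_map(m2$person_pos_hat, ip[c(perm, 4 + perm), ])
  expect_equal(difficulty_separation_correlation(m_perm, ds_perm), r2,
               tolerance = 1e-12)
})

test_that("nearest-respondent groups use stable tie-breaks and warn when short", {
  ds <- tiny_dataset(6, 2, seed = 171)
  expanded <- build_expanded(ds, checkerboard_labels(ds))
  # all persons equidistant from both positions: first n_group in person order
  m <- manual_map(matrix(rep(c(1, 0), each = 6), 6, 2),
                  rbind(c(0, 1), c(0, 5), c(0, -1), c(0, -5)))
  grp <- nearest_respondent_groups(m, expanded, 1, n_group = 3)
  expect_identical(grp$near_slow, sprintf("p%02d", 1:3))
  expect_identical(grp$near_fast, sprintf("p%02d", 1:3))

  expect_warning(grp_all <- nearest_respondent_groups(m, expanded, 1,
                                                      n_group = 50),
                 "eligible")
  expect_length(grp_all$near_slow, 6)

  # accuracy entries are proportions among the group's labeled responses
  expect_true(all(is.na(grp$accuracy) | (grp$accuracy >= 0 & grp$accuracy <= 1)))
})

test_that("planted respondent clusters show condition-matched accuracy contrasts", {
  # persons near the slow position succeed when slow; persons near the fast
  # position succeed when fast
  set.seed(181)
  P <- 40
  slow_pos <- c(-2, 0)
  fast_pos <- c(2, 0)
  person_pos <- rbind(
    sweep(matrix(rnorm(P, 0, 0.3), P / 2, 2), 2, slow_pos, "+"),
    sweep(matrix(rnorm(P, 0, 0.3), P / 2, 2), 2, fast_pos, "+"))
  cfg_truth <- list()
  theta <- rep(0, P)
  gamma <- 1.5
  d_slow <- sqrt(colSums((t(person_pos) - slow_pos)^2))
  d_fast <- sqrt(colSums((t(person_pos) - fast_pos)^2))
  # alternate labels so every person answers the item in one condition
  lab <- rep(c("slow", "fast"), P / 2)
  pr <- ifelse(lab == "slow", plogis(1 - gamma * d_slow),
               plogis(1 - gamma * d_fast))
  y <- rbinom(P, 1, pr)
  rows <- long_rows(sprintf("p%02d", 1:P), "i01", y, exp(rnorm(P, 3, 0.3)))
  rows2 <- long_rows(sprintf("p%02d", 1:P), "i02", rbinom(P, 1, 0.5),
                     exp(rnorm(P, 3, 0.3)))
  ds <- load_long_table(rbind(rows, rows2))
  labels <- data.frame(person_id = rep(sprintf("p%02d", 1:P), 2),
                       item_id = rep(c("i01", "i02"), each = P),
                       residual = ifelse(rep(lab, 2) == "slow", 0.4, -0.4),
                       label = rep(lab, 2), stringsAsFactors = FALSE)
  class(labels) <- c("speed_labels", "data.frame")
  expanded <- build_expanded(ds, labels)
  m <- manual_map(person_pos, rbind(slow_pos, c(0, 3), fast_pos, c(0, -3)))
  grp <- nearest_respondent_groups(m, expanded, 1, n_group = 15)
  # the slow-cluster group does better on slow responses than fast ones
  expect_gt(grp$accuracy["near_slow", "slow"], grp$accuracy["near_slow", "fast"])
  expect_gt(grp$accuracy["near_fast", "fast"], grp$accuracy["near_fast", "slow"])
})
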