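# small fixtures built in code; all randomness is seeded

rotation2 <- function(angle) {
  matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
}

# independent oracle: Henderson mixed-model equations at given variance
# components; returns conditional residuals y - X beta - Z u
henderson_residuals <- function(ds, var_person, var_item, var_resid) {
  long <- as_long_table(ds)
  y <- log(long$rt)
  n <- length(y)
  P <- length(ds$person_ids); I <- length(ds$item_ids)
  X <- matrix(1, n, 1)
  Z1 <- outer(long$person_id, ds$person_ids, "==") * 1
  Z2 <- outer(long$item_id, ds$item_ids, "==") * 1
  Z <- cbind(Z1, Z2)
  Ginv <- diag(c(rep(1 / var_person, P), rep(1 / var_item, I)))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + var_resid * Ginv))
  rhs <- rbind(crossprod(X, y), crossprod(Z, y))
  sol <- solve(C, rhs)
  beta <- sol[1]
  u <- sol[-1]
  list(beta = beta, u_person = u[seq_len(P)], u_item = u[P + seq_len(I)],
       residuals = y - beta - Z %*% u, long = long)
}

long_rows <- function(person, item, response, rt) {
  data.frame(person_id = person, item_id = item, response = response, rt = rt,
             stringsAsFactors = FALSE)
}

# fully crossed P x I dataset with iid log-normal RTs and Bernoulli(p) responses
tiny_dataset <- function(P = 4, I = 3, seed = 1, p = 0.6) {
  set.seed(seed)
  grid <- expand.grid(person_id = sprintf("p%02d", seq_len(P)),
                      item_id = sprintf("i%02d", seq_len(I)),
                      stringsAsFactors = FALSE)
  grid$response <- rbinom(nrow(grid), 1, p)
  grid$rt <- exp(rnorm(nrow(grid), 3, 0.5))
  load_long_table(grid)
}

# labels alternating by (person + item) parity; covers all observed cells
checkerboard_labels <- function(ds) {
  obs <- which(ds$observed, arr.ind = TRUE)
  obs <- obs[order(obs[, 1], obs[, 2]), , drop = FALSE]
  lab <- ifelse((obs[, 1] + obs[, 2]) %% 2 == 0, "slow", "fast")
  out <- data.frame(person_id = ds$person_ids[obs[, 1]],
                    item_id = ds$item_ids[obs[, 2]],
                    residual = ifelse(lab == "slow", 0.5, -0.5),
                    label = lab, stringsAsFactors = FALSE)
  class(out) <- c("speed_labels", "data.frame")
  out
}

# a small expanded dataset + params for model-layer tests
tiny_expanded <- function(P = 5, I = 3, seed = 2) {
  ds <- tiny_dataset(P, I, seed = seed)
  build_expanded(ds, checkerboard_labels(ds))
}

random_params <- function(P, I, k = 2, constrained = TRUE, seed = 3,
                          gamma = 0.8) {
  set.seed(seed)
  nc <- if (constrained) I else 2L * I
  lsirt_params(theta = rnorm(P), easiness = rnorm(nc), gamma = gamma,
               person_pos = matrix(rnorm(P * k), P, k),
               item_pos = matrix(rnorm(2 * I * k), 2 * I, k),
               sigma_theta = 1.2, mu_c = 0.1, sigma_c = 0.9)
}

# fast end-to-end fit on a small synthetic dataset (memoised per session)
small_fit_cache <- new.env()
small_synthetic_fit <- function() {
  if (!is.null(small_fit_cache$fit)) return(small_fit_cache$fit)
  cfg <- synthetic_config(P = 40, I = 8, gamma = 1, seed = 99)
  g <- generate_dataset(cfg)
  cls <- classify_responses(g$data)
  expanded <- build_expanded(g$data, cls$labels)
  fit <- run_mcmc(expanded, lsirt_spec(constrained = TRUE),
                  n_chains = 2, n_iter = 1200, seed = 5)
  small_fit_cache$fit <- list(cfg = cfg, g = g, expanded = expanded, fit = fit)
  small_fit_cache$fit
}
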