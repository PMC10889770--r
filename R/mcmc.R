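# ---- parameter vector layout (shared with src/lsirt_core.cpp) ----

par_layout <- function(P, J, k, constrained) {
  nc <- if (constrained) J %/% 2L else J
  off_c <- P
  off_lg <- P + nc
  off_mu <- off_lg + 1L
  off_lst <- off_mu + 1L
  off_lsc <- off_lst + 1L
  off_a <- off_lsc + 1L
  off_b <- off_a + P * k
  npar <- off_b + J * k
  nm <- c(paste0("theta[", seq_len(P), "]"),
          paste0("c[", seq_len(nc), "]"),
          "gamma", "mu_c", "sigma_theta", "sigma_c",
          paste0("a[", rep(seq_len(P), k), ",", rep(seq_len(k), each = P), "]"),
          paste0("b[", rep(seq_len(J), k), ",", rep(seq_len(k), each = J), "]"))
  list(P = P, J = J, k = k, nc = nc, off_c = off_c, off_lg = off_lg,
       off_mu = off_mu, off_lst = off_lst, off_lsc = off_lsc,
       off_a = off_a, off_b = off_b, npar = npar, names = nm)
}

# unconstrained vector -> lsirt_params (natural scale)
vec_to_params <- function(v, layout, log_scale = TRUE) {
  L <- layout
  tf <- if (log_scale) exp else identity
  v <- unname(v)
  lsirt_params(
    theta = v[seq_len(L$P)],
    easiness = v[L$off_c + seq_len(L$nc)],
    gamma = tf(v[L$off_lg + 1L]),
    person_pos = matrix(v[L$off_a + seq_len(L$P * L$k)], L$P, L$k),
    item_pos = matrix(v[L$off_b + seq_len(L$J * L$k)], L$J, L$k),
    sigma_theta = tf(v[L$off_lst + 1L]),
    mu_c = v[L$off_mu + 1L],
    sigma_c = tf(v[L$off_lsc + 1L]))
}

# Data-driven starting configuration: rough Rasch estimates for theta and
# easiness, and a spectral embedding of the residual matrix for positions.
# A random start collapses the distance term (position gradients vanish as
# gamma -> 0, making the Rasch limit quasi-absorbing for the sampler), so
# positions must begin correlated with the residual structure; the top-k
# singular vectors of the centered residuals provide exactly that, up to
# the isometries the model cannot identify anyway.
spectral_init <- function(data, spec, layout) {
  y <- data$responses
  obs <- !is.na(y)
  P <- nrow(y); J <- ncol(y); k <- spec$k
  pm <- (rowSums(y, na.rm = TRUE) + 0.5) / (rowSums(obs) + 1)
  jm <- (colSums(y, na.rm = TRUE) + 0.5) / (colSums(obs) + 1)
  theta0 <- qlogis(pm) - mean(qlogis(pm))
  c0 <- qlogis(jm)
  eta0 <- outer(theta0, c0, "+")
  R <- y - plogis(eta0)
  R[!obs] <- 0
  k_eff <- min(k, dim(R))
  sv <- svd(R, nu = k_eff, nv = k_eff)
  a0 <- matrix(0, P, k)
  b0 <- matrix(0, J, k)
  a0[, seq_len(k_eff)] <- sv$u %*% diag(sqrt(sv$d[seq_len(k_eff)]), k_eff)
  b0[, seq_len(k_eff)] <- sv$v %*% diag(sqrt(sv$d[seq_len(k_eff)]), k_eff)
  s <- sd(c(a0, b0))
  if (s > 0) {
    a0 <- 0.7 * a0 / s
    b0 <- 0.7 * b0 / s
  }
  c_init <- if (spec$constrained) {
    (c0[seq_len(J / 2)] + c0[J / 2 + seq_len(J / 2)]) / 2
  } else c0
  list(theta = theta0, easiness = c_init, a = a0, b = b0)
}

# fix= entries (natural scale) -> positions in the unconstrained vector
resolve_fixed <- function(fix, layout) {
  L <- layout
  idx <- integer(0); val <- numeric(0)
  add <- function(i, v) { idx <<- c(idx, i); val <<- c(val, v) }
  safe_log <- function(x) ifelse(x <= 0, -690, log(x))
  for (nm in names(fix)) {
    v <- fix[[nm]]
    switch(nm,
      theta = add(seq_len(L$P), rep_len(v, L$P)),
      easiness = add(L$off_c + seq_len(L$nc), rep_len(v, L$nc)),
      gamma = add(L$off_lg + 1L, safe_log(v)),
      mu_c = add(L$off_mu + 1L, v),
      sigma_theta = add(L$off_lst + 1L, safe_log(v)),
      sigma_c = add(L$off_lsc + 1L, safe_log(v)),
      person_pos = add(L$off_a + seq_len(L$P * L$k), as.numeric(v)),
      item_pos = add(L$off_b + seq_len(L$J * L$k), as.numeric(v)),
      stop("unknown fixed parameter block: ", nm))
  }
  list(idx = idx, val = val)
}

lp_grad_fun <- function(data, spec) {
  Y <- data$responses
  storage.mode(Y) <- "integer"
  itemmap0 <- if (spec$constrained) data$item_of - 1L else seq_along(data$item_of) - 1L
  pr <- spec$priors
  function(par, want_grad = TRUE) {
    .lsirt_lp_grad(par, Y, itemmap0, spec$k,
                   pr$gamma_sd, pr$easiness_mean_sd,
                   pr$theta_sd_scale, pr$easiness_sd_scale, want_grad)
  }
}

# full leapfrog trajectory in compiled code; free_idx is 0-based
traj_fun <- function(data, spec, free_idx0) {
  Y <- data$responses
  storage.mode(Y) <- "integer"
  itemmap0 <- if (spec$constrained) data$item_of - 1L else seq_along(data$item_of) - 1L
  pr <- spec$priors
  function(q, p, eps, L, inv_mass) {
    .lsirt_leapfrog(q, p, free_idx0, eps, L, inv_mass, Y, itemmap0, spec$k,
                    pr$gamma_sd, pr$easiness_mean_sd,
                    pr$theta_sd_scale, pr$easiness_sd_scale)
  }
}

find_reasonable_eps <- function(q, lp0, traj, nfree, inv_mass) {
  eps <- 0.1
  p <- rnorm(nfree) / sqrt(inv_mass)
  h0 <- -lp0 + 0.5 * sum(p^2 * inv_mass)
  step <- function(eps) {
    out <- traj(q, p, eps, 1L, inv_mass)
    if (out$diverged) return(0)
    h1 <- -out$lp + 0.5 * sum(out$p^2 * inv_mass)
    a <- exp(h0 - h1)
    if (is.finite(a)) a else 0
  }
  dir <- if (step(eps) > 0.5) 1 else -1
  for (it in 1:40) {
    eps <- eps * 2^dir
    a <- step(eps)
    if ((dir == 1 && a < 0.5) || (dir == -1 && a > 0.5)) break
  }
  max(eps, 1e-6)
}

hmc_chain <- function(fn, traj, init, free, n_iter, warmup, chain_seed, control) {
  set.seed(chain_seed)
  nfree <- sum(free)
  q <- init
  inv_mass <- rep(1, nfree)
  lp0 <- fn(q, want_grad = FALSE)$lp
  if (!is.finite(lp0)) stop("non-finite log posterior at initialization")
  eps <- min(find_reasonable_eps(q, lp0, traj, nfree, inv_mass),
             control$max_init_step)

  # dual averaging; the shrinkage point sits just above the current step
  # size rather than the usual 10x, because aggressive early exploration
  # can eject the chain from the narrow data-informed basin it starts in
  target <- control$target_accept
  da_reset <- function(eps) list(mu = log(2 * eps), Hbar = 0, log_ebar = 0, m = 0)
  da <- da_reset(eps)
  gamma_da <- 0.05; t0 <- 10; kappa <- 0.75

  w_lo <- floor(warmup * 0.25); w_hi <- floor(warmup * 0.75)
  mass_buf <- matrix(NA_real_, max(w_hi - w_lo, 1), nfree)
  buf_n <- 0L

  n_keep <- n_iter - warmup
  draws <- matrix(NA_real_, n_keep, length(init))
  lp_keep <- numeric(n_keep)
  cur_lp <- lp0
  n_div <- 0L; n_acc <- 0L; n_post <- 0L

  for (iter in seq_len(n_iter)) {
    Lmax <- max(1L, min(control$max_leapfrog,
                        as.integer(ceiling(control$traj_length / eps))))
    L <- sample.int(Lmax, 1L)
    p <- rnorm(nfree) / sqrt(inv_mass)
    h0 <- -cur_lp + 0.5 * sum(p^2 * inv_mass)
    out <- traj(q, p, eps, L, inv_mass)
    diverged <- out$diverged
    alpha <- 0
    if (!diverged) {
      h1 <- -out$lp + 0.5 * sum(out$p^2 * inv_mass)
      dH <- h0 - h1
      alpha <- if (is.finite(dH)) min(1, exp(dH)) else 0
      if (is.finite(dH) && dH < -1000) { diverged <- TRUE; alpha <- 0 }
    }
    if (diverged) n_div <- n_div + 1L
    if (runif(1) < alpha) { q <- out$q; cur_lp <- out$lp }

    if (iter <= warmup) {
      da$m <- da$m + 1
      da$Hbar <- (1 - 1 / (da$m + t0)) * da$Hbar +
        (target - alpha) / (da$m + t0)
      log_eps <- da$mu - sqrt(da$m) / gamma_da * da$Hbar
      w <- da$m^(-kappa)
      da$log_ebar <- w * log_eps + (1 - w) * da$log_ebar
      eps <- exp(log_eps)
      if (iter > w_lo && iter <= w_hi) {
        buf_n <- buf_n + 1L
        mass_buf[buf_n, ] <- q[free]
      }
      if (iter == w_hi && buf_n > 10L) {
        v <- apply(mass_buf[seq_len(buf_n), , drop = FALSE], 2, var)
        n <- buf_n
        inv_mass <- pmax(v * n / (n + 5) + 1e-3 * 5 / (n + 5), 1e-8)
        eps <- exp(da$log_ebar)
        da <- da_reset(eps)
      }
      if (iter == warmup) eps <- exp(da$log_ebar)
    } else {
      n_post <- n_post + 1L
      n_acc <- n_acc + alpha  # accumulate mean acceptance probability
      draws[iter - warmup, ] <- q
      lp_keep[iter - warmup] <- cur_lp
    }
  }
  accept_rate <- if (n_post > 0) n_acc / n_post else NA_real_
  if (!is.finite(eps) || eps < 1e-8) {
    stop("step-size adaptation failed (step size collapsed); ",
         "the posterior may be degenerate for these data")
  }
  if (is.finite(accept_rate) && accept_rate < 0.05) {
    stop("sampler failed to move after warm-up (mean acceptance ",
         sprintf("%.3f", accept_rate), "); check the model/data")
  }
  list(draws = draws, lp = lp_keep, eps = eps, accept_rate = accept_rate,
       divergences = n_div)
}

#' Sample the latent space Rasch posterior by Hamiltonian Monte Carlo
#'
#' Runs independent HMC chains targeting [log_posterior()] on the expanded
#' slow/fast matrix. Step size is tuned by dual averaging during warm-up
#' (target acceptance 0.8) with a diagonal mass-matrix update mid warm-up;
#' the distance weight and scale hyperparameters are sampled on the log scale
#' with the appropriate Jacobians, so positivity is automatic. Draws are
#' stored on the natural scale.
#'
#' The default run (2 chains of 2000 iterations, first half warm-up) is a
#' desk-scale preset; the reference analysis configuration of 2 chains of
#' 10,000 iterations is available by setting `n_iter = 10000`.
#'
#' @param data An `expanded_dataset` from [build_expanded()].
#' @param spec An [lsirt_spec()].
#' @param n_chains Number of chains (default 2).
#' @param n_iter Iterations per chain (default 2000).
#' @param warmup Warm-up iterations discarded from the front of each chain
#'   (default `n_iter / 2`).
#' @param seed Master seed (required; every source of randomness derives from
#'   it, so equal seeds give identical draws).
#' @param fix Optional named list of parameter blocks to hold fixed at given
#'   values (e.g. `list(gamma = 0)`); used for reduced-model checks.
#' @param control List: `target_accept` (0.8), `max_leapfrog` (96),
#'   `traj_length` (4), `init_scale` (0.2). Trajectory length is in
#'   integrator time units; the leapfrog count per iteration is drawn
#'   uniformly up to `traj_length / step_size` to avoid resonances.
#' @return An `lsirt_posterior` object: per-chain draw matrices (post
#'   warm-up, named columns), per-draw log posterior, the spec, layout and
#'   data bookkeeping needed by the diagnostics and summaries.
#' @export
run_mcmc <- function(data, spec, n_chains = 2, n_iter = 2000,
                     warmup = floor(n_iter / 2), seed, fix = NULL,
                     control = list()) {
  stopifnot(inherits(data, "expanded_dataset"), inherits(spec, "lsirt_spec"))
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  if (sum(!is.na(data$responses)) == 0L) stop("no observed responses")
  stopifnot(n_chains >= 1, n_iter >= 2, warmup >= 1, warmup < n_iter)
  ctl <- modifyList(list(target_accept = 0.8, max_leapfrog = 96,
                         traj_length = 4, init_scale = 0.2,
                         max_init_step = 0.1), control)

  P <- nrow(data$responses); J <- ncol(data$responses)
  layout <- par_layout(P, J, spec$k, spec$constrained)
  fn <- lp_grad_fun(data, spec)
  fixed <- resolve_fixed(fix, layout)
  free <- rep(TRUE, layout$npar)
  free[fixed$idx] <- FALSE
  if (!any(free)) stop("all parameters fixed; nothing to sample")
  traj <- traj_fun(data, spec, which(free) - 1L)

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, n_chains)

  # shared starting configuration: spectral embedding refined by a short
  # penalized optimization with the scale hyperparameters pinned at unit
  # values (optimizing them too would chase the hierarchical-funnel
  # degeneracy). A data-informed start matters here: from an arbitrary
  # configuration the position gradients vanish as gamma -> 0 and chains
  # can lodge in the Rasch-limit basin.
  start <- spectral_init(data, spec, layout)
  base <- numeric(layout$npar)
  base[seq_len(layout$P)] <- start$theta
  base[layout$off_c + seq_len(layout$nc)] <- start$easiness
  pos_idx <- c(layout$off_a + seq_len(layout$P * layout$k),
               layout$off_b + seq_len(layout$J * layout$k))
  base[pos_idx] <- c(start$a, start$b)
  base[fixed$idx] <- fixed$val
  hyper_idx <- c(layout$off_mu, layout$off_lst, layout$off_lsc) + 1L
  idx_opt <- setdiff(which(free), hyper_idx)
  if (length(idx_opt)) {
    opt <- stats::optim(
      base[idx_opt],
      fn = function(z) { v <- base; v[idx_opt] <- z; -fn(v, want_grad = FALSE)$lp },
      gr = function(z) { v <- base; v[idx_opt] <- z; -fn(v)$grad[idx_opt] },
      method = "L-BFGS-B", control = list(maxit = 100))
    base[idx_opt] <- opt$par
  }

  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(chain_seeds[ch])
    init <- base
    init[idx_opt] <- init[idx_opt] + rnorm(length(idx_opt)) * ctl$init_scale
    init[fixed$idx] <- fixed$val
    chains[[ch]] <- hmc_chain(fn, traj, init, free, n_iter, warmup,
                              chain_seeds[ch], ctl)
  }

  # store draws on the natural scale; log posterior without the sampling
  # Jacobian so it matches log_posterior() on the extracted parameters
  log_cols <- c(layout$off_lg, layout$off_lst, layout$off_lsc) + 1L
  draws <- lapply(chains, function(x) {
    d <- x$draws
    jac <- rowSums(d[, log_cols, drop = FALSE])
    d[, log_cols] <- exp(d[, log_cols])
    colnames(d) <- layout$names
    attr(d, "lp") <- x$lp - jac
    d
  })
  structure(
    list(draws = lapply(draws, function(d) { attr(d, "lp") <- NULL; d }),
         log_post = lapply(draws, function(d) attr(d, "lp")),
         spec = spec, layout = layout,
         condition = data$condition, item_of = data$item_of,
         person_ids = data$person_ids, item_ids = data$item_ids,
         pseudo_item_ids = data$pseudo_item_ids,
         observed = !is.na(data$responses),
         seed = seed, n_iter = n_iter, warmup = warmup,
         n_chains = n_chains, fixed = fixed,
         step_size = vapply(chains, `[[`, numeric(1), "eps"),
         accept_rate = vapply(chains, `[[`, numeric(1), "accept_rate"),
         divergences = vapply(chains, `[[`, integer(1), "divergences"),
         aligned = FALSE),
    class = "lsirt_posterior")
}

#' @export
print.lsirt_posterior <- function(x, ...) {
  cat("lsirt_posterior:", x$n_chains, "chains x", x$n_iter - x$warmup,
      "post-warm-up draws |", if (x$spec$constrained) "constrained" else "unconstrained",
      "easiness | k =", x$spec$k, "\n")
  cat(sprintf("  gamma posterior mean %.3f | mean acceptance %.2f | %s\n",
              mean(unlist(lapply(x$draws, function(d) d[, "gamma"]))),
              mean(x$accept_rate),
              if (x$aligned) "Procrustes-aligned" else "not aligned"))
  invisible(x)
}

#' Extract one posterior draw as an `lsirt_params` object
#'
#' @param samples An `lsirt_posterior`.
#' @param chain Chain index.
#' @param draw Draw index within the chain.
#' @return An [lsirt_params()] object on the natural scale.
#' @export
extract_draw <- function(samples, chain, draw) {
  vec_to_params(samples$draws[[chain]][draw, ], samples$layout,
                log_scale = FALSE)
}

# ---- Gelman-Rubin diagnostic ----

#' Potential scale-reduction factor (Gelman-Rubin R-hat)
#'
#' Classic (non-split, non-rank-normalized) two-or-more-chain diagnostic:
#' with m chains of length n, within-chain variance \eqn{W}, between-chain
#' variance \eqn{B = n \cdot var(\bar x_j)}, the pooled variance estimate is
#' \eqn{\widehat{var}^+ = (n-1)/n \cdot W + B/n} and
#' \eqn{\hat R = \sqrt{\widehat{var}^+ / W}}. When every value in every chain
#' is identical (zero total variance) the value is 1 by convention.
#'
#' @param chains A list of numeric vectors (equal lengths >= 4), or a matrix
#'   with one chain per column.
#' @return The PSRF (scalar).
#' @export
psrf <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2L) stop("need at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal lengths")
  if (n < 4L) stop("insufficient draws (need >= 4 per chain)")
  x <- matrix(unlist(chains), n, m)
  W <- mean(apply(x, 2, var))
  B_over_n <- var(colMeans(x))
  if (W == 0 && B_over_n == 0) return(1.0)
  if (W == 0) return(Inf)
  var_plus <- (n - 1) / n * W + B_over_n
  sqrt(var_plus / W)
}

#' Convergence diagnostics on person-item distances
#'
#' Because the position coordinates are only identified up to isometry, the
#' monitored scalars are the person-to-pseudo-item Euclidean distances (for
#' the selected pairs; by default every observed pair), together with the
#' abilities, easiness parameters, the distance weight and the scale
#' hyperparameters. Each scalar's per-chain trace gets a [psrf()] value; the
#' run passes when the maximum is below the threshold. Distances are
#' invariant to any per-draw isometry, so the report does not depend on
#' whether draws were Procrustes-aligned.
#'
#' @param samples An `lsirt_posterior` with >= 2 chains.
#' @param pairs Optional 2-column matrix of (person, pseudo-item) indices;
#'   default all observed pairs.
#' @param threshold PSRF pass threshold (default 1.05).
#' @param max_pairs If the pair set is larger than this, a seeded subsample
#'   of this size is monitored instead (default `Inf`).
#' @param seed Seed for the subsample (only used when subsampling).
#' @return A `convergence_report`: data.frame `psrf_by_quantity`
#'   (quantity, psrf), `threshold`, `max_psrf`, `passed`.
#' @export
convergence_on_distances <- function(samples, pairs = NULL, threshold = 1.05,
                                     max_pairs = Inf, seed = 1) {
  stopifnot(inherits(samples, "lsirt_posterior"))
  if (samples$n_chains < 2L) stop("need at least 2 chains")
  n <- nrow(samples$draws[[1]])
  if (n < 4L) stop("insufficient draws")
  L <- samples$layout

  if (is.null(pairs)) {
    pairs <- which(samples$observed, arr.ind = TRUE)
  }
  if (nrow(pairs) > max_pairs) {
    set.seed(seed)
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
  }

  dist_chains <- lapply(samples$draws, function(d)
    .lsirt_distance_draws(d, L$off_a, L$off_b, L$P, L$J, L$k,
                          as.integer(pairs[, 1] - 1L),
                          as.integer(pairs[, 2] - 1L)))
  psrf_cols <- function(mats) {
    vapply(seq_len(ncol(mats[[1]])), function(j)
      psrf(lapply(mats, function(m) m[, j])), numeric(1))
  }
  r_dist <- psrf_cols(dist_chains)

  scalar_idx <- c(seq_len(L$P), L$off_c + seq_len(L$nc),
                  L$off_lg + 1L, L$off_mu + 1L, L$off_lst + 1L, L$off_lsc + 1L)
  scalar_chains <- lapply(samples$draws, function(d) d[, scalar_idx, drop = FALSE])
  r_scalar <- psrf_cols(scalar_chains)

  tab <- data.frame(
    quantity = c(paste0("d[", pairs[, 1], ",", pairs[, 2], "]"),
                 L$names[scalar_idx]),
    psrf = c(r_dist, r_scalar),
    stringsAsFactors = FALSE)
  max_psrf <- max(tab$psrf)
  structure(list(psrf_by_quantity = tab, threshold = threshold,
                 max_psrf = max_psrf, passed = max_psrf < threshold),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("convergence_report: max PSRF %.4f over %d quantities (threshold %.2f) -> %s\n",
              x$max_psrf, nrow(x$psrf_by_quantity), x$threshold,
              if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

# ---- Procrustes post-processing ----

# orthogonal + translation Procrustes of X (n x k) onto ref (n x k)
procrustes_onto <- function(X, ref_centered, ref_mean) {
  mx <- colMeans(X)
  Xc <- sweep(X, 2, mx)
  s <- svd(crossprod(Xc, ref_centered))
  R <- s$u %*% t(s$v)
  sweep(Xc %*% R, 2, ref_mean, "+")
}

#' Procrustes-align posterior position draws
#'
#' The person-item distances, not the coordinates, are identified: any
#' rotation, reflection or translation of a configuration leaves every
#' distance (and hence the likelihood) unchanged. To make the position draws
#' comparable, the draw with the highest log posterior density (pooled over
#' chains) is taken as the reference configuration, and every other draw's
#' stacked (P + 2I) x k configuration is mapped onto it by the
#' translation-plus-rotation/reflection minimizing squared distance (no
#' scaling, which would change distances). Within-draw distances are
#' preserved exactly; aligning twice is a no-op.
#'
#' @param samples An `lsirt_posterior`.
#' @return The same object with aligned position draws and `aligned = TRUE`.
#' @export
procrustes_align <- function(samples) {
  stopifnot(inherits(samples, "lsirt_posterior"))
  L <- samples$layout

  best <- which.max(vapply(samples$log_post, max, numeric(1)))
  ref_draw <- which.max(samples$log_post[[best]])
  ref <- stacked_config(samples$draws[[best]][ref_draw, ], L)
  ref_mean <- colMeans(ref)
  ref_centered <- sweep(ref, 2, ref_mean)

  a_idx <- L$off_a + seq_len(L$P * L$k)
  b_idx <- L$off_b + seq_len(L$J * L$k)
  for (ch in seq_along(samples$draws)) {
    d <- samples$draws[[ch]]
    for (i in seq_len(nrow(d))) {
      X <- stacked_config(d[i, ], L)
      Y <- procrustes_onto(X, ref_centered, ref_mean)
      d[i, a_idx] <- Y[seq_len(L$P), ]
      d[i, b_idx] <- Y[L$P + seq_len(L$J), ]
    }
    samples$draws[[ch]] <- d
  }
  samples$aligned <- TRUE
  samples$reference <- list(chain = best, draw = ref_draw)
  samples
}

# (P + 2I) x k configuration matrix of one draw (persons stacked over items)
stacked_config <- function(v, layout) {
  rbind(matrix(v[layout$off_a + seq_len(layout$P * layout$k)], layout$P, layout$k),
        matrix(v[layout$off_b + seq_len(layout$J * layout$k)], layout$J, layout$k))
}

# ---- posterior predictive checks ----

#' Posterior predictive check of item proportions and total scores
#'
#' For `n_rep` posterior draws, responses are replicated over the observed
#' cell pattern from the model's correct-response probabilities, and two
#' observable summaries are compared with their predictive distributions:
#' the per-pseudo-item proportion correct and the distribution of
#' respondents' total scores. Only abilities, easiness, the distance weight
#' and distances enter, so the check does not depend on alignment.
#'
#' @param samples An `lsirt_posterior`.
#' @param data The `expanded_dataset` the model was fitted to.
#' @param n_rep Number of predictive replications (> 0).
#' @param seed Seed for draw selection and replication noise.
#' @return A `ppc_report`: per-pseudo-item observed proportion, predictive
#'   mean and 95% interval (`item_table`), the observed and predictive
#'   total-score counts (`score_table`), and the share of items whose
#'   observed proportion falls inside its interval (`item_coverage`).
#' @export
posterior_predictive_check <- function(samples, data, n_rep = 200, seed = 1) {
  stopifnot(inherits(samples, "lsirt_posterior"),
            inherits(data, "expanded_dataset"))
  if (n_rep <= 0) stop("n_rep must be positive")
  set.seed(seed)
  y <- data$responses
  obs <- !is.na(y)
  J <- ncol(y); P <- nrow(y)
  n_item_obs <- colSums(obs)

  pool <- do.call(rbind, samples$draws)
  pick <- sample.int(nrow(pool), min(n_rep, nrow(pool)))
  spec <- samples$spec; L <- samples$layout

  item_prop <- matrix(NA_real_, length(pick), J)
  scores_rep <- matrix(NA_integer_, length(pick), P)
  for (r in seq_along(pick)) {
    pr <- vec_to_params(pool[pick[r], ], L, log_scale = FALSE)
    c_full <- if (spec$constrained) pr$easiness[samples$item_of] else pr$easiness
    D <- distance_matrix(pr$person_pos, pr$item_pos)
    eta <- outer(pr$theta, c_full, "+") - pr$gamma * D
    mu <- plogis(pmin(pmax(eta, -ETA_CLIP), ETA_CLIP))
    yr <- matrix(NA_integer_, P, J)
    yr[obs] <- rbinom(sum(obs), 1, mu[obs])
    item_prop[r, ] <- colSums(yr, na.rm = TRUE) / n_item_obs
    scores_rep[r, ] <- rowSums(yr, na.rm = TRUE)
  }

  item_obs <- colSums(y, na.rm = TRUE) / n_item_obs
  item_table <- data.frame(
    pseudo_item = data$pseudo_item_ids,
    condition = data$condition,
    observed = item_obs,
    predictive_mean = colMeans(item_prop),
    lower = apply(item_prop, 2, quantile, 0.025),
    upper = apply(item_prop, 2, quantile, 0.975),
    stringsAsFactors = FALSE)
  item_table$inside <- item_table$observed >= item_table$lower &
    item_table$observed <= item_table$upper

  obs_scores <- rowSums(y, na.rm = TRUE)
  smax <- max(obs_scores, scores_rep)
  svals <- 0:smax
  count_of <- function(s) tabulate(factor(s, levels = svals), nbins = length(svals))
  rep_counts <- t(apply(scores_rep, 1, count_of))
  score_table <- data.frame(
    score = svals,
    observed = count_of(obs_scores),
    predictive_mean = colMeans(rep_counts),
    lower = apply(rep_counts, 2, quantile, 0.025),
    upper = apply(rep_counts, 2, quantile, 0.975))

  structure(list(item_table = item_table, score_table = score_table,
                 item_coverage = mean(item_table$inside), n_rep = length(pick)),
            class = "ppc_report")
}

#' @export
print.ppc_report <- function(x, ...) {
  cat(sprintf("ppc_report: %d replications | %.0f%% of pseudo-item proportions inside 95%% predictive intervals\n",
              x$n_rep, 100 * x$item_coverage))
  invisible(x)
}
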