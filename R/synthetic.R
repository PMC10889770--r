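#' Configuration for the synthetic-data generator
#'
#' The generator emulates exactly the statistical structure the analysis
#' assumes: log response times from the cross-classified model
#' \eqn{\ln RT = \beta_0 + u_p + u_i + e}, a slow/fast label from the sign of
#' the residual \eqn{e}, and a Bernoulli response from the latent space Rasch
#' logit \eqn{\theta_p + c_{i,cond} - \gamma\, d(a_p, b_{i,cond})} with
#' condition-specific easiness and item positions. Dependence between
#' responses and response times is planted only through those
#' condition-specific quantities — the same mechanisms the fitted models can
#' express — so recovery is attributable.
#'
#' Defaults are the desk-scale recovery preset (P = 300, I = 30, k = 2,
#' gamma = 1.2, full design). Response-time parameters default to a grand
#' mean of 3.5 log-seconds (about 33 s) with person, item and residual
#' standard deviations of 0.4, 0.5 and 0.5 — magnitudes typical of timed
#' cognitive-test items. By default (`slow_fast_displacement = NULL`) each
#' item's slow and fast positions are drawn independently from the
#' standard-normal position distribution — exactly the fitted model's
#' prior, which is what makes recovery studies calibrated. A numeric
#' displacement instead *plants* the slow position at that distance from
#' the fast one (0 = identical positions, the degenerate null case;
#' difficulty-linked displacements produce the canonical slow/fast
#' signatures). Note that planted constructions make the truth atypical
#' under the model's independent-position priors, so credible-interval
#' coverage guarantees do not apply to them.
#'
#' @param P,I Numbers of persons and items (>= 2 each).
#' @param k Latent-space dimension.
#' @param gamma True distance weight (>= 0).
#' @param sigma_theta,mu_c,sigma_c Ability SD and easiness mean/SD.
#' @param rt_beta0 Grand mean of log response time.
#' @param rt_var_person,rt_var_item,rt_var_resid Variance components of the
#'   log-RT model (all > 0).
#' @param slow_fast_displacement `NULL` (default) for independent slow/fast
#'   positions, or the magnitude of the planted displacement of each item's
#'   slow position relative to its fast position (0 = identical positions).
#' @param difficulty_linked If `TRUE`, displacement magnitudes scale with
#'   item difficulty rank (hardest items displaced most, mean magnitude kept
#'   at `slow_fast_displacement`).
#' @param condition_easiness_shift Per-item (recycled) difference
#'   `c_slow - c_fast`; 0 for none.
#' @param person_clusters Optional list of length-k numeric centers; persons
#'   are assigned to clusters uniformly and positions drawn N(center, 0.25).
#' @param n_forms If given, a block design: persons are assigned round-robin
#'   to `n_forms` forms of `items_per_form` items each (forms are seeded
#'   random subsets), and only form items are observed.
#' @param items_per_form Items per form (required with `n_forms`).
#' @param seed Master seed; all sub-streams derive from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(P = 300, I = 30, k = 2, gamma = 1.2,
                             sigma_theta = 1, mu_c = 0, sigma_c = 1,
                             rt_beta0 = 3.5, rt_var_person = 0.16,
                             rt_var_item = 0.25, rt_var_resid = 0.25,
                             slow_fast_displacement = NULL,
                             difficulty_linked = FALSE,
                             condition_easiness_shift = 0,
                             person_clusters = NULL,
                             n_forms = NULL, items_per_form = NULL,
                             seed = 1) {
  stopifnot(P >= 2, I >= 2, k >= 1, gamma >= 0, sigma_theta > 0, sigma_c > 0,
            rt_var_person > 0, rt_var_item > 0,
            is.null(slow_fast_displacement) || slow_fast_displacement >= 0)
  if (rt_var_resid <= 0) {
    stop("rt_var_resid must be > 0: without residual variation every ",
         "response would fall in a single speed condition")
  }
  if (!is.null(n_forms) && is.null(items_per_form)) {
    stop("items_per_form required with n_forms")
  }
  structure(list(P = as.integer(P), I = as.integer(I), k = as.integer(k),
                 gamma = gamma, sigma_theta = sigma_theta, mu_c = mu_c,
                 sigma_c = sigma_c, rt_beta0 = rt_beta0,
                 rt_var_person = rt_var_person, rt_var_item = rt_var_item,
                 rt_var_resid = rt_var_resid,
                 slow_fast_displacement = slow_fast_displacement,
                 difficulty_linked = difficulty_linked,
                 condition_easiness_shift = condition_easiness_shift,
                 person_clusters = person_clusters,
                 n_forms = n_forms, items_per_form = items_per_form,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# zero-padded ids keep the lexicographic load order equal to generation order
pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

#' Generate a synthetic response/response-time dataset with known truth
#'
#' See [synthetic_config()] for the generative model. The returned truth
#' records every generated parameter, the response-time effects and
#' residuals, and the true slow/fast label of every observed cell (slow iff
#' the true residual is >= 0, exactly).
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `data` (a `response_dataset`) and `truth` (a
#'   `synthetic_truth` list: `theta`, `c_slow`, `c_fast`, `person_pos`,
#'   `item_pos_slow`, `item_pos_fast`, `gamma`, `u_person`, `u_item`,
#'   `residuals`, `labels` (P x I character matrix), `prob` (true success
#'   probability per observed cell), and the config).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  P <- cfg$P; I <- cfg$I; k <- cfg$k
  person_ids <- pad_ids("p", P)
  item_ids <- pad_ids("i", I)

  theta <- rnorm(P, 0, cfg$sigma_theta)
  c_base <- rnorm(I, cfg$mu_c, cfg$sigma_c)
  shift <- rep_len(cfg$condition_easiness_shift, I)
  c_slow <- c_base + shift / 2
  c_fast <- c_base - shift / 2

  if (is.null(cfg$person_clusters)) {
    person_pos <- matrix(rnorm(P * k), P, k)
  } else {
    centers <- do.call(rbind, cfg$person_clusters)
    assign <- sample.int(nrow(centers), P, replace = TRUE)
    person_pos <- centers[assign, , drop = FALSE] + matrix(rnorm(P * k, 0, 0.5), P, k)
  }
  item_pos_fast <- matrix(rnorm(I * k), I, k)
  if (is.null(cfg$slow_fast_displacement)) {
    # prior-matched: condition positions independent standard normal
    item_pos_slow <- matrix(rnorm(I * k), I, k)
  } else {
    disp_mag <- if (cfg$difficulty_linked) {
      # hardest items (lowest easiness) displaced most; mean magnitude kept
      cfg$slow_fast_displacement * 2 *
        (I + 1 - rank(c_base, ties.method = "first")) / (I + 1)
    } else {
      rep(cfg$slow_fast_displacement, I)
    }
    dir <- matrix(rnorm(I * k), I, k)
    dir <- dir / sqrt(rowSums(dir^2))
    item_pos_slow <- item_pos_fast + disp_mag * dir
  }

  u_person <- rnorm(P, 0, sqrt(cfg$rt_var_person))
  u_item <- rnorm(I, 0, sqrt(cfg$rt_var_item))
  e <- matrix(rnorm(P * I, 0, sqrt(cfg$rt_var_resid)), P, I)
  log_rt <- cfg$rt_beta0 + outer(u_person, u_item, "+") + e
  labels <- ifelse(e >= 0, "slow", "fast")

  D_slow <- distance_matrix(person_pos, item_pos_slow)
  D_fast <- distance_matrix(person_pos, item_pos_fast)
  eta <- ifelse(labels == "slow",
                outer(theta, c_slow, "+") - cfg$gamma * D_slow,
                outer(theta, c_fast, "+") - cfg$gamma * D_fast)
  prob <- plogis(pmin(pmax(eta, -ETA_CLIP), ETA_CLIP))
  y <- matrix(rbinom(P * I, 1, prob), P, I)

  observed <- matrix(TRUE, P, I)
  if (!is.null(cfg$n_forms)) {
    if (cfg$n_forms * cfg$items_per_form < I) {
      stop("forms do not cover all items: n_forms * items_per_form < I")
    }
    # cyclic blocks of a random item permutation, so every item is on a form
    perm <- sample.int(I)
    forms <- lapply(seq_len(cfg$n_forms), function(f) {
      idx <- ((f - 1L) * cfg$items_per_form + seq_len(cfg$items_per_form) - 1L) %% I + 1L
      sort(perm[idx])
    })
    assign_f <- rep_len(seq_len(cfg$n_forms), P)
    observed[] <- FALSE
    for (p in seq_len(P)) observed[p, forms[[assign_f[p]]]] <- TRUE
  }
  y[!observed] <- NA_integer_
  rt <- exp(log_rt)
  rt[!observed] <- NA_real_
  labels[!observed] <- NA_character_
  e[!observed] <- NA_real_
  dimnames(y) <- dimnames(rt) <- dimnames(labels) <-
    list(person_ids, item_ids)

  data <- new_response_dataset(person_ids, item_ids,
                               matrix(as.integer(y), P, I,
                                      dimnames = dimnames(y)), rt)
  truth <- structure(
    list(theta = theta, c_slow = c_slow, c_fast = c_fast,
         person_pos = person_pos, item_pos_slow = item_pos_slow,
         item_pos_fast = item_pos_fast, gamma = cfg$gamma,
         u_person = u_person, u_item = u_item, residuals = e,
         labels = labels, prob = prob, config = cfg),
    class = "synthetic_truth")
  list(data = data, truth = truth)
}

#' True speed labels of a synthetic dataset
#'
#' Formats the generator's true labels as a `speed_labels` object, usable by
#' [build_expanded()] to bypass the estimated classification.
#'
#' @param truth A `synthetic_truth`.
#' @return A `speed_labels` data.frame.
#' @export
true_speed_labels <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  obs <- which(!is.na(truth$labels), arr.ind = TRUE)
  obs <- obs[order(obs[, 1], obs[, 2]), , drop = FALSE]
  out <- data.frame(
    person_id = rownames(truth$labels)[obs[, 1]],
    item_id = colnames(truth$labels)[obs[, 2]],
    residual = truth$residuals[obs],
    label = truth$labels[obs],
    stringsAsFactors = FALSE)
  class(out) <- c("speed_labels", "data.frame")
  out
}

# true P x 2I distance matrix in expanded (slow columns first) order
true_distance_matrix <- function(truth) {
  cbind(distance_matrix(truth$person_pos, truth$item_pos_slow),
        distance_matrix(truth$person_pos, truth$item_pos_fast))
}

#' Parameter-recovery report for a synthetic fit
#'
#' Compares a posterior fitted to a generated dataset against the
#' generator's truth: the distance-weight posterior mean and 95% credible
#' interval (with a coverage indicator), the easiness RMSE, and the Pearson
#' correlation between the true and posterior-mean person-to-pseudo-item
#' distance matrices.
#'
#' @param truth A `synthetic_truth`.
#' @param samples An `lsirt_posterior` fitted to the generated dataset (or a
#'   `synthetic_truth`, in which case the truth is compared with itself and
#'   the report is exact: zero RMSE, correlation 1).
#' @return A `recovery_report` list.
#' @export
recovery_report <- function(truth, samples) {
  stopifnot(inherits(truth, "synthetic_truth"))
  I <- truth$config$I
  c_true_uncon <- c(truth$c_slow, truth$c_fast)
  D_true <- true_distance_matrix(truth)

  if (inherits(samples, "synthetic_truth")) {
    if (!identical(dim(samples$residuals), dim(truth$residuals))) {
      stop("dimension mismatch between truth objects")
    }
    return(structure(list(
      gamma_true = truth$gamma, gamma_mean = samples$gamma,
      gamma_ci = c(samples$gamma, samples$gamma),
      gamma_covered = TRUE,
      easiness_rmse = 0, distance_correlation = 1,
      theta_correlation = 1), class = "recovery_report"))
  }

  stopifnot(inherits(samples, "lsirt_posterior"))
  if (length(samples$item_ids) != I || samples$layout$P != truth$config$P) {
    stop("dimension mismatch between truth and samples")
  }
  map <- interaction_map(samples)
  c_hat <- map$easiness_hat
  c_true <- if (samples$spec$constrained) (truth$c_slow + truth$c_fast) / 2
            else c_true_uncon
  easiness_rmse <- sqrt(mean((c_hat - c_true)^2))

  # posterior-mean distances: mean of per-draw distances over all pairs
  L <- samples$layout
  all_pairs <- cbind(rep(seq_len(L$P), L$J), rep(seq_len(L$J), each = L$P))
  D_hat <- Reduce(`+`, lapply(samples$draws, function(d)
    colMeans(.lsirt_distance_draws(d, L$off_a, L$off_b, L$P, L$J, L$k,
                                   as.integer(all_pairs[, 1] - 1L),
                                   as.integer(all_pairs[, 2] - 1L))))) /
    length(samples$draws)
  dist_cor <- cor(as.vector(D_true), D_hat)

  structure(list(
    gamma_true = truth$gamma, gamma_mean = map$gamma_hat,
    gamma_ci = map$gamma_ci,
    gamma_covered = truth$gamma >= map$gamma_ci[1] &&
      truth$gamma <= map$gamma_ci[2],
    easiness_rmse = easiness_rmse,
    distance_correlation = dist_cor,
    theta_correlation = cor(truth$theta, map$theta_hat)),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report: gamma %.3f (true %.3f), 95%% CI [%.3f, %.3f] %s\n",
              x$gamma_mean, x$gamma_true, x$gamma_ci[1], x$gamma_ci[2],
              if (x$gamma_covered) "covers truth" else "misses truth"))
  cat(sprintf("  easiness RMSE %.3f | distance correlation %.3f | theta correlation %.3f\n",
              x$easiness_rmse, x$distance_correlation, x$theta_correlation))
  invisible(x)
}

#' Write a synthetic truth to a JSON file
#'
#' @param truth A `synthetic_truth`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth[c("theta", "c_slow", "c_fast", "gamma", "u_person", "u_item")]
  out$person_pos <- unclass(truth$person_pos)
  out$item_pos_slow <- unclass(truth$item_pos_slow)
  out$item_pos_fast <- unclass(truth$item_pos_fast)
  out$config <- unclass(truth$config)
  out$config$person_clusters <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
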