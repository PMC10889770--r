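#' Prior configuration for the latent space Rasch model
#'
#' Defaults follow the analysis's reference prior set: abilities
#' \eqn{\theta_p \sim N(0, \sigma^2)} with \eqn{\sigma \sim}
#' half-Cauchy(0, 5); easiness \eqn{c_i \sim N(\mu_c, \sigma_c^2)} with
#' \eqn{\mu_c \sim N(0, 5^2)} and \eqn{\sigma_c \sim} half-Cauchy(0, 5); the
#' distance weight \eqn{\gamma \sim N(0, 3^2)} truncated to \eqn{\gamma \ge 0}
#' (a half-normal with scale 3); and each person/item position row
#' \eqn{\sim MVN(0, I_k)}.
#'
#' @param theta_sd_scale Half-Cauchy scale for \eqn{\sigma}.
#' @param easiness_mean_sd SD of the normal prior on \eqn{\mu_c}.
#' @param easiness_sd_scale Half-Cauchy scale for \eqn{\sigma_c}.
#' @param gamma_sd Scale of the half-normal prior on \eqn{\gamma}.
#' @return A `lsirt_priors` list.
#' @export
lsirt_priors <- function(theta_sd_scale = 5, easiness_mean_sd = 5,
                         easiness_sd_scale = 5, gamma_sd = 3) {
  stopifnot(theta_sd_scale > 0, easiness_mean_sd > 0,
            easiness_sd_scale > 0, gamma_sd > 0)
  structure(list(theta_sd_scale = theta_sd_scale,
                 easiness_mean_sd = easiness_mean_sd,
                 easiness_sd_scale = easiness_sd_scale,
                 gamma_sd = gamma_sd),
            class = "lsirt_priors")
}

#' Model specification for the latent space Rasch model
#'
#' @param k Latent-space dimension (default 2, the interpretable map).
#' @param constrained If `TRUE` (default), item easiness is tied across the
#'   slow and fast pseudo-items of an item (length-I easiness vector); if
#'   `FALSE` each pseudo-item has its own easiness (length 2I).
#' @param priors A [lsirt_priors()] configuration.
#' @return A `lsirt_spec` list.
#' @export
lsirt_spec <- function(k = 2, constrained = TRUE, priors = lsirt_priors()) {
  stopifnot(k >= 1, is.logical(constrained), inherits(priors, "lsirt_priors"))
  structure(list(k = as.integer(k), constrained = constrained, priors = priors),
            class = "lsirt_spec")
}

#' Euclidean distance between two latent positions
#'
#' @param a,b Numeric vectors of equal length.
#' @return The Euclidean distance \eqn{\sqrt{\sum_j (a_j - b_j)^2}}.
#' @export
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop("dimension mismatch")
  sqrt(sum((a - b)^2))
}

# linear predictors are clipped here before the inverse logit; avoids
# log(0) in the likelihood without affecting results at realistic scales
ETA_CLIP <- 35

#' Correct-response probability under the latent space Rasch model
#'
#' \deqn{logit(P(Y_{pi} = 1)) = \theta_p + c_i - \gamma\, d(a_p, b_i)}
#' so the probability is non-increasing in the person-item distance.
#'
#' @param theta Person ability.
#' @param c Item easiness.
#' @param gamma Distance weight, \eqn{\gamma \ge 0}.
#' @param a,b Person and item position vectors (equal length).
#' @return Probability in (0, 1).
#' @export
#' @examples
#' response_probability(0, 0, 1, c(0, 0), c(0, 0)) # 0.5
response_probability <- function(theta, c, gamma, a, b) {
  if (gamma < 0) stop("gamma must be >= 0")
  eta <- theta + c - gamma * euclidean_distance(a, b)
  plogis(pmin(pmax(eta, -ETA_CLIP), ETA_CLIP))
}

#' Bundle latent space Rasch parameters
#'
#' @param theta Length-P ability vector.
#' @param easiness Length-I (constrained) or length-2I (unconstrained)
#'   easiness vector.
#' @param gamma Distance weight (scalar, >= 0).
#' @param person_pos P x k matrix of person positions.
#' @param item_pos 2I x k matrix of pseudo-item positions.
#' @param sigma_theta,mu_c,sigma_c Hyperparameters (scales > 0).
#' @return An `lsirt_params` list.
#' @export
lsirt_params <- function(theta, easiness, gamma, person_pos, item_pos,
                         sigma_theta = 1, mu_c = 0, sigma_c = 1) {
  person_pos <- as.matrix(person_pos)
  item_pos <- as.matrix(item_pos)
  stopifnot(length(theta) == nrow(person_pos),
            ncol(person_pos) == ncol(item_pos),
            length(gamma) == 1L)
  structure(list(theta = theta, easiness = easiness, gamma = gamma,
                 person_pos = person_pos, item_pos = item_pos,
                 sigma_theta = sigma_theta, mu_c = mu_c, sigma_c = sigma_c),
            class = "lsirt_params")
}

# expand a length-I easiness vector to the 2I pseudo-items when constrained
expand_easiness <- function(params, data, spec) {
  J <- length(data$item_of)
  if (spec$constrained) {
    if (length(params$easiness) != J / 2L) {
      stop("constrained spec needs one easiness per original item")
    }
    params$easiness[data$item_of]
  } else {
    if (length(params$easiness) != J) {
      stop("unconstrained spec needs one easiness per pseudo-item")
    }
    params$easiness
  }
}

# P x J matrix of person-to-pseudo-item Euclidean distances
distance_matrix <- function(person_pos, item_pos) {
  an <- rowSums(person_pos^2)
  bn <- rowSums(item_pos^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(person_pos, item_pos)
  sqrt(pmax(d2, 0))
}

#' Log likelihood of the latent space Rasch model on expanded data
#'
#' Sum of Bernoulli log probabilities over the observed cells of the expanded
#' slow/fast matrix; missing cells (structural, by design) contribute
#' nothing. With `gamma = 0` this reduces to the ordinary Rasch likelihood.
#'
#' @param params An [lsirt_params()] object.
#' @param data An `expanded_dataset`.
#' @param spec An [lsirt_spec()].
#' @return The log likelihood (scalar).
#' @export
log_likelihood <- function(params, data, spec) {
  stopifnot(inherits(data, "expanded_dataset"), inherits(spec, "lsirt_spec"))
  c_full <- expand_easiness(params, data, spec)
  D <- distance_matrix(params$person_pos, params$item_pos)
  eta <- outer(params$theta, c_full, "+") - params$gamma * D
  eta <- pmin(pmax(eta, -ETA_CLIP), ETA_CLIP)
  y <- data$responses
  obs <- !is.na(y)
  # log P(y=1) = plogis(eta, log=TRUE); log P(y=0) = plogis(-eta, log=TRUE)
  s <- ifelse(y[obs] == 1L, 1, -1)
  sum(plogis(s * eta[obs], log.p = TRUE))
}

log_half_cauchy <- function(x, scale) {
  ifelse(x <= 0, -Inf, log(2) + dcauchy(x, 0, scale, log = TRUE))
}

#' Log prior density of the latent space Rasch parameters
#'
#' Includes the hyperpriors; returns `-Inf` when `gamma < 0` or a scale
#' hyperparameter is non-positive.
#'
#' @inheritParams log_likelihood
#' @return The log prior density (scalar).
#' @export
log_prior <- function(params, spec) {
  stopifnot(inherits(spec, "lsirt_spec"))
  pr <- spec$priors
  if (params$gamma < 0 || params$sigma_theta <= 0 || params$sigma_c <= 0) {
    return(-Inf)
  }
  sum(dnorm(params$theta, 0, params$sigma_theta, log = TRUE)) +
    sum(dnorm(params$easiness, params$mu_c, params$sigma_c, log = TRUE)) +
    log(2) + dnorm(params$gamma, 0, pr$gamma_sd, log = TRUE) +
    sum(dnorm(params$person_pos, 0, 1, log = TRUE)) +
    sum(dnorm(params$item_pos, 0, 1, log = TRUE)) +
    dnorm(params$mu_c, 0, pr$easiness_mean_sd, log = TRUE) +
    log_half_cauchy(params$sigma_theta, pr$theta_sd_scale) +
    log_half_cauchy(params$sigma_c, pr$easiness_sd_scale)
}

#' Log posterior (unnormalized) of the latent space Rasch model
#'
#' `log_likelihood + log_prior`. Invariant under any common rotation or
#' reflection of all person and item positions (distances and the isotropic
#' position prior are preserved); translations preserve the likelihood but
#' shift the position prior, which is why posterior draws are aligned after
#' sampling rather than constrained during it.
#'
#' @inheritParams log_likelihood
#' @return The unnormalized log posterior density (scalar).
#' @export
log_posterior <- function(params, data, spec) {
  lp <- log_prior(params, spec)
  if (!is.finite(lp)) return(lp)
  lp + log_likelihood(params, data, spec)
}
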