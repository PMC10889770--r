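#' Fit the cross-classified random-effects model for log response times
#'
#' Models natural-log response times as a grand mean plus crossed person and
#' item random intercepts,
#' \deqn{\ln RT_{pi} = \beta_0 + u_p + u_i + e_{pi},}
#' with \eqn{u_p \sim N(0, \sigma^2_{u1})}, \eqn{u_i \sim N(0, \sigma^2_{u2})}
#' and residual \eqn{e_{pi} \sim N(0, \sigma^2_e)}. Variance components are
#' estimated by REML, random effects are the corresponding BLUPs, and the
#' residual for each observed cell is the conditional residual
#' \eqn{e_{pi} = \ln RT_{pi} - \beta_0 - u_p - u_i} ("double-centered" log
#' response time). The residual's sign is what later separates slow from fast
#' responses.
#'
#' Degenerate data in which all log response times are equal are handled
#' without an optimizer call: all variance components are 0 and all residuals
#' are exactly 0 (with a warning).
#'
#' @param ds A `response_dataset` with at least 2 persons, 2 items, and one
#'   observation per person and item.
#' @return A `crossclassified_fit`: list with `beta0`, `var_person`,
#'   `var_item`, `var_resid`, `u_person`, `u_item`, `residuals` (P x I matrix,
#'   NA at unobserved cells), and `person_ids`/`item_ids`.
#' @export
fit_crossclassified <- function(ds) {
  stopifnot(inherits(ds, "response_dataset"))
  if (length(ds$person_ids) < 2L || length(ds$item_ids) < 2L) {
    stop("need at least 2 persons and 2 items")
  }
  long <- as_long_table(ds)
  y <- log(long$rt)

  P <- length(ds$person_ids)
  I <- length(ds$item_ids)
  resid_mat <- matrix(NA_real_, P, I,
                      dimnames = list(ds$person_ids, ds$item_ids))
  pidx <- match(long$person_id, ds$person_ids)
  iidx <- match(long$item_id, ds$item_ids)

  if (isTRUE(all.equal(var(y), 0)) || var(y) == 0) {
    warning("constant log response times: all variance components are 0")
    resid_mat[cbind(pidx, iidx)] <- 0
    return(new_crossclassified_fit(
      beta0 = mean(y), var_person = 0, var_item = 0, var_resid = 0,
      u_person = setNames(numeric(P), ds$person_ids),
      u_item = setNames(numeric(I), ds$item_ids),
      residuals = resid_mat))
  }

  dat <- data.frame(
    y = y,
    person = factor(long$person_id, levels = ds$person_ids),
    item = factor(long$item_id, levels = ds$item_ids))
  fit <- suppressMessages(lme4::lmer(
    y ~ 1 + (1 | person) + (1 | item), data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_person <- vc$vcov[vc$grp == "person"]
  var_item <- vc$vcov[vc$grp == "item"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  if (var_person <= 1e-10 || var_item <= 1e-10) {
    warning("a variance component estimate is at the zero boundary")
  }

  beta0 <- unname(lme4::fixef(fit)[["(Intercept)"]])
  re <- lme4::ranef(fit)
  u_person <- setNames(numeric(P), ds$person_ids)
  u_item <- setNames(numeric(I), ds$item_ids)
  u_person[rownames(re$person)] <- re$person[["(Intercept)"]]
  u_item[rownames(re$item)] <- re$item[["(Intercept)"]]

  e <- y - beta0 - u_person[pidx] - u_item[iidx]
  resid_mat[cbind(pidx, iidx)] <- e

  new_crossclassified_fit(beta0, var_person, var_item, var_resid,
                          u_person, u_item, resid_mat)
}

new_crossclassified_fit <- function(beta0, var_person, var_item, var_resid,
                                    u_person, u_item, residuals) {
  stopifnot(var_person >= 0, var_item >= 0, var_resid >= 0)
  structure(
    list(beta0 = beta0, var_person = var_person, var_item = var_item,
         var_resid = var_resid, u_person = u_person, u_item = u_item,
         residuals = residuals,
         person_ids = rownames(residuals), item_ids = colnames(residuals)),
    class = "crossclassified_fit")
}

#' @export
print.crossclassified_fit <- function(x, ...) {
  cat("cross-classified log-RT model (REML)\n",
      sprintf("  beta0 = %.4f | var(person) = %.4f | var(item) = %.4f | var(resid) = %.4f\n",
              x$beta0, x$var_person, x$var_item, x$var_resid))
  invisible(x)
}

#' Classify responses as slow or fast from residual log response times
#'
#' A response is slow when its residual log response time is at or above the
#' threshold (default 0, i.e. slower than expected given the person's speed
#' and the item's time intensity: \eqn{e_{pi} \ge 0}), and fast when below.
#' The threshold is configurable only for sensitivity analyses (e.g. a
#' median split); the default sign rule is the analysis contract.
#'
#' @param fit A `crossclassified_fit` from [fit_crossclassified()].
#' @param threshold Residual cut point; default 0.
#' @return A `speed_labels` data.frame with columns `person_id`, `item_id`,
#'   `residual`, `label` (`"slow"`/`"fast"`), one row per observed cell.
#' @export
classify_speed <- function(fit, threshold = 0) {
  stopifnot(inherits(fit, "crossclassified_fit"))
  obs <- which(!is.na(fit$residuals), arr.ind = TRUE)
  obs <- obs[order(obs[, 1], obs[, 2]), , drop = FALSE]
  residual <- fit$residuals[obs]
  out <- data.frame(
    person_id = fit$person_ids[obs[, 1]],
    item_id = fit$item_ids[obs[, 2]],
    residual = residual,
    label = ifelse(residual >= threshold, "slow", "fast"),
    stringsAsFactors = FALSE)
  class(out) <- c("speed_labels", "data.frame")
  out
}

#' Write speed labels as a long CSV
#'
#' @param labels A `speed_labels` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_speed_labels <- function(labels, path) {
  write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify a dataset's responses in one step
#'
#' Convenience wrapper: fits the cross-classified log-RT model and applies the
#' residual sign rule.
#'
#' @inheritParams fit_crossclassified
#' @inheritParams classify_speed
#' @return A list with `fit` (`crossclassified_fit`) and `labels`
#'   (`speed_labels`).
#' @export
classify_responses <- function(ds, threshold = 0) {
  fit <- fit_crossclassified(ds)
  list(fit = fit, labels = classify_speed(fit, threshold = threshold))
}
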