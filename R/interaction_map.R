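# aligned posterior means of positions and scalar parameters, plus the
# distance summaries used for reporting

#' Build an interaction map from aligned posterior samples
#'
#' Point estimates are per-coordinate means of the Procrustes-aligned draws
#' (the samples are aligned first if they were not already); abilities,
#' easiness and the distance weight are posterior means, the distance weight
#' with a 95% credible interval. The map is the reporting surface for all
#' distance summaries: how far each pseudo-item sits from the respondents,
#' how far apart an item's slow and fast positions are, and how those relate
#' to item difficulty.
#'
#' @param samples An `lsirt_posterior`.
#' @param ci_level Credible-interval level for the distance weight
#'   (default 0.95).
#' @return An `interaction_map`: `person_pos_hat` (P x k), `item_pos_hat`
#'   (2I x k), `theta_hat`, `easiness_hat`, `gamma_hat`, `gamma_ci`,
#'   `condition`, `item_of`, ids, and `k`.
#' @export
interaction_map <- function(samples, ci_level = 0.95) {
  stopifnot(inherits(samples, "lsirt_posterior"))
  if (!samples$aligned) samples <- procrustes_align(samples)
  L <- samples$layout
  pool <- do.call(rbind, samples$draws)
  m <- colMeans(pool)

  person_pos <- matrix(m[L$off_a + seq_len(L$P * L$k)], L$P, L$k)
  item_pos <- matrix(m[L$off_b + seq_len(L$J * L$k)], L$J, L$k)
  rownames(person_pos) <- samples$person_ids
  rownames(item_pos) <- samples$pseudo_item_ids
  alpha <- (1 - ci_level) / 2
  structure(
    list(person_pos_hat = person_pos, item_pos_hat = item_pos,
         theta_hat = setNames(m[seq_len(L$P)], samples$person_ids),
         easiness_hat = m[L$off_c + seq_len(L$nc)],
         gamma_hat = m[L$off_lg + 1L],
         gamma_ci = unname(quantile(pool[, "gamma"], c(alpha, 1 - alpha))),
         condition = samples$condition, item_of = samples$item_of,
         person_ids = samples$person_ids, item_ids = samples$item_ids,
         pseudo_item_ids = samples$pseudo_item_ids,
         k = L$k, constrained = samples$spec$constrained),
    class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf("interaction_map: %d persons, %d pseudo-items (k = %d, %s easiness)\n",
              nrow(x$person_pos_hat), nrow(x$item_pos_hat), x$k,
              if (x$constrained) "constrained" else "unconstrained"))
  cat(sprintf("  gamma_hat = %.3f [%.3f, %.3f]\n",
              x$gamma_hat, x$gamma_ci[1], x$gamma_ci[2]))
  invisible(x)
}

#' Mean item-respondent distance for a pseudo-item
#'
#' \eqn{\bar d_i = \sum_{p=1}^{P} d(a_p, b_i) / P}: the average Euclidean
#' distance from the respondents to the pseudo-item's position. By default
#' the average runs over all P respondents (the definition used in the
#' summaries); `persons = "answered"` restricts it to respondents with an
#' observed response to that pseudo-item, which can be more interpretable
#' under block designs.
#'
#' @param map An `interaction_map`.
#' @param pseudo_item Pseudo-item index (1..2I).
#' @param persons `"all"` (default) or `"answered"`.
#' @param observed P x 2I logical mask; required for `persons = "answered"`.
#' @return The mean distance (scalar).
#' @export
mean_item_distance <- function(map, pseudo_item, persons = c("all", "answered"),
                               observed = NULL) {
  stopifnot(inherits(map, "interaction_map"),
            pseudo_item >= 1, pseudo_item <= nrow(map$item_pos_hat))
  persons <- match.arg(persons)
  b <- map$item_pos_hat[pseudo_item, ]
  d <- sqrt(colSums((t(map$person_pos_hat) - b)^2))
  if (persons == "answered") {
    if (is.null(observed)) stop("`observed` mask required for persons = \"answered\"")
    d <- d[observed[, pseudo_item]]
    if (!length(d)) return(NA_real_)
  }
  mean(d)
}

#' Distance between an item's slow and fast positions
#'
#' @param map An `interaction_map`.
#' @param item Original item index (1..I).
#' @return The Euclidean distance between the slow and fast pseudo-item
#'   positions of the item.
#' @export
slow_fast_separation <- function(map, item) {
  stopifnot(inherits(map, "interaction_map"))
  I <- length(map$item_ids)
  stopifnot(item >= 1, item <= I)
  euclidean_distance(map$item_pos_hat[item, ], map$item_pos_hat[I + item, ])
}

#' Group respondents by estimated ability
#'
#' Low below -0.5, high above 0.5, medium in between (boundaries inclusive
#' in the medium group).
#'
#' @param theta_hat Numeric vector of ability estimates.
#' @return A factor with levels `low`, `medium`, `high`.
#' @export
ability_grouping <- function(theta_hat) {
  out <- ifelse(theta_hat < -0.5, "low", ifelse(theta_hat > 0.5, "high", "medium"))
  factor(out, levels = c("low", "medium", "high"))
}

#' Relative easiness vs distance-difference table
#'
#' For each original item, pairs the difference in easiness across its slow
#' and fast pseudo-items under the unconstrained model
#' (\eqn{c_i - c_{I+i}}, "relative easiness") with the difference in its mean
#' item-respondent distance under the constrained model
#' (\eqn{\bar d_i - \bar d_{I+i}}). When the constrained-model map shows
#' slow responses sitting disproportionately farther from respondents, the
#' unconstrained model absorbs that into a lower slow easiness, so the two
#' columns are expected to correlate negatively.
#'
#' @param constrained_map An `interaction_map` from the constrained fit.
#' @param unconstrained_map An `interaction_map` (or `lsirt_posterior`) from
#'   the unconstrained fit on the same data.
#' @return A data.frame (one row per item: `item`, `relative_easiness`,
#'   `distance_diff`) with the Pearson correlation of the two columns in
#'   attribute `"correlation"`.
#' @export
easiness_distance_table <- function(constrained_map, unconstrained_map) {
  stopifnot(inherits(constrained_map, "interaction_map"),
            constrained_map$constrained)
  if (inherits(unconstrained_map, "lsirt_posterior")) {
    unconstrained_map <- interaction_map(unconstrained_map)
  }
  stopifnot(inherits(unconstrained_map, "interaction_map"),
            !unconstrained_map$constrained)
  I <- length(constrained_map$item_ids)
  stopifnot(length(unconstrained_map$easiness_hat) == 2L * I)

  c_hat <- unconstrained_map$easiness_hat
  rel_easiness <- c_hat[seq_len(I)] - c_hat[I + seq_len(I)]
  dbar <- vapply(seq_len(2L * I), mean_item_distance, numeric(1),
                 map = constrained_map)
  dist_diff <- dbar[seq_len(I)] - dbar[I + seq_len(I)]

  out <- data.frame(item = constrained_map$item_ids,
                    relative_easiness = rel_easiness,
                    distance_diff = dist_diff,
                    stringsAsFactors = FALSE)
  attr(out, "correlation") <-
    if (sd(rel_easiness) == 0 || sd(dist_diff) == 0) NA_real_
    else cor(rel_easiness, dist_diff)
  out
}

#' Correlation between slow-fast separation and item difficulty
#'
#' Pearson correlation between each item's slow-fast position separation and
#' its overall observed proportion correct (pooled over the two speed
#' conditions). Sign convention: proportion correct orients items from hard
#' to easy, so a *negative* value here means more difficult items have
#' larger slow-fast separations (the association reported as negative with
#' respect to difficulty ordering).
#'
#' @param map An `interaction_map` (typically from the unconstrained fit).
#' @param ds The source `response_dataset`.
#' @return The correlation, or `NA` with a warning when a column is constant.
#' @export
difficulty_separation_correlation <- function(map, ds) {
  stopifnot(inherits(map, "interaction_map"), inherits(ds, "response_dataset"))
  I <- length(map$item_ids)
  stopifnot(length(ds$item_ids) == I)
  sep <- vapply(seq_len(I), slow_fast_separation, numeric(1), map = map)
  prop <- colSums(ds$responses == 1L, na.rm = TRUE) / colSums(ds$observed)
  if (sd(sep) < 1e-10 * max(1, mean(sep)) || sd(prop) < 1e-12) {
    warning("constant separations or proportions: correlation undefined")
    return(NA_real_)
  }
  cor(sep, unname(prop))
}

#' Respondent groups nearest an item's slow and fast positions
#'
#' Among respondents with an observed response to the item, selects the
#' `n_group` nearest the slow position and the `n_group` nearest the fast
#' position (ties broken by person ordering; the two sets may overlap), and
#' reports each group's proportion correct among its slow-labeled and
#' fast-labeled responses to that item. Respondents very close to the slow
#' position are expected to do disproportionately better when answering
#' slower, and vice versa, when the conditional dependence is heterogeneous.
#'
#' @param map An `interaction_map`.
#' @param expanded The `expanded_dataset` the model was fitted to.
#' @param item Original item index.
#' @param n_group Group size (default 30). When fewer respondents are
#'   eligible, all are used with a warning.
#' @return A list with `near_slow`/`near_fast` (person ids) and `accuracy`
#'   (2 x 2 matrix: group x response condition; `NaN` where a group has no
#'   responses under a condition).
#' @export
nearest_respondent_groups <- function(map, expanded, item, n_group = 30) {
  stopifnot(inherits(map, "interaction_map"),
            inherits(expanded, "expanded_dataset"))
  I <- length(map$item_ids)
  stopifnot(item >= 1, item <= I, n_group >= 1)

  y_slow <- expanded$responses[, item]
  y_fast <- expanded$responses[, I + item]
  eligible <- which(!is.na(y_slow) | !is.na(y_fast))
  if (!length(eligible)) stop("no respondent answered this item")
  if (length(eligible) < n_group) {
    warning("only ", length(eligible), " eligible respondents; using all")
    n_group <- length(eligible)
  }

  nearest <- function(b) {
    d <- sqrt(colSums((t(map$person_pos_hat[eligible, , drop = FALSE]) - b)^2))
    eligible[order(d, seq_along(d))[seq_len(n_group)]]
  }
  near_slow <- nearest(map$item_pos_hat[item, ])
  near_fast <- nearest(map$item_pos_hat[I + item, ])

  acc <- function(group) {
    c(slow = mean(y_slow[group], na.rm = TRUE),
      fast = mean(y_fast[group], na.rm = TRUE))
  }
  accuracy <- rbind(near_slow = acc(near_slow), near_fast = acc(near_fast))
  list(near_slow = map$person_ids[near_slow],
       near_fast = map$person_ids[near_fast],
       accuracy = accuracy)
}

#' Per-item summary table of the interaction map
#'
#' One row per original item: mean item-respondent distances under the slow
#' and fast conditions, the slow-fast separation, the per-condition and
#' pooled observed proportions correct.
#'
#' @param map An `interaction_map`.
#' @param expanded The `expanded_dataset` the model was fitted to.
#' @return A data.frame with columns `item`, `dbar_slow`, `dbar_fast`,
#'   `separation`, `prop_slow`, `prop_fast`, `prop_overall`.
#' @export
item_summary_table <- function(map, expanded) {
  stopifnot(inherits(map, "interaction_map"),
            inherits(expanded, "expanded_dataset"))
  I <- length(map$item_ids)
  dbar <- vapply(seq_len(2L * I), mean_item_distance, numeric(1), map = map)
  y <- expanded$responses
  prop <- colSums(y == 1L, na.rm = TRUE) / colSums(!is.na(y))
  n_obs <- colSums(!is.na(y))
  pooled <- (colSums(y[, seq_len(I), drop = FALSE] == 1L, na.rm = TRUE) +
             colSums(y[, I + seq_len(I), drop = FALSE] == 1L, na.rm = TRUE)) /
            (n_obs[seq_len(I)] + n_obs[I + seq_len(I)])
  data.frame(item = map$item_ids,
             dbar_slow = dbar[seq_len(I)], dbar_fast = dbar[I + seq_len(I)],
             separation = vapply(seq_len(I), slow_fast_separation, numeric(1),
                                 map = map),
             prop_slow = unname(prop[seq_len(I)]),
             prop_fast = unname(prop[I + seq_len(I)]),
             prop_overall = unname(pooled),
             stringsAsFactors = FALSE)
}

#' Write map coordinates to CSV
#'
#' Rows for persons then pseudo-items with columns
#' `entity,type,condition,dim1,...`.
#'
#' @param map An `interaction_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_map_coords <- function(map, path) {
  k <- map$k
  coords <- rbind(map$person_pos_hat, map$item_pos_hat)
  df <- data.frame(
    entity = c(map$person_ids, map$pseudo_item_ids),
    type = rep(c("person", "item"),
               c(nrow(map$person_pos_hat), nrow(map$item_pos_hat))),
    condition = c(rep(NA_character_, nrow(map$person_pos_hat)), map$condition),
    stringsAsFactors = FALSE)
  for (t in seq_len(k)) df[[paste0("dim", t)]] <- coords[, t]
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# ---- figures (untested rendering; the tables above are the tested surface) ----

#' Plot an interaction map
#'
#' Two-panel display (slow / fast condition) of person and item positions,
#' persons colored by ability group, items by overall proportion correct.
#' Requires ggplot2.
#'
#' @param map An `interaction_map`.
#' @param expanded Optional `expanded_dataset` for item coloring.
#' @return A ggplot object.
#' @export
plot_interaction_map <- function(map, expanded = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) stop("ggplot2 not available")
  I <- length(map$item_ids)
  persons <- data.frame(x = map$person_pos_hat[, 1], y = map$person_pos_hat[, 2],
                        ability = ability_grouping(map$theta_hat))
  items <- data.frame(x = map$item_pos_hat[, 1], y = map$item_pos_hat[, 2],
                      condition = factor(map$condition, c("slow", "fast")),
                      label = rep(seq_len(I), 2))
  if (!is.null(expanded)) {
    st <- item_summary_table(map, expanded)
    items$prop_correct <- st$prop_overall[items$label]
  }
  g <- ggplot2::ggplot() +
    ggplot2::geom_point(data = persons,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$ability),
                        size = 0.8, alpha = 0.6) +
    ggplot2::facet_wrap(~condition)
  if (!is.null(expanded)) {
    g <- g + ggplot2::geom_text(
      data = items,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label,
                   alpha = .data$prop_correct), color = "black")
  } else {
    g <- g + ggplot2::geom_text(
      data = items, ggplot2::aes(x = .data$x, y = .data$y, label = .data$label))
  }
  g + ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}

#' Boxplots of mean item-respondent distances by speed condition
#'
#' @param map An `interaction_map`.
#' @return A ggplot object.
#' @export
plot_distance_boxplots <- function(map) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) stop("ggplot2 not available")
  I <- length(map$item_ids)
  dbar <- vapply(seq_len(2L * I), mean_item_distance, numeric(1), map = map)
  df <- data.frame(condition = factor(map$condition, c("slow", "fast")),
                   dbar = dbar)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$dbar)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = "mean item-respondent distance") +
    ggplot2::theme_minimal()
}

#' Scatter plot of relative easiness against distance difference
#'
#' @param tab The table from [easiness_distance_table()].
#' @return A ggplot object.
#' @export
plot_easiness_distance <- function(tab) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) stop("ggplot2 not available")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$distance_diff,
                                    y = .data$relative_easiness)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", se = FALSE, formula = y ~ x) +
    ggplot2::labs(x = "mean-distance difference (slow - fast)",
                  y = "relative easiness (slow - fast)") +
    ggplot2::theme_minimal()
}

#' Bar chart of group accuracies from nearest-respondent contrasts
#'
#' @param groups Output of [nearest_respondent_groups()].
#' @return A ggplot object.
#' @export
plot_group_accuracy <- function(groups) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) stop("ggplot2 not available")
  acc <- groups$accuracy
  df <- data.frame(group = rep(rownames(acc), 2),
                   condition = rep(colnames(acc), each = 2),
                   accuracy = as.vector(acc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$accuracy,
                                   fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::theme_minimal()
}
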