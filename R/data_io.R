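#' Assemble a response dataset from long-format records
#'
#' Builds the internal wide representation (binary response matrix, response
#' time matrix, observation mask) from long-format rows of
#' (person, item, response, response time). Persons and items are ordered
#' lexicographically on their identifiers so matrix indices are reproducible
#' across runs; pairs absent from the input become structurally missing cells
#' (block-design missingness).
#'
#' @param rows A data.frame with columns `person_id`, `item_id`, `response`
#'   (0/1) and `rt` (response time in seconds, > 0).
#' @return An object of class `response_dataset`: a list with `person_ids`,
#'   `item_ids`, `responses` (P x I integer matrix with NA for unobserved),
#'   `rt_seconds` (P x I numeric matrix), and `observed` (P x I logical mask).
#' @export
#' @examples
#' rows <- data.frame(person_id = c("p1", "p1"), item_id = c("i1", "i2"),
#'                    response = c(1, 0), rt = c(10, 20))
#' ds <- load_long_table(rows)
#' ds$responses
load_long_table <- function(rows) {
  required <- c("person_id", "item_id", "response", "rt")
  if (!is.data.frame(rows)) {
    stop("`rows` must be a data.frame with columns ",
         paste(required, collapse = ", "))
  }
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(rows) == 0L) stop("no records")

  person <- as.character(rows$person_id)
  item <- as.character(rows$item_id)
  resp <- rows$response
  rt <- as.numeric(rows$rt)

  bad <- !(resp %in% c(0, 1))
  if (any(bad)) {
    stop("non-binary response for (", person[which(bad)[1]], ", ",
         item[which(bad)[1]], ")")
  }
  bad_rt <- !is.finite(rt) | rt <= 0
  if (any(bad_rt)) {
    stop("non-positive response time for (", person[which(bad_rt)[1]], ", ",
         item[which(bad_rt)[1]], ")")
  }
  key <- paste(person, item, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    parts <- strsplit(dup, "\r", fixed = TRUE)[[1]]
    stop("duplicate record for (", parts[1], ", ", parts[2], ")")
  }

  person_ids <- sort(unique(person))
  item_ids <- sort(unique(item))
  P <- length(person_ids)
  I <- length(item_ids)
  pi_ <- match(person, person_ids)
  ii <- match(item, item_ids)

  responses <- matrix(NA_integer_, P, I, dimnames = list(person_ids, item_ids))
  rt_seconds <- matrix(NA_real_, P, I, dimnames = list(person_ids, item_ids))
  idx <- cbind(pi_, ii)
  responses[idx] <- as.integer(resp)
  rt_seconds[idx] <- rt

  new_response_dataset(person_ids, item_ids, responses, rt_seconds)
}

new_response_dataset <- function(person_ids, item_ids, responses, rt_seconds) {
  observed <- !is.na(responses)
  ds <- structure(
    list(person_ids = person_ids, item_ids = item_ids,
         responses = responses, rt_seconds = rt_seconds, observed = observed),
    class = "response_dataset")
  validate_response_dataset(ds)
}

validate_response_dataset <- function(ds) {
  stopifnot(identical(dim(ds$responses), dim(ds$rt_seconds)),
            identical(is.na(ds$responses), is.na(ds$rt_seconds)),
            identical(ds$observed, !is.na(ds$responses)))
  if (any(ds$rt_seconds[ds$observed] <= 0)) stop("observed response times must be > 0")
  if (any(rowSums(ds$observed) == 0L)) stop("every person needs >= 1 observed response")
  if (any(colSums(ds$observed) == 0L)) stop("every item needs >= 1 observed response")
  ds
}

#' @export
print.response_dataset <- function(x, ...) {
  cat("response_dataset:", length(x$person_ids), "persons x",
      length(x$item_ids), "items;", sum(x$observed), "observed responses (",
      sprintf("%.1f%%", 100 * mean(x$observed)), "of cells)\n")
  invisible(x)
}

#' Read a long-format response table from CSV
#'
#' @param path Path to a CSV file with header `person_id,item_id,response,rt`.
#' @return A [load_long_table()] `response_dataset`.
#' @export
read_response_csv <- function(path) {
  load_long_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a response dataset as a long-format CSV
#'
#' @param ds A `response_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_response_csv <- function(ds, path) {
  write.csv(as_long_table(ds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a response dataset back to long format
#'
#' @param ds A `response_dataset`.
#' @return A data.frame with columns `person_id,item_id,response,rt`, one row
#'   per observed cell, ordered by person then item.
#' @export
as_long_table <- function(ds) {
  idx <- which(t(ds$observed))  # row-major so persons vary slowest
  I <- length(ds$item_ids)
  p <- (idx - 1L) %/% I + 1L
  i <- (idx - 1L) %% I + 1L
  data.frame(person_id = ds$person_ids[p], item_id = ds$item_ids[i],
             response = ds$responses[cbind(p, i)],
             rt = ds$rt_seconds[cbind(p, i)],
             stringsAsFactors = FALSE)
}

#' Apply response-time validity filters
#'
#' Removes (as in the source studies' data cleaning) individual responses
#' slower than an upper limit, and whole persons whose every observed response
#' was faster than a lower limit (a marker of inattentive responding). Both
#' filters are opt-in via their thresholds; persons or items left without any
#' observation are dropped and recorded.
#'
#' Responses exactly at `rt_limit` are kept: only strictly longer times are
#' removed.
#'
#' @param ds A `response_dataset`.
#' @param rt_limit Upper limit in seconds; cells with `rt > rt_limit` become
#'   missing. `Inf` disables. Default 180 (a per-item time limit common to the
#'   motivating tests).
#' @param min_rt_all_items Persons with all observed `rt < min_rt_all_items`
#'   (seconds) are removed. 0 disables. Default 5.
#' @return A list of class `filtered_responses` with elements `data` (the
#'   filtered `response_dataset`) and `report` (counts of cells and persons
#'   removed, plus ids of persons/items dropped for losing all observations).
#' @export
filter_responses <- function(ds, rt_limit = 180, min_rt_all_items = 5) {
  stopifnot(inherits(ds, "response_dataset"), rt_limit > 0, min_rt_all_items >= 0)

  responses <- ds$responses
  rt <- ds$rt_seconds
  over <- ds$observed & !is.na(rt) & rt > rt_limit
  cells_removed <- sum(over)
  responses[over] <- NA_integer_
  rt[over] <- NA_real_
  observed <- !is.na(responses)

  # inattentive persons: every remaining observed rt strictly below threshold
  fast_all <- vapply(seq_len(nrow(rt)), function(p) {
    obs <- observed[p, ]
    any(obs) && all(rt[p, obs] < min_rt_all_items)
  }, logical(1))
  persons_removed <- ds$person_ids[fast_all & min_rt_all_items > 0]

  keep_p <- !(ds$person_ids %in% persons_removed)
  responses <- responses[keep_p, , drop = FALSE]
  rt <- rt[keep_p, , drop = FALSE]
  observed <- observed[keep_p, , drop = FALSE]
  person_ids <- ds$person_ids[keep_p]

  empty_p <- rowSums(observed) == 0L
  empty_i <- colSums(observed) == 0L
  persons_dropped_empty <- person_ids[empty_p]
  items_dropped_empty <- ds$item_ids[empty_i]

  responses <- responses[!empty_p, !empty_i, drop = FALSE]
  rt <- rt[!empty_p, !empty_i, drop = FALSE]
  person_ids <- person_ids[!empty_p]
  item_ids <- ds$item_ids[!empty_i]

  if (length(person_ids) == 0L || length(item_ids) == 0L) {
    stop("filtering removed all data")
  }

  out <- new_response_dataset(person_ids, item_ids, responses, rt)
  report <- list(cells_removed = cells_removed,
                 persons_removed = persons_removed,
                 persons_dropped_empty = persons_dropped_empty,
                 items_dropped_empty = items_dropped_empty,
                 rt_limit = rt_limit, min_rt_all_items = min_rt_all_items)
  structure(list(data = out, report = report), class = "filtered_responses")
}

#' @export
print.filtered_responses <- function(x, ...) {
  r <- x$report
  cat("filter_responses: removed", r$cells_removed, "cells (rt >", r$rt_limit,
      "s),", length(r$persons_removed), "inattentive persons (all rt <",
      r$min_rt_all_items, "s)\n")
  if (length(r$persons_dropped_empty))
    cat("  persons dropped (no observations left):",
        paste(r$persons_dropped_empty, collapse = ", "), "\n")
  if (length(r$items_dropped_empty))
    cat("  items dropped (no observations left):",
        paste(r$items_dropped_empty, collapse = ", "), "\n")
  print(x$data)
  invisible(x)
}

#' Build the expanded slow/fast response matrix
#'
#' Treats slow and fast responses to the same item as responses to different
#' pseudo-items: a P x 2I matrix in which a slow response to item i sits in
#' column i and a fast response in column I+i, the sibling column being
#' missing. Each observed cell of the source data therefore appears in exactly
#' one of its two pseudo-item columns, and every person has exactly half of
#' the potentially observable expanded entries structurally missing.
#'
#' @param ds A `response_dataset`.
#' @param labels A `speed_labels` object from [classify_speed()] covering
#'   exactly the observed cells of `ds`.
#' @return An `expanded_dataset`: list with `responses` (P x 2I), `condition`
#'   (per pseudo-item, `"slow"`/`"fast"`), `item_of` (pseudo-item -> original
#'   item index), `person_ids`, `item_ids`, `pseudo_item_ids`
#'   (`<item>_slow` / `<item>_fast`), and `source_observed`.
#' @export
build_expanded <- function(ds, labels) {
  stopifnot(inherits(ds, "response_dataset"), inherits(labels, "speed_labels"))
  P <- length(ds$person_ids)
  I <- length(ds$item_ids)

  lp <- match(labels$person_id, ds$person_ids)
  li <- match(labels$item_id, ds$item_ids)
  if (anyNA(lp) || anyNA(li)) {
    stop("labels refer to persons/items absent from the dataset")
  }
  obs_key <- which(ds$observed)
  lab_key <- sort((li - 1L) * P + lp)
  if (!identical(sort(obs_key), lab_key)) {
    extra <- setdiff((li - 1L) * P + lp, obs_key)
    if (length(extra)) stop("label supplied for an unobserved cell")
    stop("labels must cover every observed cell exactly once")
  }

  responses <- matrix(NA_integer_, P, 2L * I)
  is_slow <- labels$label == "slow"
  col <- ifelse(is_slow, li, I + li)
  responses[cbind(lp, col)] <- ds$responses[cbind(lp, li)]

  pseudo_item_ids <- c(paste0(ds$item_ids, "_slow"), paste0(ds$item_ids, "_fast"))
  dimnames(responses) <- list(ds$person_ids, pseudo_item_ids)
  structure(
    list(responses = responses,
         condition = rep(c("slow", "fast"), each = I),
         item_of = rep(seq_len(I), 2L),
         person_ids = ds$person_ids, item_ids = ds$item_ids,
         pseudo_item_ids = pseudo_item_ids,
         source_observed = ds$observed),
    class = "expanded_dataset")
}

#' @export
print.expanded_dataset <- function(x, ...) {
  I <- length(x$item_ids)
  obs <- !is.na(x$responses)
  cat("expanded_dataset:", length(x$person_ids), "persons x", 2L * I,
      "pseudo-items (", I, "items );", sum(obs[, seq_len(I)]), "slow /",
      sum(obs[, I + seq_len(I)]), "fast responses\n")
  invisible(x)
}

#' Collapse an expanded dataset over its slow/fast column pairs
#'
#' Inverse of [build_expanded()] at the response level: merges the slow and
#' fast pseudo-item columns of each item back into one column.
#'
#' @param expanded An `expanded_dataset`.
#' @return A P x I integer matrix with NA for cells unobserved in the source.
#' @export
collapse_expanded <- function(expanded) {
  stopifnot(inherits(expanded, "expanded_dataset"))
  I <- length(expanded$item_ids)
  slow <- expanded$responses[, seq_len(I), drop = FALSE]
  fast <- expanded$responses[, I + seq_len(I), drop = FALSE]
  both <- !is.na(slow) & !is.na(fast)
  if (any(both)) stop("cell observed in both slow and fast columns")
  out <- slow
  out[is.na(out)] <- fast[is.na(out)]
  dimnames(out) <- list(expanded$person_ids, expanded$item_ids)
  out
}

#' Write an expanded dataset to CSV
#'
#' One row per person, one column per pseudo-item (`<item>_slow`,
#' `<item>_fast`), empty cells for missing entries.
#'
#' @param expanded An `expanded_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expanded_csv <- function(expanded, path) {
  df <- data.frame(person_id = expanded$person_ids,
                   expanded$responses, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
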