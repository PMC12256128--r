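# The central statistic: aggregate per-run mispredictions across pipeline
# runs into per-specimen Reoccurring Prediction Values (RPV), the
# high-confidence flag list, and the interval report.

#' Aggregate prediction records into per-specimen RPVs
#'
#' For every specimen that ever appeared in a test pool, counts across
#' runs how often the classifier assigned a label different from the
#' current catalog label. The RPV is the count of the modal mispredicted
#' label (ties break to the lexicographically smallest label and are
#' marked inconsistent); a specimen whose mispredictions all name the same
#' label is `consistent`. Specimens never mispredicted get an RPV of 0 and
#' no modal label. Eligible runs - runs in which the specimen was in the
#' test pool - are counted from the partitions, and `rpv_rate =
#' rpv / eligible_runs` is exported alongside the raw count because
#' eligibility varies per specimen.
#'
#' @param prediction_records data frame of per-run inference outcomes with
#'   columns `run_id`, `specimen_id`, `current_label`, `predicted_label`
#'   (and optionally `confidence`, `match`).
#' @param partitions list of [make_partition()] objects covering every
#'   `run_id` present in the records.
#' @return data frame with one row per tested specimen: `specimen_id`,
#'   `current_label`, `modal_predicted_label` (`NA` when never
#'   mispredicted), `rpv`, `mismatch_runs`, `eligible_runs`, `consistent`,
#'   `rpv_rate`, sorted by `specimen_id`.
#' @export
compute_rpv <- function(prediction_records, partitions) {
  run_ids <- vapply(partitions, `[[`, integer(1), "run_id")
  names(partitions) <- as.character(run_ids)
  unknown <- setdiff(unique(prediction_records$run_id), run_ids)
  if (length(unknown) > 0) {
    stop_integrity_error(sprintf("no partition for run_id(s): %s",
                                 paste(unknown, collapse = ", ")))
  }
  test_keys <- unlist(lapply(partitions, function(p) {
    paste(p$run_id, partition_test_ids(p))
  }), use.names = FALSE)
  rec_keys <- paste(prediction_records$run_id,
                    prediction_records$specimen_id)
  bad <- !(rec_keys %in% test_keys)
  if (any(bad)) {
    ex <- prediction_records[which(bad)[1], ]
    stop_integrity_error(sprintf(
      "specimen %s has a prediction in run %s but was not in that run's test set",
      ex$specimen_id, ex$run_id))
  }

  specimens <- sort(unique(prediction_records$specimen_id))
  eligible <- table(unlist(lapply(partitions, partition_test_ids),
                           use.names = FALSE))
  current <- prediction_records$current_label[
    match(specimens, prediction_records$specimen_id)]

  mism <- prediction_records[
    prediction_records$predicted_label != prediction_records$current_label, ,
    drop = FALSE]
  by_spec <- split(mism$predicted_label, mism$specimen_id)

  out <- data.frame(
    specimen_id = specimens,
    current_label = current,
    modal_predicted_label = NA_character_,
    rpv = 0L,
    mismatch_runs = 0L,
    eligible_runs = as.integer(eligible[specimens]),
    consistent = TRUE,
    stringsAsFactors = FALSE
  )
  hit <- match(names(by_spec), specimens)
  for (j in seq_along(by_spec)) {
    tab <- table(by_spec[[j]])
    i <- hit[j]
    top <- max(tab)
    out$modal_predicted_label[i] <- min(names(tab)[tab == top])
    out$rpv[i] <- as.integer(top)
    out$mismatch_runs[i] <- as.integer(sum(tab))
    out$consistent[i] <- length(tab) == 1
  }
  out$rpv_rate <- out$rpv / out$eligible_runs
  out[order(out$specimen_id), , drop = FALSE]
}

#' Flag specimens above an RPV threshold
#'
#' Selects specimens with RPV strictly greater than `threshold` (the
#' high-confidence review list), sorted by RPV descending with ties broken
#' by specimen id, a stable deterministic ordering. Raising the threshold
#' never grows the flagged set.
#'
#' @param rpv_records data frame from [compute_rpv()].
#' @param threshold non-negative RPV threshold; strict inequality.
#' @return the flagged subset of `rpv_records`, reordered.
#' @export
flag_rpv <- function(rpv_records, threshold) {
  if (threshold < 0) stop_invalid_argument("threshold must be >= 0")
  out <- rpv_records[rpv_records$rpv > threshold, , drop = FALSE]
  out[order(-out$rpv, out$specimen_id), , drop = FALSE]
}

#' RPV interval table from pre-tabulated counts
#'
#' Builds the interval report directly from per-interval counts and an
#' explicit denominator; [interval_table()] tabulates the counts from RPV
#' records and delegates here. Interval labels are zero-padded
#' (`"01-10"` ... `"91-100"` with an en dash) and percentages are rounded
#' half-up to two decimals.
#'
#' @param counts integer vector of flagged-specimen counts, one per
#'   interval in ascending order (`[1, w]` first).
#' @param interval_width interval width; must divide `n_runs`.
#' @param n_runs total number of pipeline runs.
#' @param denominator percentage denominator (normally the total number of
#'   flagged specimens).
#' @return data frame with `interval`, `lo`, `hi`, `count`, `percentage`,
#'   ordered from the highest interval down.
#' @export
interval_table_from_counts <- function(counts, interval_width, n_runs,
                                       denominator) {
  if (n_runs %% interval_width != 0) {
    stop_invalid_argument("interval_width must divide n_runs")
  }
  n_bins <- n_runs / interval_width
  if (length(counts) != n_bins) {
    stop_invalid_argument(sprintf("expected %d interval counts, got %d",
                                  n_bins, length(counts)))
  }
  lo <- seq(1, n_runs, by = interval_width)
  hi <- lo + interval_width - 1
  out <- data.frame(
    interval = sprintf("%02d–%d", lo, hi),
    lo = lo, hi = hi, count = as.integer(counts),
    percentage = round_half_up(100 * counts / denominator, 2),
    stringsAsFactors = FALSE
  )
  out[order(-out$lo), , drop = FALSE]
}

#' RPV interval table
#'
#' Histogram of flagged specimens (RPV of at least 1) in intervals of
#' `interval_width`, with each interval's share of the flagged total as a
#' percentage. The percentage denominator is the number of flagged
#' specimens, unless `total_flagged_override` supplies an external total.
#'
#' @param rpv_records data frame from [compute_rpv()].
#' @param interval_width interval width; must divide `n_runs`.
#' @param n_runs total number of pipeline runs.
#' @param total_flagged_override optional externally supplied percentage
#'   denominator.
#' @return see [interval_table_from_counts()]; zero rows (with a warning)
#'   when nothing is flagged and no override is given.
#' @export
interval_table <- function(rpv_records, interval_width = 10, n_runs = 100,
                           total_flagged_override = NULL) {
  if (n_runs %% interval_width != 0) {
    stop_invalid_argument("interval_width must divide n_runs")
  }
  flagged <- rpv_records$rpv[rpv_records$rpv >= 1]
  denom <- total_flagged_override %||% length(flagged)
  if (length(flagged) == 0 && is.null(total_flagged_override)) {
    warning("no flagged specimens; returning an empty interval table")
    return(interval_table_from_counts(integer(n_runs / interval_width),
                                      interval_width, n_runs,
                                      denominator = 1)[0, ])
  }
  bins <- pmin((flagged - 1) %/% interval_width + 1, n_runs / interval_width)
  counts <- tabulate(bins, nbins = n_runs / interval_width)
  interval_table_from_counts(counts, interval_width, n_runs, denom)
}

#' Render an interval table as aligned text
#'
#' @param tab data frame from [interval_table()].
#' @return character vector of report lines.
#' @export
format_interval_table <- function(tab) {
  c(sprintf("%-8s %10s %12s", "RPV", "specimens", "% of total"),
    sprintf("%-8s %10d %12.2f", tab$interval, tab$count, tab$percentage))
}
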