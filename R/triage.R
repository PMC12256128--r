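# Expert-verification record keeping and summary statistics: verdict
# tallies, difficulty-by-RPV histograms, genetic-reconciliation counts and
# the flagged-fraction headline figure. These functions only ever report
# sums over their input records; no study total is hard-coded.

#' Closed vocabulary of expert verdicts
#'
#' `labelled_wrong`: the specimen is incorrectly labelled in the physical
#' collection. `pipeline_wrong`: the classifier misidentified a correctly
#' labelled specimen. `portal_wrong`: the collection label is correct but
#' the digital portal record is wrong or missing. `unknown`: the experts
#' could not verify the specimen.
#'
#' @format character vector.
#' @export
verification_verdicts <- c("labelled_wrong", "pipeline_wrong",
                           "portal_wrong", "unknown")

#' Closed vocabulary of visual-difficulty scores
#'
#' 1 = easy to verify by eye; 2 = difficult but possible; 3 = required
#' additional context (locality, date, relative size); 4 = impossible to
#' verify visually, referred for genetic confirmation.
#'
#' @format integer vector.
#' @export
difficulty_levels <- 1:4

#' Closed vocabulary of genetic-reconciliation outcomes
#'
#' `confirms_pipeline_wrong`: sequencing confirmed the experts' view that
#' the pipeline misidentified the specimen. `contradicts_both`: sequencing
#' contradicted both the pipeline's prediction and the experts'
#' assessment.
#'
#' @format character vector.
#' @export
genetic_outcomes <- c("confirms_pipeline_wrong", "contradicts_both")

validate_verification <- function(records) {
  bad <- which(!(records$verdict %in% verification_verdicts))
  if (length(bad) > 0) {
    stop_schema_error(sprintf(
      "unknown verdict '%s' in row %d (specimen %s)",
      records$verdict[bad[1]], bad[1], records$specimen_id[bad[1]]))
  }
  badd <- which(!(records$difficulty %in% difficulty_levels))
  if (length(badd) > 0) {
    stop_schema_error(sprintf(
      "difficulty must be one of 1-4; row %d has '%s'",
      badd[1], records$difficulty[badd[1]]))
  }
  invisible(records)
}

#' Tally expert verdicts by taxon group
#'
#' @param records data frame of verification records with columns
#'   `specimen_id`, `group`, `verdict` (see [verification_verdicts]) and
#'   `difficulty`.
#' @return list with `counts` (contingency table group x verdict, all
#'   verdict levels always present), `by_verdict` (column totals) and
#'   `total`.
#' @export
verification_summary <- function(records) {
  if (nrow(records) > 0) validate_verification(records)
  counts <- table(
    factor(records$group, levels = sort(unique(records$group))),
    factor(records$verdict, levels = verification_verdicts)
  )
  list(counts = counts,
       by_verdict = colSums(counts),
       total = nrow(records))
}

#' Histogram of visual difficulty by RPV interval
#'
#' @param records verification records that additionally carry an `rpv`
#'   column (copied from the RPV output).
#' @param interval_width RPV interval width; must divide `n_runs`.
#' @param n_runs total number of pipeline runs.
#' @return integer matrix with one row per difficulty level (1-4) and one
#'   column per RPV interval; every record is counted exactly once.
#' @export
difficulty_rpv_histogram <- function(records, interval_width = 10,
                                     n_runs = 100) {
  if (n_runs %% interval_width != 0) {
    stop_invalid_argument("interval_width must divide n_runs")
  }
  if (nrow(records) > 0) validate_verification(records)
  lo <- seq(1, n_runs, by = interval_width)
  labels <- sprintf("%02d–%d", lo, lo + interval_width - 1)
  bins <- pmin((records$rpv - 1) %/% interval_width + 1,
               n_runs / interval_width)
  m <- table(factor(records$difficulty, levels = difficulty_levels),
             factor(labels[bins], levels = labels))
  matrix(as.integer(m), nrow = 4, dimnames = dimnames(m))
}

#' Tally genetic-reconciliation outcomes by taxon group
#'
#' @param genetic_records data frame with columns `specimen_id`, `group`,
#'   `outcome` (see [genetic_outcomes]) and optionally
#'   `barcode_recovered`.
#' @return list with `counts` (group x outcome table), `by_group` (row
#'   totals) and `total`.
#' @export
genetic_reconciliation <- function(genetic_records) {
  bad <- which(!(genetic_records$outcome %in% genetic_outcomes))
  if (length(bad) > 0) {
    stop_schema_error(sprintf("unknown genetic outcome '%s' in row %d",
                              genetic_records$outcome[bad[1]], bad[1]))
  }
  counts <- table(
    factor(genetic_records$group, levels = sort(unique(genetic_records$group))),
    factor(genetic_records$outcome, levels = genetic_outcomes)
  )
  list(counts = counts, by_group = rowSums(counts),
       total = nrow(genetic_records))
}

#' Percentage of the collection flagged at least once
#'
#' @param n_flagged number of specimens flagged at least once.
#' @param n_total total number of specimens audited; must be positive.
#' @return percentage rounded half-up to two decimals.
#' @export
flagged_fraction <- function(n_flagged, n_total) {
  if (n_total <= 0) stop_invalid_argument("n_total must be positive")
  if (n_flagged < 0 || n_flagged > n_total) {
    stop_invalid_argument("n_flagged must be between 0 and n_total")
  }
  round_half_up(100 * n_flagged / n_total, 2)
}

#' Build a triage template for expert review
#'
#' All flagged specimens sorted by RPV descending (mirroring review
#' prioritisation of the most consistently flagged specimens), with empty
#' verdict, difficulty and notes columns for the experts to fill in.
#'
#' @param rpv_records data frame from [compute_rpv()].
#' @param group taxon group recorded on each row.
#' @param threshold RPV threshold; strictly greater flags (default 0:
#'   every specimen flagged at least once).
#' @return data frame with columns `specimen_id`, `group`,
#'   `current_label`, `modal_predicted_label`, `rpv`, `eligible_runs`,
#'   `verdict`, `difficulty`, `notes`.
#' @export
triage_template <- function(rpv_records, group = "all", threshold = 0) {
  flagged <- flag_rpv(rpv_records, threshold)
  data.frame(
    specimen_id = flagged$specimen_id,
    group = group,
    current_label = flagged$current_label,
    modal_predicted_label = flagged$modal_predicted_label,
    rpv = flagged$rpv,
    eligible_runs = flagged$eligible_runs,
    verdict = "", difficulty = "", notes = "",
    stringsAsFactors = FALSE
  )
}

#' Read and write verification CSV files
#'
#' The verification CSV has columns
#' `specimen_id,group,verdict,difficulty,rpv,notes`. Reading then writing
#' a file produced by [write_verification_csv()] is byte-stable.
#'
#' @param path CSV path.
#' @return data frame of verification records.
#' @export
read_verification_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(specimen_id = "character",
                                group = "character", verdict = "character",
                                difficulty = "integer", rpv = "integer",
                                notes = "character"))
  validate_verification(df)
}

#' @param records data frame of verification records.
#' @rdname read_verification_csv
#' @export
write_verification_csv <- function(records, path) {
  cols <- c("specimen_id", "group", "verdict", "difficulty", "rpv", "notes")
  write.csv(records[, cols], path, row.names = FALSE, quote = 6)
  invisible(path)
}
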