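# Minimal hand-built partition: one class, explicit test membership per run.
manual_partitions <- function(membership) {
  # membership: list per run of list(test = ids, trainval = ids)
  lapply(seq_along(membership), function(r) {
    tv <- membership[[r]]$trainval %||% character(0)
    structure(list(
      run_id = as.integer(r), sampling_seed = r,
      classes = list(all = list(
        train = tv, val = character(0), test = membership[[r]]$test
      ))
    ), class = "run_partition")
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a specimen mispredicted identically in every run gets the full RPV", {
  n_runs <- 100
  parts <- manual_partitions(lapply(seq_len(n_runs), function(r) {
    list(test = "S1")
  }))
  preds <- data.frame(run_id = seq_len(n_runs), specimen_id = "S1",
                      current_label = "B", predicted_label = "A",
                      stringsAsFactors = FALSE)
  rpv <- compute_rpv(preds, parts)
  expect_equal(rpv$rpv, 100)
  expect_equal(rpv$modal_predicted_label, "A")
  expect_equal(rpv$mismatch_runs, 100)
  expect_equal(rpv$eligible_runs, 100)
  expect_true(rpv$consistent)
  expect_equal(rpv$rpv_rate, 1)
})

test_that("correct predictions give RPV zero and no modal label", {
  parts <- manual_partitions(list(list(test = c("S1", "S2")),
                                  list(test = c("S1", "S2"))))
  preds <- data.frame(
    run_id = c(1, 1, 2, 2), specimen_id = c("S1", "S2", "S1", "S2"),
    current_label = "A", predicted_label = "A", stringsAsFactors = FALSE)
  rpv <- compute_rpv(preds, parts)
  expect_equal(rpv$rpv, c(0, 0))
  expect_true(all(is.na(rpv$modal_predicted_label)))
  expect_true(all(rpv$consistent))
})

test_that("mixed mispredictions count the modal label only", {
  # 100 eligible runs: 60 predict A, 5 predict C, 35 correct
  n_runs <- 100
  parts <- manual_partitions(lapply(seq_len(n_runs),
                                    function(r) list(test = "S9")))
  pred <- c(rep("A", 60), rep("C", 5), rep("B", 35))
  preds <- data.frame(run_id = seq_len(n_runs), specimen_id = "S9",
                      current_label = "B", predicted_label = pred,
                      stringsAsFactors = FALSE)
  rpv <- compute_rpv(preds, parts)
  expect_equal(rpv$rpv, 60)
  expect_equal(rpv$mismatch_runs, 65)
  expect_equal(rpv$modal_predicted_label, "A")
  expect_false(rpv$consistent)
  # ties break to the lexicographically smallest label
  preds2 <- preds
  preds2$predicted_label <- c(rep("C", 30), rep("A", 30), rep("B", 40))
  rpv2 <- compute_rpv(preds2, parts)
  expect_equal(rpv2$rpv, 30)
  expect_equal(rpv2$modal_predicted_label, "A")
  expect_false(rpv2$consistent)
})

test_that("predictions for specimens outside the test pool are rejected", {
  parts <- manual_partitions(list(list(test = "S1", trainval = "S2")))
  preds <- data.frame(run_id = 1, specimen_id = "S2",
                      current_label = "A", predicted_label = "B",
                      stringsAsFactors = FALSE)
  expect_error(compute_rpv(preds, parts), class = "integrity_error")
  preds2 <- data.frame(run_id = 7, specimen_id = "S1",
                       current_label = "A", predicted_label = "B",
                       stringsAsFactors = FALSE)
  expect_error(compute_rpv(preds2, parts), class = "integrity_error")
})

test_that("compute_rpv matches the brute-force recount on random logs", {
  for (seed in 1:12) {
    inst <- random_rpv_instance(n_specimens = 30, n_runs = 12,
                                n_labels = 4, seed = seed)
    got <- compute_rpv(inst$predictions, inst$partitions)
    want <- oracle_rpv(inst$predictions, inst$partitions)
    expect_equal(got$specimen_id, want$specimen_id)
    expect_equal(got$rpv, want$rpv)
    expect_equal(got$mismatch_runs, want$mismatch_runs)
    expect_equal(got$eligible_runs, want$eligible_runs)
    expect_equal(got$modal_predicted_label, want$modal)
    expect_equal(got$consistent, want$consistent)
    # structural invariants
    expect_true(all(got$rpv <= got$mismatch_runs))
    expect_true(all(got$mismatch_runs <= got$eligible_runs))
    expect_true(all(got$rpv[got$consistent] ==
                      got$mismatch_runs[got$consistent]))
    expect_true(all(is.na(got$modal_predicted_label) == (got$rpv == 0)))
  }
})

test_that("eligibility equals runs minus train/validation appearances", {
  inst <- random_rpv_instance(40, 10, 3, seed = 99)
  got <- compute_rpv(inst$predictions, inst$partitions)
  for (s in got$specimen_id) {
    tv <- sum(vapply(inst$partitions, function(p) {
      s %in% c(p$classes$all$train, p$classes$all$val)
    }, logical(1)))
    expect_equal(got$eligible_runs[got$specimen_id == s], 10 - tv)
  }
})

test_that("flagging uses a strict threshold and a stable order", {
  rpv <- data.frame(
    specimen_id = c("S1", "S2", "S3", "S4", "S5"),
    current_label = "A", modal_predicted_label = "B",
    rpv = c(81, 80, 95, 95, 1), mismatch_runs = c(81, 80, 95, 95, 1),
    eligible_runs = 100, consistent = TRUE, rpv_rate = NA,
    stringsAsFactors = FALSE
  )
  fl <- flag_rpv(rpv, 80)
  expect_equal(fl$specimen_id, c("S3", "S4", "S1"))  # 81 in, 80 out
  fl0 <- flag_rpv(rpv, 0)
  expect_equal(nrow(fl0), 5)
  # monotonicity: higher thresholds never grow the flagged set
  sizes <- vapply(c(0, 1, 50, 80, 94, 95), function(t) nrow(flag_rpv(rpv, t)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(flag_rpv(rpv, -1), class = "invalid_argument")
})

test_that("interval tables tile the run range and reproduce percentages", {
  rpv <- data.frame(specimen_id = sprintf("S%02d", 1:6),
                    rpv = c(0, 1, 10, 11, 95, 100))
  tab <- interval_table(rpv, interval_width = 10, n_runs = 100)
  expect_equal(nrow(tab), 10)
  expect_equal(sum(tab$count), 5)  # rpv 0 is not flagged
  expect_equal(tab$lo, seq(91, 1, by = -10))
  expect_equal(tab$hi - tab$lo, rep(9, 10))
  expect_equal(tab$count[tab$lo == 1], 2)     # rpv 1 and 10
  expect_equal(tab$count[tab$lo == 11], 1)
  expect_equal(tab$count[tab$lo == 91], 2)    # 95 and 100
  expect_equal(tab$percentage[tab$lo == 91], 40)
  expect_equal(tab$interval[tab$lo == 1], "01–10")

  # single specimen with the maximum RPV: one row holds 100%
  one <- interval_table(data.frame(specimen_id = "S1", rpv = 100), 10, 100)
  expect_equal(one$count[one$lo == 91], 1)
  expect_equal(one$percentage[one$lo == 91], 100)
  expect_equal(sum(one$count), 1)

  expect_warning(empty <- interval_table(data.frame(specimen_id = "S",
                                                    rpv = 0), 10, 100),
                 "no flagged")
  expect_equal(nrow(empty), 0)
  expect_error(interval_table(rpv, interval_width = 7, n_runs = 100),
               class = "invalid_argument")
})

test_that("an explicit denominator overrides the flagged total", {
  rpv <- data.frame(specimen_id = c("S1", "S2"), rpv = c(5, 95))
  tab <- interval_table(rpv, 10, 100, total_flagged_override = 200)
  expect_equal(tab$percentage[tab$lo == 1], 0.5)
  expect_equal(tab$percentage[tab$lo == 91], 0.5)
})
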