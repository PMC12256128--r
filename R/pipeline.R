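# End-to-end audit pipeline: load catalog -> filter classes -> crop ->
# repeated (sample, augment, train, predict) runs -> RPV aggregation and
# reports. Every source of randomness is derived from the configuration's
# two seed streams, so a pipeline execution is exactly repeatable.

#' Run the full mislabel-audit pipeline
#'
#' For each of `config$n_runs` runs: draw a fresh per-class
#' train/validation sample (seeded with `base_seed + run_id`), augment the
#' training and validation images `aug_copies` times, train the classifier
#' with the two-phase protocol from identical initial weights
#' (`model_init_seed`), and run inference on every remaining (test)
#' specimen, recording whether each prediction matches the current catalog
#' label. Mispredictions are then aggregated into per-specimen RPVs.
#'
#' @param catalog a catalog CSV path or a loaded catalog data frame
#'   ([load_catalog()]).
#' @param config a [pipeline_config()]; [desk_config()] by default.
#' @param backbone a [backbone_spec()].
#' @param detector detector used for cropping, or `NULL` to skip cropping.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param verbose print per-run progress.
#' @return list with `predictions` (all runs' prediction records),
#'   `partitions`, `rpv` ([compute_rpv()] output), `flagged`
#'   (high-confidence list at `config$flag_threshold`), `intervals`
#'   (interval table), `run_f1` (per-run macro-F1), `traces` (per-run
#'   training traces), `config` and `manifest`.
#' @export
run_pipeline <- function(catalog, config = desk_config(),
                         backbone = tiny_backbone(),
                         detector = default_detector, out_dir = NULL,
                         verbose = FALSE) {
  records <- if (is.character(catalog)) load_catalog(catalog) else catalog
  filtered <- filter_classes(records, config$min_class_size)
  records <- filtered$records
  classes <- filtered$classes
  paths <- resolve_image_paths(records)

  # load and crop once; cache at model input resolution
  images <- vector("list", nrow(records))
  names(images) <- records$specimen_id
  for (i in seq_len(nrow(records))) {
    img <- read_image(paths[i])
    if (!is.null(detector)) {
      img <- detect_and_crop(img, detector, config$crop_margin)$image
    }
    images[[i]] <- resize_image(img, backbone$input_size,
                                backbone$input_size)
  }

  partitions <- vector("list", config$n_runs)
  predictions <- vector("list", config$n_runs)
  traces <- vector("list", config$n_runs)
  run_f1 <- numeric(config$n_runs)

  for (run_id in seq_len(config$n_runs)) {
    part <- make_partition(records, classes, run_id, config)
    partitions[[run_id]] <- part

    label_of <- function(ids) {
      records$current_label[match(ids, records$specimen_id)]
    }
    augment_set <- function(ids) {
      imgs <- images[ids]
      labels <- label_of(ids)
      out_imgs <- imgs
      out_labels <- labels
      for (j in seq_along(ids)) {
        copies <- augment(imgs[[j]],
                          rng_state = derive_seed(config$base_seed, run_id,
                                                  match(ids[j],
                                                        records$specimen_id)),
                          n_copies = config$aug_copies)
        out_imgs <- c(out_imgs, copies)
        out_labels <- c(out_labels, rep(labels[j], length(copies)))
      }
      list(images = out_imgs, labels = out_labels)
    }

    train_ids <- unlist(lapply(part$classes, `[[`, "train"),
                        use.names = FALSE)
    val_ids <- unlist(lapply(part$classes, `[[`, "val"), use.names = FALSE)
    test_ids <- partition_test_ids(part)

    tr <- augment_set(train_ids)
    va <- augment_set(val_ids)
    outcome <- train_classifier(tr$images, tr$labels, va$images, va$labels,
                                backbone = backbone, config = config)
    traces[[run_id]] <- outcome$trace

    pred <- predict(outcome$model, images[test_ids])
    run_records <- data.frame(
      run_id = run_id,
      specimen_id = test_ids,
      current_label = label_of(test_ids),
      predicted_label = pred$predicted_label,
      confidence = pred$confidence,
      stringsAsFactors = FALSE
    )
    run_records$match <- run_records$predicted_label ==
      run_records$current_label
    predictions[[run_id]] <- run_records
    run_f1[run_id] <- f1_score(run_records)$macro_f1
    if (verbose) {
      message(sprintf("run %d/%d: macro-F1 %.4f, %d/%d mismatches",
                      run_id, config$n_runs, run_f1[run_id],
                      sum(!run_records$match), nrow(run_records)))
    }
  }

  predictions <- do.call(rbind, predictions)
  rpv <- compute_rpv(predictions, partitions)
  flagged <- flag_rpv(rpv, config$flag_threshold)
  intervals <- withCallingHandlers(
    interval_table(rpv, config$interval_width, config$n_runs),
    warning = function(w) invokeRestart("muffleWarning")
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("rpvaudit")),
    n_runs = config$n_runs,
    base_seed = config$base_seed,
    model_init_seed = config$model_init_seed,
    backbone = backbone$name,
    classes = classes,
    n_specimens = nrow(records),
    config_hash = fnv1a_hash(jsonlite::toJSON(unclass(config),
                                              auto_unbox = TRUE))
  )

  result <- list(predictions = predictions, partitions = partitions,
                 rpv = rpv, flagged = flagged, intervals = intervals,
                 run_f1 = run_f1, traces = traces, config = config,
                 manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write pipeline outputs to a directory
#'
#' Writes `predictions.csv`, `rpv.csv`, `intervals.csv` and
#' `intervals.txt`, `partitions.json` and `manifest.json`. Floating-point
#' columns use fixed six-decimal formatting so repeated executions with
#' identical seeds produce byte-identical files.
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_prediction_csv(result$predictions,
                       file.path(out_dir, "predictions.csv"))
  rpv <- result$rpv
  rpv$rpv_rate <- format_confidence(rpv$rpv_rate)
  write.csv(rpv, file.path(out_dir, "rpv.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(result$intervals, file.path(out_dir, "intervals.csv"),
            row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  writeLines(format_interval_table(result$intervals),
             file.path(out_dir, "intervals.txt"))
  write_partitions(result$partitions, file.path(out_dir, "partitions.json"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Read and write prediction-record CSV files
#'
#' Columns: `run_id,specimen_id,current_label,predicted_label,confidence,`
#' `match`; confidence is written with fixed six-decimal formatting.
#'
#' @param predictions prediction-record data frame.
#' @param path CSV path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_prediction_csv <- function(predictions, path) {
  out <- predictions
  out$confidence <- format_confidence(out$confidence)
  out$match <- ifelse(out$match, "true", "false")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_prediction_csv
#' @export
read_prediction_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(run_id = "integer",
                                specimen_id = "character",
                                current_label = "character",
                                predicted_label = "character",
                                confidence = "numeric",
                                match = "character"))
  df$match <- df$match == "true"
  df
}
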