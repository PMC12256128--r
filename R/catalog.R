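# Specimen catalog handling: loading, the minimum-class-size filter, and
# per-run train/validation/test partitions. Class membership is always by
# the *current* catalog label (the label under audit), never ground truth.

#' Pipeline configuration
#'
#' Collection-scale defaults follow the published protocol: classes with at
#' least 400 specimens are kept; each run samples 300 images per class (250
#' train, 50 validation) leaving the remainder as the test pool; 100 runs;
#' four augmented copies per training image; the high-confidence flag list
#' uses RPV strictly greater than 80; RPV interval reports use width-10
#' bins. Two seed streams reconcile reproducible model initialisation with
#' fresh per-run subsets: `model_init_seed` is constant across runs (every
#' run starts from identical weights) while run `r` samples with
#' `base_seed + r`.
#'
#' @param min_class_size minimum specimens per class to keep a class.
#' @param sample_n images sampled per class per run
#'   (`train_n + val_n`).
#' @param train_n,val_n training and validation images per class per run.
#' @param n_runs number of pipeline runs.
#' @param aug_copies augmented copies per training/validation image.
#' @param flag_threshold high-confidence flag threshold; specimens with
#'   RPV strictly greater are flagged for expert review.
#' @param interval_width RPV interval width for reporting; must divide
#'   `n_runs`.
#' @param base_seed base of the per-run sampling seed stream.
#' @param model_init_seed seed for model weight initialisation, identical
#'   across runs.
#' @param phase1_epochs epochs of head-only training (phase 1).
#' @param max_epochs safety cap on fine-tuning epochs (phase 2).
#' @param learning_rate,batch_size optimiser hyperparameters.
#' @param crop_margin margin fraction per side when cropping to a
#'   detection.
#' @param background_tolerance per-channel tolerance of the default
#'   detector's background test.
#' @return a validated configuration list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(min_class_size = 400, sample_n = 300,
                            train_n = 250, val_n = 50, n_runs = 100,
                            aug_copies = 4, flag_threshold = 80,
                            interval_width = 10, base_seed = 1000,
                            model_init_seed = 42, phase1_epochs = 5,
                            max_epochs = 100, learning_rate = 5e-3,
                            batch_size = 32, crop_margin = 0.05,
                            background_tolerance = 0.06) {
  cfg <- list(
    min_class_size = min_class_size, sample_n = sample_n, train_n = train_n,
    val_n = val_n, n_runs = n_runs, aug_copies = aug_copies,
    flag_threshold = flag_threshold, interval_width = interval_width,
    base_seed = base_seed, model_init_seed = model_init_seed,
    phase1_epochs = phase1_epochs, max_epochs = max_epochs,
    learning_rate = learning_rate, batch_size = batch_size,
    crop_margin = crop_margin, background_tolerance = background_tolerance
  )
  if (cfg$train_n + cfg$val_n != cfg$sample_n) {
    stop_invalid_argument("train_n + val_n must equal sample_n")
  }
  if (cfg$sample_n > cfg$min_class_size) {
    stop_invalid_argument("sample_n must not exceed min_class_size")
  }
  if (cfg$flag_threshold >= cfg$n_runs) {
    stop_invalid_argument("flag_threshold must be smaller than n_runs")
  }
  if (cfg$n_runs %% cfg$interval_width != 0) {
    stop_invalid_argument("interval_width must divide n_runs")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Desk-scale pipeline configuration
#'
#' A scaled-down preset for validating the method on synthetic data on a
#' single CPU: 40 images sampled per class per run (32 train / 8
#' validation), 20 runs, and a flag threshold of 16 (the same 80%-of-runs
#' proportion as the collection-scale threshold of 80 out of 100). The
#' sample is kept to half of a typical desk-scale class so that the test
#' pool clearly exceeds the sampled pool and specimens accumulate enough
#' eligible runs for their `rpv_rate` denominators to be meaningful — the
#' same regime as a full-scale audit, where the test pool vastly exceeds
#' the per-run sample.
#'
#' @param ... overrides passed to [pipeline_config()].
#' @return a `"pipeline_config"` object.
#' @export
desk_config <- function(...) {
  defaults <- list(min_class_size = 60, sample_n = 40, train_n = 32,
                   val_n = 8, n_runs = 20, flag_threshold = 16,
                   interval_width = 2, max_epochs = 30)
  do.call(pipeline_config, modifyList(defaults, list(...)))
}

catalog_required_cols <- c("specimen_id", "current_label", "image_path",
                           "group")

#' Load a specimen catalog
#'
#' The catalog is a comma-delimited UTF-8 file with a header row and
#' columns `specimen_id,current_label,image_path,group`; extra columns are
#' preserved as metadata. Relative image paths are resolved against the
#' catalog's directory and checked for existence (recorded in the
#' `image_ok` column, not an error, so catalogs can be validated before
#' images are staged).
#'
#' @param path catalog CSV path.
#' @return a data frame of specimen records with an added `image_ok`
#'   column; the catalog directory is attached as attribute
#'   `"catalog_dir"`.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) {
    stop_invalid_argument(sprintf("catalog file not found: %s", path))
  }
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 check.names = FALSE)
  missing <- setdiff(catalog_required_cols, names(df))
  if (length(missing) > 0) {
    stop_schema_error(sprintf("catalog is missing required column(s): %s",
                              paste(missing, collapse = ", ")))
  }
  dup <- unique(df$specimen_id[duplicated(df$specimen_id)])
  if (length(dup) > 0) {
    stop_integrity_error(sprintf("duplicate specimen_id(s): %s",
                                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  dir <- dirname(normalizePath(path))
  resolved <- ifelse(grepl("^(/|[A-Za-z]:)", df$image_path), df$image_path,
                     file.path(dir, df$image_path))
  df$image_ok <- file.exists(resolved)
  attr(df, "catalog_dir") <- dir
  df
}

# Absolute image path for each record of a loaded catalog.
resolve_image_paths <- function(records) {
  dir <- attr(records, "catalog_dir") %||% "."
  ifelse(grepl("^(/|[A-Za-z]:)", records$image_path), records$image_path,
         file.path(dir, records$image_path))
}

#' Filter classes by minimum specimen count
#'
#' A class (current catalog label) is kept if and only if its specimen
#' count is greater than or equal to `min_class_size`; the boundary is
#' inclusive. Idempotent: filtering retained records again changes nothing.
#'
#' @param records specimen records (from [load_catalog()] or equivalent).
#' @param min_class_size inclusive minimum class size.
#' @return list with `classes` (kept class names, sorted) and `records`
#'   (the retained records).
#' @export
filter_classes <- function(records, min_class_size) {
  if (nrow(records) == 0) stop_invalid_argument("records must be non-empty")
  counts <- table(records$current_label)
  kept <- sort(names(counts)[counts >= min_class_size])
  if (length(kept) == 0) {
    stop_empty_result(
      sprintf("no class has %d or more specimens (largest: %s with %d)",
              min_class_size, names(counts)[which.max(counts)], max(counts)),
      counts = counts
    )
  }
  out <- records[records$current_label %in% kept, , drop = FALSE]
  attr(out, "catalog_dir") <- attr(records, "catalog_dir")
  list(classes = kept, records = out)
}

#' Build the train/validation/test partition for one pipeline run
#'
#' Per class, `sample_n` specimen ids are drawn uniformly without
#' replacement using `sampling_seed = base_seed + run_id`; the first
#' `train_n` go to training, the next `val_n` to validation, and every
#' remaining specimen of the class forms the test pool. Deterministic for
#' fixed seeds and independent of catalog row order.
#'
#' @param records specimen records.
#' @param class_names classes to partition (from [filter_classes()]).
#' @param run_id run number, 1-based.
#' @param config a [pipeline_config()].
#' @return an object of class `"run_partition"`: `run_id`,
#'   `sampling_seed`, and `classes`, a named list with `train`, `val` and
#'   `test` id vectors per class.
#' @export
make_partition <- function(records, class_names, run_id, config) {
  sampling_seed <- config$base_seed + run_id
  parts <- with_seed(sampling_seed, {
    out <- list()
    for (cls in sort(class_names)) {
      ids <- sort(records$specimen_id[records$current_label == cls])
      if (length(ids) < config$sample_n) {
        stop_invalid_state(sprintf(
          "class '%s' has %d specimens but sample_n is %d; apply filter_classes first",
          cls, length(ids), config$sample_n))
      }
      sampled <- sample(ids, config$sample_n)
      out[[cls]] <- list(
        train = sampled[seq_len(config$train_n)],
        val = sampled[config$train_n + seq_len(config$val_n)],
        test = setdiff(ids, sampled)
      )
    }
    out
  })
  structure(list(run_id = as.integer(run_id),
                 sampling_seed = as.integer(sampling_seed),
                 classes = parts),
            class = "run_partition")
}

partition_test_ids <- function(partition) {
  unlist(lapply(partition$classes, `[[`, "test"), use.names = FALSE)
}
partition_trainval_ids <- function(partition) {
  unlist(lapply(partition$classes, function(p) c(p$train, p$val)),
         use.names = FALSE)
}

#' Serialise run partitions to JSON
#'
#' Partitions are written with their run ids and sampling seeds so that
#' runs are resumable and auditable.
#'
#' @param partitions list of [make_partition()] objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(partitions, path) {
  payload <- lapply(partitions, function(p) {
    list(run_id = p$run_id, sampling_seed = p$sampling_seed,
         classes = p$classes)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read run partitions from JSON
#'
#' @param path JSON file written by [write_partitions()].
#' @return list of `"run_partition"` objects.
#' @export
read_partitions <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(p) {
    structure(list(
      run_id = as.integer(p$run_id),
      sampling_seed = as.integer(p$sampling_seed),
      classes = lapply(p$classes, function(cl) {
        list(train = unlist(cl$train), val = unlist(cl$val),
             test = unlist(cl$test))
      })
    ), class = "run_partition")
  })
}
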