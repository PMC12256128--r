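# Independent oracles and shared fixtures. The oracles deliberately use
# naive loops / brute-force scans so they share no code path with the
# package implementations they check.

# Brute-force RPV recount: plain loops over the raw prediction log.
oracle_rpv <- function(predictions, partitions) {
  specs <- sort(unique(predictions$specimen_id))
  out <- data.frame(specimen_id = specs, rpv = 0L, mismatch_runs = 0L,
                    eligible_runs = 0L, modal = NA_character_,
                    consistent = TRUE, stringsAsFactors = FALSE)
  for (i in seq_along(specs)) {
    s <- specs[i]
    elig <- 0
    for (p in partitions) {
      for (cl in p$classes) if (s %in% cl$test) elig <- elig + 1
    }
    labs <- c()
    for (r in seq_len(nrow(predictions))) {
      if (predictions$specimen_id[r] == s &&
          predictions$predicted_label[r] != predictions$current_label[r]) {
        labs <- c(labs, predictions$predicted_label[r])
      }
    }
    out$eligible_runs[i] <- elig
    if (length(labs) > 0) {
      tab <- table(labs)
      out$rpv[i] <- max(tab)
      out$mismatch_runs[i] <- length(labs)
      out$modal[i] <- sort(names(tab)[tab == max(tab)])[1]
      out$consistent[i] <- length(unique(labs)) == 1
    }
  }
  out
}

# Brute-force foreground bounding box: per-pixel scan against a reference
# background colour.
oracle_foreground_box <- function(img, bg, tol = 1e-6) {
  h <- dim(img)[1]; w <- dim(img)[2]
  xmin <- Inf; xmax <- -Inf; ymin <- Inf; ymax <- -Inf
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      if (any(abs(img[y, x, ] - bg) > tol)) {
        xmin <- min(xmin, x - 1); xmax <- max(xmax, x)
        ymin <- min(ymin, y - 1); ymax <- max(ymax, y)
      }
    }
  }
  if (!is.finite(xmin)) return(NULL)
  bbox(xmin, ymin, xmax, ymax)
}

# Random prediction-log instance for the RPV oracle check: random
# eligibility per run, random per-run predictions over a small label set.
random_rpv_instance <- function(n_specimens, n_runs, n_labels, seed) {
  set.seed(seed)
  labels <- paste0("sp", seq_len(n_labels))
  ids <- sprintf("S%03d", seq_len(n_specimens))
  current <- sample(labels, n_specimens, replace = TRUE)
  partitions <- list()
  rows <- list()
  for (run in seq_len(n_runs)) {
    in_test <- runif(n_specimens) < 0.7
    if (!any(in_test)) in_test[1] <- TRUE
    tv <- ids[!in_test]
    k <- length(tv)
    partitions[[run]] <- structure(list(
      run_id = as.integer(run), sampling_seed = run,
      classes = list(all = list(
        train = tv[seq_len(floor(k / 2))],
        val = tv[setdiff(seq_len(k), seq_len(floor(k / 2)))],
        test = ids[in_test]
      ))
    ), class = "run_partition")
    idx <- which(in_test)
    pred <- ifelse(runif(length(idx)) < 0.6, current[idx],
                   sample(labels, length(idx), replace = TRUE))
    rows[[run]] <- data.frame(
      run_id = run, specimen_id = ids[idx], current_label = current[idx],
      predicted_label = pred, confidence = 1,
      stringsAsFactors = FALSE
    )
  }
  preds <- do.call(rbind, rows)
  preds$match <- preds$predicted_label == preds$current_label
  list(predictions = preds, partitions = partitions)
}

# Mann-Whitney AUC for scores of positives vs negatives.
rank_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Session-cached small synthetic dataset (4 species, 1 confusable pair,
# 14 images each) shared by tests that need real images on disk.
.fixture_env <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(.fixture_env$tiny)) {
    specs <- make_species_set(4, 1, seed = 5)
    dir <- file.path(tempdir(), "rpvaudit-tiny-fixture")
    gen <- generate_dataset(specs, 14, 0.05, seed = 17, out_dir = dir,
                            canvas_size = 48)
    .fixture_env$tiny <- list(specs = specs, dir = dir, gen = gen,
                              catalog = load_catalog(gen$catalog_path))
  }
  .fixture_env$tiny
}

# Features + labels for two well-separated (non-confusable) species from
# the tiny dataset, split into train/validation halves. Labels are the
# ground-truth ones so the task is noise-free by construction.
two_class_split <- function(input_size = 16) {
  fx <- tiny_dataset()
  specs <- fx$specs
  gt <- fx$gen$ground_truth
  keep <- specs$species_name[is.na(specs$confusable_with)][1:2]
  rec <- fx$catalog[gt$true_label[match(fx$catalog$specimen_id,
                                        gt$specimen_id)] %in% keep, ]
  labels <- gt$true_label[match(rec$specimen_id, gt$specimen_id)]
  paths <- file.path(fx$dir, rec$image_path)
  imgs <- lapply(paths, read_image)
  feats <- image_features(imgs, input_size)
  n <- nrow(rec)
  set.seed(3)
  tr <- sort(sample(n, round(0.7 * n)))
  va <- setdiff(seq_len(n), tr)
  list(
    train_x = feats[tr, , drop = FALSE], train_y = labels[tr],
    val_x = feats[va, , drop = FALSE], val_y = labels[va],
    images = imgs, labels = labels
  )
}
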