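test_that("well-separated classes reach perfect validation accuracy", {
  sp <- two_class_split(input_size = 16)
  bb <- backbone_spec("t", 16, c(64, 32), 1)
  out <- train_classifier(sp$train_x, sp$train_y, sp$val_x, sp$val_y,
                          backbone = bb,
                          config = desk_config(batch_size = 4))
  expect_equal(max(out$trace$val_accuracy), 1)
  expect_equal(out$trace$val_accuracy[out$best_epoch], 1)
})

test_that("phase 1 runs exactly the configured number of head-only epochs", {
  sp <- two_class_split(input_size = 16)
  bb <- backbone_spec("t", 16, c(32, 16), 1)
  out <- train_classifier(sp$train_x, sp$train_y, sp$val_x, sp$val_y,
                          backbone = bb, config = desk_config())
  expect_equal(sum(out$trace$phase == 1), 5)
  expect_equal(out$trace$phase[1:5], rep(1L, 5))
  # head-only phase leaves every backbone layer untouched
  expect_identical(out$initial_layers[[1]], out$model$layers[[1]])
})

test_that("training is deterministic given identical seeds and data", {
  sp <- two_class_split(input_size = 16)
  bb <- backbone_spec("t", 16, c(32, 16), 1)
  cfg <- desk_config()
  o1 <- train_classifier(sp$train_x, sp$train_y, sp$val_x, sp$val_y, bb, cfg)
  o2 <- train_classifier(sp$train_x, sp$train_y, sp$val_x, sp$val_y, bb, cfg)
  expect_identical(o1$model$layers, o2$model$layers)
  expect_identical(o1$trace, o2$trace)
  p1 <- predict(o1$model, sp$val_x)
  p2 <- predict(o2$model, sp$val_x)
  expect_identical(p1, p2)
})

test_that("early stopping halts at the first non-improving epoch", {
  # noisy labels force validation accuracy to stop improving well before
  # the epoch cap
  fx <- tiny_dataset()
  rec <- fx$catalog
  paths <- file.path(fx$dir, rec$image_path)
  imgs <- lapply(paths, read_image)
  feats <- image_features(imgs, 16)
  set.seed(8)
  labels <- rec$current_label
  flip <- sample(length(labels), round(0.3 * length(labels)))
  labels[flip] <- sample(unique(labels), length(flip), replace = TRUE)
  bb <- backbone_spec("t", 16, c(32, 16), 1)
  out <- train_classifier(feats, labels, feats, labels, bb,
                          desk_config(max_epochs = 50))
  tr <- out$trace
  ph2 <- tr[tr$phase == 2, ]
  expect_lt(nrow(ph2), 50)  # stopped before the cap
  # every phase-2 epoch except the last strictly improved the running best
  best_before <- cummax(c(-Inf, tr$val_accuracy))[seq_len(nrow(tr))]
  ph2_idx <- which(tr$phase == 2)
  improving <- tr$val_accuracy[ph2_idx] > best_before[ph2_idx]
  expect_true(all(improving[-length(improving)]))
  expect_false(improving[length(improving)])
  # hence nothing in phase 2 beyond one epoch after the best
  expect_lte(max(ph2$epoch), out$best_epoch + 1)
})

test_that("best-epoch weights are restored and frozen layers never move", {
  fx <- tiny_dataset()
  rec <- fx$catalog
  feats <- image_features(lapply(file.path(fx$dir, rec$image_path),
                                 read_image), 16)
  labels <- rec$current_label
  bb <- backbone_spec("t", 16, c(32, 16), 1)
  out <- train_classifier(feats, labels, feats, labels, bb, desk_config())
  # trace invariant: best epoch is the earliest maximum
  expect_equal(out$trace$val_accuracy[out$best_epoch],
               max(out$trace$val_accuracy))
  expect_false(any(out$trace$val_accuracy[seq_len(out$best_epoch - 1)] >=
                     out$trace$val_accuracy[out$best_epoch]))
  # returned model reproduces the best epoch's validation accuracy
  pr <- predict(out$model, feats)
  expect_equal(mean(pr$predicted_label == labels),
               max(out$trace$val_accuracy))
  # frozen bottom layer is bit-identical to its initialisation
  expect_identical(out$model$layers[[1]]$W, out$initial_layers[[1]]$W)
  expect_identical(out$model$layers[[1]]$b, out$initial_layers[[1]]$b)
  # the head trains from epoch 1, so it must have moved
  expect_false(identical(out$model$layers[[3]]$W, out$initial_layers[[3]]$W))
})

test_that("training rejects degenerate label sets", {
  x <- matrix(runif(20 * 48), 20)
  expect_error(
    train_classifier(x, rep("a", 20), x, rep("a", 20),
                     backbone_spec("t", 4, c(8), 0), desk_config()),
    class = "invalid_argument")
  expect_error(
    train_classifier(x, rep(c("a", "b"), 10), x, rep("c", 20),
                     backbone_spec("t", 4, c(8), 0), desk_config()),
    class = "invalid_argument")
})

test_that("prediction takes the argmax with label-order tie-breaking", {
  # hand-built model: zero weights give a uniform distribution
  bb <- backbone_spec("t", 2, c(4), 1)
  model <- structure(list(
    layers = list(list(W = matrix(0, 12, 4), b = rep(0, 4)),
                  list(W = matrix(0, 4, 3), b = c(0, 0, 0))),
    label_levels = c("a", "b", "c"), input_size = 2, backbone = bb
  ), class = "rpv_classifier")
  x <- matrix(runif(12), 1)
  pr <- predict(model, x)
  expect_equal(pr$predicted_label, "a")  # tie -> first label
  expect_equal(pr$confidence, 1 / 3)
  # a strongly positive bias on one class wins with confidence near 1
  model$layers[[2]]$b <- c(0, 50, 0)
  pr2 <- predict(model, x)
  expect_equal(pr2$predicted_label, "b")
  expect_equal(pr2$confidence, 1, tolerance = 1e-6)
  # probabilities sum to one
  probs <- predict(model, rbind(x, x), type = "prob")
  expect_equal(rowSums(probs), c(1, 1), tolerance = 1e-6)
})

test_that("batch and single-image predictions agree elementwise", {
  sp <- two_class_split(input_size = 16)
  bb <- backbone_spec("t", 16, c(32, 16), 1)
  out <- train_classifier(sp$train_x, sp$train_y, sp$val_x, sp$val_y, bb,
                          desk_config())
  batch <- predict(out$model, sp$val_x)
  single <- do.call(rbind, lapply(seq_len(nrow(sp$val_x)), function(i) {
    predict(out$model, sp$val_x[i, , drop = FALSE])
  }))
  expect_equal(batch, single, ignore_attr = TRUE)
})

test_that("F1 scores match the closed form and are permutation-invariant", {
  # one class with TP=8 FP=2 FN=2 -> precision = recall = 0.8 -> F1 = 0.8
  rec <- data.frame(
    current_label = c(rep("A", 8), rep("B", 2), rep("A", 2), rep("B", 8)),
    predicted_label = c(rep("A", 8), rep("A", 2), rep("B", 2), rep("B", 8)),
    stringsAsFactors = FALSE
  )
  f <- f1_score(rec)
  expect_equal(f$per_class$f1[f$per_class$class == "A"], 0.8)
  expect_equal(f$micro_f1, 16 / 20)
  # permuting records changes nothing
  set.seed(1)
  f2 <- f1_score(rec[sample(nrow(rec)), ])
  expect_equal(f, f2)
  # all correct -> macro F1 = 1
  allc <- data.frame(current_label = c("A", "B"),
                     predicted_label = c("A", "B"))
  expect_equal(f1_score(allc)$macro_f1, 1)
  # a class never predicted scores F1 = 0
  none <- data.frame(current_label = c("A", "A", "B"),
                     predicted_label = c("B", "B", "B"))
  expect_equal(f1_score(none)$per_class$f1[1], 0)
  expect_error(f1_score(allc[0, ]), class = "invalid_argument")
})

test_that("gradient saliency is non-negative with the model input shape", {
  sp <- two_class_split(input_size = 16)
  bb <- backbone_spec("t", 16, c(32, 16), 1)
  out <- train_classifier(sp$train_x, sp$train_y, sp$val_x, sp$val_y, bb,
                          desk_config())
  sal <- gradient_saliency(out$model, sp$images[[1]])
  expect_equal(dim(sal), c(16, 16))
  expect_true(all(sal >= 0))
  expect_gt(sum(sal), 0)
})
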