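# Training and inference contract: two-phase transfer-style training with a
# frozen backbone in phase 1, fine-tuning of all but the bottom layers in
# phase 2, patience-1 early stopping on validation accuracy, best-epoch
# weight restoration, and fully seeded determinism. The backbone is
# pluggable; the desk-scale default is a small fully connected network over
# resized RGB input, which carries the same freeze/fine-tune semantics as a
# large pretrained convolutional backbone without needing GPU-scale
# training.

#' Describe a classifier backbone
#'
#' @param name backbone name, recorded in manifests.
#' @param input_size side of the square RGB model input in pixels.
#' @param hidden_sizes integer vector of hidden layer widths; together
#'   with the classification head these form `length(hidden_sizes) + 1`
#'   dense layers.
#' @param frozen_bottom_layers number of layers, counted from the input,
#'   that stay frozen during fine-tuning.
#' @return an object of class `"backbone_spec"`.
#' @export
backbone_spec <- function(name, input_size, hidden_sizes,
                          frozen_bottom_layers) {
  n_layers <- length(hidden_sizes) + 1L
  if (frozen_bottom_layers < 0 || frozen_bottom_layers > n_layers) {
    stop_invalid_argument("frozen_bottom_layers must be in [0, n_layers]")
  }
  structure(list(name = name, input_size = as.integer(input_size),
                 hidden_sizes = as.integer(hidden_sizes),
                 n_layers = n_layers,
                 frozen_bottom_layers = as.integer(frozen_bottom_layers)),
            class = "backbone_spec")
}

#' Desk-scale default backbone
#'
#' A two-hidden-layer dense network over 24x24 RGB input: a wide (256
#' unit) first layer whose random projection provides serviceable features
#' for head-only training even before fine-tuning — playing the role a
#' pretrained feature extractor plays at collection scale — followed by a
#' 64-unit layer and the classification head. Small enough to train in
#' seconds per run on one CPU while cleanly exercising the
#' freeze/fine-tune protocol: the first layer stays frozen during phase 2.
#'
#' @param input_size,hidden_sizes,frozen_bottom_layers see
#'   [backbone_spec()].
#' @return a `"backbone_spec"`.
#' @export
tiny_backbone <- function(input_size = 24, hidden_sizes = c(256, 64),
                          frozen_bottom_layers = 1) {
  backbone_spec("tiny-dense", input_size, hidden_sizes,
                frozen_bottom_layers)
}

# He-normal initialisation of all dense layers; consumes the current RNG
# stream (callers seed it).
nn_init <- function(backbone, n_classes) {
  dims <- c(backbone$input_size^2 * 3, backbone$hidden_sizes, n_classes)
  lapply(seq_len(length(dims) - 1), function(l) {
    d_in <- dims[l]; d_out <- dims[l + 1]
    list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)),
                    d_in, d_out),
         b = rep(0, d_out))
  })
}

nn_forward <- function(layers, X) {
  L <- length(layers)
  H <- vector("list", L + 1)
  Z <- vector("list", L)
  H[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(H[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    H[[l + 1]] <- if (l < L) pmax(Z[[l]], 0) else Z[[l]]
  }
  logits <- Z[[L]]
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(H = H, Z = Z, logits = logits, probs = probs)
}

# Cross-entropy loss and gradients for all layers.
nn_grads <- function(layers, X, y_idx) {
  fw <- nn_forward(layers, X)
  n <- nrow(X)
  loss <- -mean(log(pmax(fw$probs[cbind(seq_len(n), y_idx)], 1e-12)))
  L <- length(layers)
  grads <- vector("list", L)
  dZ <- fw$probs
  dZ[cbind(seq_len(n), y_idx)] <- dZ[cbind(seq_len(n), y_idx)] - 1
  dZ <- dZ / n
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(fw$H[[l]], dZ), b = colSums(dZ))
    if (l > 1) {
      dH <- tcrossprod(dZ, layers[[l]]$W)
      dZ <- dH * (fw$Z[[l - 1]] > 0)
    }
  }
  list(loss = loss, grads = grads)
}

adam_init <- function(layers) {
  lapply(layers, function(ly) list(mW = ly$W * 0, vW = ly$W * 0,
                                   mb = ly$b * 0, vb = ly$b * 0))
}

adam_step <- function(layers, grads, state, trainable, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    if (!trainable[l]) next
    g <- grads[[l]]
    st <- state[[l]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    layers[[l]]$W <- layers[[l]]$W -
      lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
    layers[[l]]$b <- layers[[l]]$b -
      lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
    state[[l]] <- st
  }
  list(layers = layers, state = state)
}

as_feature_matrix <- function(x, input_size) {
  if (is.matrix(x)) {
    if (ncol(x) != input_size^2 * 3) {
      stop_invalid_argument(sprintf(
        "feature matrix has %d columns; expected %d for input_size %d",
        ncol(x), input_size^2 * 3, input_size))
    }
    x
  } else {
    image_features(x, input_size)
  }
}

# Centre pixel features about mid-grey; a constant shift that puts the
# network inputs roughly symmetric about zero.
feature_centre <- 0.5

#' Train a classifier with the two-phase protocol
#'
#' Phase 1 trains only the classification head for exactly
#' `config$phase1_epochs` epochs with every backbone layer frozen. Phase 2
#' unfreezes all layers except the bottom `frozen_bottom_layers` and
#' continues until the first epoch whose validation accuracy fails to
#' improve on the running best (patience 1), capped at
#' `config$max_epochs`. The weights of the best validation epoch (earliest
#' on ties) are restored before returning. Training is fully deterministic
#' given `config$model_init_seed` and the data order.
#'
#' @param train_x training images (list of arrays) or a ready feature
#'   matrix from [image_features()].
#' @param train_labels character/factor labels, one per training row; at
#'   least two distinct classes.
#' @param val_x,val_labels validation inputs and labels; validation labels
#'   must be a subset of the training label set.
#' @param backbone a [backbone_spec()].
#' @param config a [pipeline_config()] (or any list with the training
#'   fields).
#' @return an object of class `"training_outcome"`: `model` (class
#'   `"rpv_classifier"`), `trace` (per-epoch data frame with `epoch`,
#'   `phase`, `train_loss`, `val_accuracy`), `best_epoch` and
#'   `label_levels`.
#' @export
train_classifier <- function(train_x, train_labels, val_x, val_labels,
                             backbone = tiny_backbone(),
                             config = desk_config()) {
  train_labels <- as.character(train_labels)
  val_labels <- as.character(val_labels)
  label_levels <- sort(unique(train_labels))
  if (length(label_levels) < 2) {
    stop_invalid_argument("training data must contain at least two classes")
  }
  if (!all(val_labels %in% label_levels)) {
    stop_invalid_argument("validation labels must be a subset of training labels")
  }
  X <- as_feature_matrix(train_x, backbone$input_size) - feature_centre
  Xv <- as_feature_matrix(val_x, backbone$input_size) - feature_centre
  y_idx <- match(train_labels, label_levels)
  yv_idx <- match(val_labels, label_levels)
  n <- nrow(X)
  L <- length(backbone$hidden_sizes) + 1L
  head_only <- c(rep(FALSE, L - 1), TRUE)
  fine_tune <- seq_len(L) > backbone$frozen_bottom_layers

  with_seed(config$model_init_seed %||% 42, {
    layers <- nn_init(backbone, length(label_levels))
    initial_layers <- layers
    state <- adam_init(layers)
    t_step <- 0
    trace <- list()
    best <- list(acc = -Inf, epoch = NA_integer_, layers = NULL)
    epoch <- 0

    val_accuracy <- function(layers) {
      probs <- nn_forward(layers, Xv)$probs
      mean(max.col(probs, ties.method = "first") == yv_idx)
    }

    run_epoch <- function(trainable) {
      perm <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1, n)]
        gr <- nn_grads(layers, X[idx, , drop = FALSE], y_idx[idx])
        if (!is.finite(gr$loss)) {
          stop_training_failure(
            sprintf("non-finite training loss at epoch %d", epoch + 1),
            epoch = epoch + 1)
        }
        t_step <<- t_step + 1
        upd <- adam_step(layers, gr$grads, state, trainable,
                         lr = config$learning_rate, t = t_step)
        layers <<- upd$layers
        state <<- upd$state
        losses <- c(losses, gr$loss)
      }
      mean(losses)
    }

    record <- function(phase, loss) {
      epoch <<- epoch + 1
      acc <- val_accuracy(layers)
      trace[[epoch]] <<- data.frame(epoch = epoch, phase = phase,
                                    train_loss = loss, val_accuracy = acc)
      if (acc > best$acc) {
        best <<- list(acc = acc, epoch = epoch, layers = layers)
      }
      acc
    }

    # phase 1: head only, fixed epoch count
    for (e in seq_len(config$phase1_epochs)) {
      record(1L, run_epoch(head_only))
    }
    # phase 2: fine-tune until validation accuracy stops improving
    for (e in seq_len(config$max_epochs)) {
      prev_best <- best$acc
      acc <- record(2L, run_epoch(fine_tune))
      if (acc <= prev_best) break
    }

    model <- structure(
      list(layers = best$layers, label_levels = label_levels,
           input_size = backbone$input_size, backbone = backbone),
      class = "rpv_classifier"
    )
    structure(
      list(model = model, trace = do.call(rbind, trace),
           best_epoch = best$epoch, label_levels = label_levels,
           initial_layers = initial_layers,
           phase1_epochs = config$phase1_epochs),
      class = "training_outcome"
    )
  })
}

#' Predict species labels for images
#'
#' Assigns each image the label with the highest softmax confidence;
#' exact ties break towards the earlier label in the model's sorted label
#' order.
#'
#' @param object an `"rpv_classifier"` model.
#' @param newdata list of image arrays or a feature matrix.
#' @param type `"label"` for a data frame of predicted labels and
#'   confidences, `"prob"` for the full per-class probability matrix.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.rpv_classifier <- function(object, newdata,
                                   type = c("label", "prob"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata, object$input_size) - feature_centre
  probs <- nn_forward(object$layers, X)$probs
  colnames(probs) <- object$label_levels
  if (type == "prob") return(probs)
  idx <- max.col(probs, ties.method = "first")
  data.frame(
    predicted_label = object$label_levels[idx],
    confidence = probs[cbind(seq_len(nrow(probs)), idx)],
    stringsAsFactors = FALSE
  )
}

#' Gradient saliency map for one image
#'
#' The absolute gradient of the winning logit with respect to the input
#' pixels, summed over colour channels: a simple, dependency-free stand-in
#' for class-activation heat maps, sufficient for the attention
#' quality-control metric ([attention_on_specimen_fraction()]).
#'
#' @param model an `"rpv_classifier"`.
#' @param image image array (resized internally to the model input).
#' @return non-negative numeric matrix `input_size x input_size`.
#' @export
gradient_saliency <- function(model, image) {
  x <- image_features(list(image), model$input_size) - feature_centre
  fw <- nn_forward(model$layers, x)
  k <- which.max(fw$logits[1, ])
  L <- length(model$layers)
  dZ <- matrix(0, 1, ncol(fw$logits))
  dZ[1, k] <- 1
  for (l in rev(seq_len(L))) {
    dH <- tcrossprod(dZ, model$layers[[l]]$W)
    dZ <- if (l > 1) dH * (fw$Z[[l - 1]] > 0) else dH
  }
  g <- array(abs(as.vector(dZ)), dim = c(model$input_size, model$input_size, 3))
  g[, , 1] + g[, , 2] + g[, , 3]
}

#' Precision, recall and F1 from prediction records
#'
#' Per class, `F1 = 2PR / (P + R)` with `F1 = 0` when `P + R = 0`;
#' the macro score is the unweighted mean over classes. The micro-F1
#' (equal to overall accuracy) is reported alongside.
#'
#' @param prediction_records data frame with `current_label` and
#'   `predicted_label` columns.
#' @return list with `macro_f1`, `micro_f1` and `per_class` (data frame:
#'   `class`, `precision`, `recall`, `f1`, `support`).
#' @export
f1_score <- function(prediction_records) {
  if (nrow(prediction_records) == 0) {
    stop_invalid_argument("prediction_records must contain at least one record")
  }
  truth <- prediction_records$current_label
  pred <- prediction_records$predicted_label
  classes <- sort(union(truth, pred))
  per <- lapply(classes, function(cls) {
    tp <- sum(truth == cls & pred == cls)
    fp <- sum(truth != cls & pred == cls)
    fn <- sum(truth == cls & pred != cls)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(class = cls, precision = p, recall = r, f1 = f1,
               support = sum(truth == cls), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(macro_f1 = mean(per$f1), micro_f1 = mean(truth == pred),
       per_class = per)
}
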