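# Binary good/bad quality classification protocol: stratified K-fold
# cross-validation, confusion-matrix metrics, AUC, and the
# maximum-accuracy operating point. The positive class is "good".

#' Classifier configuration
#'
#' Defaults follow the published fine-tuning protocol: learning rate 1e-4,
#' cross-entropy loss, input size 224 (300 for the larger EfficientNet
#' variant). Only the `small-cnn` backbone — a compact two-convolution
#' network trained from scratch — is bundled; the other identifiers are
#' accepted for configuration fidelity but require a user-supplied backbone.
#'
#' @param backbone one of `"small-cnn"`, `"resnet18"`, `"enet-b0"`,
#'   `"enet-b3"`.
#' @param input_size input side length in pixels; defaults to 64 for
#'   `small-cnn`, 300 for `enet-b3`, 224 otherwise.
#' @param learning_rate optimizer step size.
#' @param epochs training epochs.
#' @param loss loss function identifier (only `"cross_entropy"`).
#' @param batch_size minibatch size.
#' @param n_filters channel counts of the two convolution blocks
#'   (`small-cnn` only).
#' @param seed integer seed controlling initialization and batch shuffling.
#' @return an object of class `model_config`.
#' @seealso [small_cnn_config()] for the from-scratch training preset.
#' @export
model_config <- function(backbone = c("small-cnn", "resnet18", "enet-b0",
                                      "enet-b3"),
                         input_size = NULL, learning_rate = 1e-4,
                         epochs = 10L, loss = "cross_entropy",
                         batch_size = 16L, n_filters = c(12L, 24L),
                         seed = 1L) {
  backbone <- match.arg(backbone)
  if (is.null(input_size))
    input_size <- switch(backbone, "small-cnn" = 64L, "enet-b3" = 300L, 224L)
  if (!identical(loss, "cross_entropy"))
    stop("only cross_entropy loss is supported")
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1)
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 loss = loss, batch_size = as.integer(batch_size),
                 n_filters = as.integer(n_filters), seed = as.integer(seed)),
            class = "model_config")
}

#' Training preset for the bundled small CNN
#'
#' A from-scratch network needs a larger step size than a fine-tuned
#' pretrained backbone; this preset uses Adam with learning rate 1e-3 and
#' 10 epochs at 64x64 input.
#'
#' @param ... overrides passed to [model_config()].
#' @return a `model_config`.
#' @export
small_cnn_config <- function(...) {
  args <- modifyList(list(backbone = "small-cnn", learning_rate = 1e-3,
                          epochs = 10L), list(...))
  do.call(model_config, args)
}

#' Stratified K-fold partition
#'
#' Randomly partitions sample indices into `K` folds preserving the class
#' ratio: within each class, a shuffled round-robin deal guarantees that
#' every fold's class count is within one of the exact proportional split.
#'
#' @param labels vector of class labels (two or more classes).
#' @param K number of folds (>= 2).
#' @param seed integer seed.
#' @return object of class `fold_split`: list with `assignments` (per-sample
#'   fold index in `1..K`) and `K`.
#' @export
stratified_kfold <- function(labels, K = 5L, seed = 1L) {
  K <- as.integer(K)
  stopifnot(K >= 2)
  tab <- table(labels)
  if (any(tab < K))
    stop("every class needs at least K members; smallest has ", min(tab))
  assignments <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      start <- sample.int(K, 1L) - 1L
      assignments[idx] <- ((seq_along(idx) - 1L + start) %% K) + 1L
    }
  })
  structure(list(assignments = assignments, K = K), class = "fold_split")
}

#' Confusion-matrix performance measures
#'
#' Computes, from true/false positive/negative counts:
#' accuracy `(TP+TN)/(TP+FP+TN+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and F1 `2/(precision^-1 + recall^-1)`, which equals
#' `TP/(TP + 0.5(FP+FN))`.
#'
#' @param counts named vector or list with entries `TP`, `TN`, `FP`, `FN`.
#' @return named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#'   An undefined metric (zero denominator) is returned as `NaN` with a
#'   warning.
#' @export
compute_metrics <- function(counts) {
  counts <- unlist(counts)[c("TP", "TN", "FP", "FN")]
  if (anyNA(counts) || any(counts < 0))
    stop("counts must provide non-negative TP, TN, FP, FN")
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  total <- tp + tn + fp + fn
  if (total == 0) stop("no samples")
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("precision undefined: no predicted positives"); NaN
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("recall undefined: no actual positives"); NaN
  }
  f1 <- if (tp + 0.5 * (fp + fn) > 0) tp / (tp + 0.5 * (fp + fn)) else {
    warning("F1 undefined"); NaN
  }
  c(accuracy = (tp + tn) / total, precision = precision, recall = recall,
    f1 = f1)
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC with mid-rank tie handling (equivalently, the probability
#' that a random positive outscores a random negative, ties counted 1/2).
#'
#' @param scores numeric scores for the positive class.
#' @param labels binary labels: logical, 0/1, or `"good"`/`"bad"` (with
#'   `"good"` positive).
#' @return scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2)
    stop("both classes must be present to compute AUC")
  r <- pROC::roc(response = y, predictor = scores, quiet = TRUE,
                 levels = c(0, 1), direction = "<")
  as.numeric(pROC::auc(r))
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  lab <- as.character(labels)
  if (!all(lab %in% c("good", "bad")))
    stop("labels must be logical, 0/1, or \"good\"/\"bad\"")
  as.integer(lab == "good")
}

#' Maximum-accuracy operating point
#'
#' Selects, from the candidate set of observed scores plus `Inf`, the
#' decision threshold (predict positive when `score >= threshold`)
#' maximizing accuracy. Ties are broken toward the higher threshold (fewer
#' predicted positives).
#'
#' @inheritParams roc_auc
#' @return the selected threshold.
#' @export
select_operating_point <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2)
    stop("both classes must be present to select an operating point")
  cand <- sort(unique(c(scores, Inf)), decreasing = TRUE)
  acc <- vapply(cand, function(th)
    mean((scores >= th) == (y == 1L)), numeric(1))
  cand[which.max(acc)]  # first index = highest threshold among ties
}

#' Train the quality classifier
#'
#' Trains the bundled small CNN with minibatch Adam on cross-entropy loss.
#' Images are rescaled to `config$input_size` per side (bilinear) and used
#' as single-channel input in `[0, 1]`. The trained model exposes class
#' scores ([predict_scores()]) and the final-convolution activations and
#' gradients that [gradcam()] consumes.
#'
#' @param images list of grayscale matrices in `[0, 1]` (any sizes), or a
#'   4-D array `[size, size, 1, N]` already at input size.
#' @param labels per-image quality labels, `"good"`/`"bad"` (or 0/1 with 1
#'   = good).
#' @param config a [model_config()]; `epochs = 0` returns an untrained
#'   (randomly initialized) model.
#' @return object of class `qc_model`: list with the network, `config`,
#'   `classes`, and per-epoch training `loss` history.
#' @export
train_classifier <- function(images, labels, config = small_cnn_config()) {
  stopifnot(inherits(config, "model_config"))
  if (config$backbone != "small-cnn")
    stop("backbone '", config$backbone, "' is not bundled; ",
         "construct it with qc_network() or use small-cnn")
  y <- as_binary_labels(labels)
  if (config$epochs > 0 && length(unique(y)) < 2)
    stop("training requires at least one sample of each class")
  x4 <- as_input_batch(images, config$input_size)
  n <- dim(x4)[4]
  stopifnot(length(y) == n)
  net <- small_cnn_network(config$input_size, config$n_filters,
                           seed = config$seed)
  Y <- cbind(1 - y, y)   # columns follow classes = c("bad", "good")

  loss_hist <- numeric(config$epochs)
  if (config$epochs > 0) {
    opt <- adam_init(net)
    withr::with_seed(config$seed + 1L, {
      for (ep in seq_len(config$epochs)) {
        ord <- sample.int(n)
        ep_loss <- 0
        for (start in seq(1L, n, by = config$batch_size)) {
          b <- ord[start:min(start + config$batch_size - 1L, n)]
          fwd <- net_forward(net, x4[, , , b, drop = FALSE])
          logits <- fwd$acts[[length(net$layers)]]
          p <- softmax_rows(logits)
          ep_loss <- ep_loss - sum(log(pmax(
            p[cbind(seq_along(b), y[b] + 1L)], 1e-12)))
          dlogits <- (p - Y[b, , drop = FALSE]) / length(b)
          bwd <- net_backward(net, fwd, dlogits)
          upd <- adam_step(net, bwd$param_grads, opt, config$learning_rate)
          net <- upd$net; opt <- upd$opt
        }
        loss_hist[ep] <- ep_loss / n
      }
    })
  }
  structure(list(net = net, config = config, classes = net$classes,
                 loss = loss_hist),
            class = "qc_model")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

as_input_batch <- function(images, size) {
  if (is.array(images) && length(dim(images)) == 4L) {
    stopifnot(dim(images)[1] == size, dim(images)[2] == size)
    return(images)
  }
  if (is.matrix(images)) images <- list(images)
  x4 <- array(0, c(size, size, 1L, length(images)))
  for (i in seq_along(images))
    x4[, , 1L, i] <- resize_gray(images[[i]], size, size)
  x4
}

adam_init <- function(net) {
  st <- lapply(net$layers, function(l) {
    if (!is.null(l$W))
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
  list(state = st, t = 0L)
}

adam_step <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t; c2 <- 1 - beta2^opt$t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- opt$state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    net$layers[[i]]$W <- net$layers[[i]]$W -
      lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b -
      lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    opt$state[[i]] <- s
  }
  list(net = net, opt = opt)
}

#' Positive-class scores for images
#'
#' @param model a trained [train_classifier()] model.
#' @param images list of grayscale matrices, a single matrix, or a 4-D
#'   input batch at the model's input size.
#' @param batch_size scoring batch size.
#' @return numeric vector of softmax probabilities of the positive
#'   (`"good"`) class.
#' @export
predict_scores <- function(model, images, batch_size = 64L) {
  stopifnot(inherits(model, "qc_model"))
  x4 <- as_input_batch(images, model$config$input_size)
  n <- dim(x4)[4]
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    b <- start:min(start + batch_size - 1L, n)
    p <- softmax_rows(network_logits(model$net, x4[, , , b, drop = FALSE]))
    out[b] <- p[, 2L]
  }
  out
}

#' Stratified K-fold cross-validated evaluation
#'
#' Runs the full evaluation protocol: stratified `K`-fold partition, one
#' model trained per fold on the remaining folds, AUC of the held-out
#' scores, and accuracy/precision/recall/F1 recorded at each fold's
#' maximum-accuracy operating point; fold means and standard deviations are
#' reported.
#'
#' @inheritParams train_classifier
#' @param K number of folds.
#' @param seed seed for the fold partition (training uses `config$seed`
#'   offset per fold).
#' @param keep_models keep the per-fold trained models in the report (needed
#'   to compute saliency afterwards).
#' @return object of class `metrics_report`: `per_fold` data frame (AUC,
#'   accuracy, precision, recall, F1, threshold, confusion counts), `mean`
#'   and `std` per metric, `oof` data frame of out-of-fold scores and
#'   predictions, `folds` (the [stratified_kfold()] split), and optionally
#'   `models`.
#' @export
cross_validate <- function(images, labels, config = small_cnn_config(),
                           K = 5L, seed = 1L, keep_models = FALSE) {
  y <- as_binary_labels(labels)
  x4 <- as_input_batch(images, config$input_size)
  n <- dim(x4)[4]
  stopifnot(length(y) == n)
  folds <- stratified_kfold(y, K, seed)
  per_fold <- vector("list", K)
  models <- if (keep_models) vector("list", K)
  oof <- data.frame(index = seq_len(n), fold = folds$assignments,
                    label = y, score = NA_real_, predicted = NA_integer_)
  for (k in seq_len(K)) {
    test <- which(folds$assignments == k)
    train <- which(folds$assignments != k)
    cfg <- config
    cfg$seed <- config$seed + k
    model <- train_classifier(x4[, , , train, drop = FALSE], y[train], cfg)
    scores <- predict_scores(model, x4[, , , test, drop = FALSE])
    th <- select_operating_point(scores, y[test])
    pred <- as.integer(scores >= th)
    cm <- c(TP = sum(pred == 1 & y[test] == 1),
            TN = sum(pred == 0 & y[test] == 0),
            FP = sum(pred == 1 & y[test] == 0),
            FN = sum(pred == 0 & y[test] == 1))
    m <- compute_metrics(cm)
    per_fold[[k]] <- data.frame(fold = k,
                                auc = roc_auc(scores, y[test]),
                                accuracy = m[["accuracy"]],
                                precision = m[["precision"]],
                                recall = m[["recall"]], f1 = m[["f1"]],
                                threshold = th,
                                TP = cm[["TP"]], TN = cm[["TN"]],
                                FP = cm[["FP"]], FN = cm[["FN"]])
    oof$score[test] <- scores
    oof$predicted[test] <- pred
    if (keep_models) models[[k]] <- model
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("auc", "accuracy", "precision", "recall", "f1")
  report <- list(per_fold = per_fold,
                 mean = colMeans(per_fold[metric_cols]),
                 std = vapply(per_fold[metric_cols], sd, numeric(1)),
                 oof = oof, folds = folds, config = config)
  if (keep_models) report$models <- models
  structure(report, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d-fold cross-validation (%s backbone)\n",
              x$folds$K, x$config$backbone))
  for (m in names(x$mean))
    cat(sprintf("  %-9s %6.2f%% ± %.2f\n", m, 100 * x$mean[[m]],
                100 * x$std[[m]]))
  cat("  (accuracy/precision/recall/F1 at the maximum-accuracy",
      "operating point per fold)\n")
  invisible(x)
}
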