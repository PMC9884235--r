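# Grad-CAM: gradients of a class logit with respect to the activation maps
# of the (hooked) final convolution layer are global-average-pooled into
# importance weights; the ReLU of the weighted activation sum, upsampled to
# the image and min-max normalized, is the relevance map g_c in [0, 1].

#' Grad-CAM relevance map
#'
#' Computes the class activation map for `image` under `model`: gradients
#' `g_1..g_n` of the selected class logit with respect to the activation
#' maps `A_1..A_n` of the hooked convolution layer are reduced to importance
#' weights `w_k` by global average pooling; the raw map `ReLU(sum_k w_k
#' A_k)` is bilinearly upsampled to the image size and min-max normalized to
#' `[0, 1]`. Only positive class evidence survives the ReLU, so a map with
#' no positive contribution is identically zero.
#'
#' @param model a trained [train_classifier()] model or a [qc_network()].
#' @param image grayscale matrix in `[0, 1]` at any resolution; it is
#'   rescaled to the model input internally and the saliency map is
#'   returned at the image's own resolution.
#' @param class `"predicted"` (default), a class name, or a class index:
#'   which class logit to explain.
#' @param target_size optional `c(height, width)` for the output map;
#'   defaults to `dim(image)`.
#' @return object of class `saliency_map`: the `H x W` relevance matrix in
#'   `[0, 1]` with attributes `class_index` and `class_name`.
#' @export
gradcam <- function(model, image, class = "predicted", target_size = NULL) {
  net <- if (inherits(model, "qc_model")) model$net else model
  stopifnot(inherits(net, "qc_network"), is.matrix(image))
  if (is.null(target_size)) target_size <- dim(image)

  x4 <- as_input_batch(list(image), net$input_size)
  fwd <- net_forward(net, x4)
  logits <- fwd$acts[[length(net$layers)]]
  class_index <- resolve_class(class, net$classes, logits)

  dlogits <- matrix(0, 1L, ncol(logits))
  dlogits[1L, class_index] <- 1
  bwd <- net_backward(net, fwd, dlogits, stop_at = net$hook,
                      want_params = FALSE)
  A <- fwd$acts[[net$hook]]
  G <- bwd$dx
  stopifnot(identical(dim(A), dim(G)))

  n_maps <- dim(A)[3]
  w <- vapply(seq_len(n_maps), function(k) mean(G[, , k, 1L]), numeric(1))
  raw <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(n_maps)) raw <- raw + w[k] * A[, , k, 1L]
  raw <- pmax(raw, 0)
  up <- resize_gray(raw, target_size[1], target_size[2])
  up <- pmax(up, 0)           # bilinear interpolation cannot undershoot,
                              # but guard the boundary arithmetic
  out <- normalize_map(up)
  attr(out, "class_index") <- class_index
  attr(out, "class_name") <- net$classes[class_index]
  out
}

resolve_class <- function(class, classes, logits) {
  if (identical(class, "predicted")) return(which.max(logits[1L, ]))
  if (is.character(class)) {
    i <- match(class, classes)
    if (is.na(i)) stop("unknown class: ", class)
    return(i)
  }
  i <- as.integer(class)
  if (i < 1L || i > length(classes)) stop("class index out of range")
  i
}

#' Min-max normalize a relevance map
#'
#' Maps `(x - min) / (max - min)` onto `[0, 1]`. A constant map (no dynamic
#' range, hence no localized relevance) is mapped to all zeros by
#' convention, so an uninformative map yields an empty visible region
#' downstream.
#'
#' @param raw_map numeric matrix.
#' @return matrix of class `saliency_map` with values in `[0, 1]`.
#' @export
normalize_map <- function(raw_map) {
  stopifnot(is.matrix(raw_map))
  lo <- min(raw_map); hi <- max(raw_map)
  out <- if (hi > lo) (raw_map - lo) / (hi - lo)
         else matrix(0, nrow(raw_map), ncol(raw_map))
  class(out) <- c("saliency_map", class(out))
  out
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %d x %d, range [%.3f, %.3f]",
              nrow(x), ncol(x), min(x), max(x)))
  if (!is.null(attr(x, "class_name")))
    cat(sprintf(", explains class '%s'", attr(x, "class_name")))
  cat("\n")
  invisible(x)
}
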