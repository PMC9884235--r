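# A compact convolutional network engine in base R matrix operations.
#
# Feature tensors are 4-D arrays [row, col, channel, batch]. Convolutions
# are 3x3, stride 1, no padding, computed by im2col: patches gathered into a
# (positions*batch) x (9*cin) matrix and multiplied by a (9*cin) x cout
# weight matrix. Patch-index matrices are cached per geometry.
#
# A network is a plain list of layers; each layer is
#   list(type = "conv"|"relu"|"maxpool"|"gap"|"dense", W = ..., b = ...)
# ending in a dense layer producing one logit per class. The layer whose
# output serves as the Grad-CAM activation stack is named by `hook`.

.idx_cache <- new.env(parent = emptyenv())

# batched patch-index matrix: row r = (position within image, image) in
# image-major order, column j = patch element (di, dj, channel). Within any
# single column all indices are distinct, which backward exploits for a
# collision-free scatter-add.
im2col_index <- function(h, w, cin, B, k = 3L) {
  key <- paste(h, w, cin, B, k, sep = "x")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  oh <- h - k + 1L; ow <- w - k + 1L
  base <- rep(seq_len(oh), ow) + (rep(seq_len(ow), each = oh) - 1L) * h
  base <- rep(base, B) +
    rep((seq_len(B) - 1L) * h * w * cin, each = oh * ow)
  dij <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * h, "+"))
  off <- as.vector(outer(dij, (seq_len(cin) - 1L) * h * w, "+"))
  idx <- outer(base, off, "+")
  storage.mode(idx) <- "integer"
  .idx_cache[[key]] <- idx
  idx
}

im2col <- function(x4, k = 3L) {
  d <- dim(x4)
  idx <- im2col_index(d[1], d[2], d[3], d[4], k)
  P <- as.vector(x4)[idx]
  dim(P) <- dim(idx)
  P
}

conv_forward <- function(x4, W, b) {
  d <- dim(x4)
  k <- as.integer(sqrt(nrow(W) / d[3]))
  P <- im2col(x4, k)
  out <- P %*% W
  out <- out + rep(b, each = nrow(out))
  oh <- d[1] - k + 1L; ow <- d[2] - k + 1L
  cout <- ncol(W); B <- d[4]
  out4 <- aperm(array(out, c(oh * ow, B, cout)), c(1, 3, 2))
  dim(out4) <- c(oh, ow, cout, B)
  list(out = out4, P = P)
}

conv_backward <- function(dout4, P, W, in_dim) {
  d <- dim(dout4)
  npos <- d[1] * d[2]; cout <- d[3]; B <- d[4]
  dm <- array(dout4, c(npos, cout, B))
  dmat <- array(aperm(dm, c(1, 3, 2)), c(npos * B, cout))
  dW <- crossprod(P, dmat)
  db <- colSums(dmat)
  dP <- tcrossprod(dmat, W)
  k <- as.integer(sqrt(nrow(W) / in_dim[3]))
  idx <- im2col_index(in_dim[1], in_dim[2], in_dim[3], B, k)
  dx <- numeric(prod(in_dim[1:3]) * B)
  for (j in seq_len(ncol(idx))) {     # indices within a column are distinct
    ind <- idx[, j]
    dx[ind] <- dx[ind] + dP[, j]
  }
  dim(dx) <- c(in_dim[1:3], B)
  list(dx = dx, dW = dW, db = db)
}

pool_forward <- function(x4) {
  d <- dim(x4)
  oh <- d[1] %/% 2L; ow <- d[2] %/% 2L
  ri <- seq_len(oh) * 2L - 1L; ci <- seq_len(ow) * 2L - 1L
  a <- x4[ri, ci, , , drop = FALSE]
  b <- x4[ri + 1L, ci, , , drop = FALSE]
  cc <- x4[ri, ci + 1L, , , drop = FALSE]
  dd <- x4[ri + 1L, ci + 1L, , , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  list(out = m, parts = list(a, b, cc, dd), in_dim = d)
}

pool_backward <- function(dout4, cache) {
  p <- cache$parts; m <- pmax(p[[1]], p[[2]], p[[3]], p[[4]])
  wa <- p[[1]] == m
  wb <- p[[2]] == m & !wa
  wc <- p[[3]] == m & !wa & !wb
  wd <- p[[4]] == m & !wa & !wb & !wc
  d <- cache$in_dim
  oh <- dim(dout4)[1]; ow <- dim(dout4)[2]
  ri <- seq_len(oh) * 2L - 1L; ci <- seq_len(ow) * 2L - 1L
  dx <- array(0, d)
  dx[ri, ci, , ] <- dout4 * wa
  dx[ri + 1L, ci, , ] <- dx[ri + 1L, ci, , , drop = FALSE] + dout4 * wb
  dx[ri, ci + 1L, , ] <- dx[ri, ci + 1L, , , drop = FALSE] + dout4 * wc
  dx[ri + 1L, ci + 1L, , ] <- dx[ri + 1L, ci + 1L, , , drop = FALSE] +
    dout4 * wd
  dx
}

gap_forward <- function(x4) {
  d <- dim(x4)
  v <- colMeans(matrix(x4, d[1] * d[2], d[3] * d[4]))
  list(out = t(matrix(v, d[3], d[4])), in_dim = d)   # B x channels
}

gap_backward <- function(dout, in_dim) {
  npos <- in_dim[1] * in_dim[2]
  dx <- rep(as.vector(t(dout)) / npos, each = npos)
  dim(dx) <- in_dim
  dx
}

#' Assemble a convolutional quality-scoring network
#'
#' Builds a network object from an explicit layer list. Used internally by
#' [train_classifier()]; exported so that small fixed-weight networks can be
#' constructed directly (e.g. for saliency-map verification or custom
#' backbones).
#'
#' Layers: `layer_conv(W, b)` (3x3, stride 1, valid; `W` is a
#' `(9*cin) x cout` matrix), `layer_relu()`, `layer_maxpool()` (2x2, stride
#' 2), `layer_gap()` (global average pooling to one value per channel),
#' `layer_dense(W, b)` (`cin x nclass`).
#'
#' @param layers list of layer objects, ending with a dense layer.
#' @param input_size input side length in pixels (images are resized to
#'   `input_size x input_size` before scoring).
#' @param hook index of the layer whose output is the Grad-CAM activation
#'   stack (conventionally the ReLU after the final convolution).
#' @param classes length-2 character vector of class names; the second entry
#'   is the positive class.
#' @return an object of class `qc_network`.
#' @export
qc_network <- function(layers, input_size, hook,
                       classes = c("bad", "good")) {
  stopifnot(length(layers) >= 1, hook >= 1, hook <= length(layers),
            length(classes) == 2)
  if (!any(vapply(layers, function(l) l$type == "conv", logical(1))))
    stop("network must contain at least one convolution layer")
  structure(list(layers = layers, input_size = as.integer(input_size),
                 hook = as.integer(hook), classes = classes),
            class = "qc_network")
}

#' @rdname qc_network
#' @param W,b layer weights and bias.
#' @export
layer_conv <- function(W, b) list(type = "conv", W = W, b = b)
#' @rdname qc_network
#' @export
layer_relu <- function() list(type = "relu")
#' @rdname qc_network
#' @export
layer_maxpool <- function() list(type = "maxpool")
#' @rdname qc_network
#' @export
layer_gap <- function() list(type = "gap")
#' @rdname qc_network
#' @export
layer_dense <- function(W, b) list(type = "dense", W = W, b = b)

# randomly initialized two-conv backbone (He initialization)
small_cnn_network <- function(input_size, n_filters = c(12L, 24L),
                              n_classes = 2L, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    W1 <- matrix(rnorm(9 * n_filters[1], sd = sqrt(2 / 9)), 9, n_filters[1])
    W2 <- matrix(rnorm(9 * n_filters[1] * n_filters[2],
                       sd = sqrt(2 / (9 * n_filters[1]))),
                 9 * n_filters[1], n_filters[2])
    Wd <- matrix(rnorm(n_filters[2] * n_classes,
                       sd = sqrt(1 / n_filters[2])),
                 n_filters[2], n_classes)
  })
  qc_network(
    layers = list(layer_conv(W1, numeric(n_filters[1])),
                  layer_relu(),
                  layer_maxpool(),
                  layer_conv(W2, numeric(n_filters[2])),
                  layer_relu(),                       # Grad-CAM hook
                  layer_maxpool(),
                  layer_gap(),
                  layer_dense(Wd, numeric(n_classes))),
    input_size = input_size, hook = 5L)
}

# Forward pass over a batch; x4 is [h, w, c, B]. Returns per-layer outputs
# (acts) and the caches backward needs.
net_forward <- function(net, x4) {
  acts <- vector("list", length(net$layers))
  caches <- vector("list", length(net$layers))
  cur <- x4
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    cur <- switch(l$type,
      conv = {
        r <- conv_forward(cur, l$W, l$b)
        caches[[i]] <- list(P = r$P, in_dim = dim_or_stop(acts, i, x4))
        r$out
      },
      relu = { caches[[i]] <- cur > 0; pmax(cur, 0) },
      maxpool = { r <- pool_forward(cur); caches[[i]] <- r; r$out },
      gap = { r <- gap_forward(cur); caches[[i]] <- r$in_dim; r$out },
      dense = { caches[[i]] <- cur; cur %*% l$W + rep(l$b, each = nrow(cur)) },
      stop("unknown layer type: ", l$type))
    acts[[i]] <- cur
  }
  list(acts = acts, caches = caches)
}

dim_or_stop <- function(acts, i, x4) {
  if (i == 1L) dim(x4) else dim(acts[[i - 1L]])
}

# Backward pass from dlogits (B x nclass). Stops after computing the
# gradient with respect to the output of layer `stop_at` (0 = input).
# Returns parameter gradients (when want_params) and the stopping gradient.
net_backward <- function(net, fwd, dlogits, stop_at = 0L,
                         want_params = TRUE) {
  grads <- vector("list", length(net$layers))
  d <- dlogits
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    if (l$type == "dense") {
      A <- fwd$caches[[i]]
      if (want_params)
        grads[[i]] <- list(dW = crossprod(A, d), db = colSums(d))
      d <- tcrossprod(d, l$W)
    } else if (l$type == "gap") {
      d <- gap_backward(d, fwd$caches[[i]])
    } else if (l$type == "maxpool") {
      d <- pool_backward(d, fwd$caches[[i]])
    } else if (l$type == "relu") {
      d <- d * fwd$caches[[i]]
    } else if (l$type == "conv") {
      r <- conv_backward(d, fwd$caches[[i]]$P, l$W, fwd$caches[[i]]$in_dim)
      if (want_params) grads[[i]] <- list(dW = r$dW, db = r$db)
      d <- r$dx
    }
    if (i - 1L == stop_at) break
  }
  list(param_grads = grads, dx = d)
}

#' Class logits for activations injected at an intermediate layer
#'
#' Runs the network forward from the output of layer `from` (e.g. the
#' Grad-CAM hook layer) to the logits. This is the primitive that lets the
#' gradient computation of [gradcam()] be verified against finite
#' differences.
#'
#' @param net a [qc_network()] or the network inside a trained model.
#' @param from layer index whose output is being supplied.
#' @param act activations array `[h, w, c]` or `[h, w, c, B]`.
#' @return numeric matrix `B x nclass` of logits.
#' @export
network_logits_from <- function(net, from, act) {
  if (inherits(net, "qc_model")) net <- net$net
  stopifnot(inherits(net, "qc_network"))
  if (length(dim(act)) == 3L) dim(act) <- c(dim(act), 1L)
  cur <- act
  n <- length(net$layers)
  if (from >= n) stop("'from' must precede the final layer")
  for (i in (from + 1L):n) {
    l <- net$layers[[i]]
    cur <- switch(l$type,
      conv = conv_forward(cur, l$W, l$b)$out,
      relu = pmax(cur, 0),
      maxpool = pool_forward(cur)$out,
      gap = gap_forward(cur)$out,
      dense = cur %*% l$W + rep(l$b, each = nrow(cur)))
  }
  cur
}

# logits for a batch of images already at network input size
network_logits <- function(net, x4) {
  n <- length(net$layers)
  net_forward(net, x4)$acts[[n]]
}
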