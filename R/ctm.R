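# Color transparency maps: per-pixel relevance g_c attenuates the gray
# image while 1 - g_c fills a red mask, so the structures the model relied
# on stay visible and irrelevant regions are painted over in red.

#' Render a color transparency map
#'
#' The grayscale image is multiplied pixel-wise by the relevance map
#' (`m = image * g_c`) and replicated to three channels; a red mask valued
#' `1 - g_c` is then composited into the red channel. With the default
#' `"add"` compositing the red channel is `min(m + (1 - g_c), 1)`: fully
#' relevant pixels (`g_c = 1`) reproduce the source exactly and fully
#' irrelevant pixels (`g_c = 0`) are pure red. The `"replace"` alternative
#' sets the red channel to `max(m, 1 - g_c)`.
#'
#' @param image grayscale matrix in `[0, 1]`.
#' @param saliency relevance map in `[0, 1]`, same dimensions (see
#'   [gradcam()]).
#' @param mode red-mask compositing, `"add"` (default) or `"replace"`.
#' @return object of class `ctm_image`: `H x W x 3` array in `[0, 1]` with
#'   attributes `mode` and `grid_spacing` (`NULL` until [overlay_grid()]).
#' @export
make_ctm <- function(image, saliency, mode = c("add", "replace")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(image), is.matrix(saliency))
  if (!identical(dim(image), dim(saliency)))
    stop("image and saliency map dimensions differ")
  if (min(saliency) < 0 || max(saliency) > 1)
    stop("saliency values must lie in [0, 1]")
  m <- image * saliency
  red_mask <- 1 - saliency
  red <- if (mode == "add") pmin(m + red_mask, 1) else pmax(m, red_mask)
  out <- array(c(red, m, m), c(dim(image), 3L))
  structure(out, class = "ctm_image", mode = mode, grid_spacing = NULL)
}

#' Overlay a reference grid on a CTM
#'
#' Draws 1-pixel grid lines every `spacing` rows and columns (at offsets
#' `spacing, 2*spacing, ...` from the top-left corner) in a fixed
#' contrasting color, leaving all other pixels untouched. The grid helps a
#' reader compare areas between the raw scan and the CTM.
#'
#' @param ctm a [make_ctm()] image (any `H x W x 3` array works).
#' @param spacing grid period in pixels, >= 2.
#' @param color length-3 RGB in `[0, 1]`; default cyan.
#' @return the CTM with grid lines drawn and `grid_spacing` set.
#' @export
overlay_grid <- function(ctm, spacing = 50L, color = c(0, 1, 1)) {
  stopifnot(length(dim(ctm)) == 3L, dim(ctm)[3] == 3L, length(color) == 3)
  spacing <- as.integer(spacing)
  if (spacing < 2) stop("grid spacing must be at least 2 pixels")
  h <- dim(ctm)[1]; w <- dim(ctm)[2]
  rows <- grid_positions(h, spacing)
  cols <- grid_positions(w, spacing)
  out <- ctm
  for (ch in 1:3) {
    if (length(rows)) out[rows, , ch] <- color[ch]
    if (length(cols)) out[, cols, ch] <- color[ch]
  }
  attr(out, "grid_spacing") <- spacing
  out
}

# interior line positions: 0-based offsets spacing, 2*spacing, ... that fall
# strictly inside the image; floor((dim - 1) / spacing) lines
grid_positions <- function(extent, spacing) {
  k <- (extent - 1L) %/% spacing
  if (k < 1L) integer(0) else seq_len(k) * spacing + 1L
}

#' Classic heat-map overlay
#'
#' Maps the relevance values through a fixed "hot" colormap (black - red -
#' yellow - white, hotter meaning more relevant) and alpha-blends the
#' result with the grayscale image.
#'
#' @inheritParams make_ctm
#' @param alpha blend fraction in `[0, 1]`: 0 returns the gray image, 1 the
#'   pure colormap.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
make_heatmap_overlay <- function(image, saliency, alpha = 0.5) {
  stopifnot(is.matrix(image), is.matrix(saliency),
            identical(dim(image), dim(saliency)),
            alpha >= 0, alpha <= 1)
  cmap <- array(c(clip01(3 * saliency),
                  clip01(3 * saliency - 1),
                  clip01(3 * saliency - 2)), c(dim(image), 3L))
  gray3 <- array(image, c(dim(image), 3L))
  (1 - alpha) * gray3 + alpha * cmap
}

#' Side-by-side explanation panel
#'
#' Writes a horizontal panel (raw scan | CTM | CTM with grid) as one PNG.
#'
#' @param image grayscale matrix.
#' @param saliency matching relevance map.
#' @param path output PNG path.
#' @param grid_spacing grid period for the third panel.
#' @param mode passed to [make_ctm()].
#' @return `path`, invisibly.
#' @export
write_ctm_panel <- function(image, saliency, path, grid_spacing = 50L,
                            mode = "add") {
  ctm <- make_ctm(image, saliency, mode = mode)
  ctm_grid <- overlay_grid(ctm, grid_spacing)
  h <- nrow(image); w <- ncol(image)
  panel <- array(0, c(h, 3L * w + 2L, 3L))
  panel[, seq_len(w), ] <- array(image, c(h, w, 3L))
  panel[, w + 1L + seq_len(w), ] <- ctm
  panel[, 2L * w + 2L + seq_len(w), ] <- ctm_grid
  write_rgb_image(panel, path)
}
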