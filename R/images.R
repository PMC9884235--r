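# Thin wrappers around EBImage keeping the package-internal convention:
# a grayscale image is a base R matrix indexed [row, column], origin top-left,
# values in [0, 1]. EBImage stores images [x = column, y = row], hence the
# transposes.

#' Read a grayscale image
#'
#' Reads a PNG or TIFF image and returns it as a `[row, column]` matrix with
#' values in `[0, 1]`. Color images are converted to luminance by channel
#' averaging.
#'
#' @param path file path of a PNG or TIFF image.
#' @return numeric matrix (rows x columns) in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 3L) a <- apply(a, c(1L, 2L), mean)
  t(a)
}

#' Write a grayscale image
#'
#' Writes a `[row, column]` matrix in `[0, 1]` as an 8-bit grayscale PNG
#' (or TIFF, by file extension).
#'
#' @param x numeric matrix in `[0, 1]`.
#' @param path output file path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(x, path) {
  stopifnot(is.matrix(x))
  EBImage::writeImage(EBImage::Image(t(clip01(x))), path)
  invisible(path)
}

#' Write an RGB image
#'
#' Writes a `[row, column, 3]` array in `[0, 1]` as an 8-bit color PNG.
#'
#' @param x numeric array `H x W x 3` in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(x, path) {
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[3L] == 3L)
  img <- EBImage::Image(aperm(clip01(x), c(2L, 1L, 3L)), colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Bilinearly resize a grayscale image
#'
#' @param x numeric matrix (rows x columns).
#' @param height,width target size in pixels.
#' @return resized matrix of dimension `height x width`.
#' @export
resize_gray <- function(x, height, width) {
  stopifnot(is.matrix(x), height >= 1, width >= 1)
  if (nrow(x) == height && ncol(x) == width) return(x)
  t(as.array(EBImage::resize(EBImage::Image(t(x)), w = width, h = height)))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# binary mask written as {0, 255} PNG
write_mask_image <- function(mask, path) {
  write_gray_image(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
}

read_mask_image <- function(path) {
  read_gray_image(path) >= 0.5
}
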