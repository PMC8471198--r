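#' Read a radiograph as an 8-bit grayscale matrix
#'
#' Reads TIFF or PNG (by file extension). Color images are converted to
#' luminance (Rec. 601 weights); 16-bit images are rescaled to the 0-255
#' range. The returned matrix is integer-valued on `[0, 255]`.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @return a numeric intensity matrix (rows x cols).
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           tif = , tiff = tiff::readTIFF(path),
           png = png::readPNG(path),
           stop("unsupported image format: ", ext)),
    error = function(e) stop("cannot read image: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE))
  if (is.list(arr)) arr <- arr[[1]]            # multi-page TIFF: first page
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    arr <- if (nch >= 3L) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else arr[, , 1]                          # gray+alpha: drop alpha
  }
  round(arr * 255)
}

#' Write an intensity matrix as an 8-bit grayscale image
#'
#' @param image numeric matrix with values in `[0, 255]`.
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return invisibly, `path`.
#' @export
save_image <- function(image, path) {
  assert_gray(image, "image")
  x <- round(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
         png = png::writePNG(x, path),
         stop("unsupported image format: ", ext))
  invisible(path)
}

#' Photographic negative
#'
#' Replaces every pixel `v` by `255 - v`. On radiographs this renders the
#' radio-opaque bone dark and the joint gap bright, which some readers find
#' enhances joint-margin visibility. The operation is an involution.
#'
#' @param image numeric matrix with values in `[0, 255]`.
#' @return the inverted matrix.
#' @export
negative_image <- function(image) {
  assert_gray(image, "image")
  255 - image
}

#' Bilinear downscaling
#'
#' Resamples with bilinear interpolation under the half-pixel-center
#' convention: output pixel `i` (0-based) maps to input coordinate
#' `(i + 0.5) * in/out - 0.5`. Under this convention an exact 2x reduction
#' equals 2x2 block averaging, and outputs are convex combinations of input
#' pixels (never outside the input range).
#'
#' @param image numeric matrix.
#' @param out_h,out_w target size; must satisfy `1 <= out <= input size`.
#' @return the resampled matrix.
#' @export
downscale_bilinear <- function(image, out_h, out_w) {
  assert_gray(image, "image")
  out_h <- as.integer(out_h)
  out_w <- as.integer(out_w)
  if (out_h < 1L || out_w < 1L) {
    stop("target size must be positive", call. = FALSE)
  }
  if (out_h > nrow(image) || out_w > ncol(image)) {
    stop("downscale target exceeds input size", call. = FALSE)
  }
  resize_bilinear_cpp(image, out_h, out_w)
}
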