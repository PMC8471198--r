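#' HOG descriptor parameters
#'
#' The default geometry is the one that yields exactly 1296 features on a
#' 28x28 image: the input is resized to 28x28, divided into 4x4-pixel cells
#' (7x7 cells), orientations are folded to unsigned `[0, 180)` degrees and
#' accumulated into 9 bins per cell with magnitude-weighted linear
#' interpolation, and blocks of 2x2 cells advance with a 4-pixel (one-cell)
#' stride, giving 6x6 block positions; each block is L2-normalized. Feature
#' length = 6 x 6 x (2 x 2) x 9 = 1296.
#'
#' @param resize_to working size `c(rows, cols)` the image is resampled to
#'   before gradient computation.
#' @param cell_size cell side in pixels.
#' @param block_cells block side in cells.
#' @param block_stride block stride in pixels (must be a multiple of
#'   `cell_size`).
#' @param n_bins number of unsigned orientation bins over `[0, 180)`.
#' @return an object of class `koa_hog_params`.
#' @export
hog_params <- function(resize_to = c(28L, 28L), cell_size = 4L,
                       block_cells = 2L, block_stride = 4L, n_bins = 9L) {
  resize_to <- as.integer(rep(resize_to, length.out = 2L))
  cell_size <- as.integer(cell_size)
  block_cells <- as.integer(block_cells)
  block_stride <- as.integer(block_stride)
  n_bins <- as.integer(n_bins)
  if (any(resize_to < 1L) || cell_size < 1L || block_cells < 1L ||
      block_stride < 1L || n_bins < 1L) {
    stop("invalid HOG parameters", call. = FALSE)
  }
  if (block_stride %% cell_size != 0L) {
    stop("`block_stride` must be a multiple of `cell_size`", call. = FALSE)
  }
  if (any(resize_to %/% cell_size < block_cells)) {
    stop("resize target smaller than one block", call. = FALSE)
  }
  structure(list(resize_to = resize_to, cell_size = cell_size,
                 block_cells = block_cells, block_stride = block_stride,
                 n_bins = n_bins),
            class = "koa_hog_params")
}

#' @rdname hog_params
#' @param params a `koa_hog_params` object.
#' @return `hog_length()` returns the descriptor length implied by the
#'   geometry: `n_block_positions * cells_per_block * n_bins`.
#' @export
hog_length <- function(params) {
  sc <- params$block_stride %/% params$cell_size
  nb <- (params$resize_to %/% params$cell_size - params$block_cells) %/% sc + 1L
  as.integer(nb[1] * nb[2] * params$block_cells^2 * params$n_bins)
}

#' Histogram-of-oriented-gradients features
#'
#' Resizes the image to the working size, computes centered-difference
#' gradients (one-sided at the borders), folds the gradient orientation to
#' unsigned `[0, 180)` degrees (opposite directions share a bin), and
#' accumulates magnitude-weighted, linearly interpolated votes into
#' per-cell orientation histograms which are grouped into overlapping
#' L2-normalized blocks and concatenated.
#'
#' @param image intensity matrix.
#' @param params a [hog_params()] object.
#' @return a feature vector of class `koa_features`, kind `"HOG"`, length
#'   [hog_length()]; entries are nonnegative.
#' @export
hog_features <- function(image, params = hog_params()) {
  assert_gray(image, "image")
  stopifnot(inherits(params, "koa_hog_params"))
  if (nrow(image) != params$resize_to[1] || ncol(image) != params$resize_to[2]) {
    image <- resize_bilinear_cpp(image, params$resize_to[1], params$resize_to[2])
  }
  v <- hog_cpp(image, params$cell_size, params$block_cells,
               params$block_stride, params$n_bins)
  feature_vector(v, "HOG")
}
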