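#' Local binary pattern codes and histogram features
#'
#' Each interior pixel is compared with its `k` ring neighbors; neighbor `i`
#' contributes `2^i` to the pixel's code when its intensity is greater than
#' or equal to the center (equality counts as 1). Neighbors are enumerated
#' clockwise starting from the top-left corner of the ring -- a fixed integer
#' sampling convention:
#'
#' * `k = 8`, radius 1: the eight pixels of the 3x3 ring;
#' * `k = 4`, radius 1: the four diagonal pixels of the 3x3 ring;
#' * `k = 16`, radius 2: the sixteen pixels of the 5x5 ring.
#'
#' A constant image therefore yields the all-ones code `2^k - 1` everywhere,
#' and any strictly increasing intensity transform leaves all codes (hence
#' the histogram) unchanged.
#'
#' @param image intensity matrix, at least `(2r+1) x (2r+1)`.
#' @param k neighborhood size: 4, 8 (default) or 16.
#' @return `lbp_codes()` returns the integer code matrix for interior
#'   pixels; `lbp_features()` returns the normalized code histogram as a
#'   `koa_features` vector of kind `"LBP"` and length `2^k`, with attribute
#'   `n_pixels` (the number of encoded interior pixels).
#' @export
lbp_codes <- function(image, k = 8L) {
  assert_gray(image, "image")
  k <- as.integer(k)
  if (!k %in% c(4L, 8L, 16L)) {
    stop("`k` must be one of 4, 8, 16", call. = FALSE)
  }
  off <- lbp_offsets(k)
  r <- max(abs(off))
  h <- nrow(image); w <- ncol(image)
  if (h < 2L * r + 1L || w < 2L * r + 1L) {
    stop("image too small for the LBP neighborhood", call. = FALSE)
  }
  rows <- (r + 1L):(h - r)
  cols <- (r + 1L):(w - r)
  center <- image[rows, cols, drop = FALSE]
  code <- matrix(0, length(rows), length(cols))
  for (i in seq_len(k)) {
    nb <- image[rows + off[i, 1L], cols + off[i, 2L], drop = FALSE]
    code <- code + (nb >= center) * 2^(i - 1L)
  }
  code
}

#' @rdname lbp_codes
#' @export
lbp_features <- function(image, k = 8L) {
  code <- lbp_codes(image, k)
  n <- length(code)
  counts <- tabulate(as.integer(code) + 1L, nbins = 2L^as.integer(k))
  v <- feature_vector(counts / n, "LBP")
  attr(v, "n_pixels") <- n
  v
}

# Ring offsets (row, col), clockwise from the top-left corner.
lbp_offsets <- function(k) {
  if (k == 8L) {
    m <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  } else if (k == 4L) {
    m <- rbind(c(-1, -1), c(-1, 1), c(1, 1), c(1, -1))
  } else {
    m <- rbind(c(-2, -2), c(-2, -1), c(-2, 0), c(-2, 1), c(-2, 2),
               c(-1, 2), c(0, 2), c(1, 2),
               c(2, 2), c(2, 1), c(2, 0), c(2, -1), c(2, -2),
               c(1, -2), c(0, -2), c(-1, -2))
  }
  storage.mode(m) <- "integer"
  m
}
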