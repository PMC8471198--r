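#' Valid-mode 2-D convolution (cross-correlation) with bias
#'
#' Computes `(I * f)[x, y] = sum_{s,t} f[s, t] * I[x+s-1, y+t-1] + b` over
#' every position where the kernel fits entirely inside the image -- the
#' index convention used by the CNN's convolutional layers.
#'
#' @param image numeric matrix.
#' @param kernel numeric weight matrix, no larger than the image.
#' @param bias scalar added to every output element.
#' @return a `(nrow(image) - nrow(kernel) + 1) x (ncol(image) -
#'   ncol(kernel) + 1)` numeric matrix.
#' @export
convolve2d <- function(image, kernel, bias = 0) {
  stopifnot(is.matrix(image), is.matrix(kernel), length(bias) == 1L)
  kh <- nrow(kernel); kw <- ncol(kernel)
  ho <- nrow(image) - kh + 1L
  wo <- ncol(image) - kw + 1L
  if (ho < 1L || wo < 1L) stop("kernel larger than image", call. = FALSE)
  out <- matrix(bias, ho, wo)
  for (s in seq_len(kh)) {
    for (t in seq_len(kw)) {
      out <- out + kernel[s, t] *
        image[s:(s + ho - 1L), t:(t + wo - 1L), drop = FALSE]
    }
  }
  out
}
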