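#' Tagged feature vectors and feature-level fusion
#'
#' Descriptor outputs are plain numeric vectors tagged with their
#' provenance: `HOG`, `LBP`, `CNN`, or a fused combination such as
#' `HOG+CNN`. Fusion is concatenation in the given order; the fused kind is
#' the set of base kinds joined in the canonical order HOG, LBP, CNN.
#'
#' @param values numeric vector.
#' @param kind descriptor provenance tag.
#' @return `feature_vector()` returns a `koa_features` object.
#' @export
feature_vector <- function(values, kind) {
  values <- as.numeric(values)
  if (anyNA(values) || !all(is.finite(values))) {
    stop("feature values must be finite", call. = FALSE)
  }
  structure(values, kind = as.character(kind), class = "koa_features")
}

#' @rdname feature_vector
#' @param x a `koa_features` vector.
#' @return `feature_kind()` returns the provenance tag.
#' @export
feature_kind <- function(x) attr(x, "kind")

#' @rdname feature_vector
#' @param vectors a list of `koa_features` vectors (at least one).
#' @return `fuse()` returns the concatenated `koa_features` vector; its
#'   length is the sum of the input lengths.
#' @export
fuse <- function(vectors) {
  if (inherits(vectors, "koa_features")) vectors <- list(vectors)
  if (!length(vectors)) stop("nothing to fuse", call. = FALSE)
  kinds <- unlist(lapply(vectors, function(v) {
    strsplit(feature_kind(v), "+", fixed = TRUE)[[1]]
  }))
  canon <- c("HOG", "LBP", "CNN")
  kinds <- canon[canon %in% kinds]
  vals <- unlist(lapply(vectors, as.numeric), use.names = FALSE)
  feature_vector(vals, paste(kinds, collapse = "+"))
}
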