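# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps the package's stochastic stages (generator,
# CNN init/shuffle, forest, splits) reproducible without clobbering user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a base seed and a small stage offset, kept inside
# the 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131L + offset) %% 2147483647)
}

assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop(sprintf("`%s` must have at least one row and column", arg), call. = FALSE)
  }
  rng <- range(img)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255) {
    stop(sprintf("`%s` intensities must be finite and within [0, 255]", arg),
         call. = FALSE)
  }
  invisible(img)
}
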