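#' Kellgren-Lawrence grade labels
#'
#' The package grades knees on the Kellgren-Lawrence (KL) scale with five
#' classes: `Healthy` (no radiographic disease) and `GradeI` (doubtful)
#' through `GradeIV` (severe). `Healthy` is the designated negative class
#' when five-class predictions are collapsed to a diseased-vs-healthy
#' binary confusion matrix.
#'
#' @return `grade_levels()` returns the five level names in severity order.
#' @export
grade_levels <- function() {
  c("Healthy", "GradeI", "GradeII", "GradeIII", "GradeIV")
}

#' @rdname grade_levels
#' @param x a character or factor vector of grade labels.
#' @return `as_grade()` returns `x` as a factor with the five canonical
#'   levels, erroring on unknown labels.
#' @export
as_grade <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), grade_levels())
  if (length(bad)) {
    stop("unknown grade label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = grade_levels())
}

# TRUE for the four diseased grades, FALSE for Healthy.
is_diseased <- function(x) as_grade(x) != "Healthy"
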