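#' Rectangular region of interest
#'
#' Boxes are 0-based and half-open: a box covers rows
#' `[row, row + height)` and columns `[col, col + width)` of the image, in
#' row-major convention. This single convention is used everywhere in the
#' package (generator ground truth, matcher output, manifests).
#'
#' @param row,col top-left corner (0-based).
#' @param height,width box size in pixels (>= 1).
#' @return an object of class `koa_roi`.
#' @export
roi_box <- function(row, col, height, width) {
  row <- as.integer(row); col <- as.integer(col)
  height <- as.integer(height); width <- as.integer(width)
  if (row < 0L || col < 0L || height < 1L || width < 1L) {
    stop("invalid ROI box", call. = FALSE)
  }
  structure(list(row = row, col = col, height = height, width = width),
            class = "koa_roi")
}

#' @rdname roi_box
#' @param image intensity matrix to crop.
#' @param box a `koa_roi`.
#' @return `crop_roi()` returns the sub-matrix covered by `box`.
#' @export
crop_roi <- function(image, box) {
  stopifnot(inherits(box, "koa_roi"))
  if (box$row + box$height > nrow(image) || box$col + box$width > ncol(image)) {
    stop("ROI box exceeds image bounds", call. = FALSE)
  }
  image[(box$row + 1L):(box$row + box$height),
        (box$col + 1L):(box$col + box$width), drop = FALSE]
}

#' @rdname roi_box
#' @param a,b two `koa_roi` boxes.
#' @return `roi_iou()` returns the intersection-over-union of the two boxes.
#' @export
roi_iou <- function(a, b) {
  stopifnot(inherits(a, "koa_roi"), inherits(b, "koa_roi"))
  ir <- max(0L, min(a$row + a$height, b$row + b$height) - max(a$row, b$row))
  ic <- max(0L, min(a$col + a$width, b$col + b$width) - max(a$col, b$col))
  inter <- as.numeric(ir) * ic
  uni <- as.numeric(a$height) * a$width + as.numeric(b$height) * b$width - inter
  inter / uni
}

#' Mean absolute difference between two feature vectors
#'
#' The template-matching similarity score: for vectors of common length `h`,
#' `(1/h) * sum(|v_s - v_d|)`. Zero iff the vectors are identical; smaller
#' means more similar.
#'
#' @param v_s,v_d numeric vectors of equal length.
#' @return a nonnegative scalar.
#' @export
mad_similarity <- function(v_s, v_d) {
  if (length(v_s) != length(v_d)) {
    stop("feature vectors must have equal length", call. = FALSE)
  }
  if (length(v_s) < 1L) stop("feature vectors must be non-empty", call. = FALSE)
  mean(abs(as.numeric(v_s) - as.numeric(v_d)))
}

#' Build a HOG template bank for ROI matching
#'
#' Stores one or more equally sized template images together with their HOG
#' descriptors, computed with the same parameters later used on every search
#' window so that an exact copy of a template scores a mean absolute
#' difference of zero.
#'
#' @param templates a single intensity matrix or a list of equally sized
#'   matrices (typically joint-region crops).
#' @param hog_params a [hog_params()] object used for both bank and windows.
#' @return an object of class `koa_template_bank`.
#' @export
template_bank <- function(templates, hog_params = koagrader::hog_params()) {
  if (is.matrix(templates)) templates <- list(templates)
  if (!length(templates)) stop("need at least one template", call. = FALSE)
  dims <- vapply(templates, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all templates must share one size", call. = FALSE)
  }
  feats <- vapply(templates,
                  function(tm) as.numeric(hog_features(tm, hog_params)),
                  numeric(hog_length(hog_params)))
  structure(list(templates = templates,
                 hog_features = if (is.matrix(feats)) feats else
                   matrix(feats, ncol = 1L),
                 d_r = dims[1, 1], d_c = dims[2, 1],
                 hog_params = hog_params),
            class = "koa_template_bank")
}

#' Save / load a template bank
#'
#' The bank is stored as a directory of 8-bit grayscale TIFFs plus a
#' `bank.json` manifest recording the template size and HOG parameters;
#' descriptors are recomputed on load so the stored images remain the
#' single source of truth.
#'
#' @param bank a [template_bank()].
#' @param dir directory to write to (created if absent).
#' @return `save_template_bank()` invisibly returns `dir`;
#'   `load_template_bank()` returns the reconstructed bank.
#' @export
save_template_bank <- function(bank, dir) {
  stopifnot(inherits(bank, "koa_template_bank"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("template_%03d.tif", seq_along(bank$templates))
  for (i in seq_along(bank$templates)) {
    save_image(bank$templates[[i]], file.path(dir, files[i]))
  }
  p <- bank$hog_params
  jsonlite::write_json(list(templates = files,
                            d_r = bank$d_r, d_c = bank$d_c,
                            hog_params = list(resize_to = p$resize_to,
                                              cell_size = p$cell_size,
                                              block_cells = p$block_cells,
                                              block_stride = p$block_stride,
                                              n_bins = p$n_bins)),
                       file.path(dir, "bank.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_template_bank
#' @export
load_template_bank <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "bank.json"),
                              simplifyVector = TRUE)
  p <- meta$hog_params
  template_bank(lapply(file.path(dir, meta$templates), load_image),
                hog_params(resize_to = p$resize_to, cell_size = p$cell_size,
                           block_cells = p$block_cells,
                           block_stride = p$block_stride,
                           n_bins = p$n_bins))
}

#' Locate the tibiofemoral joint by HOG template matching
#'
#' Slides a template-sized window across the image (stride 1 by default,
#' i.e. every valid placement), computes the window's HOG descriptor with
#' the bank's parameters, and scores it against every bank template by
#' [mad_similarity()]. The window with the minimum score wins; ties are
#' broken by smallest row-major position, then smallest template index.
#'
#' @param image intensity matrix to search.
#' @param bank a [template_bank()].
#' @param stride search stride in pixels (default 1, per-pixel search).
#' @return a list with `box` (a [roi_box()] of template size), `score`
#'   (the winning MAD value) and `template_index` (1-based).
#' @export
match_roi <- function(image, bank, stride = 1L) {
  assert_gray(image, "image")
  stopifnot(inherits(bank, "koa_template_bank"))
  if (bank$d_r > nrow(image) || bank$d_c > ncol(image)) {
    stop("template larger than image", call. = FALSE)
  }
  p <- bank$hog_params
  res <- match_roi_cpp(image, bank$hog_features,
                       bank$d_r, bank$d_c,
                       p$resize_to[1], p$resize_to[2],
                       p$cell_size, p$block_cells, p$block_stride, p$n_bins,
                       as.integer(stride))
  list(box = roi_box(res$row, res$col, bank$d_r, bank$d_c),
       score = res$score,
       template_index = res$template_index + 1L)
}

#' Two-phase region-based segmentation of a joint crop
#'
#' A piecewise-constant (Chan-Vese-style) two-phase segmentation evolved
#' with 3x3 morphological neighborhood steps. Each iteration reassigns every
#' pixel to the phase whose current mean intensity is nearer (ties keep the
#' previous label), then despeckles the label field with a 3x3 morphological
#' cleanup: a pixel with no same-label neighbour in its 3x3 window flips to
#' the surrounding phase (this removes isolated noise pixels but, unlike a
#' majority vote, preserves one-pixel-thin structures such as a severely
#' narrowed joint gap).
#' Iteration stops when the fraction of changed labels drops below `tol` or
#' after `max_iter` sweeps. The returned mask is oriented so that 1 marks
#' bone: the brighter phase by default, or the darker phase when the crop
#' comes from a negative-preprocessed radiograph (`bone = "dark"`).
#'
#' @param roi_img intensity matrix (a joint-region crop).
#' @param max_iter maximum number of sweeps (>= 1).
#' @param tol convergence threshold on the changed-label fraction.
#' @param bone which phase is bone: `"bright"` (default) or `"dark"`.
#' @param init optional initial binary mask. The default thresholds at the
#'   intensity midpoint `(min + max)/2`, which starts the evolution in the
#'   bone-versus-gap basin; a geometric (e.g. border-inset) start can fall
#'   into a local optimum separating sclerotic from plain bone instead.
#'   Also useful for checking idempotence at convergence.
#' @return a binary integer matrix (1 = bone) with attributes `iterations`,
#'   `converged` and `degenerate` (constant input).
#' @export
segment_roi <- function(roi_img, max_iter = 200L, tol = 1e-4,
                        bone = c("bright", "dark"), init = NULL) {
  assert_gray(roi_img, "roi_img")
  bone <- match.arg(bone)
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  h <- nrow(roi_img); w <- ncol(roi_img)

  if (is.null(init)) {
    mask <- roi_img > (min(roi_img) + max(roi_img)) / 2
  } else {
    mask <- init > 0
    stopifnot(identical(dim(mask), dim(roi_img)))
  }

  degenerate <- FALSE
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    n1 <- sum(mask)
    if (n1 == 0L || n1 == length(mask)) { degenerate <- TRUE; converged <- TRUE; break }
    c1 <- mean(roi_img[mask]); c2 <- mean(roi_img[!mask])
    if (c1 == c2) { degenerate <- TRUE; converged <- TRUE; break }
    d1 <- (roi_img - c1)^2; d2 <- (roi_img - c2)^2
    new_mask <- ifelse(d1 == d2, mask, d1 < d2)    # tie keeps previous label
    # 3x3 despeckle over in-bounds neighbors: flip pixels whose label has no
    # other supporter in the window (complement-symmetric by construction)
    cnt1 <- neighbor_sum3(new_mask)
    tot <- neighbor_sum3(matrix(TRUE, h, w))
    cnt0 <- tot - cnt1
    new_mask <- ifelse(new_mask & cnt1 <= 1, FALSE,
                       ifelse(!new_mask & cnt0 <= 1, TRUE, new_mask))
    changed <- mean(new_mask != mask)
    mask <- new_mask
    if (changed < tol) { converged <- TRUE; break }
  }

  m1 <- if (any(mask)) mean(roi_img[mask]) else NA_real_
  m2 <- if (any(!mask)) mean(roi_img[!mask]) else NA_real_
  want_bright <- bone == "bright"
  if (!is.na(m1) && !is.na(m2)) {
    if ((want_bright && m1 < m2) || (!want_bright && m1 > m2)) mask <- !mask
  }
  out <- matrix(as.integer(mask), h, w)
  attr(out, "iterations") <- iterations
  attr(out, "converged") <- converged
  attr(out, "degenerate") <- degenerate
  out
}

# Sum of a logical matrix over each pixel's 3x3 neighborhood (zero padding).
neighbor_sum3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  x <- matrix(0, h + 2L, w + 2L)
  x[2:(h + 1L), 2:(w + 1L)] <- as.numeric(m)
  out <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2) {
    out <- out + x[(1L + dr):(h + dr), (1L + dc):(w + dc), drop = FALSE]
  }
  out
}
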