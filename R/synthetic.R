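#' Configuration for the synthetic radiograph generator
#'
#' The generator emulates a frontal (anteroposterior) tibiofemoral radiograph
#' at desk scale: two bright horizontal bone bands (femur above, tibia below)
#' separated by a dark joint-space gap whose width in pixels shrinks
#' monotonically with Kellgren-Lawrence grade. Higher grades additionally show
#' osteophyte-like bright blobs at the lateral gap margins and a subchondral
#' sclerosis band (a brighter strip of bone adjacent to the gap). Additive
#' Gaussian noise models detector noise.
#'
#' The joint-space-width (JSW) ranges are free parameters of the generator,
#' not radiological claims; the defaults give five disjoint, strictly ordered
#' ranges so the classes are separable but adjacent.
#'
#' @param image_height,image_width image size in pixels.
#' @param jsw_by_grade named list mapping each grade to an integer
#'   `c(min, max)` gap-width range in pixels. Ranges must be disjoint and
#'   strictly decreasing from `Healthy` to `GradeIV`.
#' @param osteophyte_prob_by_grade named numeric vector of per-margin
#'   osteophyte probabilities in `[0, 1]`.
#' @param noise_sigma standard deviation of additive Gaussian intensity noise.
#' @param bone_intensity,gap_intensity mean intensities (0-255) of bone and
#'   joint gap; bone must be brighter (radio-opaque).
#' @param roi_height,roi_width size in pixels of the ground-truth region of
#'   interest bracketing the joint gap.
#' @param seed integer seed controlling all stochasticity of
#'   [generate_dataset()] through a single stream.
#' @return an object of class `koa_synth_config`.
#' @seealso [generate_image()], [generate_dataset()]
#' @export
synth_config <- function(image_height = 200L,
                         image_width = 200L,
                         jsw_by_grade = list(Healthy  = c(16L, 20L),
                                             GradeI   = c(12L, 15L),
                                             GradeII  = c(8L, 11L),
                                             GradeIII = c(4L, 7L),
                                             GradeIV  = c(1L, 3L)),
                         osteophyte_prob_by_grade = c(Healthy = 0, GradeI = 0.2,
                                                      GradeII = 0.5,
                                                      GradeIII = 0.8,
                                                      GradeIV = 0.95),
                         noise_sigma = 8,
                         bone_intensity = 200,
                         gap_intensity = 40,
                         roi_height = 48L,
                         roi_width = 120L,
                         seed = 1L) {
  lv <- grade_levels()
  if (!setequal(names(jsw_by_grade), lv)) {
    stop("`jsw_by_grade` must name all five grades", call. = FALSE)
  }
  if (!setequal(names(osteophyte_prob_by_grade), lv)) {
    stop("`osteophyte_prob_by_grade` must name all five grades", call. = FALSE)
  }
  jsw <- lapply(jsw_by_grade[lv], function(r) as.integer(round(r)))
  for (r in jsw) {
    if (length(r) != 2L || r[1] < 1L || r[2] < r[1]) {
      stop("each JSW range must be c(min, max) with 1 <= min <= max",
           call. = FALSE)
    }
  }
  # disjoint + strictly decreasing with severity: min of each grade must
  # exceed the max of the next
  for (i in seq_len(length(lv) - 1L)) {
    if (jsw[[i]][1] <= jsw[[i + 1L]][2]) {
      stop("JSW ranges must be disjoint and strictly decreasing with grade",
           call. = FALSE)
    }
  }
  op <- osteophyte_prob_by_grade[lv]
  if (any(op < 0 | op > 1)) stop("osteophyte probabilities must lie in [0,1]",
                                 call. = FALSE)
  if (bone_intensity <= gap_intensity) {
    stop("`bone_intensity` must exceed `gap_intensity` (bone is radio-opaque)",
         call. = FALSE)
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  image_height <- as.integer(image_height)
  image_width <- as.integer(image_width)
  roi_height <- as.integer(roi_height)
  roi_width <- as.integer(roi_width)
  max_jsw <- jsw[["Healthy"]][2]
  if (roi_height <= max_jsw + 4L || roi_height > image_height ||
      roi_width > image_width) {
    stop("ROI must fit in the image and bracket the widest gap", call. = FALSE)
  }
  structure(list(image_height = image_height, image_width = image_width,
                 jsw_by_grade = jsw, osteophyte_prob_by_grade = op,
                 noise_sigma = noise_sigma, bone_intensity = bone_intensity,
                 gap_intensity = gap_intensity, roi_height = roi_height,
                 roi_width = roi_width, seed = as.integer(seed)),
            class = "koa_synth_config")
}

#' Generate one synthetic labeled knee radiograph
#'
#' Draws a joint-space width from the configured range for `label`, renders
#' the two-band bone/gap geometry with grade-dependent osteophytes and
#' sclerosis, and adds clipped Gaussian noise. The function consumes the
#' calling RNG stream: seed it with `set.seed()` (or use
#' [generate_dataset()], which seeds from `config$seed`).
#'
#' @param config a [synth_config()] object.
#' @param label one of [grade_levels()].
#' @return an object of class `koa_image`: a list with `image` (numeric
#'   matrix, integer-valued 0-255), `label` (factor), `true_roi`
#'   ([roi_box()], gap-centered) and `true_jsw` (pixels).
#' @export
generate_image <- function(config, label) {
  stopifnot(inherits(config, "koa_synth_config"))
  label <- as_grade(label)
  if (is.na(label) || length(label) != 1L) stop("invalid label", call. = FALSE)
  h <- config$image_height
  w <- config$image_width
  rng <- config$jsw_by_grade[[as.character(label)]]
  jsw <- if (rng[1] == rng[2]) rng[1] else
    sample(seq.int(rng[1], rng[2]), 1L)

  # gap position: vertical jitter around mid-height, horizontal ROI jitter
  jit_r <- sample(-10:10, 1L)
  jit_c <- sample(-8:8, 1L)
  gap_top <- h %/% 2L - jsw %/% 2L + jit_r        # 1-based first gap row
  gap_bot <- gap_top + jsw - 1L

  # ground-truth ROI: gap centered vertically, jittered horizontally
  roi_r0 <- gap_top + (jsw - 1L) %/% 2L - config$roi_height %/% 2L  # 1-based
  roi_c0 <- (w - config$roi_width) %/% 2L + 1L + jit_c
  roi_r0 <- max(1L, min(roi_r0, h - config$roi_height + 1L))
  roi_c0 <- max(1L, min(roi_c0, w - config$roi_width + 1L))

  # knee silhouette: the bone columns span the ROI width, flanked by dark
  # soft-tissue/air margins (what anchors template matching horizontally)
  anat <- roi_c0:(roi_c0 + config$roi_width - 1L)
  img <- matrix(15, h, w)
  img[, anat] <- config$bone_intensity
  img[gap_top:gap_bot, anat] <- config$gap_intensity

  # subchondral sclerosis: brighter bone strip hugging the gap (grades III-IV)
  if (label %in% c("GradeIII", "GradeIV")) {
    depth <- 5L
    above <- max(1L, gap_top - depth):(gap_top - 1L)
    below <- (gap_bot + 1L):min(h, gap_bot + depth)
    img[above, anat] <- img[above, anat] + 20
    img[below, anat] <- img[below, anat] + 20
  }

  # osteophytes: truncated Gaussian bright blobs at the four lateral gap
  # margins (offset from mid-column so the center JSW profile stays clean)
  p <- config$osteophyte_prob_by_grade[[as.character(label)]]
  blob_rows <- c(gap_top - 2L, gap_bot + 2L)
  blob_cols <- c(roi_c0 + 4L, roi_c0 + config$roi_width - 5L)
  sigma_b <- 3
  rad <- 9L
  for (br in blob_rows) {
    for (bc in blob_cols) {
      if (runif(1L) < p) {
        rr <- max(1L, br - rad):min(h, br + rad)
        cc <- max(1L, bc - rad):min(w, bc + rad)
        d2 <- outer((rr - br)^2, (cc - bc)^2, "+")
        img[rr, cc] <- img[rr, cc] + 55 * exp(-d2 / (2 * sigma_b^2))
      }
    }
  }

  if (config$noise_sigma > 0) {
    img <- img + matrix(rnorm(h * w, 0, config$noise_sigma), h, w)
  }
  img[] <- round(pmin(255, pmax(0, img)))

  structure(list(image = img,
                 label = label,
                 true_roi = roi_box(roi_r0 - 1L, roi_c0 - 1L,
                                    config$roi_height, config$roi_width),
                 true_jsw = jsw),
            class = "koa_image")
}

#' Generate a balanced, seeded synthetic dataset
#'
#' Produces `n_per_class` images for each of the five grades, class-blocked
#' in severity order (`Healthy` first). All randomness flows through a single
#' stream seeded from `config$seed`, so a given configuration reproduces
#' bit-identical pixel data.
#'
#' @inheritParams generate_image
#' @param n_per_class number of images per grade (>= 1).
#' @return a list of `5 * n_per_class` [generate_image()] objects with the
#'   configuration attached as attribute `config`.
#' @export
generate_dataset <- function(config, n_per_class) {
  stopifnot(inherits(config, "koa_synth_config"))
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stop("`n_per_class` must be >= 1", call. = FALSE)
  out <- with_seed(config$seed, {
    unlist(lapply(grade_levels(), function(lv) {
      lapply(seq_len(n_per_class), function(i) generate_image(config, lv))
    }), recursive = FALSE)
  })
  attr(out, "config") <- config
  out
}

#' @rdname generate_dataset
#' @param dataset a list of `koa_image` objects.
#' @return `dataset_labels()` returns the factor of grade labels.
#' @export
dataset_labels <- function(dataset) {
  as_grade(vapply(dataset, function(im) as.character(im$label), character(1)))
}

#' Measure the joint-space width by a vertical column scan
#'
#' Counts the longest run of below-threshold pixels in one image column -- the
#' 1-D profile a radiologist's caliper would see on the two-band phantom. On a
#' noiseless generated image the mid-column scan recovers the true JSW exactly.
#'
#' @param image a numeric intensity matrix.
#' @param column column to scan (1-based); default the middle column.
#' @param threshold intensity below which a pixel counts as joint gap.
#' @return integer run length (0 if no pixel is below threshold).
#' @export
measure_jsw <- function(image, column = NULL, threshold = 128) {
  assert_gray(image, "image")
  if (is.null(column)) column <- (ncol(image) + 1L) %/% 2L
  dark <- image[, column] < threshold
  if (!any(dark)) return(0L)
  runs <- rle(dark)
  max(runs$lengths[runs$values])
}

#' Write a synthetic dataset to disk
#'
#' Writes each image as an 8-bit grayscale TIFF (or PNG) plus a
#' `manifest.csv` with columns `filename, label, roi_row, roi_col, roi_h,
#' roi_w, jsw` (ROI coordinates 0-based, as everywhere in the package).
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if absent).
#' @param format `"tiff"` or `"png"`.
#' @return invisibly, the manifest data frame.
#' @export
write_dataset <- function(dataset, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "tiff") "tif" else "png"
  rows <- lapply(seq_along(dataset), function(i) {
    im <- dataset[[i]]
    fn <- sprintf("img_%04d_%s.%s", i, as.character(im$label), ext)
    save_image(im$image, file.path(dir, fn))
    data.frame(filename = fn, label = as.character(im$label),
               roi_row = im$true_roi$row, roi_col = im$true_roi$col,
               roi_h = im$true_roi$height, roi_w = im$true_roi$width,
               jsw = im$true_jsw, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
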