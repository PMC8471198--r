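# Independent brute-force oracles, written as plain nested loops against the
# documented conventions. They deliberately share no code with the package
# implementations they check.

# Longest run of below-threshold pixels in one column.
oracle_jsw <- function(image, column, threshold = 128) {
  best <- 0L
  run <- 0L
  for (r in seq_len(nrow(image))) {
    if (image[r, column] < threshold) {
      run <- run + 1L
      if (run > best) best <- run
    } else {
      run <- 0L
    }
  }
  best
}

# Valid-mode cross-correlation with bias, four explicit loops.
oracle_conv <- function(image, kernel, bias = 0) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  ho <- nrow(image) - kh + 1L
  wo <- ncol(image) - kw + 1L
  out <- matrix(0, ho, wo)
  for (x in seq_len(ho)) {
    for (y in seq_len(wo)) {
      acc <- bias
      for (s in seq_len(kh)) {
        for (t in seq_len(kw)) {
          acc <- acc + kernel[s, t] * image[x + s - 1L, y + t - 1L]
        }
      }
      out[x, y] <- acc
    }
  }
  out
}

oracle_mad <- function(a, b) {
  s <- 0
  for (l in seq_along(a)) s <- s + abs(a[l] - b[l])
  s / length(a)
}

# LBP code of every interior pixel; neighbor tables re-stated by hand from
# the documented clockwise-from-top-left ring convention.
oracle_lbp_codes <- function(image, k) {
  off <- switch(as.character(k),
    "8" = list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1)),
    "4" = list(c(-1, -1), c(-1, 1), c(1, 1), c(1, -1)),
    "16" = list(c(-2, -2), c(-2, -1), c(-2, 0), c(-2, 1), c(-2, 2),
                c(-1, 2), c(0, 2), c(1, 2),
                c(2, 2), c(2, 1), c(2, 0), c(2, -1), c(2, -2),
                c(1, -2), c(0, -2), c(-1, -2)))
  r <- max(abs(unlist(off)))
  h <- nrow(image); w <- ncol(image)
  out <- matrix(0, h - 2L * r, w - 2L * r)
  for (i in (r + 1L):(h - r)) {
    for (j in (r + 1L):(w - r)) {
      code <- 0
      for (b in seq_along(off)) {
        p <- image[i + off[[b]][1], j + off[[b]][2]]
        if (p >= image[i, j]) code <- code + 2^(b - 1)
      }
      out[i - r, j - r] <- code
    }
  }
  out
}

# Full HOG pipeline as explicit loops: centered-difference gradients
# (one-sided at borders), unsigned orientation in [0, 180), linear votes
# between bin centers at (b + 0.5) * 180/nbins, cell histograms, 2x2-cell
# blocks with L2 normalization (eps = 1e-12 inside the root).
oracle_hog <- function(im, cell = 4L, block = 2L, stride_px = 4L, nbins = 9L) {
  h <- nrow(im); w <- ncol(im)
  gx <- gy <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      gx[r, c] <- if (c == 1L) im[r, 2L] - im[r, 1L]
        else if (c == w) im[r, w] - im[r, w - 1L]
        else (im[r, c + 1L] - im[r, c - 1L]) / 2
      gy[r, c] <- if (r == 1L) im[2L, c] - im[1L, c]
        else if (r == h) im[h, c] - im[h - 1L, c]
        else (im[r + 1L, c] - im[r - 1L, c]) / 2
    }
  }
  nc_r <- h %/% cell; nc_c <- w %/% cell
  hist <- array(0, c(nc_r, nc_c, nbins))
  binw <- 180 / nbins
  for (r in seq_len(nc_r * cell)) {
    for (c in seq_len(nc_c * cell)) {
      m <- sqrt(gx[r, c]^2 + gy[r, c]^2)
      if (m == 0) next
      ang <- atan2(gy[r, c], gx[r, c]) * 180 / pi
      ang <- ang - 180 * floor(ang / 180)
      if (ang >= 180) ang <- 0
      tt <- ang / binw - 0.5
      b0 <- floor(tt)
      w1 <- tt - b0
      bin0 <- (b0 %% nbins) + 1L
      bin1 <- ((b0 + 1) %% nbins) + 1L
      ci <- (r - 1L) %/% cell + 1L
      cj <- (c - 1L) %/% cell + 1L
      hist[ci, cj, bin0] <- hist[ci, cj, bin0] + m * (1 - w1)
      hist[ci, cj, bin1] <- hist[ci, cj, bin1] + m * w1
    }
  }
  sc <- stride_px %/% cell
  nb_r <- (nc_r - block) %/% sc + 1L
  nb_c <- (nc_c - block) %/% sc + 1L
  out <- numeric(0)
  for (br in seq_len(nb_r)) {
    for (bc in seq_len(nb_c)) {
      v <- numeric(0)
      for (i in 0:(block - 1L)) {
        for (j in 0:(block - 1L)) {
          v <- c(v, hist[(br - 1L) * sc + i + 1L, (bc - 1L) * sc + j + 1L, ])
        }
      }
      out <- c(out, v / sqrt(sum(v^2) + 1e-12))
    }
  }
  out
}

# Binary confusion counting by a per-sample loop.
oracle_collapse <- function(true, pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(true)) {
    td <- true[i] != "Healthy"
    pd <- pred[i] != "Healthy"
    if (td && pd) tp <- tp + 1L
    else if (!td && !pd) tn <- tn + 1L
    else if (!td && pd) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Small random test image with values in [0, 255].
random_image <- function(h, w) {
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}
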