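#' Specification of the small CNN feature descriptor
#'
#' A five-stage convolutional stack over 50x50 grayscale input:
#' `conv(20 filters, 5x5)` -> `maxpool 2x2` -> `conv(32 filters, 4x4)` ->
#' `maxpool 2x2` -> rectifier -> `conv(40 filters, 4x4x32)` ->
#' global average pool -> dense softmax over the five grades. The CNN
#' *feature vector* is the global-average-pooled activation of the last
#' convolution (length `conv3_filters`, default 40); the softmax head is
#' used only to train the weights.
#'
#' All sizes are configurable; the defaults give the map sizes
#' 46x46x20 -> 23x23x20 -> 20x20x32 -> 10x10x32 -> 7x7x40.
#'
#' @param input_size input image size `c(rows, cols)`.
#' @param conv1_filters,conv1_kernel first convolution: number of filters
#'   and square kernel side.
#' @param conv2_filters,conv2_kernel second convolution.
#' @param conv3_filters,conv3_kernel final (feature) convolution.
#' @param pool max-pooling window and stride.
#' @param n_classes softmax classes (the five KL grades).
#' @param seed integer seed for weight initialization and epoch shuffling.
#' @return an object of class `koa_cnn_spec`.
#' @export
cnn_spec <- function(input_size = c(50L, 50L),
                     conv1_filters = 20L, conv1_kernel = 5L,
                     conv2_filters = 32L, conv2_kernel = 4L,
                     conv3_filters = 40L, conv3_kernel = 4L,
                     pool = 2L, n_classes = 5L, seed = 1L) {
  input_size <- as.integer(rep(input_size, length.out = 2L))
  spec <- list(input_size = input_size,
               conv1_filters = as.integer(conv1_filters),
               conv1_kernel = as.integer(conv1_kernel),
               conv2_filters = as.integer(conv2_filters),
               conv2_kernel = as.integer(conv2_kernel),
               conv3_filters = as.integer(conv3_filters),
               conv3_kernel = as.integer(conv3_kernel),
               pool = as.integer(pool), n_classes = as.integer(n_classes),
               seed = as.integer(seed))
  g <- cnn_geometry(spec)   # validates divisibility/positivity
  spec$feature_length <- spec$conv3_filters
  structure(spec, class = "koa_cnn_spec", geometry = g)
}

# Layer-by-layer map sizes; errors if the architecture is inconsistent.
cnn_geometry <- function(spec) {
  s1 <- spec$input_size - spec$conv1_kernel + 1L
  if (any(s1 < 1L)) stop("conv1 kernel larger than input", call. = FALSE)
  if (any(s1 %% spec$pool != 0L)) {
    stop("conv1 output not divisible by pool size", call. = FALSE)
  }
  p1 <- s1 %/% spec$pool
  s2 <- p1 - spec$conv2_kernel + 1L
  if (any(s2 < 1L)) stop("conv2 kernel larger than its input", call. = FALSE)
  if (any(s2 %% spec$pool != 0L)) {
    stop("conv2 output not divisible by pool size", call. = FALSE)
  }
  p2 <- s2 %/% spec$pool
  s3 <- p2 - spec$conv3_kernel + 1L
  if (any(s3 < 1L)) stop("conv3 kernel larger than its input", call. = FALSE)
  list(s1 = s1, p1 = p1, s2 = s2, p2 = p2, s3 = s3)
}

# im2col index matrix: rows = output pixels (column-major), cols = kernel
# elements (s, t) column-major; entries are linear indices into the input
# plane. Output pixel (r, c) with kernel element (s, t) reads input
# (r + s - 1, c + t - 1) -- valid-mode cross-correlation.
im2col_idx <- function(h_in, w_in, k) {
  ho <- h_in - k + 1L
  wo <- w_in - k + 1L
  r <- rep(seq_len(ho), times = wo)
  c <- rep(seq_len(wo), each = ho)
  idx <- matrix(0L, ho * wo, k * k)
  j <- 1L
  for (t in seq_len(k)) {
    for (s in seq_len(k)) {
      idx[, j] <- (r + s - 1L) + (c + t - 2L) * h_in
      j <- j + 1L
    }
  }
  idx
}

# Pool index matrix: rows = output pixels, 4 columns = the 2x2 input pixels
# (generalizes to pool p: p^2 columns).
pool_idx <- function(h_in, w_in, p) {
  ho <- h_in %/% p
  wo <- w_in %/% p
  r <- rep(seq_len(ho), times = wo)
  c <- rep(seq_len(wo), each = ho)
  idx <- matrix(0L, ho * wo, p * p)
  j <- 1L
  for (t in seq_len(p)) {
    for (s in seq_len(p)) {
      idx[, j] <- ((r - 1L) * p + s) + ((c - 1L) * p + t - 1L) * h_in
      j <- j + 1L
    }
  }
  idx
}

# X: (npix_in x ch_in) activation matrix -> (npix_out x k^2*ch_in)
im2col_apply <- function(X, idx) {
  M <- X[as.vector(idx), , drop = FALSE]
  dim(M) <- c(nrow(idx), ncol(idx) * ncol(X))
  M
}

# Scatter-add the im2col gradient back onto the input plane.
col2im_apply <- function(dM, idx, npix_in, ch_in) {
  kk <- ncol(idx)
  G <- matrix(0, npix_in, ch_in)
  gidx <- as.vector(idx)
  for (ch in seq_len(ch_in)) {
    sub <- dM[, ((ch - 1L) * kk + 1L):(ch * kk), drop = FALSE]
    rs <- rowsum(as.vector(sub), gidx)
    G[as.integer(rownames(rs)), ch] <- rs
  }
  G
}

pool_forward <- function(Z, pidx) {
  out <- Z[pidx[, 1L], , drop = FALSE]
  for (j in 2L:ncol(pidx)) {
    out <- pmax(out, Z[pidx[, j], , drop = FALSE])
  }
  out
}

# Routes gradient to every input attaining the window maximum (ties are
# vanishingly rare with continuous weights and resolved deterministically).
pool_backward <- function(dP, Z, P, pidx) {
  G <- matrix(0, nrow(Z), ncol(Z))
  for (j in seq_len(ncol(pidx))) {
    sel <- Z[pidx[, j], , drop = FALSE] == P
    G[pidx[, j], ] <- G[pidx[, j], ] + dP * sel
  }
  G
}

cnn_setup <- function(spec) {
  g <- attr(spec, "geometry")
  list(g = g,
       idx1 = im2col_idx(spec$input_size[1], spec$input_size[2],
                         spec$conv1_kernel),
       pidx1 = pool_idx(g$s1[1], g$s1[2], spec$pool),
       idx2 = im2col_idx(g$p1[1], g$p1[2], spec$conv2_kernel),
       pidx2 = pool_idx(g$s2[1], g$s2[2], spec$pool),
       idx3 = im2col_idx(g$p2[1], g$p2[2], spec$conv3_kernel))
}

cnn_init_weights <- function(spec) {
  he <- function(fan_in, n) rnorm(n) * sqrt(2 / fan_in)
  k1 <- spec$conv1_kernel^2
  k2 <- spec$conv2_kernel^2 * spec$conv1_filters
  k3 <- spec$conv3_kernel^2 * spec$conv2_filters
  list(W1 = matrix(he(k1, k1 * spec$conv1_filters), k1, spec$conv1_filters),
       b1 = numeric(spec$conv1_filters),
       W2 = matrix(he(k2, k2 * spec$conv2_filters), k2, spec$conv2_filters),
       b2 = numeric(spec$conv2_filters),
       W3 = matrix(he(k3, k3 * spec$conv3_filters), k3, spec$conv3_filters),
       b3 = numeric(spec$conv3_filters),
       W4 = matrix(he(spec$conv3_filters,
                      spec$conv3_filters * spec$n_classes),
                   spec$conv3_filters, spec$n_classes),
       b4 = numeric(spec$n_classes))
}

add_bias <- function(Z, b) Z + matrix(b, nrow(Z), length(b), byrow = TRUE)

# Full forward pass on one [0,1]-scaled input vector; returns activations
# needed for backprop (or just the feature/probabilities).
cnn_forward <- function(x, wts, su) {
  M1 <- im2col_apply(matrix(x, ncol = 1L), su$idx1)
  Z1 <- add_bias(M1 %*% wts$W1, wts$b1)
  P1 <- pool_forward(Z1, su$pidx1)
  M2 <- im2col_apply(P1, su$idx2)
  Z2 <- add_bias(M2 %*% wts$W2, wts$b2)
  P2 <- pool_forward(Z2, su$pidx2)
  A2 <- pmax(P2, 0)
  M3 <- im2col_apply(A2, su$idx3)
  Z3 <- add_bias(M3 %*% wts$W3, wts$b3)
  f <- colMeans(Z3)
  logits <- as.numeric(f %*% wts$W4) + wts$b4
  logits <- logits - max(logits)
  p <- exp(logits) / sum(exp(logits))
  list(M1 = M1, Z1 = Z1, P1 = P1, M2 = M2, Z2 = Z2, P2 = P2, A2 = A2,
       M3 = M3, Z3 = Z3, f = f, p = p)
}

cnn_backward <- function(fw, y_onehot, wts, su) {
  n3 <- nrow(fw$Z3)
  dlog <- fw$p - y_onehot
  dW4 <- outer(fw$f, dlog)
  db4 <- dlog
  df <- as.numeric(wts$W4 %*% dlog)
  dZ3 <- matrix(df / n3, n3, length(df), byrow = TRUE)
  dW3 <- crossprod(fw$M3, dZ3)
  db3 <- colSums(dZ3)
  dM3 <- dZ3 %*% t(wts$W3)
  dA2 <- col2im_apply(dM3, su$idx3, nrow(fw$P2), ncol(fw$P2))
  dP2 <- dA2 * (fw$P2 > 0)
  dZ2 <- pool_backward(dP2, fw$Z2, fw$P2, su$pidx2)
  dW2 <- crossprod(fw$M2, dZ2)
  db2 <- colSums(dZ2)
  dM2 <- dZ2 %*% t(wts$W2)
  dP1 <- col2im_apply(dM2, su$idx2, nrow(fw$P1), ncol(fw$P1))
  dZ1 <- pool_backward(dP1, fw$Z1, fw$P1, su$pidx1)
  dW1 <- crossprod(fw$M1, dZ1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

# Scale an image to the CNN input: resize to input_size, intensities to [0,1].
cnn_input <- function(image, spec) {
  if (nrow(image) != spec$input_size[1] || ncol(image) != spec$input_size[2]) {
    image <- resize_bilinear_cpp(image, spec$input_size[1], spec$input_size[2])
  }
  as.vector(image) / 255
}

#' Train the CNN feature descriptor
#'
#' Trains the [cnn_spec()] stack with softmax cross-entropy over the grade
#' labels by mini-batch stochastic gradient descent with momentum. Training
#' is deterministic under `spec$seed`: weight initialization and the
#' per-epoch shuffle come from one seeded stream, so two runs with the same
#' inputs produce bit-identical weights.
#'
#' @param images list of intensity matrices (resized internally to the CNN
#'   input size).
#' @param labels grade labels, one per image; at least two distinct classes.
#' @param spec a [cnn_spec()].
#' @param epochs number of passes over the data.
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param batch_size mini-batch size.
#' @return an object of class `koa_cnn`: spec, trained weights, per-epoch
#'   mean cross-entropy `loss_history`, and the class levels.
#' @export
train_cnn <- function(images, labels, spec = cnn_spec(), epochs = 10L,
                      lr = 0.01, momentum = 0.9, batch_size = 16L) {
  stopifnot(inherits(spec, "koa_cnn_spec"))
  labels <- as_grade(labels)
  if (length(images) != length(labels)) {
    stop("`images` and `labels` lengths differ", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("training needs at least two distinct classes", call. = FALSE)
  }
  su <- cnn_setup(spec)
  xs <- lapply(images, cnn_input, spec = spec)
  yi <- as.integer(labels)
  n <- length(xs)
  ncl <- spec$n_classes
  eye <- diag(ncl)

  with_seed(spec$seed, {
    wts <- cnn_init_weights(spec)
    vel <- lapply(wts, function(w) w * 0)
    loss_history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        batch <- ord[start:min(start + batch_size - 1L, n)]
        grads <- NULL
        for (i in batch) {
          fw <- cnn_forward(xs[[i]], wts, su)
          ep_loss <- ep_loss - log(max(fw$p[yi[i]], 1e-12))
          g <- cnn_backward(fw, eye[yi[i], ], wts, su)
          grads <- if (is.null(grads)) g else Map(`+`, grads, g)
        }
        nb <- length(batch)
        for (nm in names(wts)) {
          vel[[nm]] <- momentum * vel[[nm]] - lr * grads[[nm]] / nb
          wts[[nm]] <- wts[[nm]] + vel[[nm]]
        }
      }
      loss_history[ep] <- ep_loss / n
    }
    structure(list(spec = spec, weights = wts, loss_history = loss_history,
                   classes = levels(labels)),
              class = "koa_cnn")
  })
}

#' CNN feature vector of an image
#'
#' Forward pass of a trained (or freshly initialized) network up to the
#' feature tap: the global average pool of the last convolution's
#' activation map.
#'
#' @param image intensity matrix.
#' @param model a `koa_cnn` from [train_cnn()].
#' @return a `koa_features` vector of kind `"CNN"`, length
#'   `spec$conv3_filters`.
#' @export
cnn_features <- function(image, model) {
  stopifnot(inherits(model, "koa_cnn"))
  su <- cnn_setup(model$spec)
  fw <- cnn_forward(cnn_input(image, model$spec), model$weights, su)
  feature_vector(fw$f, "CNN")
}

#' @rdname cnn_features
#' @return `cnn_probs()` returns the softmax class probabilities (they sum
#'   to one for any input and any weights).
#' @export
cnn_probs <- function(image, model) {
  stopifnot(inherits(model, "koa_cnn"))
  su <- cnn_setup(model$spec)
  fw <- cnn_forward(cnn_input(image, model$spec), model$weights, su)
  stats::setNames(fw$p, model$classes)
}

#' @rdname cnn_features
#' @param spec a [cnn_spec()].
#' @return `cnn_untrained()` returns a `koa_cnn` with seeded initial
#'   weights and no training (useful for architecture checks).
#' @export
cnn_untrained <- function(spec = cnn_spec()) {
  wts <- with_seed(spec$seed, cnn_init_weights(spec))
  structure(list(spec = spec, weights = wts, loss_history = numeric(0),
                 classes = grade_levels()),
            class = "koa_cnn")
}
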