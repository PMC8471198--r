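test_that("HOG has the configured length and nonnegative entries", {
  v <- hog_features(random_image(28, 28))
  expect_length(v, 1296L)
  expect_identical(feature_kind(v), "HOG")
  expect_true(all(v >= 0))
  # resizing happens internally for off-size inputs
  expect_length(hog_features(random_image(48, 120)), 1296L)
  # constant image has zero gradients everywhere
  expect_true(all(hog_features(matrix(100, 28, 28)) == 0))
  expect_error(hog_params(resize_to = c(6, 6), cell_size = 4,
                          block_cells = 2), "smaller than one block")
})

test_that("HOG length formula holds across random geometries", {
  set.seed(1)
  for (i in 1:15) {
    cell <- sample(2:5, 1)
    block <- sample(1:3, 1)
    stride <- cell * sample(1:2, 1)
    size <- sample((block * cell + stride):(8 * cell), 2, replace = TRUE)
    p <- hog_params(resize_to = size, cell_size = cell, block_cells = block,
                    block_stride = stride)
    v <- hog_features(random_image(size[1], size[2]), p)
    sc <- stride %/% cell
    nb <- (size %/% cell - block) %/% sc + 1L
    expect_length(v, nb[1] * nb[2] * block^2 * 9L)
    expect_identical(length(v), as.integer(hog_length(p)))
  }
})

test_that("HOG is invariant to global intensity shifts", {
  img <- random_image(28, 28)
  img[img > 225] <- 225
  expect_equal(as.numeric(hog_features(img)),
               as.numeric(hog_features(img + 30)), tolerance = 1e-12)
})

test_that("HOG agrees with the loop oracle on random images", {
  set.seed(2)
  for (i in 1:8) {
    img <- random_image(28, 28)
    expect_equal(as.numeric(hog_features(img)), oracle_hog(img),
                 tolerance = 1e-12)
  }
  # non-default geometry too
  p <- hog_params(resize_to = c(18, 15), cell_size = 3, block_cells = 2,
                  block_stride = 3)
  img <- random_image(18, 15)
  expect_equal(as.numeric(hog_features(img, p)),
               oracle_hog(img, cell = 3L, block = 2L, stride_px = 3L),
               tolerance = 1e-12)
})

test_that("LBP codes follow the clockwise-from-top-left convention", {
  patch <- matrix(1:9, 3, 3, byrow = TRUE)
  # neighbors clockwise from top-left: 1,2,3,6,9,8,7,4 vs center 5
  # bits >= 5: positions 4..7 -> 8 + 16 + 32 + 64 = 120
  expect_equal(lbp_codes(patch, 8)[1, 1], 120)
  expect_equal(lbp_codes(patch, 8), oracle_lbp_codes(patch, 8))

  # constant image: every comparison is >= so every bit is set
  cst <- matrix(7, 6, 6)
  expect_true(all(lbp_codes(cst, 8) == 255))
  h <- lbp_features(cst, 8)
  expect_equal(h[256], 1)
  expect_equal(sum(h), 1)
  expect_identical(attr(h, "n_pixels"), 16L)
})

test_that("LBP histogram length is 2^k and codes stay in range", {
  expect_length(lbp_features(random_image(8, 8), 16), 65536L)
  expect_length(lbp_features(random_image(5, 5), 4), 16L)
  codes <- lbp_codes(random_image(9, 9), 16)
  expect_true(all(codes >= 0 & codes < 65536))
  expect_error(lbp_features(random_image(8, 8), 5), "4, 8, 16")
  expect_error(lbp_codes(matrix(0, 2, 2), 8), "too small")
})

test_that("LBP is invariant under strictly increasing transforms", {
  set.seed(3)
  img <- random_image(12, 12)
  f1 <- lbp_features(img, 8)
  expect_equal(as.numeric(f1), as.numeric(lbp_features(img / 2 + 10, 8)))
  expect_equal(as.numeric(f1), as.numeric(lbp_features(sqrt(img) * 15, 8)))
})

test_that("LBP agrees with the loop oracle", {
  set.seed(4)
  for (k in c(4L, 8L, 16L)) {
    img <- random_image(10, 11)
    expect_equal(lbp_codes(img, k), oracle_lbp_codes(img, k))
  }
})

test_that("convolve2d implements valid cross-correlation with bias", {
  img <- random_image(5, 5)
  expect_equal(convolve2d(img, matrix(1, 1, 1)), img, ignore_attr = TRUE)
  expect_true(all(convolve2d(img, matrix(0, 2, 2), bias = 7) == 7))
  set.seed(5)
  for (i in 1:10) {
    im <- matrix(rnorm(30), 5, 6)
    kh <- sample(1:3, 1)
    kw <- sample(1:2, 1)
    k <- matrix(rnorm(kh * kw), kh, kw)
    b <- rnorm(1)
    expect_equal(convolve2d(im, k, b), oracle_conv(im, k, b),
                 tolerance = 1e-12)
  }
  expect_error(convolve2d(matrix(0, 2, 2), matrix(0, 3, 3)), "larger")
})

test_that("fusion concatenates values and canonicalizes kinds", {
  cnn <- feature_vector(rnorm(40), "CNN")
  hog <- feature_vector(abs(rnorm(1296)), "HOG")
  lbp <- feature_vector(abs(rnorm(256)), "LBP")
  f <- fuse(list(cnn, hog))
  expect_length(f, 1336L)
  expect_identical(feature_kind(f), "HOG+CNN")
  expect_equal(as.numeric(f)[1:40], as.numeric(cnn))
  expect_identical(feature_kind(fuse(list(cnn, hog, lbp))), "HOG+LBP+CNN")
  expect_equal(as.numeric(fuse(list(hog))), as.numeric(hog))
  expect_identical(feature_kind(fuse(list(lbp, cnn))), "LBP+CNN")
  expect_error(fuse(list()), "nothing to fuse")
})

test_that("CNN training is seed-deterministic and reduces the loss", {
  cfg <- synth_config(seed = 31)
  ds <- generate_dataset(cfg, 6)
  crops <- lapply(ds, function(x) crop_roi(x$image, x$true_roi))
  labs <- dataset_labels(ds)
  spec <- cnn_spec(seed = 13)
  n1 <- train_cnn(crops, labs, spec, epochs = 5)
  n2 <- train_cnn(crops, labs, spec, epochs = 5)
  expect_identical(n1$weights, n2$weights)
  expect_identical(n1$loss_history, n2$loss_history)
  expect_lt(n1$loss_history[5], n1$loss_history[1])
  expect_error(train_cnn(crops[1:6], rep("Healthy", 6), spec),
               "two distinct classes")
})

test_that("CNN features are deterministic, length-40, and softmax is proper", {
  net <- cnn_untrained(cnn_spec(seed = 2))
  img <- random_image(50, 50)
  f1 <- cnn_features(img, net)
  f2 <- cnn_features(img, net)
  expect_identical(as.numeric(f1), as.numeric(f2))
  expect_length(f1, 40L)
  expect_identical(feature_kind(f1), "CNN")
  p <- cnn_probs(img, net)
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0))
  # zero weights with zero bias give a zero feature vector
  net0 <- net
  net0$weights <- lapply(net0$weights, function(w) w * 0)
  expect_true(all(cnn_features(img, net0) == 0))
})

test_that("the CNN map sizes follow the architecture arithmetic", {
  g <- attr(cnn_spec(), "geometry")
  expect_equal(g$s1, c(46L, 46L))
  expect_equal(g$p1, c(23L, 23L))
  expect_equal(g$s2, c(20L, 20L))
  expect_equal(g$p2, c(10L, 10L))
  expect_equal(g$s3, c(7L, 7L))
  expect_error(cnn_spec(input_size = c(49, 49)), "not divisible")
})
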