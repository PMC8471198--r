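# Small separable feature clouds for classifier behavior tests.
make_clouds <- function(n_per_class = 8, d = 6, sep = 6, sd = 0.5,
                        classes = grade_levels()) {
  set.seed(99)
  x <- do.call(rbind, lapply(seq_along(classes), function(i) {
    matrix(rnorm(n_per_class * d, mean = i * sep, sd = sd), n_per_class, d)
  }))
  list(x = x, y = as_grade(rep(classes, each = n_per_class)))
}

test_that("KNN with k = 1 memorizes distinct training points", {
  cl <- make_clouds()
  m <- train_classifier(cl$x, cl$y, "KNN")
  expect_identical(predict(m, cl$x), cl$y)
  # a duplicated training vector keeps its training label
  expect_identical(as.character(predict(m, cl$x[3, , drop = FALSE])),
                   as.character(cl$y[3]))
})

test_that("SVM separates linearly separable clouds perfectly", {
  cl <- make_clouds()
  m <- train_classifier(cl$x, cl$y, "SVM")
  expect_identical(predict(m, cl$x), cl$y)
})

test_that("RF is bit-reproducible under a fixed seed", {
  cl <- make_clouds(n_per_class = 10)
  test_idx <- seq(1, 50, by = 5)
  m1 <- train_classifier(cl$x[-test_idx, ], cl$y[-test_idx], "RF", seed = 7)
  m2 <- train_classifier(cl$x[-test_idx, ], cl$y[-test_idx], "RF", seed = 7)
  expect_identical(predict(m1, cl$x[test_idx, ]),
                   predict(m2, cl$x[test_idx, ]))
})

test_that("SVM and KNN predictions are invariant to training order", {
  cl <- make_clouds()
  perm <- sample(length(cl$y))
  probe <- cl$x + 0.1
  for (algo in c("SVM", "KNN")) {
    m1 <- train_classifier(cl$x, cl$y, algo)
    m2 <- train_classifier(cl$x[perm, ], cl$y[perm], algo)
    expect_identical(predict(m1, probe), predict(m2, probe))
  }
})

test_that("models round-trip through serialization unchanged", {
  cl <- make_clouds()
  probe <- cl$x + 0.2
  for (algo in c("SVM", "KNN", "RF")) {
    m <- train_classifier(cl$x, cl$y, algo, seed = 3)
    path <- withr::local_tempfile(fileext = ".rds")
    save_model(m, path)
    expect_true(file.exists(paste0(path, ".json")))
    m2 <- load_model(path)
    expect_identical(predict(m, probe), predict(m2, probe))
  }
})

test_that("input validation: empty predictions, dimension and class checks", {
  cl <- make_clouds()
  m <- train_classifier(cl$x, cl$y, "KNN")
  expect_length(predict(m, matrix(numeric(0), 0, 6)), 0L)
  expect_error(predict(m, matrix(0, 2, 5)), "length")
  expect_error(train_classifier(cl$x, cl$y[1:3], "KNN"), "differ")
  expect_error(train_classifier(cl$x, rep("Healthy", nrow(cl$x)), "SVM"),
               "two distinct classes")
})

test_that("feature kind mismatches are rejected", {
  feats <- lapply(1:10, function(i) {
    feature_vector(rnorm(5) + 3 * (i > 5), "HOG")
  })
  labs <- rep(c("Healthy", "GradeIV"), each = 5)
  m <- train_classifier(feats, labs, "KNN")
  expect_identical(m$feature_kind, "HOG")
  bad <- lapply(1:2, function(i) feature_vector(rnorm(5), "LBP"))
  expect_error(predict(m, bad), "kind")
})

test_that("descriptor-group weighting equalizes block contributions", {
  set.seed(8)
  n <- 20
  # informative narrow block + wide noise block
  info <- matrix(rnorm(n * 2, mean = rep(c(0, 5), each = n / 2)), n, 2)
  noise <- matrix(rnorm(n * 200), n, 200)
  x <- cbind(info, noise)
  y <- rep(c("Healthy", "GradeIV"), each = n / 2)
  groups <- rep(c("A", "B"), times = c(2, 200))
  m <- train_classifier(x, y, "KNN", feature_groups = groups)
  probe <- cbind(matrix(rnorm(10 * 2, mean = rep(c(0, 5), each = 5)), 10, 2),
                 matrix(rnorm(10 * 200), 10, 200))
  expect_identical(as.character(predict(m, probe)),
                   rep(c("Healthy", "GradeIV"), each = 5))
  expect_error(train_classifier(x, y, "KNN", feature_groups = groups[-1]),
               "one entry per feature")
})
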