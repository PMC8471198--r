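test_that("binary collapse counts positives and negatives correctly", {
  true <- c("GradeI", "GradeII", "GradeIV", "Healthy", "Healthy")
  cm <- collapse_binary(true, true)
  expect_equal(unclass(cm)[c("tp", "tn", "fp", "fn")],
               list(tp = 3L, tn = 2L, fp = 0L, fn = 0L))
  cm2 <- collapse_binary(true, rep("Healthy", 5))
  expect_equal(cm2$fn, 3L)
  expect_equal(cm2$tn, 2L)
  expect_error(collapse_binary(true, true[1:3]), "differ")

  set.seed(12)
  labs <- grade_levels()
  for (i in 1:5) {
    t <- sample(labs, 50, replace = TRUE)
    p <- sample(labs, 50, replace = TRUE)
    cm <- collapse_binary(t, p)
    o <- oracle_collapse(t, p)
    expect_equal(c(tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn), o)
    # totals conserved
    expect_equal(cm$tp + cm$fn, sum(t != "Healthy"))
    expect_equal(cm$tn + cm$fp, sum(t == "Healthy"))
  }
})

test_that("metric arithmetic is truncated, not rounded", {
  m <- metrics_paper(binary_confusion(360, 15, 37, 8))
  expect_equal(m$accuracy, 89.28)          # 89.285... floors to 89.28
  expect_equal(m$precision_paper, 97.82)   # 97.826... floors to 97.82
  expect_equal(m$recall_paper, 90.68)
  # the standard definitions are the swapped pair
  expect_equal(m$precision_std, m$recall_paper)
  expect_equal(m$recall_std, m$precision_paper)
  # degenerate all-positive case
  m2 <- metrics_paper(binary_confusion(10, 0, 0, 0))
  expect_equal(m2$accuracy, 100)
  expect_equal(m2$precision_paper, 100)
  expect_equal(m2$recall_paper, 100)
  # undefined denominators
  m3 <- metrics_paper(binary_confusion(0, 5, 0, 0))
  expect_true(is.na(m3$recall_paper))
  expect_error(metrics_paper(binary_confusion(0, 0, 0, 0)), "empty")
})

test_that("accuracy is convention-invariant; precision/recall swap with fp/fn", {
  a <- metrics_paper(binary_confusion(30, 20, 7, 3))
  # swapping the positive/negative convention maps (tp,tn,fp,fn)->(tn,tp,fn,fp)
  b <- metrics_paper(binary_confusion(20, 30, 3, 7))
  expect_equal(a$accuracy, b$accuracy)
  # transposing fp <-> fn swaps the two paper metrics
  c <- metrics_paper(binary_confusion(30, 20, 3, 7))
  expect_equal(a$precision_paper, c$recall_paper)
  expect_equal(a$recall_paper, c$precision_paper)
})

test_that("percentage splits partition each class at the stated proportions", {
  labels <- rep(grade_levels(), each = 100)
  splits <- kfold_splits(labels, paper_split_scheme(), seed = 5)
  expect_length(splits, 5L)
  train_frac <- c(50, 25, 30, 40, 20)
  for (f in seq_along(splits)) {
    tr <- splits[[f]]$train
    te <- splits[[f]]$test
    expect_length(intersect(tr, te), 0L)
    expect_setequal(c(tr, te), seq_along(labels))
    for (lv in grade_levels()) {
      expect_equal(sum(labels[tr] == lv), train_frac[f])
      expect_equal(sum(labels[te] == lv), 100 - train_frac[f])
    }
  }
  # deterministic under the seed
  splits2 <- kfold_splits(labels, paper_split_scheme(), seed = 5)
  expect_identical(splits, splits2)
  expect_error(kfold_splits(rep("Healthy", 10)), "at least 2")
  expect_error(split_scheme(list(c(60, 50))), "summing to 100")
})

test_that("classical stratified k-fold is a disjoint cover", {
  labels <- rep(grade_levels(), each = 20)
  folds <- classical_kfold(labels, k = 4, seed = 2)
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(all_test, seq_along(labels))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0L)
  }
})

test_that("evaluate_pipeline emits the full 15-row grid deterministically", {
  ds <- generate_dataset(synth_config(seed = 77), 6)
  rep1 <- evaluate_pipeline(ds, seed = 9, cnn_epochs = 1)
  expect_equal(nrow(rep1), 15L)
  expect_setequal(rep1$method, c(
    "SVM_HOG", "SVM_LBP", "SVM_CNN", "SVM_HOG_CNN", "SVM_LBP_CNN",
    "RF_HOG", "RF_LBP", "RF_CNN", "RF_HOG_CNN", "RF_LBP_CNN",
    "KNN_HOG", "KNN_LBP", "KNN_CNN", "KNN_HOG_CNN", "KNN_LBP_CNN"))
  det <- attr(rep1, "detailed")
  expect_length(det, 15L)
  expect_true(all(vapply(det, sum, numeric(1)) ==
                    sum(vapply(det, sum, numeric(1))[1])))
  # binary totals equal detailed totals per method
  bin <- attr(rep1, "binary")
  for (m in names(det)) {
    cm <- bin[[m]]
    expect_equal(cm$tp + cm$tn + cm$fp + cm$fn, sum(det[[m]]))
  }
  rep2 <- evaluate_pipeline(ds, seed = 9, cnn_epochs = 1)
  expect_identical(rep1, rep2)
})
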