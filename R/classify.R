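#' Train a multi-class grade classifier
#'
#' Fits one of the three classifiers over any feature kind: a linear
#' support vector machine (one-vs-one, `e1071::svm`), a k-nearest-neighbour
#' rule (default `k = 1`), or a random forest
#' (`randomForest::randomForest`, 100 trees). Features are z-score
#' standardized per dimension (statistics fitted on the training set only)
#' before SVM and KNN, since fused vectors mix descriptor scales;
#' the forest, invariant to monotone per-feature transforms, sees raw
#' features. The KNN rule is evaluated in-package so that distance and
#' voting ties resolve deterministically (smallest training index, then
#' smallest class index).
#'
#' @param features numeric matrix (rows = samples) or list of
#'   [feature_vector()]s of a common kind and length.
#' @param labels grade labels, one per row; at least two distinct classes.
#' @param algorithm `"SVM"`, `"KNN"` or `"RF"`.
#' @param hyperparams optional list: `cost` (SVM, default 1), `k` (KNN,
#'   default 1), `ntree` (RF, default 100).
#' @param feature_groups optional integer/character vector, one entry per
#'   feature dimension, identifying which descriptor a dimension came from
#'   in a fused vector. After z-scoring, each group's dimensions are scaled
#'   by `1/sqrt(group size)` so that every descriptor contributes equally
#'   to squared Euclidean distance regardless of its dimensionality
#'   (otherwise a 1296-dim descriptor drowns a 40-dim one in SVM/KNN).
#' @param seed integer seed (consumed by the forest; SVM and KNN are
#'   deterministic).
#' @return an object of class `koa_model`.
#' @export
train_classifier <- function(features, labels,
                             algorithm = c("SVM", "KNN", "RF"),
                             hyperparams = list(), feature_groups = NULL,
                             seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- as_feature_matrix(features)
  labels <- as_grade(labels)
  if (nrow(x) != length(labels)) {
    stop("`features` and `labels` lengths differ", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("training needs at least two distinct classes", call. = FALSE)
  }
  y <- droplevels(labels)

  center <- scale_ <- NULL
  xs <- x
  if (algorithm %in% c("SVM", "KNN")) {
    center <- colMeans(x)
    scale_ <- apply(x, 2L, sd)
    scale_[!is.finite(scale_) | scale_ == 0] <- 1
    if (!is.null(feature_groups)) {
      if (length(feature_groups) != ncol(x)) {
        stop("`feature_groups` must have one entry per feature dimension",
             call. = FALSE)
      }
      gsize <- table(feature_groups)
      scale_ <- scale_ * sqrt(as.numeric(gsize[as.character(feature_groups)]))
    }
    xs <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  }

  fit <- switch(algorithm,
    SVM = e1071::svm(x = xs, y = y, kernel = "linear",
                     cost = hyperparams$cost %||% 1, scale = FALSE),
    KNN = list(x = xs, y = y, k = as.integer(hyperparams$k %||% 1L)),
    RF = with_seed(seed,
      randomForest::randomForest(x = x, y = y,
                                 ntree = hyperparams$ntree %||% 100L)))

  structure(list(algorithm = algorithm,
                 feature_kind = attr(x, "kind"),
                 feature_length = ncol(x),
                 hyperparams = hyperparams,
                 fit = fit, center = center, scale = scale_,
                 classes = levels(y), seed = as.integer(seed)),
            class = "koa_model")
}

#' @rdname train_classifier
#' @param object a `koa_model`.
#' @param newdata feature matrix or list of feature vectors to classify.
#' @param ... unused.
#' @return `predict()` returns a factor of grade labels, one per row
#'   (empty input gives an empty factor).
#' @export
predict.koa_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata, allow_empty = TRUE)
  if (nrow(x) == 0L) return(factor(character(0), levels = grade_levels()))
  if (ncol(x) != object$feature_length) {
    stop("feature length ", ncol(x), " does not match model (",
         object$feature_length, ")", call. = FALSE)
  }
  kind <- attr(x, "kind")
  if (!is.null(kind) && !is.null(object$feature_kind) &&
      !identical(kind, object$feature_kind)) {
    stop("feature kind ", kind, " does not match model (",
         object$feature_kind, ")", call. = FALSE)
  }
  if (!is.null(object$center)) {
    x <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  }
  pred <- switch(object$algorithm,
    SVM = as.character(predict(object$fit, x)),
    KNN = knn_predict(object$fit, x),
    RF = as.character(predict(object$fit, x)))
  as_grade(pred)
}

# Deterministic KNN: nearest by squared Euclidean distance; distance ties
# resolve to the smallest training index, voting ties (k > 1) to the
# smallest class index.
knn_predict <- function(fit, x) {
  tr <- fit$x
  d2 <- outer(rowSums(x^2), rowSums(tr^2), "+") - 2 * tcrossprod(x, tr)
  k <- min(fit$k, nrow(tr))
  cls <- levels(fit$y)
  vapply(seq_len(nrow(x)), function(i) {
    nn <- order(d2[i, ])[seq_len(k)]     # order() is stable: ties -> low index
    votes <- tabulate(as.integer(fit$y[nn]), nbins = length(cls))
    cls[which.max(votes)]                # which.max: ties -> smallest class
  }, character(1))
}

#' Save / load a trained model
#'
#' The fitted state is serialized as one RDS blob with a JSON sidecar
#' recording algorithm, feature kind and length, hyperparameters and seed.
#'
#' @param model a `koa_model`.
#' @param path output path for the blob (`.rds`); the sidecar is written
#'   next to it as `<path>.json`.
#' @return `save_model()` invisibly returns `path`; `load_model()` returns
#'   the `koa_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "koa_model"))
  saveRDS(model, path)
  meta <- list(algorithm = model$algorithm,
               feature_kind = model$feature_kind,
               feature_length = model$feature_length,
               hyperparams = model$hyperparams,
               seed = model$seed, classes = model$classes)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "koa_model"))
  model
}

# Coerce a list of tagged feature vectors (or a plain matrix) to a samples
# x features matrix carrying the kind attribute when known.
as_feature_matrix <- function(features, allow_empty = FALSE) {
  if (is.matrix(features)) {
    m <- features
  } else if (is.list(features)) {
    if (!length(features)) {
      if (allow_empty) return(matrix(numeric(0), 0L, 0L))
      stop("empty feature list", call. = FALSE)
    }
    lens <- lengths(features)
    if (length(unique(lens)) != 1L) {
      stop("feature vectors must share one length", call. = FALSE)
    }
    kinds <- unique(vapply(features, function(v) {
      k <- feature_kind(v); if (is.null(k)) NA_character_ else k
    }, character(1)))
    m <- do.call(rbind, lapply(features, as.numeric))
    if (length(kinds) == 1L && !is.na(kinds)) attr(m, "kind") <- kinds
  } else {
    stop("`features` must be a matrix or a list of feature vectors",
         call. = FALSE)
  }
  storage.mode(m) <- "double"
  if (ncol(m) > 0L) colnames(m) <- paste0("f", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
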