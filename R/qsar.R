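#' Variance and correlation feature filter
#'
#' Removes low-variance bits first (population variance `p(1-p)` for a binary
#' column), then scans the remaining bits in ascending column order and drops
#' any bit whose absolute Pearson correlation with an earlier kept bit exceeds
#' the threshold. The kept-bit list is returned so the identical selection can
#' be applied to new data (a transform, never a refit).
#'
#' @param mat Feature matrix (compounds x bits).
#' @param variance_threshold Bits with variance strictly below this are
#'   removed (default 0.1).
#' @param correlation_threshold Bits correlated above this with an earlier
#'   kept bit are removed (default 0.90).
#' @return List with `matrix` (reduced), `kept` (column indices into the
#'   original matrix) and the thresholds used.
#' @export
select_features <- function(mat, variance_threshold = 0.1,
                            correlation_threshold = 0.90) {
  mat <- as.matrix(mat)
  stopifnot(variance_threshold >= 0,
            correlation_threshold > 0, correlation_threshold <= 1)
  n <- nrow(mat)
  mu <- colMeans(mat)
  pop_var <- colMeans(mat^2) - mu^2
  keep1 <- which(pop_var >= variance_threshold)
  if (!length(keep1)) stop("all features removed by the variance filter")
  sub <- mat[, keep1, drop = FALSE]
  cm <- suppressWarnings(stats::cor(sub))
  p <- ncol(sub)
  kept_local <- logical(p)
  kept_local[1] <- TRUE
  if (p > 1) {
    for (j in 2:p) {
      earlier <- which(kept_local[seq_len(j - 1)])
      kept_local[j] <- !any(abs(cm[j, earlier]) > correlation_threshold, na.rm = TRUE)
    }
  }
  kept <- keep1[kept_local]
  if (!length(kept)) stop("all features removed by the correlation filter")
  list(matrix = mat[, kept, drop = FALSE], kept = kept,
       variance_threshold = variance_threshold,
       correlation_threshold = correlation_threshold)
}

#' Apply a fitted feature selection to new data
#'
#' @param selection Result of [select_features()].
#' @param mat New feature matrix with the same columns as the training matrix.
#' @return Reduced matrix using the training kept-bit list unchanged.
#' @export
apply_feature_selection <- function(selection, mat) {
  as.matrix(mat)[, selection$kept, drop = FALSE]
}

#' Random oversampling to the majority class
#'
#' Every original record is retained; minority classes are topped up with
#' records drawn uniformly with replacement from that class until each class
#' matches the majority count. Deterministic given `seed`.
#'
#' @param features Feature matrix (rows = compounds).
#' @param labels Class labels aligned with rows (>= 2 classes present).
#' @param seed Integer seed.
#' @return List with `features`, `labels` and `index` (row indices into the
#'   input, originals first).
#' @export
oversample <- function(features, labels, seed = 42L) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) stop("oversampling needs at least 2 classes")
  counts <- table(labels)
  target <- max(counts)
  idx <- seq_along(labels)
  extra <- withr::with_seed(seed, {
    unlist(lapply(levels(labels), function(cl) {
      pool <- which(labels == cl)
      need <- target - length(pool)
      if (need > 0) sample(pool, need, replace = TRUE) else integer(0)
    }))
  })
  all_idx <- c(idx, extra)
  list(features = features[all_idx, , drop = FALSE],
       labels = labels[all_idx],
       index = all_idx)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is `trace/total`. Recall and Matthews correlation coefficient are
#' computed per class from its one-vs-rest 2x2 table (TP, TN, FP, FN) with the
#' standard binary formulas, then macro-averaged. A per-class MCC (or recall)
#' with a zero denominator is defined as 0.
#'
#' @param confusion Square confusion matrix, rows = true classes, columns =
#'   predicted classes, non-negative counts.
#' @return Tibble: `accuracy`, `macro_recall`, `macro_mcc`.
#' @export
confusion_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (!nrow(cm) || nrow(cm) != ncol(cm)) stop("confusion matrix must be square and non-empty")
  if (any(cm < 0)) stop("confusion matrix must be non-negative")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  acc <- sum(diag(cm)) / total
  per_class <- vapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    c(recall = recall, mcc = mcc)
  }, numeric(2))
  tibble::tibble(accuracy = acc,
                 macro_recall = mean(per_class["recall", ]),
                 macro_mcc = mean(per_class["mcc", ]))
}

#' PCA bounding-box applicability domain
#'
#' A query is inside the applicability domain when each of its first `k`
#' principal-component scores lies within the [min, max] range of the training
#' scores on that component. The PCA must have been fitted on training
#' features only; queries are projected with the same loadings (see
#' [pca_project()]).
#'
#' @param train_scores Training score matrix (observations x components).
#' @param query_scores Query score matrix from the same projection.
#' @param k Number of leading components to bound (default 2).
#' @return List with `inside` (logical per query) and `coverage` (fraction).
#' @export
ad_bounding_box <- function(train_scores, query_scores, k = 2L) {
  train_scores <- as.matrix(train_scores)
  query_scores <- as.matrix(query_scores)
  if (k > ncol(train_scores) || k > ncol(query_scores)) {
    stop("k exceeds the number of available components")
  }
  lo <- apply(train_scores[, 1:k, drop = FALSE], 2, min)
  hi <- apply(train_scores[, 1:k, drop = FALSE], 2, max)
  q <- query_scores[, 1:k, drop = FALSE]
  inside <- apply(q, 1, function(row) all(row >= lo & row <= hi))
  list(inside = inside, coverage = mean(inside))
}

#' Train/test split and cross-validation specification
#'
#' @param train_fraction Fraction of data in the training split (default 0.8).
#' @param cv_folds Number of cross-validation folds within the training set
#'   (default 10).
#' @param seed Integer seed controlling every randomized component
#'   (default 42).
#' @return List of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, cv_folds = 10L, seed = 42L) {
  stopifnot(train_fraction > 0, train_fraction < 1, cv_folds >= 2)
  structure(list(train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "split_spec")
}

# stratified index sampling: selects round(frac * n_c) per class c
stratified_split <- function(labels, frac, seed) {
  labels <- as.factor(labels)
  withr::with_seed(seed, {
    train <- unlist(lapply(levels(labels), function(cl) {
      pool <- which(labels == cl)
      n_take <- max(1L, round(frac * length(pool)))
      sample(pool, n_take)
    }))
  })
  sort(train)
}

# stratified fold assignment: a partition of seq_along(labels)
stratified_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      pool <- which(labels == cl)
      folds[pool] <- sample(rep_len(seq_len(k), length(pool)))
    }
  })
  folds
}
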