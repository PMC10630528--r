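test_that("the variance/correlation filter keeps a reusable bit list", {
  withr::with_seed(5, {
    n <- 60
    keepable <- matrix(stats::rbinom(n * 4, 1, 0.5), n)
    const <- matrix(0L, n, 1)
    rare <- matrix(stats::rbinom(n, 1, 0.02), n)      # variance ~0.02 < 0.1
    dup <- keepable[, 1, drop = FALSE]                # exact duplicate of bit 1
    m <- cbind(keepable, const, rare, dup)
    colnames(m) <- paste0("b", seq_len(ncol(m)))
    sel <- select_features(m)
    expect_false(5 %in% sel$kept)  # constant column
    expect_false(7 %in% sel$kept)  # duplicate correlates 1 with earlier bit
    expect_true(1 %in% sel$kept)

    # half-ones column has population variance 0.25 and passes
    half <- cbind(rep(c(0L, 1L), length.out = n))
    expect_equal(select_features(cbind(half, keepable))$kept[1], 1L)

    # the train-fitted list is applied unchanged to new data
    test_m <- m[1:10, ]
    reduced <- apply_feature_selection(sel, test_m)
    expect_equal(ncol(reduced), length(sel$kept))
    expect_equal(colnames(reduced), colnames(m)[sel$kept])

    expect_error(select_features(matrix(0L, 10, 3)), "variance filter")
  })
})

test_that("oversampling equalizes class counts without dropping records", {
  withr::with_seed(9, {
    x <- matrix(stats::rnorm(16 * 3), 16)
    y <- factor(c(rep("a", 10), rep("b", 4), rep("c", 2)))
    ov <- oversample(x, y, seed = 1)
    expect_equal(as.vector(table(ov$labels)), rep(10L, 3))
    # originals all retained, extras are copies of rows from their own class
    expect_equal(ov$index[1:16], 1:16)
    expect_true(all(ov$index > 0 & ov$index <= 16))
    expect_equal(ov$labels, y[ov$index])

    bal <- oversample(x[1:8, ], factor(rep(c("a", "b"), each = 4)), seed = 1)
    expect_equal(bal$index, 1:8)

    expect_identical(oversample(x, y, seed = 7)$index,
                     oversample(x, y, seed = 7)$index)
    expect_error(oversample(x, factor(rep("a", 16)), seed = 1), "2 classes")
  })
})

test_that("confusion-matrix metrics match the binary OVR formulas", {
  d <- diag(c(5L, 7L, 3L, 9L))
  m <- confusion_metrics(d)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_recall, 1)
  expect_equal(m$macro_mcc, 1)

  anti <- matrix(c(0L, 6L, 4L, 0L), 2)
  expect_equal(confusion_metrics(anti)$macro_mcc, -1)

  two <- matrix(c(8L, 3L, 2L, 7L), 2)  # rows true, cols predicted
  mm <- confusion_metrics(two)
  expect_equal(mm$accuracy, 0.75)
  expect_equal(mm$macro_mcc, 50 / sqrt(11 * 10 * 10 * 9), tolerance = 1e-12)

  expect_error(confusion_metrics(matrix(0L, 2, 2)), "empty")
  expect_error(confusion_metrics(matrix(1:6, 2)), "square")
})

test_that("the PCA bounding box flags queries outside the training ranges", {
  withr::with_seed(11, {
    train <- matrix(stats::rnorm(200), ncol = 2)
    ad <- ad_bounding_box(train, train, k = 2)
    expect_true(all(ad$inside))
    expect_equal(ad$coverage, 1)

    far <- rbind(c(2 * max(train[, 1]), 0))
    expect_false(ad_bounding_box(train, far, k = 2)$inside)

    inside <- cbind(stats::runif(50, min(train[, 1]), max(train[, 1])),
                    stats::runif(50, min(train[, 2]), max(train[, 2])))
    expect_equal(ad_bounding_box(train, inside, k = 2)$coverage, 1)
    expect_error(ad_bounding_box(train, inside, k = 5), "exceeds")
  })
})

test_that("cross-validation folds partition the training set per class", {
  y <- factor(rep(c("a", "b", "c", "d"), times = c(40, 30, 20, 10)))
  folds <- sarscape:::stratified_folds(y, 10, seed = 4)
  expect_equal(sort(unique(folds)), 1:10)
  expect_equal(length(folds), length(y))
  for (cl in levels(y)) {
    per_fold <- table(folds[y == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("separable classes are learned perfectly and reports are deterministic", {
  sep <- separable_classes()
  algs <- qsar_algorithms(c("random_forest", "knn", "lda"))
  rep1 <- benchmark_qsar(sep$x, sep$y, algorithms = algs,
                         split = split_spec(cv_folds = 5, seed = 42),
                         balance = "none")
  expect_false(any(rep1$failed))
  expect_equal(rep1$test_accuracy, rep(1, 3))
  expect_equal(rep1$test_macro_mcc, rep(1, 3))

  rep2 <- benchmark_qsar(sep$x, sep$y, algorithms = algs,
                         split = split_spec(cv_folds = 5, seed = 42),
                         balance = "none")
  expect_equal(as.data.frame(rep1), as.data.frame(rep2))

  # shuffled labels give chance-level test accuracy for 4 balanced classes
  accs <- vapply(1:15, function(i) {
    y_perm <- withr::with_seed(100 + i, sample(sep$y))
    r <- benchmark_qsar(sep$x, y_perm,
                        algorithms = qsar_algorithms("decision_tree"),
                        split = split_spec(cv_folds = 2, seed = i),
                        balance = "none")
    r$test_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.08)
})
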