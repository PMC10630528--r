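# One-vs-rest (OVR) multiclass harness over a registry of binary learners.
#
# Each registry entry supplies fit(x, y, seed) for a binary factor y with
# levels c("neg", "pos") and score(model, x) returning a numeric score that
# increases with P(pos). The OVR wrapper fits one binary model per class and
# predicts the class with the highest score.

#' The QSAR algorithm registry
#'
#' Twelve classification algorithms benchmarked one-vs-rest: random forest,
#' extremely randomized trees, bagged trees, extreme gradient boosting,
#' k-nearest neighbours, multilayer perceptron, Gaussian naive Bayes,
#' ridge-penalized logistic regression, linear and RBF support vector
#' machines, a CART decision tree and linear discriminant analysis.
#'
#' @param names Optional subset of algorithm names to return.
#' @return Named list of algorithm definitions (`fit`/`score` closures).
#' @export
qsar_algorithms <- function(names = NULL) {
  reg <- list(
    random_forest = list(
      fit = function(x, y, seed) withr::with_seed(seed,
        randomForest::randomForest(x = x, y = y, ntree = 200L)),
      score = function(m, x) stats::predict(m, x, type = "prob")[, "pos"]
    ),
    extra_trees = list(
      fit = function(x, y, seed) ranger::ranger(
        x = as.data.frame(x), y = y, num.trees = 200L,
        splitrule = "extratrees", num.random.splits = 1L,
        probability = TRUE, seed = seed, num.threads = 1L),
      score = function(m, x) stats::predict(m, as.data.frame(x),
        num.threads = 1L)$predictions[, "pos"]
    ),
    bagged_trees = list(
      fit = function(x, y, seed) withr::with_seed(seed,
        randomForest::randomForest(x = x, y = y, ntree = 100L, mtry = ncol(x))),
      score = function(m, x) stats::predict(m, x, type = "prob")[, "pos"]
    ),
    xgboost = list(
      fit = function(x, y, seed) xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 6L,
                      eta = 0.3, nthread = 1L, seed = seed),
        data = xgboost::xgb.DMatrix(x, label = as.integer(y == "pos"), nthread = 1L),
        nrounds = 50L, verbose = 0),
      score = function(m, x) stats::predict(m, xgboost::xgb.DMatrix(x, nthread = 1L))
    ),
    knn = list(
      fit = function(x, y, seed) list(x = x, y = y, k = 5L, seed = seed),
      score = function(m, x) {
        pred <- withr::with_seed(m$seed,
          class::knn(m$x, x, m$y, k = m$k, prob = TRUE))
        p_win <- attr(pred, "prob")
        ifelse(pred == "pos", p_win, 1 - p_win)
      }
    ),
    mlp = list(
      fit = function(x, y, seed) withr::with_seed(seed,
        nnet::nnet(x = x, y = as.integer(y == "pos"), size = 8L,
                   decay = 1e-3, maxit = 200L, entropy = TRUE,
                   trace = FALSE, MaxNWts = 100000L)),
      score = function(m, x) as.numeric(stats::predict(m, x))
    ),
    naive_bayes = list(
      fit = function(x, y, seed) e1071::naiveBayes(as.data.frame(x), y),
      score = function(m, x) stats::predict(m, as.data.frame(x), type = "raw")[, "pos"]
    ),
    logistic_ridge = list(
      fit = function(x, y, seed) glmnet::glmnet(
        x, y, family = "binomial", alpha = 0, lambda = 1e-2),
      score = function(m, x) as.numeric(stats::predict(m, x, type = "response"))
    ),
    svm_linear = list(
      fit = function(x, y, seed) withr::with_seed(seed,
        e1071::svm(x, y, kernel = "linear", scale = FALSE)),
      score = function(m, x) svm_pos_score(m, x)
    ),
    svm_rbf = list(
      fit = function(x, y, seed) withr::with_seed(seed,
        e1071::svm(x, y, kernel = "radial", scale = FALSE)),
      score = function(m, x) svm_pos_score(m, x)
    ),
    decision_tree = list(
      fit = function(x, y, seed) {
        df <- as.data.frame(x)
        df$.y <- y
        rpart::rpart(.y ~ ., data = df, method = "class")
      },
      score = function(m, x) stats::predict(m, as.data.frame(x))[, "pos"]
    ),
    lda = list(
      fit = function(x, y, seed) suppressWarnings(MASS::lda(x, grouping = y)),
      score = function(m, x) stats::predict(m, x)$posterior[, "pos"]
    )
  )
  if (is.null(names)) return(reg)
  missing <- setdiff(names, base::names(reg))
  if (length(missing)) stop("unknown algorithm(s): ", paste(missing, collapse = ", "))
  reg[names]
}

svm_pos_score <- function(m, x) {
  dv <- attr(stats::predict(m, x, decision.values = TRUE), "decision.values")
  s <- as.numeric(dv[, 1])
  # orient so the score increases with the "pos" class
  if (grepl("^pos/", colnames(dv)[1])) s else -s
}

# fit one binary model per class; returns list(models, classes)
ovr_fit <- function(alg, x, y, seed) {
  y <- droplevels(as.factor(y))
  models <- lapply(seq_along(levels(y)), function(i) {
    cl <- levels(y)[i]
    yb <- factor(ifelse(y == cl, "pos", "neg"), levels = c("neg", "pos"))
    alg$fit(x, yb, seed = seed + i)
  })
  list(models = models, classes = levels(y), alg = alg)
}

ovr_predict <- function(fit, x) {
  scores <- vapply(fit$models, function(m) fit$alg$score(m, x),
                   numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  factor(fit$classes[max.col(scores, ties.method = "first")],
         levels = fit$classes)
}

confusion_table <- function(truth, pred, classes) {
  table(factor(truth, levels = classes), factor(pred, levels = classes))
}

#' Benchmark multiclass QSAR classifiers
#'
#' Optionally balances classes by random oversampling, splits the data into a
#' stratified train/test partition, fits every algorithm one-vs-rest on the
#' training set, estimates internal performance by stratified k-fold
#' cross-validation inside the training set, evaluates on the held-out test
#' set, and reports applicability-domain coverage of the test set (PCA
#' bounding box fitted on the training features).
#'
#' Balancing before the split mirrors the original workflow but lets duplicate
#' records straddle the two splits, which inflates test metrics; use
#' `balance = "after_split"` for an evaluation where the test set contains no
#' copy of any training record.
#'
#' @param features Selected feature matrix (compounds x bits).
#' @param labels Activity-class labels aligned with rows.
#' @param algorithms Registry subset from [qsar_algorithms()].
#' @param split A [split_spec()].
#' @param balance `"before_split"` (default), `"after_split"` or `"none"`.
#' @param ad_components Leading PCA components bounded for the applicability
#'   domain (default 2).
#' @return Tibble of class `model_report`, one row per algorithm with train,
#'   CV (mean and sd over folds) and test accuracy / macro recall / macro MCC,
#'   AD coverage and a `failed` flag; confusion matrices are kept in the
#'   `confusion` attribute.
#' @export
benchmark_qsar <- function(features, labels,
                           algorithms = qsar_algorithms(),
                           split = split_spec(),
                           balance = c("before_split", "after_split", "none"),
                           ad_components = 2L) {
  balance <- match.arg(balance)
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- droplevels(as.factor(labels))
  stopifnot(nrow(x) == length(y))

  if (balance == "before_split") {
    ov <- oversample(x, y, seed = split$seed)
    x <- ov$features; y <- ov$labels
  }
  train_idx <- stratified_split(y, split$train_fraction, seed = split$seed)
  x_tr <- x[train_idx, , drop = FALSE]; y_tr <- y[train_idx]
  x_te <- x[-train_idx, , drop = FALSE]; y_te <- y[-train_idx]
  if (balance == "after_split") {
    ov <- oversample(x_tr, y_tr, seed = split$seed)
    x_tr <- ov$features; y_tr <- ov$labels
  }
  classes <- levels(y)

  # applicability domain: PCA fitted on training features only
  ad_cov <- tryCatch({
    pca <- withCallingHandlers(run_pca(x_tr),
                               warning = function(w) invokeRestart("muffleWarning"))
    q <- pca_project(pca, x_te)
    k <- min(ad_components, ncol(q))
    ad_bounding_box(pca$scores, q, k = k)$coverage
  }, error = function(e) NA_real_)

  folds <- stratified_folds(y_tr, split$cv_folds, seed = split$seed + 1L)

  rows <- list()
  confusions <- list()
  for (alg_name in names(algorithms)) {
    alg <- algorithms[[alg_name]]
    res <- tryCatch({
      fit <- ovr_fit(alg, x_tr, y_tr, seed = split$seed)
      pred_tr <- ovr_predict(fit, x_tr)
      m_tr <- confusion_metrics(confusion_table(y_tr, pred_tr, classes))

      cv <- lapply(seq_len(split$cv_folds), function(f) {
        hold <- folds == f
        if (!any(hold) || length(unique(y_tr[!hold])) < 2) return(NULL)
        cf <- ovr_fit(alg, x_tr[!hold, , drop = FALSE], y_tr[!hold],
                      seed = split$seed + 100L * f)
        confusion_metrics(confusion_table(
          y_tr[hold], ovr_predict(cf, x_tr[hold, , drop = FALSE]), classes))
      })
      cv <- dplyr::bind_rows(cv)

      pred_te <- ovr_predict(fit, x_te)
      cm_te <- confusion_table(y_te, pred_te, classes)
      m_te <- confusion_metrics(cm_te)

      report <- tibble::tibble(
        algorithm = alg_name,
        train_accuracy = m_tr$accuracy,
        train_macro_recall = m_tr$macro_recall,
        train_macro_mcc = m_tr$macro_mcc,
        cv_accuracy_mean = mean(cv$accuracy),
        cv_accuracy_sd = stats::sd(cv$accuracy),
        cv_macro_recall_mean = mean(cv$macro_recall),
        cv_macro_mcc_mean = mean(cv$macro_mcc),
        test_accuracy = m_te$accuracy,
        test_macro_recall = m_te$macro_recall,
        test_macro_mcc = m_te$macro_mcc,
        n_features = ncol(x_tr),
        ad_coverage = ad_cov,
        failed = FALSE
      )
      list(report = report, confusion = cm_te, error = NULL)
    }, error = function(e) {
      report <- tibble::tibble(
        algorithm = alg_name,
        train_accuracy = NA_real_, train_macro_recall = NA_real_,
        train_macro_mcc = NA_real_, cv_accuracy_mean = NA_real_,
        cv_accuracy_sd = NA_real_, cv_macro_recall_mean = NA_real_,
        cv_macro_mcc_mean = NA_real_, test_accuracy = NA_real_,
        test_macro_recall = NA_real_, test_macro_mcc = NA_real_,
        n_features = ncol(x_tr), ad_coverage = ad_cov, failed = TRUE
      )
      list(report = report, confusion = NULL, error = conditionMessage(e))
    })
    if (!is.null(res$error)) {
      warning("algorithm ", alg_name, " failed: ", res$error, call. = FALSE)
    }
    if (!is.null(res$confusion)) confusions[[alg_name]] <- res$confusion
    rows[[alg_name]] <- res$report
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "confusion") <- confusions
  attr(out, "split") <- split
  attr(out, "balance") <- balance
  class(out) <- c("model_report", class(out))
  out
}
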