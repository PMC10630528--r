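#' Six-number summary of a descriptor
#'
#' Minimum, first quartile, median, mean, third quartile and maximum, with
#' quartiles by linear interpolation (R's default type-7 convention, recorded
#' in the output attribute `quartile_type`).
#'
#' @param values Numeric vector, length >= 1, no missing values.
#' @return One-row tibble: `min`, `q1`, `median`, `mean`, `q3`, `max`, `n`.
#' @export
summarize_values <- function(values) {
  if (!length(values)) stop("cannot summarize an empty vector")
  if (anyNA(values)) stop("missing values are not allowed")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  out <- tibble::tibble(min = min(values), q1 = q[1], median = q[2],
                        mean = mean(values), q3 = q[3], max = max(values),
                        n = length(values))
  attr(out, "quartile_type") <- 7L
  out
}

#' Compare a descriptor between two compound groups
#'
#' Normality is assessed per group with the Shapiro-Wilk test at `alpha`; if
#' both groups look normal, Welch's two-sample t-test is used, otherwise the
#' Mann-Whitney U (Wilcoxon rank-sum) test. Constant-valued input under the
#' t-test branch falls back to Mann-Whitney with a warning.
#'
#' @param g1,g2 Numeric vectors (n >= 3 each).
#' @param alpha Significance level used to gate normality (default 0.05).
#' @return One-row tibble: `test` (`"t_test"` or `"mann_whitney_u"`),
#'   `p_value`, `normality_p_g1`, `normality_p_g2`.
#' @export
compare_groups <- function(g1, g2, alpha = 0.05) {
  if (length(g1) < 3 || length(g2) < 3) stop("each group needs at least 3 values")
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0) {
    warning("constant-valued group: falling back to Mann-Whitney U")
    p1 <- if (stats::sd(g1) == 0) 0 else NA_real_
    p2 <- if (stats::sd(g2) == 0) 0 else NA_real_
    p <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE))$p.value
    return(tibble::tibble(test = "mann_whitney_u", p_value = p,
                          normality_p_g1 = p1, normality_p_g2 = p2))
  }
  shapiro_p <- function(x) {
    if (length(x) > 5000) x <- sample(x, 5000)
    stats::shapiro.test(x)$p.value
  }
  p1 <- shapiro_p(g1)
  p2 <- shapiro_p(g2)
  use_t <- p1 > alpha && p2 > alpha
  if (use_t) {
    test <- "t_test"
    p <- stats::t.test(g1, g2)$p.value
  } else {
    test <- "mann_whitney_u"
    p <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE))$p.value
  }
  tibble::tibble(test = test, p_value = p, normality_p_g1 = p1, normality_p_g2 = p2)
}

#' Descriptor-wise group comparison table
#'
#' Runs [summarize_values()] per descriptor and group plus [compare_groups()]
#' per descriptor, reproducing the usual exploratory table for a two-group
#' chemical-space comparison.
#'
#' @param descriptors Tibble from [compute_descriptors()] (plus `compound_id`).
#' @param groups Factor/character of group labels aligned with rows.
#' @param alpha Normality gate for [compare_groups()].
#' @return List with `summaries` (tidy tibble) and `tests` (one row per
#'   descriptor).
#' @export
eda_table <- function(descriptors, groups, alpha = 0.05) {
  vars <- c("mw", "logp", "nha", "nhd", "nrot", "tpsa")
  stopifnot(all(vars %in% names(descriptors)),
            length(groups) == nrow(descriptors))
  groups <- as.character(groups)
  summaries <- dplyr::bind_rows(lapply(vars, function(v) {
    dplyr::bind_rows(lapply(sort(unique(groups)), function(g) {
      s <- summarize_values(descriptors[[v]][groups == g])
      dplyr::bind_cols(tibble::tibble(descriptor = v, group = g), s)
    }))
  }))
  gl <- sort(unique(groups))
  tests <- if (length(gl) == 2) {
    dplyr::bind_rows(lapply(vars, function(v) {
      r <- compare_groups(descriptors[[v]][groups == gl[1]],
                          descriptors[[v]][groups == gl[2]], alpha = alpha)
      dplyr::bind_cols(tibble::tibble(descriptor = v), r)
    }))
  } else {
    tibble::tibble()
  }
  list(summaries = summaries, tests = tests)
}

#' Principal component analysis of a descriptor matrix
#'
#' Descriptors are standardized to zero mean and unit variance before the
#' decomposition (correlation-matrix PCA), so eigenvalues sum to the number of
#' retained descriptors. Zero-variance descriptors are dropped with a warning.
#' Loadings are sign-normalized so each component's largest-magnitude loading
#' is positive, making runs comparable.
#'
#' @param mat Numeric matrix or data frame, compounds x descriptors, no
#'   missing values.
#' @return List of class `pca_result`: `eigenvalues`, `proportion`,
#'   `cumulative`, `loadings` (descriptor x component), `scores`
#'   (compound x component), `center`, `scale`, `dropped`.
#' @export
run_pca <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("PCA needs >= 2 compounds and >= 2 descriptors")
  if (anyNA(mat)) stop("missing values are not allowed in PCA input")
  v <- apply(mat, 2, stats::var)
  dropped <- colnames(mat)[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance descriptor(s): ", paste(dropped, collapse = ", "))
    mat <- mat[, v > 0, drop = FALSE]
    if (ncol(mat) < 2) stop("fewer than 2 descriptors left after dropping constants")
  }
  pr <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  flip <- apply(pr$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pr$rotation, 2, flip, "*")
  scores <- sweep(pr$x, 2, flip, "*")
  ev <- pr$sdev^2
  structure(list(
    eigenvalues = ev,
    proportion = ev / sum(ev),
    cumulative = cumsum(ev) / sum(ev),
    loadings = loadings,
    scores = scores,
    center = pr$center,
    scale = pr$scale,
    dropped = dropped
  ), class = "pca_result")
}

#' Project new data onto a fitted PCA
#'
#' Applies the training centering, scaling and (sign-normalized) loadings to
#' new observations - a transform, never a refit.
#'
#' @param pca A `pca_result`.
#' @param newdata Matrix/data frame with the descriptors the PCA retained.
#' @return Score matrix, observations x components.
#' @export
pca_project <- function(pca, newdata) {
  stopifnot(inherits(pca, "pca_result"))
  nd <- as.matrix(newdata)[, names(pca$center), drop = FALSE]
  scale(nd, center = pca$center, scale = pca$scale) %*% pca$loadings
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", length(x$eigenvalues), "components; cumulative variance:",
      paste(sprintf("%.1f%%", 100 * x$cumulative), collapse = " "), "\n")
  invisible(x)
}
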