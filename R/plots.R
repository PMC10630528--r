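#' SAS map of a structure-activity landscape
#'
#' Scatter of pairwise activity difference against structural similarity,
#' colored by SALI (finite values only; green = low, red = high), with the
#' similarity and activity thresholds that delimit the four quadrants.
#'
#' @param landscape A `landscape` tibble from [build_landscape()].
#' @return A ggplot object.
#' @export
plot_sas_map <- function(landscape) {
  df <- as.data.frame(landscape)
  df$sali_finite <- ifelse(is.finite(df$sali), df$sali, NA_real_)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$similarity, y = .data$delta_activity,
                                   color = .data$sali_finite)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_color_gradient(low = "forestgreen", high = "red",
                                  na.value = "grey50", name = "SALI") +
    ggplot2::geom_vline(xintercept = attr(landscape, "sim_threshold"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = attr(landscape, "activity_threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = paste0("Tanimoto similarity (", attr(landscape, "scheme"), ")"),
                  y = expression(Delta * "pIC"[50]),
                  title = "Structure-activity similarity map") +
    ggplot2::theme_minimal()
}

#' PC1-PC2 score plot colored by potency group
#'
#' @param pca A `pca_result` from [run_pca()].
#' @param groups Group labels aligned with score rows.
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(pca, groups) {
  stopifnot(inherits(pca, "pca_result"))
  df <- data.frame(pc1 = pca$scores[, 1], pc2 = pca$scores[, 2],
                   group = as.factor(groups))
  pct <- round(100 * pca$proportion[1:2], 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2, color = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = paste0("PC1 (", pct[1], "%)"), y = paste0("PC2 (", pct[2], "%)"),
                  title = "Chemical space (standardized descriptor PCA)") +
    ggplot2::theme_minimal()
}
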