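#!/usr/bin/env Rscript
# Chemical-space exploration: six drug-likeness descriptors, univariate
# group comparisons (normality-gated t / Mann-Whitney U), and standardized
# PCA with eigenvalues and loadings.

library(sarscape)

rec <- read.csv("results/curated.csv")
desc <- compute_descriptors(rec$canonical_smiles, rec$compound_id)
write.csv(desc, "results/descriptors.csv", row.names = FALSE)

eda <- eda_table(desc, rec$group)
write.csv(eda$summaries, "results/eda_summaries.csv", row.names = FALSE)
write.csv(eda$tests, "results/eda_tests.csv", row.names = FALSE)
cat("descriptor group tests (p < 0.05 marked):\n")
print(cbind(eda$tests[, c("descriptor", "test")],
            p = signif(eda$tests$p_value, 3),
            sig = ifelse(eda$tests$p_value < 0.05, "*", "")))

pca <- run_pca(as.matrix(desc[, c("mw", "logp", "nha", "nhd", "nrot", "tpsa")]))
write.csv(data.frame(component = seq_along(pca$eigenvalues),
                     eigenvalue = pca$eigenvalues,
                     proportion = pca$proportion,
                     cumulative = pca$cumulative),
          "results/pca_eigenvalues.csv", row.names = FALSE)
write.csv(cbind(descriptor = rownames(pca$loadings), as.data.frame(pca$loadings)),
          "results/pca_loadings.csv", row.names = FALSE)
cat(sprintf("\nfirst three components explain %.1f%% of the variance\n",
            100 * pca$cumulative[3]))

dir.create("scratch", showWarnings = FALSE)
ggplot2::ggsave("scratch/pca_scores.png", plot_pca_scores(pca, rec$group),
                width = 6, height = 5, dpi = 150)
cat("wrote results/eda_*.csv, results/pca_*.csv, scratch/pca_scores.png\n")
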