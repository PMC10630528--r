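#!/usr/bin/env Rscript
# Chemotype analysis: Murcko scaffolds, generic cyclic skeletons, frequency
# and favorability of the recurring scaffolds, and scaffold diversity of the
# potency groups.

library(sarscape)

ds <- curate_activity_file("results/synthetic_library.csv")
st <- scaffold_table(ds, min_frequency = 10)

head_tab <- st$scaffolds[st$scaffolds$headline,
                         c("scaffold_smiles", "skeleton_smiles", "frequency",
                           "pic50_median", "group1_fraction", "favorability")]
cat("scaffolds with frequency >= 10:\n")
print(as.data.frame(head_tab))

cat("\nscaffold diversity by subset:\n")
print(as.data.frame(st$diversity))
cat("acyclic molecules (no scaffold):", st$n_acyclic, "\n")

flat <- st$scaffolds
flat$member_ids <- vapply(flat$member_ids, paste, "", collapse = ";")
write.csv(flat, "results/scaffolds.csv", row.names = FALSE)
write.csv(st$diversity, "results/scaffold_diversity.csv", row.names = FALSE)
cat("wrote results/scaffolds.csv, results/scaffold_diversity.csv\n")
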