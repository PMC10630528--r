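#!/usr/bin/env Rscript
# Build the synthetic inhibitor library that stands in for a curated activity
# export: six recurring chemotypes, an imbalanced four-class pIC50
# distribution, and ten planted activity cliffs with five cliff generators.

library(sarscape)

dir.create("results", showWarnings = FALSE)

spec <- synthetic_spec(seed = 42)  # defaults: 211 molecules, noise SD 0.3
lib <- generate_library(spec)

write_synthetic(lib, "results/synthetic_library.csv")

cat("molecules:", nrow(lib$activities), "\n")
cat("true class counts:\n")
print(lib$truth$class_counts)
cat("planted cliff pairs:", nrow(lib$truth$cliff_pairs),
    "| planted generators:", length(lib$truth$generators), "\n")
cat("wrote results/synthetic_library.csv (+ .truth.json)\n")
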