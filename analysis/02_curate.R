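#!/usr/bin/env Rscript
# Curate the activity table: keep exact IC50 measurements, convert to pIC50,
# collapse duplicate structures, assign activity classes and potency groups.

library(sarscape)

ds <- curate_activity_file("results/synthetic_library.csv")
write_curated(ds, "results/curated.csv")

print(ds)
cat("\nremovals by filter:\n")
str(ds$provenance$removed)
cat("group sizes:\n")
print(table(ds$records$group))
cat("wrote results/curated.csv (+ provenance JSON)\n")
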