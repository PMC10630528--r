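# sarscape

Structure-activity landscapes, activity cliffs and multiclass QSAR for
inhibitor series.

## The problem

Medicinal-chemistry campaigns against a single protein target (the motivating
case is LpxC, the zinc deacetylase of the Gram-negative lipid A pathway)
accumulate hundreds of IC50 measurements over recurring chemotypes. Making
sense of such a series requires more than a potency table: which regions of
chemical space the potent compounds occupy, where the structure-activity
relationship (SAR) is smooth enough for predictive modeling, which
near-identical compound pairs flip from inactive to potent (activity cliffs),
and which scaffolds are worth elaborating. `sarscape` packages that whole
analysis — curation, chemical-space statistics, SAS maps, activity-cliff
detection, multiclass QSAR benchmarking with an applicability domain, and
Murcko-scaffold chemotype analysis — as tested R functions, plus a
synthetic-library generator with known ground truth so every stage can be
verified without downloading anything.

It is written for computational chemists and cheminformaticians who work with
ChEMBL-style activity exports in R.

## What it computes

- **Curation.** IC50 (nM) → pIC50 = −log10(IC50 in mol/L); classes
  potent (pIC50 ≥ 9), active (9 > pIC50 ≥ 8), intermediate (8 > pIC50 ≥ 7),
  inactive (pIC50 < 7); group 1 = potent ∪ active, group 2 = the rest.
  Censored relations (`>`, `<`), non-IC50 rows, unparseable SMILES and
  duplicate canonical structures are removed with per-filter accounting.
- **Descriptors and fingerprints.** MW, LogP, nHA, nHD, nRot, TPSA;
  MACCS-166 keys (OpenBabel) and a PubChem-style 881-key substructure set
  (own generator; see `pubchem_key_info()` for which sections of the
  published layout are populated).
- **Landscape.** For every compound pair: Tanimoto similarity
  `|A∩B| / |A∪B|`, activity difference ΔpIC50, and the
  structure-activity landscape index

      SALI(i, j) = |pIC50_i − pIC50_j| / (1 − sim(i, j)).

  The SAS map partitions pairs by a similarity threshold (mean + 2 SD of the
  pairwise similarity distribution, or fixed) and an activity threshold
  (ΔpIC50 ≥ 2) into smooth SAR, activity cliff, nondescript and
  scaffold-hopping quadrants. Cliff generators are compounds in ≥ 2 cliffs;
  consensus cliffs/generators are the intersection across fingerprint
  schemes.
- **QSAR.** Variance (< 0.1) and correlation (> 0.90) feature filtering,
  random oversampling to the majority class, stratified 80:20 split, 10-fold
  CV inside the training set, 12 classifiers fitted one-vs-rest, and
  accuracy / macro recall / macro Matthews correlation coefficient from the
  per-class one-vs-rest confusion tables, with a PCA bounding-box
  applicability domain for the test set.
- **Chemotypes.** Bemis-Murcko scaffolds (rings + linkers, exocyclic double
  bonds retained), generic cyclic skeletons (all atoms → C, all bonds →
  single), scaffold frequencies, diversity statistics and a favorability
  label from group-1 enrichment.

## Worked example

```r
library(sarscape)

# a 211-compound synthetic inhibitor library with known ground truth
lib <- generate_library(synthetic_spec(noise_sd = 0, seed = 42))
ds  <- curate_activities(lib$activities)
table(ds$records$activity_class)
#>       potent       active intermediate     inactive
#>           10            5           47          149

# pairwise landscape under the MACCS fingerprint
fps <- compute_fingerprints(ds, "MACCS166")
ls  <- build_landscape(ds, fps)          # mean + 2 SD similarity threshold
attr(ls, "sim_threshold")
#> [1] 0.9028200
sali(9, 7, 0.8)                          # a 2-log cliff at similarity 0.8
#> [1] 10

# chemotypes: the biphenyl series dominates
st <- scaffold_table(ds, min_frequency = 10)
st$scaffolds$frequency
#> [1] 108  29  26  22  16  10
```

The class table reproduces the generator's ground truth exactly (zero assay
noise), the similarity threshold is the mean + 2 SD statistic of all 22,155
pair similarities, and the scaffold frequencies recover the library's planted
chemotype counts, biphenyl (108 members) first.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow on the default noisy library (assay noise SD 0.3 log units) and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # library + ground truth
Rscript analysis/02_curate.R        # classes, groups, provenance
Rscript analysis/03_descriptors_eda.R
Rscript analysis/04_landscape.R     # SAS maps, cliffs, consensus generators
Rscript analysis/05_qsar.R          # 12-algorithm OVR benchmark, 2 schemes
Rscript analysis/06_chemotype.R     # scaffolds, diversity, favorability
```

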