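---
title: "Methods: structure-activity landscapes, activity cliffs and multiclass QSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-activity landscapes, activity cliffs and multiclass QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures implemented in `sarscape`,
the parameters that matter, the design decisions taken where several
reasonable conventions exist, and what the synthetic-library tests do and do
not establish about behavior on real data.

## Curation model

Activity records enter as ChEMBL-style rows (compound id, SMILES,
`standard_type`, `standard_relation`, `standard_value`, `standard_units`).
The curation contract is:

1. keep only IC50 rows with an exact `"="` relation — censored values
   (`>`, `<`) cannot be converted to a point pIC50 and are counted as
   *unqualified*;
2. keep only units convertible to mol/L (nM, µM, mM, M) and positive values;
3. canonicalize SMILES (OpenBabel canonical form), optionally keeping only
   the largest fragment of salt forms (`strip_salts = TRUE` by default, since
   activity is attributed to the parent molecule);
4. convert to pIC50 = −log10(IC50 in mol/L), so 1 nM ↦ 9 and 100 nM ↦ 7;
5. collapse duplicate canonical structures, aggregating replicate pIC50
   values by the **median** (configurable: `median`, `mean`, `first`).
   The median is the robust convention for public bioactivity data, where
   replicates often come from different assays;
6. assign classes with left-closed intervals: potent (pIC50 ≥ 9), active
   (9 > pIC50 ≥ 8), intermediate (8 > pIC50 ≥ 7), inactive (pIC50 < 7), and
   the two potency groups (group 1: pIC50 ≥ 8).

Every filter's removal count is recorded; removals plus output always equal
the input count, which the tests assert. The textual description of the
inactive class boundary ("corresponding to 100 nM") is implemented as the
printed threshold on pIC50 (`< 7`), i.e. IC50 strictly above 100 nM.

## Descriptors and fingerprints

The six drug-likeness descriptors are MW (Da), LogP, nHA, nHD, nRot and TPSA
(Å²). LogP uses OpenBabel's Wildman–Crippen atom-contribution estimator; the
estimator's name is recorded in pipeline provenance because absolute LogP
values are estimator-dependent and only internal consistency matters for the
group comparisons and PCA. Rotatable bonds are counted by the standard SMARTS
(single, acyclic, non-terminal bonds excluding triple-bond neighbors).

MACCS-166 keys come from OpenBabel; the returned 256-column block is verified
to have no set bits beyond key 166 and truncated to the published key count.

The PubChem-style 881-key fingerprint is generated by this package following
the published CACTVS section layout: element counts (bits 0–114), ring counts
(bits 115–262; all simple rings up to size 10 serve as the ring set, a
documented stand-in for the ESSSR perception of the original), bonded element
pairs (bits 263–326), and a curated subset of the published substructure
patterns placed at fixed positions in the SMARTS section (bits 460+). Keys in
the atom-neighborhood sections are fixed at 0. Bit-exact parity with
PaDEL-generated fingerprints is therefore **not** claimed; the fingerprint is
a valid substructure key set with the same dimensionality and section
semantics, which is what the landscape and QSAR stages require.
`pubchem_key_info()` reports exactly what is populated. Pairs in which either
fingerprint has no set bit are excluded from similarity work with a warning
rather than silently scored 0.

## Exploratory analysis

Per-descriptor six-number summaries use type-7 (linear-interpolation)
quartiles, the R default, recorded in the output. Group comparisons are gated
on normality: Shapiro–Wilk at α = 0.05 per group; both groups normal → Welch
two-sample t-test, otherwise Mann–Whitney U. The source narrative names
"Student's t-test" in its methods but applies Mann–Whitney to the non-normal
descriptors in its results; the normality-gated rule follows that practice,
and Welch's unequal-variance form is used because group sizes and spreads
differ substantially. A constant-valued group falls back to Mann–Whitney with
a warning.

PCA standardizes descriptors to zero mean and unit variance first — MW lives
on hundreds of Da while LogP spans a few log units, so covariance PCA would
be dominated by MW. Consequently eigenvalues sum to the number of retained
descriptors. Zero-variance descriptors are dropped with a warning. Loadings
are sign-normalized (each component's largest-magnitude loading positive) so
runs and platforms agree; scores reconstruct the standardized data to
< 1e-8 when all components are retained, which is tested.

## Landscape model

For a pair (i, j): Tanimoto similarity over a fingerprint scheme, activity
difference Δ = |pIC50_i − pIC50_j|, and SALI = Δ / (1 − sim). sim = 1 with
Δ > 0 is reported as an infinite SALI flag (a true discontinuity), not
dropped; sim = 1 with Δ = 0 is 0.

The SAS map uses two thresholds. The activity threshold defaults to 2 pIC50
units (inclusive, "≥ 2"). The similarity threshold is data-driven by default:
mean + 2 standard deviations of all pairwise similarities, capped at 1, with
the sample (n − 1) standard deviation — the conventional estimator for an
empirical sample; a fixed threshold is available for ground-truth work.
Quadrants: high sim & high Δ → cliff; high sim & low Δ → smooth; low sim &
high Δ → nondescript; low sim & low Δ → scaffold hop. Pairwise statistics are
computed over **all** n(n−1)/2 pairs, with no similarity floor.

A compound is a cliff **generator** when it participates in at least
`min_cliffs` cliffs (default 2 — the literature describes generators
qualitatively as compounds with disproportionate cliff participation, so the
count is exposed rather than hard-coded). Consensus cliffs are the exact
intersection of the unordered cliff-pair sets across schemes; consensus
generators are compounds that are generators in every scheme.

## QSAR benchmark

Feature filtering removes bits with population variance < 0.1 (for a binary
bit, p(1−p), so the rule is a minimum-prevalence filter), then scans kept
bits in ascending index order and drops any bit with |Pearson r| > 0.90 to an
earlier kept bit. The methods text of the source gives 0.90 while its table
captions print 0.95; 0.90 is the default and both are exposed. The kept-bit
list is a transform applied unchanged to new data.

Class balancing is random oversampling to the majority-class count
(originals always retained). Balancing **before** the 80:20 stratified split
mirrors the original workflow but lets duplicated records straddle train and
test, which inflates test metrics; `balance = "after_split"` is provided for
honest evaluation and the caveat is printed in the analysis script.

Twelve classifiers are benchmarked one-vs-rest: random forest, extremely
randomized trees (ranger's extratrees split rule), bagged trees, XGBoost,
k-nearest neighbours (k = 5), a single-hidden-layer perceptron, Gaussian
naive Bayes, ridge-penalized logistic regression, linear and RBF SVMs, a CART
tree and LDA. The source names six of its twelve (RF, ET, XGB, KNN, MLP, NB);
the remaining six here are chosen as widely used representatives of the same
algorithm families, and the harness is algorithm-agnostic. Each binary OVR
model returns a score increasing with class membership; the predicted class
is the arg-max across the four scores. No hyperparameter optimization is
performed, matching the source. Every randomized component (split, folds,
oversampling, stochastic learners) derives from one seed; identical seeds
give identical reports, which is tested. An algorithm that errors is marked
`failed` and the run continues.

Metrics come from the 4×4 confusion matrix: accuracy = trace/total; recall
and MCC are computed per class from its one-vs-rest 2×2 table with the
standard binary formulas and macro-averaged (the source prints only the
binary formulas; macro averaging is the standard multiclass aggregation). A
per-class MCC or recall with a zero denominator is defined as 0. The
implementation is checked against a brute-force OVR enumeration on 200 random
matrices.

The applicability domain is a PCA bounding box: PCA fitted on training
features only, queries projected with the same centering/scaling/loadings,
and a query is inside iff its first k (default 2) component scores fall
within the training min–max ranges.

## Chemotype analysis

Murcko scaffolds are computed graph-theoretically: ring atoms are the
endpoints of non-bridge edges; terminal non-ring atoms are pruned iteratively
(leaving rings plus linkers); atoms double-bonded to the retained framework
(e.g. ring carbonyl oxygens) are restored — the standard Bemis–Murcko
convention of keeping exocyclic double bonds. Acyclic molecules map to the
empty sentinel `""`. The cyclic skeleton replaces every atom with carbon and
every bond with a single bond, then canonicalizes. Both operations are
idempotent (tested), and scaffolds agree with an independent cheminformatics
toolkit on reference molecules (tested).

Scaffold **favorability** has no quantitative criterion in the source, which
states conclusions only; the implemented rule is transparent enrichment:
among scaffolds with frequency ≥ `min_frequency` (default 10), favorable if
the members' group-1 fraction exceeds 1.5× the dataset-wide group-1 fraction,
unfavorable below 0.5×, else neutral. Diversity per subset (all / group 1 /
group 2) is reported as molecule count, scaffold count, scaffold-per-molecule
ratio and singleton fraction — a reasonable reconstruction, since the exact
diversity metrics of the source's table are not readable from it.

## The synthetic library: what it emulates and what it does not

`generate_library()` builds molecules by decorating six scaffold templates
(biphenyl, benzyloxybenzene, 4-phenyl-2-pyridinone, 2-phenyl-oxazoline,
phenoxymethyl-phenyl-1,2,4-oxadiazole, benzene — the recurring chemotypes of
the motivating inhibitor series) at two variable positions, with pIC50 =
scaffold base + substituent contributions + N(0, noise SD). It emulates the
structural features the pipeline must detect: recurring scaffolds with known
frequencies (defaults 108/26/22/29/10/16, echoing the frequency-≥10 table of
the source), an intermediate/inactive-heavy four-class imbalance, and planted
near-duplicate pairs with ≥ 2.5 log-unit gaps.

Design choices that make the ground truth verifiable by construction:

- **Attachment markers.** Substituents splice into explicit `(%1)`, `(%2)`
  template positions; scaffolds whose two positions are symmetry-equivalent
  are enumerated with unordered substituent pairs so distinct combos are
  distinct molecules (the curation dedup invariant).
- **A constant amide tail** at a fixed third position of every scaffold plays
  the role of a series' shared elaborated core. It keeps pairwise
  similarities in a realistic range and makes the hydroxamate warhead swap a
  small relative structural change.
- **Bounded contributions.** Scaffold bases span < 0.9 log units and
  decoration contributions < 0.45, so **only** warhead swaps (+2.55/+2.66)
  can produce a ≥ 2 log-unit gap; a +1.55 "booster" fragment populates the
  active class without ever forming a cliff.
- **Reserved anchors.** The second position of every planted pair carries a
  fragment (methylsulfonyl, CF3, Cl, Br, I) never used in random decoration,
  each bringing an element class unique in the library. A planted pair shares
  its anchor, so every *other* pair with a comparable activity gap differs by
  a loud anchor mismatch and sits below the planted pairs in similarity.
  This is what lets a fixed similarity threshold "just below the planted
  pairs' similarity" recover exactly the planted cliffs and generators at
  zero noise.
- Assay noise defaults to SD 0.3 log units, a typical inter-assay IC50
  spread; ground-truth tests set it to 0.
- IC50 values are emitted in nM with bases chosen off the class boundaries at
  the third decimal, so the nM → pIC50 round trip can never flip a class
  through floating-point error.

What the generator does **not** emulate: assay heterogeneity and censoring
patterns of real ChEMBL exports, chemically realistic synthesizability,
activity cliffs arising from scaffold rearrangements rather than substituent
swaps, and the bit-level statistics of PaDEL fingerprints on diverse real
molecules. Green tests therefore establish the correctness of the machinery
(conversions, thresholds, intersections, bookkeeping, model plumbing), not
the field performance of any particular QSAR model on real inhibitor data.

## Numerical conventions and degenerate inputs

- Quartiles: type 7. Standard deviation: sample (n − 1) everywhere.
- Similarity threshold capped at 1; SALI infinities flagged, never dropped.
- Tie-break in OVR prediction: first class in level order wins an exact
  score tie.
- Single-heavy-atom molecules (e.g. methane) are retried with explicit
  hydrogens so the SDF toolchain accepts them; their acceptor/donor counts
  come from the element rule directly.
- All-zero fingerprints: excluded from pairwise similarity with a warning.
- Empty curation results, single-class labels, k exceeding available PCA
  components, and unparseable SMILES raise typed errors naming the offenders.

## Problem sizes

The shipped analyses and tests use the generator's default study conditions:
211 molecules (seed 42) for the end-to-end pipeline, landscape and QSAR
stages (22,155 pairs per fingerprint scheme), a 500-molecule library for the
scaffold-recovery check, 20 random small specs for the class-count round
trip, and 200 random confusion matrices for the metric oracle. These sizes
were chosen so the full suite exercises every stage at the scale of the
motivating series (a few hundred compounds) while remaining quick to run.

## Known limitations

- The PubChem-style fingerprint is not PaDEL-parity; analyses that depend on
  exact bit identities of the original (reproducing its exact cliff counts on
  real data) need an external PaDEL-compatible generator.
- OpenBabel's aromaticity and LogP models differ from DataWarrior's, so
  descriptor values and MACCS bits can differ from the source's tooling in
  detail; all downstream logic is threshold- or rank-based and unaffected in
  kind.
- Balancing before splitting (the default, mirroring the source workflow)
  overstates test metrics; use `balance = "after_split"` for unbiased
  estimates.
- The favorability rule and the diversity metrics are this package's
  transparent reconstructions of qualitative statements in the source.
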