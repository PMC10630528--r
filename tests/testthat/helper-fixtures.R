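# Shared fixtures, cached so expensive chemistry runs once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the reference noise-free library: seed 42, 10 planted cliff pairs
ref_library <- function() {
  cached("ref_library", function() {
    generate_library(synthetic_spec(noise_sd = 0, seed = 42))
  })
}

ref_dataset <- function() {
  cached("ref_dataset", function() curate_activities(ref_library()$activities))
}

ref_fingerprints <- function(scheme) {
  cached(paste0("ref_fp_", scheme), function() {
    compute_fingerprints(ref_dataset(), scheme)
  })
}

# landscape under the fixed-threshold rule the planting construction
# guarantees: just below the least similar planted pair
ref_landscape <- function(scheme) {
  cached(paste0("ref_landscape_", scheme), function() {
    lib <- ref_library()
    sim <- similarity_matrix(ref_fingerprints(scheme))
    ps <- mapply(function(a, b) sim[a, b],
                 lib$truth$cliff_pairs$id_a, lib$truth$cliff_pairs$id_b)
    build_landscape(ref_dataset(), ref_fingerprints(scheme),
                    landscape_config(sim_threshold_rule = "fixed",
                                     fixed_sim_threshold = min(ps) - 0.01))
  })
}

# small raw activity table in the ChEMBL export dialect
raw_activity_rows <- function(smiles, pic50,
                              relation = "=", type = "IC50", units = "nM",
                              ids = NULL) {
  n <- max(length(smiles), length(pic50))
  tibble::tibble(
    molecule_chembl_id = if (is.null(ids)) sprintf("CPD%03d", seq_len(n)) else ids,
    canonical_smiles = rep_len(smiles, n),
    standard_type = rep_len(type, n),
    standard_relation = rep_len(relation, n),
    standard_value = 10^(9 - rep_len(pic50, n)),
    standard_units = rep_len(units, n)
  )
}

# independent oracle: one-vs-rest metrics by direct enumeration of the 2x2
# tables, written without reference to the package implementation
oracle_ovr_metrics <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  correct <- 0
  for (i in seq_len(nrow(cm))) correct <- correct + cm[i, i]
  recalls <- c()
  mccs <- c()
  for (i in seq_len(nrow(cm))) {
    tp <- cm[i, i]
    fn <- 0
    for (j in seq_len(ncol(cm))) if (j != i) fn <- fn + cm[i, j]
    fp <- 0
    for (j in seq_len(nrow(cm))) if (j != i) fp <- fp + cm[j, i]
    tn <- n - tp - fn - fp
    recalls <- c(recalls, if (tp + fn == 0) 0 else tp / (tp + fn))
    d <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mccs <- c(mccs, if (d == 0) 0 else (tp * tn - fp * fn) / d)
  }
  list(accuracy = correct / n,
       macro_recall = mean(recalls),
       macro_mcc = mean(mccs))
}

# well-separated 4-class feature blobs for model sanity checks
separable_classes <- function(n_per_class = 30, p = 10, seed = 1) {
  withr::with_seed(seed, {
    centers <- diag(4) %x% matrix(8, 1, ceiling(p / 4))
    centers <- centers[, seq_len(p), drop = FALSE]
    x <- do.call(rbind, lapply(1:4, function(k) {
      matrix(stats::rnorm(n_per_class * p, mean = rep(centers[k, ], each = n_per_class),
                          sd = 0.5), nrow = n_per_class)
    }))
    list(x = x, y = factor(rep(paste0("c", 1:4), each = n_per_class)))
  })
}
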