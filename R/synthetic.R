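# Synthetic inhibitor libraries with known ground truth.
#
# Molecules are built by decorating a small scaffold library at two marked
# attachment positions with substituent fragments; pIC50 follows an additive
# scaffold + substituent model plus optional Gaussian assay noise. Activity
# cliffs are planted as single-substituent swaps: a plain compound (H at the
# warhead position) is paired with hydroxamate-warhead analogues whose
# contribution gap (>= 2.5 log units) guarantees a >= 2 log-unit activity
# difference at zero noise, while the shared scaffold and second substituent
# keep the pair structurally near-identical.

#' Default synthetic scaffold library
#'
#' Six chemotypes echoing common inhibitor frameworks (biphenyl,
#' benzyloxybenzene, 4-phenyl-2-pyridinone, 2-phenyl-oxazoline,
#' phenoxymethyl-phenyl-oxadiazole, benzene), each with two variable
#' substituent positions (`(%1)`, `(%2)`) and one fixed position (`(%T)`)
#' that carries a constant amide tail in every molecule of the series (a
#' shared elaborated core, as real lead series have; it also keeps pairwise
#' fingerprint similarities in a realistic range). `symmetric` marks scaffolds
#' whose two variable positions are equivalent by symmetry, where substituent
#' pairs are therefore enumerated unordered.
#'
#' @return Tibble: `scaffold_id`, `template`, `base_pic50`, `frequency`,
#'   `symmetric`.
#' @export
default_scaffolds <- function() {
  tibble::tibble(
    scaffold_id = paste0("s", 1:6),
    template = c(
      "c1(%T)cc(%2)cc(-c2ccc(%1)cc2)c1",
      "c1(%T)cc(%2)ccc1COc1ccc(%1)cc1",
      "O=C1C(%2)=C(c2ccc(%1)c(%T)c2)C=CN1",
      "O1CCN=C1c1cc(%1)c(%T)c(%2)c1",
      "c1(%T)cc(%2)ccc1-c1noc(COc2ccc(%1)cc2)n1",
      "c1(%T)cc(%1)cc(%2)c1"
    ),
    base_pic50 = c(6.352, 6.653, 7.051, 6.154, 6.952, 6.453),
    frequency = c(108L, 26L, 22L, 29L, 10L, 16L),
    symmetric = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE)
  )
}

#' Default substituent library
#'
#' Fragment SMILES (attached via their first atom) with additive pIC50
#' contributions. Roles: `decoration` fragments (halogen- and sulfur-free) are
#' sampled freely; `anchor` fragments are reserved for the second position of
#' planted cliff pairs and each carries an element class absent from the rest
#' of the library (S, F, Cl, Br, I), so a planted pair - which shares its
#' anchor - is structurally closer than any other pair with a comparable
#' activity gap; `warhead` fragments are the hydroxamic-acid groups whose
#' large contribution creates the planted cliffs (fingerprint-quiet next to
#' the constant amide tail every scaffold carries); the `booster` fragment (a
#' homologated hydroxamate, +1.55) populates the active class without forming
#' cliffs. Decoration contributions span < 0.45 log units and scaffold bases
#' span < 0.9, so no compound pair without a warhead can differ by 2 log
#' units.
#'
#' @return Tibble: `smiles` (`""` = hydrogen), `contribution`, `role`.
#' @export
default_substituents <- function() {
  tibble::tibble(
    smiles = c("", "C", "CC", "C(C)C", "O", "OC", "N", "C#N",
               "NC(C)=O", "OCC", "N(C)C", "CO",
               "S(C)(=O)=O", "C(F)(F)F", "Cl", "Br", "I",
               "C(=O)NO", "C(=O)N(C)O",
               "CC(=O)NO"),
    contribution = c(0, 0.12, 0.08, 0.05, 0.33, 0.21, 0.29, -0.08,
                     0.31, 0.17, 0.27, 0.14,
                     0.24, 0.35, 0.26, 0.22, 0.18,
                     2.55, 2.66,
                     1.55),
    role = c(rep("decoration", 12), rep("anchor", 5), rep("warhead", 2),
             "booster")
  )
}

#' Specification for a synthetic inhibitor library
#'
#' @param scaffolds Scaffold tibble as in [default_scaffolds()].
#' @param substituents Substituent tibble as in [default_substituents()].
#' @param n_cliff_pairs Number of planted activity-cliff pairs (default 10).
#'   Pairs come in twos sharing their plain (warhead-free) compound, so 10
#'   pairs plant 5 cliff generators.
#' @param noise_sd Gaussian assay noise on pIC50, log units (default 0.3,
#'   a typical inter-assay IC50 spread; set 0 for exact bookkeeping).
#' @param tail_smiles Constant fragment at the fixed `(%T)` position of every
#'   scaffold (default an N-methoxy amide tail).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(scaffolds = default_scaffolds(),
                           substituents = default_substituents(),
                           n_cliff_pairs = 10L, noise_sd = 0.3,
                           tail_smiles = "CC(=O)N(C)OC", seed = 42L) {
  stopifnot(all(scaffolds$frequency >= 1), noise_sd >= 0,
            n_cliff_pairs >= 0)
  structure(list(scaffolds = scaffolds, substituents = substituents,
                 n_cliff_pairs = as.integer(n_cliff_pairs),
                 noise_sd = noise_sd, tail_smiles = tail_smiles,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

decorate <- function(template, sub1, sub2, tail = "") {
  s <- sub("(%1)", if (nzchar(sub1)) paste0("(", sub1, ")") else "",
           template, fixed = TRUE)
  s <- sub("(%2)", if (nzchar(sub2)) paste0("(", sub2, ")") else "", s, fixed = TRUE)
  sub("(%T)", if (nzchar(tail)) paste0("(", tail, ")") else "", s, fixed = TRUE)
}

#' Generate a synthetic activity table with ground truth
#'
#' Produces an activity table in the exact ChEMBL-export dialect the curation
#' module reads (IC50 in nM, relation `"="`), plus the ground truth needed to
#' verify every downstream stage: per-molecule scaffold and noise-free class,
#' planted cliff pairs and cliff generators, and class/scaffold counts.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_library`: `activities` (tibble in
#'   curation input format) and `truth` (list: `molecules`, `cliff_pairs`,
#'   `generators`, `class_counts`, `scaffold_counts`).
#' @export
generate_library <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sc <- spec$scaffolds
  su <- spec$substituents
  deco <- su[su$role == "decoration", , drop = FALSE]
  anchors <- su[su$role == "anchor", , drop = FALSE]
  warheads <- su[su$role == "warhead", , drop = FALSE]
  boosters <- su[su$role == "booster", , drop = FALSE]

  # ---- plant cliff pairs -------------------------------------------------
  n_generators <- ceiling(spec$n_cliff_pairs / 2)
  planted <- list()
  if (spec$n_cliff_pairs > 0) {
    if (nrow(warheads) < 1) stop("cliff planting needs warhead substituents")
    if (nrow(anchors) < 1) stop("cliff planting needs anchor substituents")
    asym <- which(!sc$symmetric)
    if (!length(asym)) stop("cliff planting needs at least one asymmetric scaffold")
    # plant on the highest-frequency scaffolds first: a warhead swap on a
    # large, well-populated framework is a small relative structural change,
    # so planted pairs stay the most similar high-gap pairs in the library
    asym <- asym[order(-sc$frequency[asym])]
    slots <- expand.grid(anchor = seq_len(nrow(anchors)), scaffold = asym)
    if (n_generators > nrow(slots)) {
      stop("impossible demand: ", n_generators, " cliff generators but only ",
           nrow(slots), " scaffold x anchor slots")
    }
    pair_budget <- spec$n_cliff_pairs
    used <- stats::setNames(integer(nrow(sc)), sc$scaffold_id)
    combos_per_gen <- 3L + as.integer(nrow(boosters) > 0)
    s <- 1L
    for (g in seq_len(n_generators)) {
      # skip scaffolds whose frequency cannot host another planted block
      while (s <= nrow(slots) &&
             used[slots$scaffold[s]] + combos_per_gen > sc$frequency[slots$scaffold[s]]) {
        s <- s + 1L
      }
      if (s > nrow(slots)) {
        stop("impossible demand: scaffold frequencies too small for ",
             n_generators, " cliff generators")
      }
      k <- slots$scaffold[s]; a <- slots$anchor[s]
      partners <- min(2L, pair_budget)
      planted[[g]] <- list(scaffold = k, anchor = a,
                           warheads = seq_len(nrow(warheads))[seq_len(partners)])
      used[k] <- used[k] + combos_per_gen
      pair_budget <- pair_budget - partners
      s <- s + 1L
    }
  }

  # ---- assemble per-scaffold combos --------------------------------------
  # a combo is (sub1, sub2) given as substituent SMILES
  rows <- list()
  withr::with_seed(spec$seed, {
    for (k in seq_len(nrow(sc))) {
      planted_here <- Filter(function(p) p$scaffold == k, planted)
      combos <- list()
      for (p in planted_here) {
        anc <- anchors$smiles[p$anchor]
        combos <- c(combos, list(c("", anc)))
        for (w in p$warheads) combos <- c(combos, list(c(warheads$smiles[w], anc)))
        # one active-class compound per generator; its +1.55 contribution can
        # never yield a >= 2 log-unit gap, so it forms no cliff
        if (nrow(boosters)) combos <- c(combos, list(c(boosters$smiles[1], anc)))
      }
      n_planted <- length(combos)
      n_random <- sc$frequency[k] - n_planted
      if (n_random < 0) {
        stop("impossible frequency demand for ", sc$scaffold_id[k],
             ": frequency ", sc$frequency[k], " < ", n_planted, " planted combos")
      }
      grid <- expand.grid(i = seq_len(nrow(deco)), j = seq_len(nrow(deco)))
      if (sc$symmetric[k]) grid <- grid[grid$i <= grid$j, , drop = FALSE]
      if (n_random > nrow(grid)) {
        stop("impossible frequency demand for ", sc$scaffold_id[k],
             ": frequency ", sc$frequency[k], " > ", nrow(grid) + n_planted,
             " distinct decorations available")
      }
      pick <- grid[sample.int(nrow(grid), n_random), , drop = FALSE]
      combos <- c(combos, lapply(seq_len(nrow(pick)), function(r) {
        c(deco$smiles[pick$i[r]], deco$smiles[pick$j[r]])
      }))
      for (cb in combos) {
        # empty-string SMILES (hydrogen) cannot be looked up by name
        c1 <- su$contribution[match(cb[1], su$smiles)]
        c2 <- su$contribution[match(cb[2], su$smiles)]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          scaffold_id = sc$scaffold_id[k],
          template = sc$template[k],
          sub1 = cb[1], sub2 = cb[2],
          true_pic50 = sc$base_pic50[k] + c1 + c2
        )
      }
    }
    mols <- dplyr::bind_rows(rows)
    mols$noise <- if (spec$noise_sd > 0) stats::rnorm(nrow(mols), 0, spec$noise_sd) else 0
  })
  mols$compound_id <- sprintf("SYN%05d", seq_len(nrow(mols)))
  mols$smiles <- mapply(decorate, mols$template, mols$sub1, mols$sub2,
                        MoreArgs = list(tail = spec$tail_smiles),
                        USE.NAMES = FALSE)
  mols$pic50 <- mols$true_pic50 + mols$noise
  mols$true_class <- classify_activity(mols$true_pic50)

  # ---- planted pair bookkeeping ------------------------------------------
  cliff_pairs <- tibble::tibble(id_a = character(0), id_b = character(0),
                                generator = character(0))
  generators <- character(0)
  if (length(planted)) {
    find_id <- function(k, s1, s2) {
      hit <- which(mols$scaffold_id == sc$scaffold_id[k] &
                   mols$sub1 == s1 & mols$sub2 == s2)
      mols$compound_id[hit[1]]
    }
    for (p in planted) {
      anc <- anchors$smiles[p$anchor]
      plain <- find_id(p$scaffold, "", anc)
      partners <- vapply(p$warheads, function(w) {
        find_id(p$scaffold, warheads$smiles[w], anc)
      }, character(1))
      for (pt in partners) {
        ab <- sort(c(plain, pt))
        cliff_pairs <- dplyr::bind_rows(cliff_pairs, tibble::tibble(
          id_a = ab[1], id_b = ab[2], generator = plain))
      }
      if (length(partners) >= 2) generators <- c(generators, plain)
    }
  }

  activities <- tibble::tibble(
    molecule_chembl_id = mols$compound_id,
    canonical_smiles = mols$smiles,
    standard_type = "IC50",
    standard_relation = "=",
    standard_value = 10^(9 - mols$pic50),
    standard_units = "nM"
  )
  bare <- vapply(sc$template, decorate, "", sub1 = "", sub2 = "",
                 tail = "", USE.NAMES = FALSE)
  scaffold_smiles <- canonicalize_smiles(bare)
  truth <- list(
    molecules = tibble::tibble(
      compound_id = mols$compound_id, smiles = mols$smiles,
      scaffold_id = mols$scaffold_id,
      scaffold_smiles = scaffold_smiles[match(mols$scaffold_id, sc$scaffold_id)],
      sub1 = mols$sub1, sub2 = mols$sub2,
      true_pic50 = mols$true_pic50, observed_pic50 = mols$pic50,
      true_class = mols$true_class,
      group = assign_group(mols$true_pic50)
    ),
    cliff_pairs = cliff_pairs,
    generators = generators,
    class_counts = table(mols$true_class),
    scaffold_counts = table(mols$scaffold_id)
  )
  structure(list(activities = activities, truth = truth, spec = spec),
            class = "synthetic_library")
}

#' @export
print.synthetic_library <- function(x, ...) {
  cat("synthetic_library:", nrow(x$activities), "molecules,",
      nrow(x$truth$cliff_pairs), "planted cliff pairs,",
      length(x$truth$generators), "planted generators\n")
  invisible(x)
}

#' Write a synthetic activity table to CSV
#'
#' Emits exactly the dialect [read_activity_table()] reads; byte-identical for
#' the same spec and seed.
#'
#' @param library A `synthetic_library`.
#' @param path Output CSV path; ground truth is written to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(library, path) {
  stopifnot(inherits(library, "synthetic_library"))
  df <- as.data.frame(library$activities)
  df$standard_value <- sprintf("%.10g", df$standard_value)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  truth <- library$truth
  truth$molecules <- as.data.frame(truth$molecules)
  truth$molecules$true_class <- as.character(truth$molecules$true_class)
  truth$molecules$group <- as.character(truth$molecules$group)
  truth$class_counts <- as.list(truth$class_counts)
  truth$scaffold_counts <- as.list(truth$scaffold_counts)
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
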