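#' Structure-Activity Landscape Index (SALI)
#'
#' `|pIC50_a - pIC50_b| / (1 - similarity)` for a compound pair. Identical
#' structures (similarity 1) with different activity give `Inf` (flagged
#' discontinuity); identical structures with identical activity give 0.
#'
#' @param pic50_a,pic50_b Activities (pIC50), vectorized.
#' @param similarity Tanimoto similarity in `[0, 1]`.
#' @return Numeric SALI value(s), possibly `Inf`.
#' @export
sali <- function(pic50_a, pic50_b, similarity) {
  if (any(similarity < 0 | similarity > 1, na.rm = TRUE)) {
    stop("similarity must lie in [0, 1]")
  }
  delta <- abs(pic50_a - pic50_b)
  out <- ifelse(similarity == 1,
                ifelse(delta == 0, 0, Inf),
                delta / (1 - similarity))
  out
}

#' Similarity threshold for activity-cliff calls
#'
#' Mean plus two (sample, n-1) standard deviations of the pairwise similarity
#' distribution, capped at 1.
#'
#' @param similarities Numeric vector of pairwise similarities (n >= 2).
#' @return Threshold in `[0, 1]`.
#' @export
similarity_threshold <- function(similarities) {
  similarities <- similarities[!is.na(similarities)]
  if (length(similarities) < 2) stop("need at least 2 similarity values")
  min(mean(similarities) + 2 * stats::sd(similarities), 1)
}

#' Landscape configuration
#'
#' @param activity_threshold Minimum absolute pIC50 difference for a cliff
#'   (default 2 log units).
#' @param sim_threshold_rule `"mean_plus_2sd"` (data-driven, default) or
#'   `"fixed"`.
#' @param fixed_sim_threshold Similarity threshold when `rule = "fixed"`.
#' @param min_cliffs Cliffs a compound must participate in to count as a
#'   cliff generator (default 2).
#' @return List of class `landscape_config`.
#' @export
landscape_config <- function(activity_threshold = 2,
                             sim_threshold_rule = c("mean_plus_2sd", "fixed"),
                             fixed_sim_threshold = NULL,
                             min_cliffs = 2L) {
  sim_threshold_rule <- match.arg(sim_threshold_rule)
  stopifnot(activity_threshold > 0)
  if (sim_threshold_rule == "fixed" &&
      (is.null(fixed_sim_threshold) || fixed_sim_threshold < 0 || fixed_sim_threshold > 1)) {
    stop("fixed rule needs fixed_sim_threshold in [0, 1]")
  }
  structure(list(activity_threshold = activity_threshold,
                 sim_threshold_rule = sim_threshold_rule,
                 fixed_sim_threshold = fixed_sim_threshold,
                 min_cliffs = as.integer(min_cliffs)),
            class = "landscape_config")
}

#' Build the pairwise structure-activity landscape (SAS map data)
#'
#' Emits every unordered compound pair with its similarity, activity
#' difference, SALI value and SAS-map quadrant. Quadrants: similarity >=
#' threshold & delta >= activity threshold -> `cliff`; similarity >= threshold
#' & small delta -> `smooth`; low similarity & large delta -> `nondescript`;
#' low similarity & small delta -> `scaffold_hop`.
#'
#' @param dataset A `curated_dataset`.
#' @param fps A `fingerprint_set` covering every compound in `dataset`.
#' @param config A [landscape_config()].
#' @return Tibble of class `landscape` with one row per pair (`id_a < id_b`
#'   lexicographically) and attributes `sim_threshold`, `scheme`,
#'   `activity_threshold`, `n_excluded` (all-zero fingerprints).
#' @export
build_landscape <- function(dataset, fps, config = landscape_config()) {
  stopifnot(inherits(dataset, "curated_dataset"), inherits(fps, "fingerprint_set"))
  rec <- dataset$records
  missing_fp <- setdiff(rec$compound_id, fps$ids)
  if (length(missing_fp)) {
    stop("compounds missing fingerprints: ", paste(missing_fp, collapse = ", "))
  }
  m <- fps$matrix[rec$compound_id, , drop = FALSE]
  sim <- withCallingHandlers(
    similarity_matrix(m),
    warning = function(w) invokeRestart("muffleWarning")
  )
  usable <- !is.na(diag(sim))
  n_excluded <- sum(!usable)
  if (n_excluded) {
    warning(n_excluded, " compound(s) with all-zero fingerprints excluded from the landscape")
  }
  ids <- rec$compound_id[usable]
  act <- rec$pic50[usable]
  sim <- sim[usable, usable, drop = FALSE]

  n <- length(ids)
  if (n < 2) stop("need at least 2 compounds with usable fingerprints")
  iu <- which(upper.tri(sim), arr.ind = TRUE)
  a <- iu[, 1]; b <- iu[, 2]
  swap <- ids[a] > ids[b]
  id_a <- ifelse(swap, ids[b], ids[a])
  id_b <- ifelse(swap, ids[a], ids[b])
  s <- sim[iu]
  delta <- abs(act[a] - act[b])

  sim_thr <- switch(config$sim_threshold_rule,
                    mean_plus_2sd = similarity_threshold(s),
                    fixed = config$fixed_sim_threshold)
  act_thr <- config$activity_threshold

  high_sim <- s >= sim_thr
  high_delta <- delta >= act_thr
  quadrant <- ifelse(high_sim & high_delta, "cliff",
              ifelse(high_sim, "smooth",
              ifelse(high_delta, "nondescript", "scaffold_hop")))

  out <- tibble::tibble(
    id_a = id_a, id_b = id_b,
    similarity = s, delta_activity = delta,
    sali = sali(act[a], act[b], s),
    quadrant = factor(quadrant, levels = c("smooth", "cliff", "nondescript", "scaffold_hop")),
    is_cliff = high_sim & high_delta
  )
  attr(out, "sim_threshold") <- sim_thr
  attr(out, "activity_threshold") <- act_thr
  attr(out, "scheme") <- fps$scheme
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("landscape", class(out))
  out
}

pair_key <- function(id_a, id_b) paste(id_a, id_b, sep = "\r")

#' Consensus activity cliffs and cliff generators across fingerprint schemes
#'
#' Consensus cliffs are the exact intersection of the unordered cliff-pair
#' sets of each scheme. A compound is a cliff generator in a scheme when it
#' participates in at least `min_cliffs` cliffs there; consensus generators
#' are generators in every scheme analysed.
#'
#' @param landscapes Named list of `landscape` tibbles (>= 2 schemes).
#' @param min_cliffs Generator threshold (default 2).
#' @return List with `cliffs` (consensus pair tibble), `generators`
#'   (per-compound tibble: cliff counts per scheme, per-scheme generator flags,
#'   consensus flag) and `per_scheme_cliff_counts`.
#' @export
consensus_cliffs <- function(landscapes, min_cliffs = 2L) {
  if (length(landscapes) < 2) stop("need at least 2 fingerprint schemes")
  if (is.null(names(landscapes)) || any(!nzchar(names(landscapes)))) {
    names(landscapes) <- vapply(landscapes, function(l) attr(l, "scheme"), "")
  }
  cliff_sets <- lapply(landscapes, function(l) l[l$is_cliff, c("id_a", "id_b")])
  sizes <- vapply(cliff_sets, nrow, integer(1))
  if (any(sizes == 0)) {
    warning("empty cliff set in scheme(s): ",
            paste(names(sizes)[sizes == 0], collapse = ", "),
            "; consensus is empty")
  }
  keys <- lapply(cliff_sets, function(cs) pair_key(cs$id_a, cs$id_b))
  common <- Reduce(intersect, keys)
  first <- cliff_sets[[1]]
  consensus <- first[pair_key(first$id_a, first$id_b) %in% common, , drop = FALSE]
  stopifnot(nrow(consensus) <= min(sizes))

  all_ids <- sort(unique(unlist(lapply(cliff_sets, function(cs) c(cs$id_a, cs$id_b)))))
  gen <- tibble::tibble(compound_id = all_ids)
  for (sc in names(cliff_sets)) {
    cs <- cliff_sets[[sc]]
    cnt <- table(c(cs$id_a, cs$id_b))
    gen[[paste0("n_cliffs_", sc)]] <- as.integer(cnt[gen$compound_id])
    gen[[paste0("n_cliffs_", sc)]][is.na(gen[[paste0("n_cliffs_", sc)]])] <- 0L
    gen[[paste0("generator_", sc)]] <- gen[[paste0("n_cliffs_", sc)]] >= min_cliffs
  }
  flag_cols <- grep("^generator_", names(gen), value = TRUE)
  gen$consensus_generator <- Reduce(`&`, gen[flag_cols])
  list(cliffs = tibble::as_tibble(consensus),
       generators = gen,
       per_scheme_cliff_counts = sizes)
}
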