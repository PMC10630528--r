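#' Bemis-Murcko scaffold of a molecule
#'
#' Removes all side chains, keeping ring systems and the linkers connecting
#' them. Exocyclic double-bonded atoms attached to the retained framework
#' (e.g. ring carbonyl oxygens) are kept, the standard Bemis-Murcko
#' convention. Acyclic molecules map to the empty-scaffold sentinel `""`.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical scaffold SMILES (`""` for acyclic
#'   molecules).
#' @examples
#' murcko_scaffold("Oc1ccc(-c2ccccc2)cc1")  # biphenyl
#' murcko_scaffold("Cc1ccccc1")             # benzene
#' murcko_scaffold("CCCCCC")                # "" (no ring system)
#' @export
murcko_scaffold <- function(smiles) {
  ids <- as.character(seq_along(smiles))
  sdf <- smiles_to_sdf(smiles, ids)
  vapply(seq_along(smiles), function(i) murcko_one(sdf[[i]]), character(1))
}

murcko_one <- function(mol) {
  mg <- mol_graph(mol)
  ring <- ring_atoms(mg)
  if (!length(ring)) return("")
  # iteratively prune terminal non-ring atoms: what survives is rings + linkers
  keep <- rep(TRUE, mg$n)
  deg <- igraph::degree(mg$graph)
  adj <- lapply(seq_len(mg$n), function(v) as.integer(igraph::neighbors(mg$graph, v)))
  in_ring <- logical(mg$n); in_ring[ring] <- TRUE
  repeat {
    leaves <- which(keep & !in_ring & deg <= 1)
    if (!length(leaves)) break
    keep[leaves] <- FALSE
    for (v in leaves) {
      for (u in adj[[v]]) if (keep[u]) deg[u] <- deg[u] - 1L
    }
    deg[leaves] <- 0L
  }
  # restore atoms multiple-bonded to the framework (exocyclic =O and alike)
  if (nrow(mg$edges)) {
    for (e in seq_len(nrow(mg$edges))) {
      if (mg$order[e] >= 2) {
        a <- mg$edges[e, 1]; b <- mg$edges[e, 2]
        if (keep[a] && !keep[b]) keep[b] <- TRUE
        if (keep[b] && !keep[a]) keep[a] <- TRUE
      }
    }
  }
  frame <- ChemmineR::atomsubset(mol, atomrows = which(keep))
  out <- sdf_to_canonical(frame)
  if (is.na(out)) "" else out
}

#' Generic cyclic skeleton of a scaffold
#'
#' Replaces every atom by carbon and every bond by a single bond, then
#' canonicalizes: the graph framework of the scaffold, used to group
#' chemotypes regardless of heteroatoms and bond orders. Idempotent.
#'
#' @param scaffold_smiles Character vector of scaffold SMILES; the empty
#'   sentinel `""` maps to itself.
#' @return Character vector of canonical skeleton SMILES.
#' @examples
#' cyclic_skeleton("c1ccncc1")  # cyclohexane frame "C1CCCCC1"
#' @export
cyclic_skeleton <- function(scaffold_smiles) {
  out <- character(length(scaffold_smiles))
  todo <- which(!is.na(scaffold_smiles) & nzchar(scaffold_smiles))
  if (!length(todo)) return(out)
  sdf <- smiles_to_sdf(scaffold_smiles[todo], as.character(todo))
  for (j in seq_along(todo)) {
    mol <- sdf[[j]]
    ab <- ChemmineR::atomblock(mol)
    rownames(ab) <- paste0("C_", seq_len(nrow(ab)))
    if (ncol(ab) >= 6) ab[, 6] <- 0  # clear formal charges
    bb <- ChemmineR::bondblock(mol)
    if (!is.null(dim(bb)) && nrow(bb)) bb[, 3] <- 1
    mol@atomblock <- ab
    mol@bondblock <- bb
    s <- sdf_to_canonical(mol)
    out[todo[j]] <- if (is.na(s)) "" else s
  }
  out
}

#' Scaffold frequency, activity and diversity analysis
#'
#' Groups a curated data set by Murcko scaffold, reports per-scaffold
#' frequency, pIC50 summary and a favorability label, plus scaffold-diversity
#' statistics for the whole set and for the potency groups.
#'
#' Favorability is an enrichment rule: among scaffolds at or above
#' `min_frequency`, a scaffold is `favorable` when the fraction of its member
#' compounds in group 1 (pIC50 >= 8) exceeds `enrich_hi` times the
#' dataset-wide group-1 fraction, `unfavorable` below `enrich_lo` times it,
#' otherwise `neutral`.
#'
#' @param dataset A `curated_dataset`.
#' @param min_frequency Frequency cut for the headline table (default 10); the
#'   full table is returned regardless, with `headline = frequency >= cut`.
#' @param enrich_hi,enrich_lo Enrichment multipliers for the favorability rule
#'   (defaults 1.5 and 0.5).
#' @return List with `scaffolds` (tibble: scaffold and skeleton SMILES,
#'   frequency, member ids, pIC50 summary columns, group-1 fraction,
#'   favorability, headline flag) and `diversity` (tibble per subset: number
#'   of molecules and scaffolds, scaffold/molecule ratio, singleton fraction).
#' @export
scaffold_table <- function(dataset, min_frequency = 10L,
                           enrich_hi = 1.5, enrich_lo = 0.5) {
  stopifnot(inherits(dataset, "curated_dataset"))
  rec <- dataset$records
  scaf <- murcko_scaffold(rec$canonical_smiles)
  rec$scaffold <- scaf

  cyclic <- rec[nzchar(rec$scaffold), , drop = FALSE]
  overall_g1 <- mean(rec$group == "group1")

  groups <- split(seq_len(nrow(cyclic)), cyclic$scaffold)
  uniq_scaf <- names(groups)
  skeletons <- cyclic_skeleton(uniq_scaf)
  tab <- dplyr::bind_rows(lapply(seq_along(groups), function(k) {
    ix <- groups[[k]]
    s <- summarize_values(cyclic$pic50[ix])
    g1_frac <- mean(cyclic$group[ix] == "group1")
    tibble::tibble(
      scaffold_smiles = uniq_scaf[k],
      skeleton_smiles = skeletons[k],
      frequency = length(ix),
      member_ids = list(cyclic$compound_id[ix]),
      pic50_min = s$min, pic50_median = s$median,
      pic50_mean = s$mean, pic50_max = s$max,
      group1_fraction = g1_frac
    )
  }))
  tab <- tab[order(-tab$frequency, tab$scaffold_smiles), , drop = FALSE]
  tab$headline <- tab$frequency >= min_frequency
  ratio <- if (overall_g1 > 0) tab$group1_fraction / overall_g1 else Inf
  tab$favorability <- ifelse(!tab$headline, "neutral",
                      ifelse(ratio > enrich_hi, "favorable",
                      ifelse(ratio < enrich_lo, "unfavorable", "neutral")))

  subsets <- list(all = rec,
                  group1 = rec[rec$group == "group1", , drop = FALSE],
                  group2 = rec[rec$group == "group2", , drop = FALSE])
  diversity <- dplyr::bind_rows(lapply(names(subsets), function(nm) {
    sub <- subsets[[nm]]
    sub <- sub[nzchar(sub$scaffold), , drop = FALSE]
    if (!nrow(sub)) {
      return(tibble::tibble(subset = nm, n_molecules = 0L, n_scaffolds = 0L,
                            scaffold_per_molecule = NA_real_,
                            singleton_fraction = NA_real_))
    }
    freq <- table(sub$scaffold)
    tibble::tibble(
      subset = nm,
      n_molecules = nrow(sub),
      n_scaffolds = length(freq),
      scaffold_per_molecule = length(freq) / nrow(sub),
      singleton_fraction = mean(freq == 1)
    )
  }))
  list(scaffolds = tab, diversity = diversity,
       n_acyclic = sum(!nzchar(rec$scaffold)))
}
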