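#' Compute the six drug-likeness descriptors
#'
#' Molecular weight (Da), octanol-water partition coefficient (LogP, OpenBabel
#' atom-contribution estimator), hydrogen-bond acceptor and donor counts,
#' rotatable-bond count and topological polar surface area (TPSA, Ertl).
#' All values are deterministic functions of the canonical structure.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional compound identifiers.
#' @return Tibble with columns `compound_id`, `mw`, `logp`, `nha`, `nhd`,
#'   `nrot`, `tpsa`.
#' @examples
#' compute_descriptors(c(benzene = "c1ccccc1", ethanol = "CCO"))
#' @export
compute_descriptors <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else as.character(seq_along(smiles))
  sdf <- smiles_to_sdf(smiles, ids)
  p <- ob_quiet(ChemmineR::propOB(sdf))
  nrot <- ob_quiet(ChemmineR::smartsSearchOB(sdf, rotatable_bond_smarts(), uniqueMatches = TRUE))
  out <- tibble::tibble(
    compound_id = ids,
    mw = as.numeric(p$MW),
    logp = as.numeric(p$logP),
    nha = as.integer(p$HBA1),
    nhd = as.integer(p$HBD),
    nrot = as.integer(nrot),
    tpsa = as.numeric(p$TPSA)
  )
  # single-heavy-atom molecules went through the explicit-H path, where the
  # OpenBabel acceptor count misfires; apply the element rule directly
  for (i in attr(sdf, "explicit_h")) {
    mg <- mol_graph(sdf[[i]])
    heavy <- mg$symbol[mg$symbol != "H"]
    out$nha[i] <- as.integer(length(heavy) == 1 && heavy %in% c("N", "O", "F"))
    out$nhd[i] <- as.integer(length(heavy) == 1 && heavy %in% c("N", "O") &&
                               any(mg$symbol == "H"))
  }
  out
}

# single non-ring single bond between two non-terminal, non-triple-bond atoms
rotatable_bond_smarts <- function() "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' Name of the LogP estimator used, for provenance records
#' @return Character scalar.
#' @export
logp_estimator <- function() "OpenBabel logP (Wildman-Crippen atom contributions)"
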