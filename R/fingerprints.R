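#' Compute binary substructure fingerprints
#'
#' Two schemes are supported. `MACCS166` uses the OpenBabel implementation of
#' the 166 public MACCS keys. `PubChem881` is this package's own generator for
#' the 881-key PubChem/CACTVS substructure layout; see [pubchem_key_info()]
#' for which sections of the published specification are populated.
#'
#' @param x A `curated_dataset`, or a character vector of SMILES.
#' @param scheme `"MACCS166"` or `"PubChem881"`.
#' @param ids Compound identifiers when `x` is a character vector.
#' @return A `fingerprint_set`: list with `scheme`, `n_bits`, `ids` and
#'   `matrix` (compounds x bits, 0/1 integer, rownames = ids).
#' @export
compute_fingerprints <- function(x, scheme = c("MACCS166", "PubChem881"), ids = NULL) {
  scheme <- match.arg(scheme)
  if (inherits(x, "curated_dataset")) {
    smiles <- x$records$canonical_smiles
    ids <- x$records$compound_id
  } else {
    if (is.null(ids)) ids <- if (!is.null(names(x))) names(x) else as.character(seq_along(x))
    smiles <- unname(as.character(x))
  }
  sdf <- smiles_to_sdf(smiles, ids)
  m <- switch(scheme,
              MACCS166 = maccs_fingerprints(sdf),
              PubChem881 = pubchem_fingerprints(sdf))
  rownames(m) <- ids
  structure(list(scheme = scheme, n_bits = ncol(m), ids = ids, matrix = m),
            class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat("fingerprint_set:", x$scheme, "-", length(x$ids), "compounds x",
      x$n_bits, "bits;", sum(x$matrix), "bits set\n")
  invisible(x)
}

maccs_fingerprints <- function(sdf) {
  fp <- ob_quiet(ChemmineR::fingerprintOB(sdf, "MACCS"))
  m <- fp@fpma  # bit matrix slot of the FPset
  if (ncol(m) > 166) {
    extra <- m[, 167:ncol(m), drop = FALSE]
    stopifnot(sum(extra) == 0)  # published MACCS key count is 166
    m <- m[, 1:166, drop = FALSE]
  }
  storage.mode(m) <- "integer"
  colnames(m) <- paste0("maccs", seq_len(ncol(m)))
  m
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`, the standard similarity coefficient for binary
#' substructure fingerprints.
#'
#' @param a,b Equal-length 0/1 (or logical) vectors.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprints differ in length")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) stop("undefined similarity: both fingerprints are all-zero")
  sum(a & b) / u
}

#' Pairwise Tanimoto similarity matrix
#'
#' Compounds whose fingerprint has no set bit have undefined similarity; their
#' rows/columns are set to `NA` with a warning rather than treated as 0.
#'
#' @param fps A `fingerprint_set` or a 0/1 matrix with rownames.
#' @return Symmetric matrix of Tanimoto coefficients, unit diagonal for
#'   non-empty fingerprints.
#' @export
similarity_matrix <- function(fps) {
  m <- if (inherits(fps, "fingerprint_set")) fps$matrix else as.matrix(fps)
  storage.mode(m) <- "double"
  ones <- rowSums(m)
  inter <- tcrossprod(m)
  uni <- outer(ones, ones, "+") - inter
  sim <- inter / uni
  diag(sim) <- ifelse(ones > 0, 1, NA_real_)
  empty <- ones == 0
  if (any(empty)) {
    warning(sum(empty), " all-zero fingerprint(s) excluded from similarity: ",
            paste(rownames(m)[empty], collapse = ", "))
    sim[empty, ] <- NA_real_
    sim[, empty] <- NA_real_
  }
  dimnames(sim) <- list(rownames(m), rownames(m))
  sim
}
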