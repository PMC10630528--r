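#' @import methods
#' @importFrom ChemmineR smiles2sdf read.SDFset validSDF atomblock bondblock
#'   cid datablock rings atomsubset
#' @importFrom ChemmineOB convertFormat
NULL

# OpenBabel writes parse warnings straight to stderr; they are expected for
# deliberately malformed inputs and swallowed here.
ob_quiet <- function(expr) {
  tmp <- tempfile()
  con <- file(tmp, open = "wt")
  sink(con, type = "message")
  on.exit({
    sink(type = "message")
    close(con)
    unlink(tmp)
  })
  force(expr)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form, optionally keeping only the
#' largest fragment of multi-component (salt) inputs. The same canonicalizer
#' is used everywhere in the package (deduplication, scaffolds), so canonical
#' strings are directly comparable.
#'
#' @param smiles Character vector of SMILES.
#' @param strip_salts Keep only the fragment with the most heavy atoms when a
#'   molecule has disconnected components (default `TRUE`).
#' @return Character vector of canonical SMILES, `NA` for unparseable input.
#' @export
canonicalize_smiles <- function(smiles, strip_salts = TRUE) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  out[ok] <- ob_canonical(smiles[ok])
  if (strip_salts) {
    multi <- !is.na(out) & grepl(".", out, fixed = TRUE)
    if (any(multi)) {
      out[multi] <- vapply(out[multi], function(s) {
        frags <- strsplit(s, ".", fixed = TRUE)[[1]]
        # heavy-atom count approximated by element-symbol occurrences
        heavy <- vapply(frags, function(f) {
          f <- gsub("\\[[0-9]*H[0-9]*\\]", "", f)
          sum(gregexpr("[A-IK-PR-Za-ik-pr-z]", f)[[1]] > 0)
        }, numeric(1))
        ob_canonical(frags[which.max(heavy)])
      }, character(1))
    }
  }
  out
}

# batch canonicalization; falls back to per-item calls when any line fails,
# because OpenBabel drops the whole batch output on a single bad record
ob_canonical <- function(smiles) {
  src <- paste(paste(smiles, seq_along(smiles)), collapse = "\n")
  raw <- ob_quiet(ChemmineOB::convertFormat("SMI", "CAN", source = src))
  parsed <- parse_can_output(raw, length(smiles))
  if (!anyNA(parsed) || length(smiles) == 1L) return(parsed)
  vapply(smiles, function(s) {
    r <- ob_quiet(ChemmineOB::convertFormat("SMI", "CAN", source = paste(s, "1")))
    parse_can_output(r, 1L)
  }, character(1), USE.NAMES = FALSE)
}

parse_can_output <- function(raw, n) {
  out <- rep(NA_character_, n)
  if (!length(raw) || !nzchar(raw)) return(out)
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2) {
      i <- suppressWarnings(as.integer(parts[2]))
      if (!is.na(i) && i >= 1 && i <= n) out[i] <- parts[1]
    }
  }
  out
}

#' Parse SMILES into an SDF set
#'
#' Internal workhorse used by the descriptor, fingerprint and scaffold code.
#' Single-heavy-atom molecules (which yield SDF blocks with no bond records)
#' are retried with explicit hydrogens so that downstream OpenBabel calls see
#' a valid connection table.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Compound identifiers (defaults to names or indices).
#' @return A `ChemmineR::SDFset` with `cid` set to `ids`, in input order.
#' @keywords internal
smiles_to_sdf <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else as.character(seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  bad <- is.na(smiles) | !nzchar(trimws(smiles))
  if (any(bad)) {
    stop("unparseable SMILES for compound(s): ", paste(ids[bad], collapse = ", "))
  }
  sdf <- tryCatch(
    ob_quiet(suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids)))),
    error = function(e) NULL
  )
  if (is.null(sdf)) {
    # identify offenders one by one
    ok <- vapply(smiles, function(s) {
      x <- tryCatch(ob_quiet(suppressWarnings(ChemmineR::smiles2sdf(c(z = s)))),
                    error = function(e) NULL)
      !is.null(x)
    }, logical(1), USE.NAMES = FALSE)
    stop("unparseable SMILES for compound(s): ", paste(ids[!ok], collapse = ", "))
  }
  # molecules OpenBabel cannot parse are silently dropped by smiles2sdf
  got <- ChemmineR::cid(sdf)
  missing <- setdiff(ids, got)
  if (length(missing)) {
    stop("unparseable SMILES for compound(s): ", paste(missing, collapse = ", "))
  }
  valid <- suppressWarnings(ChemmineR::validSDF(sdf))
  if (all(valid)) return(sdf)
  # retry invalid entries with explicit hydrogens (single-atom molecules)
  for (i in which(!valid)) {
    raw <- ob_quiet(ChemmineOB::convertFormat(
      "SMI", "SDF", source = paste(smiles[i], ids[i]),
      options = data.frame(names = "h", args = "", stringsAsFactors = FALSE)
    ))
    fixed <- tryCatch({
      x <- suppressWarnings(ChemmineR::read.SDFset(strsplit(raw, "\n", fixed = TRUE)[[1]]))
      if (!all(suppressWarnings(ChemmineR::validSDF(x)))) NULL else x[[1]]
    }, error = function(e) NULL)
    if (is.null(fixed)) {
      stop("unparseable SMILES for compound(s): ", ids[i], " (", smiles[i], ")")
    }
    sdf[[i]] <- fixed
  }
  attr(sdf, "explicit_h") <- which(!valid)
  sdf
}

# SDF -> canonical SMILES for one ChemmineR::SDF object
sdf_to_canonical <- function(sdf_one) {
  txt <- paste(methods::as(sdf_one, "character"), collapse = "\n")
  raw <- ob_quiet(ChemmineOB::convertFormat("SDF", "CAN", source = txt))
  out <- strsplit(raw, "\t", fixed = TRUE)[[1]][1]
  if (is.na(out) || !nzchar(out)) NA_character_ else out
}

# molecular graph helpers ----------------------------------------------------

# adjacency info from a ChemmineR::SDF bond block
mol_graph <- function(sdf_one) {
  ab <- ChemmineR::atomblock(sdf_one)
  bb <- ChemmineR::bondblock(sdf_one)
  n <- nrow(ab)
  sym <- gsub("_.*$", "", rownames(ab))
  if (is.null(dim(bb)) || nrow(bb) == 0) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    return(list(n = n, symbol = sym, graph = g,
                edges = matrix(integer(0), ncol = 2), order = integer(0)))
  }
  edges <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  list(n = n, symbol = sym, graph = g, edges = edges, order = as.integer(bb[, 3]))
}

# indices of atoms that belong to at least one ring (endpoints of non-bridge edges)
ring_atoms <- function(mg) {
  if (nrow(mg$edges) == 0) return(integer(0))
  br <- igraph::bridges(mg$graph)
  keep <- setdiff(seq_len(nrow(mg$edges)), as.integer(br))
  sort(unique(as.vector(mg$edges[keep, , drop = FALSE])))
}
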