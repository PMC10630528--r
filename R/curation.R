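#' Convert an IC50 value to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the IC50 expressed in mol/L,
#' so 1 nM corresponds to 9 and 100 nM to 7.
#'
#' @param value Positive IC50 value(s).
#' @param units Unit string(s), recycled: one of `"nM"`, `"uM"` (also
#'   `"µM"`/`"um"`), `"mM"`, `"M"`.
#' @return Numeric pIC50 value(s).
#' @examples
#' to_pic50(1, "nM")    # 9
#' to_pic50(100, "nM")  # 7
#' @export
to_pic50 <- function(value, units) {
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("IC50 values must be positive and finite")
  }
  fac <- unit_to_molar(units)
  -log10(value * fac)
}

unit_to_molar <- function(units) {
  u <- tolower(trimws(units))
  u[u == "µm"] <- "um"
  fac <- c(nm = 1e-9, um = 1e-6, mm = 1e-3, m = 1)[u]
  if (anyNA(fac)) {
    stop("unknown concentration unit(s): ", paste(unique(units[is.na(fac)]), collapse = ", "))
  }
  unname(fac)
}

#' Assign an activity class from pIC50
#'
#' The four classes partition the pIC50 axis with left-closed intervals:
#' potent (pIC50 >= 9), active (9 > pIC50 >= 8), intermediate
#' (8 > pIC50 >= 7) and inactive (pIC50 < 7).
#'
#' @param pic50 Numeric pIC50 value(s); must be finite.
#' @return Factor with levels `potent`, `active`, `intermediate`, `inactive`.
#' @export
classify_activity <- function(pic50) {
  if (any(!is.finite(pic50))) stop("pIC50 must be finite")
  cls <- ifelse(pic50 >= 9, "potent",
         ifelse(pic50 >= 8, "active",
         ifelse(pic50 >= 7, "intermediate", "inactive")))
  factor(cls, levels = activity_levels())
}

activity_levels <- function() c("potent", "active", "intermediate", "inactive")

#' Assign the two-group label used for chemical-space comparisons
#'
#' Group 1 pools potent and active compounds (pIC50 >= 8); group 2 pools
#' intermediate and inactive compounds.
#'
#' @param pic50 Numeric pIC50 value(s).
#' @return Factor with levels `group1`, `group2`.
#' @export
assign_group <- function(pic50) {
  if (any(!is.finite(pic50))) stop("pIC50 must be finite")
  factor(ifelse(pic50 >= 8, "group1", "group2"), levels = c("group1", "group2"))
}

#' Read a ChEMBL-style activity export
#'
#' Expects the ChEMBL activity-export columns `molecule_chembl_id`,
#' `canonical_smiles`, `standard_type`, `standard_relation`, `standard_value`,
#' `standard_units`. The delimiter is auto-detected (tab vs comma) unless
#' given.
#'
#' @param path File path.
#' @param delim Optional delimiter override.
#' @return A tibble of raw activity rows.
#' @export
read_activity_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", na.strings = c("", "NA"))
  need <- c("molecule_chembl_id", "canonical_smiles", "standard_type",
            "standard_relation", "standard_value", "standard_units")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Curate a raw activity table into a compound data set
#'
#' Keeps IC50 rows with an exact (`"="`) relation, a parseable SMILES and a
#' convertible concentration unit, converts values to pIC50, collapses
#' duplicate canonical structures, and assigns activity classes and group
#' labels. Every filter's removal count is recorded in the provenance so that
#' removals + output = input.
#'
#' @param raw Tibble/data frame with the ChEMBL activity-export columns (see
#'   [read_activity_table()]).
#' @param aggregation How replicate pIC50 values of the same canonical
#'   structure are merged: `"median"` (default), `"mean"` or `"first"`.
#' @param strip_salts Keep only the largest fragment before canonicalization.
#' @return An object of class `curated_dataset`: a list with `records`
#'   (tibble: `compound_id`, `canonical_smiles`, `pic50`, `activity_class`,
#'   `group`) and `provenance` (counts per filter, settings).
#' @export
curate_activities <- function(raw, aggregation = c("median", "first", "mean"),
                              strip_salts = TRUE) {
  aggregation <- match.arg(aggregation)
  if (!nrow(raw)) stop("empty input table")
  n_in <- nrow(raw)
  removed <- c()

  keep <- !is.na(raw$standard_type) & toupper(raw$standard_type) == "IC50"
  removed["not_ic50"] <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]

  keep <- !is.na(raw$standard_value) & raw$standard_value > 0 &
    !is.na(raw$standard_units) & !is.na(raw$canonical_smiles) &
    nzchar(trimws(as.character(raw$canonical_smiles)))
  removed["missing"] <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]

  keep <- !is.na(raw$standard_relation) & trimws(raw$standard_relation) == "="
  removed["unqualified"] <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]

  keep <- tolower(trimws(raw$standard_units)) %in% c("nm", "um", "µm", "mm", "m")
  removed["unconvertible_units"] <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]

  if (!nrow(raw)) stop("empty dataset: no records survive curation filters")

  can <- canonicalize_smiles(as.character(raw$canonical_smiles), strip_salts = strip_salts)
  keep <- !is.na(can)
  removed["unparseable_smiles"] <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]
  can <- can[keep]
  if (!nrow(raw)) stop("empty dataset: no records survive curation filters")

  pic50 <- to_pic50(raw$standard_value, raw$standard_units)
  df <- tibble::tibble(compound_id = as.character(raw$molecule_chembl_id),
                       canonical_smiles = can, pic50 = pic50)

  agg_fun <- switch(aggregation,
                    median = stats::median,
                    mean = mean,
                    first = function(x) x[[1]])
  grp <- split(seq_len(nrow(df)), df$canonical_smiles)
  n_dup <- nrow(df) - length(grp)
  rows <- lapply(grp, function(ix) {
    tibble::tibble(compound_id = df$compound_id[ix[1]],
                   canonical_smiles = df$canonical_smiles[ix[1]],
                   pic50 = agg_fun(df$pic50[ix]))
  })
  rec <- dplyr::bind_rows(rows)
  # keep the original input order of first occurrence
  first_pos <- vapply(grp, min, numeric(1))
  rec <- rec[order(first_pos), , drop = FALSE]
  removed["redundant"] <- n_dup

  rec$activity_class <- classify_activity(rec$pic50)
  rec$group <- assign_group(rec$pic50)

  prov <- list(
    n_input = n_in,
    removed = as.list(removed),
    n_output = nrow(rec),
    aggregation = aggregation,
    strip_salts = strip_salts,
    canonicalizer = "openbabel-can",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  stopifnot(sum(unlist(removed)) + nrow(rec) == n_in)
  structure(list(records = rec, provenance = prov), class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat("curated_dataset:", nrow(x$records), "compounds (from",
      x$provenance$n_input, "input rows)\n")
  print(table(x$records$activity_class))
  invisible(x)
}

#' Write a curated data set to CSV plus a JSON provenance sidecar
#'
#' @param dataset A `curated_dataset`.
#' @param path Output CSV path; provenance goes to `<path>.provenance.json`.
#' @return `path`, invisibly.
#' @export
write_curated <- function(dataset, path) {
  stopifnot(inherits(dataset, "curated_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE)
  jsonlite::write_json(dataset$provenance, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Reproduce the curation on an existing activity export
#'
#' Convenience wrapper for reproduction runs: reads a ChEMBL activity export
#' from disk (e.g. a download of IC50 activities for a target) and runs the
#' standard curation. No network access is performed.
#'
#' @inheritParams read_activity_table
#' @inheritParams curate_activities
#' @return A `curated_dataset`.
#' @export
curate_activity_file <- function(path, delim = NULL,
                                 aggregation = "median", strip_salts = TRUE) {
  curate_activities(read_activity_table(path, delim),
                    aggregation = aggregation, strip_salts = strip_salts)
}
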