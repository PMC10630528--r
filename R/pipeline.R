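#' Pipeline configuration
#'
#' Bundles the settings of every stage. Exactly one of `input` (path to a
#' ChEMBL-style activity export) or `synthetic` (a [synthetic_spec()]) must be
#' given. The seed is propagated to every stochastic stage.
#'
#' @param input Path to an activity CSV/TSV, or `NULL`.
#' @param synthetic A `synthetic_spec`, or `NULL`.
#' @param schemes Fingerprint schemes to run (default both).
#' @param stages Stages to execute, in dependency order; subsets allowed.
#' @param aggregation,strip_salts Curation settings (see [curate_activities()]).
#' @param landscape A [landscape_config()].
#' @param variance_threshold,correlation_threshold Feature-filter settings.
#' @param split A [split_spec()].
#' @param algorithms Algorithm names for [benchmark_qsar()] (default all 12).
#' @param balance Balancing mode for [benchmark_qsar()].
#' @param min_frequency Scaffold-table frequency cut.
#' @param outdir Output directory for CSV/JSON artifacts, or `NULL` to skip
#'   writing.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            schemes = c("MACCS166", "PubChem881"),
                            stages = c("curation", "eda", "landscape", "qsar", "chemotype"),
                            aggregation = "median", strip_salts = TRUE,
                            landscape = landscape_config(),
                            variance_threshold = 0.1,
                            correlation_threshold = 0.90,
                            split = NULL, algorithms = NULL,
                            balance = "before_split",
                            min_frequency = 10L, outdir = NULL, seed = 42L) {
  if (is.null(input) == is.null(synthetic)) {
    stop("give exactly one of `input` or `synthetic`")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (is.null(split)) split <- split_spec(seed = seed)
  structure(list(input = input, synthetic = synthetic, schemes = schemes,
                 stages = stages, aggregation = aggregation,
                 strip_salts = strip_salts, landscape = landscape,
                 variance_threshold = variance_threshold,
                 correlation_threshold = correlation_threshold,
                 split = split, algorithms = algorithms, balance = balance,
                 min_frequency = as.integer(min_frequency),
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full structure-activity analysis pipeline
#'
#' Executes the enabled stages in dependency order: curation, exploratory
#' analysis (descriptors, group tests, PCA), per-scheme landscape with
#' consensus cliffs, multiclass QSAR benchmarking with applicability domain,
#' and Murcko-scaffold chemotype analysis. A stage failure is logged and its
#' dependents skipped; completed stage outputs are kept. When `outdir` is set,
#' each stage writes tidy CSVs plus a JSON provenance record.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with one element per completed
#'   stage plus `provenance` and `errors`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(errors = list())
  prov <- list(seed = config$seed,
               schemes = config$schemes,
               stages = config$stages,
               logp_estimator = logp_estimator(),
               r_version = as.character(getRversion()),
               package_version = as.character(utils::packageVersion("sarscape")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write_out <- function(df, name) {
    if (!is.null(config$outdir)) {
      dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(as.data.frame(df), file.path(config$outdir, name),
                       row.names = FALSE)
    }
  }
  run_stage <- function(name, deps, fun) {
    if (!(name %in% config$stages) && name != "curation") return(invisible(NULL))
    if (any(vapply(deps, function(d) is.null(out[[d]]), logical(1)))) {
      out$errors[[name]] <<- paste("skipped: missing dependency",
                                   paste(deps[vapply(deps, function(d) is.null(out[[d]]), logical(1))],
                                         collapse = ", "))
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) {
      out$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) out[[name]] <<- res
    invisible(NULL)
  }

  # curation is the root of every other stage
  run_stage("curation", character(0), function() {
    raw <- if (!is.null(config$input)) {
      read_activity_table(config$input)
    } else {
      if (!is.null(config$synthetic$seed)) {
        generate_library(config$synthetic)$activities
      } else {
        stop("invalid synthetic spec")
      }
    }
    prov$input <<- if (!is.null(config$input)) config$input else "synthetic"
    ds <- curate_activities(raw, aggregation = config$aggregation,
                            strip_salts = config$strip_salts)
    write_out(ds$records, "curated.csv")
    if (!is.null(config$outdir)) {
      jsonlite::write_json(ds$provenance,
                           file.path(config$outdir, "curation_provenance.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    ds
  })

  run_stage("eda", "curation", function() {
    ds <- out$curation
    desc <- compute_descriptors(ds$records$canonical_smiles, ds$records$compound_id)
    eda <- eda_table(desc, ds$records$group)
    pca <- run_pca(as.matrix(desc[, c("mw", "logp", "nha", "nhd", "nrot", "tpsa")]))
    write_out(desc, "descriptors.csv")
    write_out(eda$summaries, "eda_summaries.csv")
    write_out(eda$tests, "eda_tests.csv")
    write_out(cbind(component = seq_along(pca$eigenvalues),
                    eigenvalue = pca$eigenvalues,
                    proportion = pca$proportion,
                    cumulative = pca$cumulative), "pca_eigenvalues.csv")
    write_out(cbind(descriptor = rownames(pca$loadings), as.data.frame(pca$loadings)),
              "pca_loadings.csv")
    list(descriptors = desc, summaries = eda$summaries, tests = eda$tests, pca = pca)
  })

  # fingerprints are an implicit dependency of landscape and qsar
  if (any(c("landscape", "qsar") %in% config$stages) && !is.null(out$curation)) {
    res <- tryCatch({
      fps <- lapply(config$schemes, function(sc) compute_fingerprints(out$curation, sc))
      names(fps) <- config$schemes
      fps
    }, error = function(e) {
      out$errors[["fingerprints"]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) out$fingerprints <- res
  }

  run_stage("landscape", c("curation", "fingerprints"), function() {
    ls <- lapply(out$fingerprints, function(fp) {
      build_landscape(out$curation, fp, config$landscape)
    })
    for (sc in names(ls)) {
      write_out(cbind(scheme = sc, as.data.frame(ls[[sc]])),
                paste0("landscape_", tolower(sc), ".csv"))
    }
    cons <- if (length(ls) >= 2) {
      consensus_cliffs(ls, min_cliffs = config$landscape$min_cliffs)
    } else NULL
    if (!is.null(cons)) {
      write_out(cons$cliffs, "consensus_cliffs.csv")
      write_out(cons$generators, "cliff_generators.csv")
    }
    thresholds <- vapply(ls, function(l) attr(l, "sim_threshold"), numeric(1))
    list(landscapes = ls, consensus = cons, sim_thresholds = thresholds)
  })

  run_stage("qsar", c("curation", "fingerprints"), function() {
    algs <- if (is.null(config$algorithms)) qsar_algorithms() else qsar_algorithms(config$algorithms)
    labels <- out$curation$records$activity_class
    reports <- lapply(names(out$fingerprints), function(sc) {
      sel <- select_features(out$fingerprints[[sc]]$matrix,
                             config$variance_threshold,
                             config$correlation_threshold)
      rep <- benchmark_qsar(sel$matrix, labels, algorithms = algs,
                            split = config$split, balance = config$balance)
      attr(rep, "selection") <- sel[c("kept", "variance_threshold", "correlation_threshold")]
      write_out(rep, paste0("qsar_", tolower(sc), ".csv"))
      rep
    })
    names(reports) <- names(out$fingerprints)
    reports
  })

  run_stage("chemotype", "curation", function() {
    st <- scaffold_table(out$curation, min_frequency = config$min_frequency)
    flat <- st$scaffolds
    flat$member_ids <- vapply(flat$member_ids, paste, "", collapse = ";")
    write_out(flat, "scaffolds.csv")
    write_out(st$diversity, "scaffold_diversity.csv")
    st
  })

  out$provenance <- prov
  if (!is.null(config$outdir)) {
    jsonlite::write_json(prov, file.path(config$outdir, "pipeline_provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  done <- setdiff(names(x), c("errors", "provenance"))
  cat("pipeline_result: stages completed:", paste(done, collapse = ", "), "\n")
  if (length(x$errors)) {
    cat("errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ":", x$errors[[nm]], "\n")
  }
  invisible(x)
}
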