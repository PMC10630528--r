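test_that("IC50 to pIC50 conversion follows the molar definition", {
  expect_equal(to_pic50(1, "nM"), 9)
  expect_equal(to_pic50(100, "nM"), 7)
  expect_equal(to_pic50(1, "M"), 0)
  expect_equal(to_pic50(1, "uM"), 6)
  expect_equal(to_pic50(10, "mM"), 2)
  expect_equal(to_pic50(c(1, 100), c("nM", "nM")), c(9, 7))
  expect_error(to_pic50(1, "parsec"), "unknown")
  expect_error(to_pic50(-1, "nM"), "positive")
  expect_error(to_pic50(0, "nM"), "positive")
})

test_that("activity classes partition the pIC50 axis with left-closed intervals", {
  expect_equal(as.character(classify_activity(c(9, 8, 7, 6.5, 9.5, 7.99))),
               c("potent", "active", "intermediate", "inactive", "potent", "intermediate"))
  expect_error(classify_activity(NaN), "finite")
  expect_error(classify_activity(NA_real_), "finite")

  # exhaustive & exclusive over random IC50 values
  withr::with_seed(1, {
    ic50 <- 10^stats::runif(500, -3, 6)  # nM, spanning pM to mM
    cls <- classify_activity(to_pic50(ic50, "nM"))
    expect_false(anyNA(cls))
    expect_true(all(as.character(cls) %in%
                      c("potent", "active", "intermediate", "inactive")))
  })
  expect_equal(as.character(assign_group(c(8, 7.999))), c("group1", "group2"))
})

test_that("curation filters, converts, deduplicates and accounts for every row", {
  raw <- dplyr::bind_rows(
    raw_activity_rows("CCOc1ccccc1", c(7.2, 7.4), ids = c("A1", "A2")),
    raw_activity_rows("CCN", 6.0, relation = ">", ids = "A3"),
    raw_activity_rows(NA_character_, 6.0, ids = "A4"),
    raw_activity_rows("CCC(=O)O", 8.1, type = "Ki", ids = "A5"),
    raw_activity_rows("c1ccncc1", 6.9, units = "furlong", ids = "A6"),
    raw_activity_rows("not-a-smiles((", 7.0, ids = "A7"),
    raw_activity_rows("Cc1ccccc1O", 8.5, ids = "A8")
  )
  ds <- suppressWarnings(curate_activities(raw, aggregation = "median"))
  rec <- ds$records
  expect_equal(nrow(rec), 2)
  expect_equal(rec$pic50[rec$compound_id == "A1"], 7.3)  # median of replicates
  expect_equal(as.character(rec$activity_class[rec$compound_id == "A8"]), "active")
  prov <- ds$provenance
  expect_equal(prov$n_input, sum(unlist(prov$removed)) + prov$n_output)
  expect_equal(prov$removed$unqualified, 1)
  expect_equal(prov$removed$missing, 1)
  expect_equal(prov$removed$not_ic50, 1)
  expect_equal(prov$removed$unconvertible_units, 1)
  expect_equal(prov$removed$unparseable_smiles, 1)
  expect_equal(prov$removed$redundant, 1)

  # aggregation alternatives
  expect_equal(curate_activities(raw[1:2, ], aggregation = "first")$records$pic50, 7.2)
  expect_equal(curate_activities(raw[1:2, ], aggregation = "mean")$records$pic50, 7.3)
})

test_that("curation is idempotent at the record level", {
  lib <- generate_library(synthetic_spec(
    scaffolds = dplyr::mutate(default_scaffolds(),
                              frequency = c(10L, 6L, 5L, 6L, 5L, 4L)),
    n_cliff_pairs = 2L, noise_sd = 0, seed = 3))
  ds1 <- curate_activities(lib$activities)
  back <- tibble::tibble(
    molecule_chembl_id = ds1$records$compound_id,
    canonical_smiles = ds1$records$canonical_smiles,
    standard_type = "IC50", standard_relation = "=",
    standard_value = 10^(9 - ds1$records$pic50), standard_units = "nM"
  )
  ds2 <- curate_activities(back)
  expect_equal(ds2$records$canonical_smiles, ds1$records$canonical_smiles)
  expect_equal(ds2$records$pic50, ds1$records$pic50, tolerance = 1e-12)
  expect_equal(ds2$records$activity_class, ds1$records$activity_class)
})

test_that("empty curation results raise an explicit error", {
  raw <- raw_activity_rows("CCO", 6, relation = ">")
  expect_error(curate_activities(raw), "empty dataset")
  expect_error(curate_activities(raw[0, ]), "empty input")
})

test_that("activity tables are read with delimiter auto-detection", {
  raw <- raw_activity_rows(c("CCO", "CCN"), c(6.2, 7.1))
  csv <- tempfile(fileext = ".csv")
  tsv <- tempfile(fileext = ".tsv")
  utils::write.csv(as.data.frame(raw), csv, row.names = FALSE)
  utils::write.table(as.data.frame(raw), tsv, row.names = FALSE, sep = "\t")
  expect_equal(read_activity_table(csv)$canonical_smiles, c("CCO", "CCN"))
  expect_equal(read_activity_table(tsv)$standard_value, raw$standard_value)
  expect_error(read_activity_table(tempfile()), "not found")

  ds <- curate_activity_file(csv)
  expect_s3_class(ds, "curated_dataset")
  expect_equal(nrow(ds$records), 2)

  out <- tempfile(fileext = ".csv")
  write_curated(ds, out)
  expect_true(file.exists(out))
  expect_true(file.exists(paste0(out, ".provenance.json")))
  prov <- jsonlite::read_json(paste0(out, ".provenance.json"))
  expect_equal(prov$n_output, 2)
})
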