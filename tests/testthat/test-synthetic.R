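small_spec <- function(seed = 5, noise_sd = 0, n_cliff_pairs = 2L) {
  synthetic_spec(
    scaffolds = dplyr::mutate(default_scaffolds(),
                              frequency = c(12L, 8L, 6L, 8L, 6L, 6L)),
    n_cliff_pairs = n_cliff_pairs, noise_sd = noise_sd, seed = seed)
}

test_that("generation is deterministic and byte-stable given a seed", {
  a <- generate_library(small_spec(seed = 21))
  b <- generate_library(small_spec(seed = 21))
  expect_identical(a$activities, b$activities)
  expect_identical(a$truth$molecules, b$truth$molecules)
  c <- generate_library(small_spec(seed = 22))
  expect_false(identical(a$activities$standard_value, c$activities$standard_value))

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_synthetic(a, f1); write_synthetic(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(paste0(f1, ".truth.json")),
                   readLines(paste0(f2, ".truth.json")))
})

test_that("a noise-free additive model yields exactly the classes it implies", {
  sc <- tibble::tibble(scaffold_id = "s", template = "c1(%T)cc(%2)ccc1-c1ccc(%1)cc1",
                       base_pic50 = 7.0, frequency = 4L, symmetric = FALSE)
  su <- tibble::tibble(smiles = c("", "C(=O)NO"),
                       contribution = c(0, 2.5),
                       role = "decoration")
  lib <- generate_library(synthetic_spec(scaffolds = sc, substituents = su,
                                         n_cliff_pairs = 0L, noise_sd = 0, seed = 1))
  cls <- as.character(lib$truth$molecules$true_class)
  expect_setequal(unique(cls), c("intermediate", "potent"))
  expect_equal(sort(unique(lib$truth$molecules$true_pic50)), c(7.0, 9.5, 12.0))
})

test_that("planted cliff pairs share a scaffold and differ by >= 2 log units at zero noise", {
  lib <- generate_library(small_spec(seed = 31, n_cliff_pairs = 4L))
  tm <- lib$truth$molecules
  pairs <- lib$truth$cliff_pairs
  expect_equal(nrow(pairs), 4)
  expect_length(lib$truth$generators, 2)
  for (i in seq_len(nrow(pairs))) {
    a <- tm[tm$compound_id == pairs$id_a[i], ]
    b <- tm[tm$compound_id == pairs$id_b[i], ]
    expect_equal(a$scaffold_id, b$scaffold_id)
    expect_equal(a$sub2, b$sub2)  # single-substituent swap
    expect_gte(abs(a$true_pic50 - b$true_pic50), 2)
  }
  # generators participate in two planted cliffs
  expect_equal(as.vector(table(pairs$generator)[lib$truth$generators]), c(2L, 2L))
})

test_that("impossible frequency demands raise errors", {
  sc <- dplyr::mutate(default_scaffolds(), frequency = c(2000L, 5L, 5L, 5L, 5L, 5L))
  expect_error(generate_library(synthetic_spec(scaffolds = sc, noise_sd = 0, seed = 1)),
               "impossible frequency")
})

test_that("planted-cliff recall is perfect at zero noise and decays with noise on average", {
  # the fingerprint side of a planted pair is noise-free by construction, so
  # the noise-limited quantity is whether the observed activity gap stays >= 2
  recall_at <- function(noise, seed) {
    lib <- generate_library(small_spec(seed = seed, noise_sd = noise,
                                       n_cliff_pairs = 4L))
    tm <- lib$truth$molecules
    p <- lib$truth$cliff_pairs
    obs <- abs(tm$observed_pic50[match(p$id_a, tm$compound_id)] -
               tm$observed_pic50[match(p$id_b, tm$compound_id)])
    mean(obs >= 2)
  }
  seeds <- 1:8
  r0 <- mean(vapply(seeds, function(s) recall_at(0, s), numeric(1)))
  r1 <- mean(vapply(seeds, function(s) recall_at(1.0, s), numeric(1)))
  r2 <- mean(vapply(seeds, function(s) recall_at(2.5, s), numeric(1)))
  expect_equal(r0, 1)
  expect_gte(r0, r1)
  expect_gte(r1, r2)
  expect_lt(r2, 1)
})

test_that("the emitted table is exactly the dialect the curation module reads", {
  lib <- generate_library(small_spec(seed = 41))
  path <- tempfile(fileext = ".csv")
  write_synthetic(lib, path)
  ds <- curate_activity_file(path)
  expect_equal(nrow(ds$records), nrow(lib$activities))
  expect_equal(ds$records$pic50,
               lib$truth$molecules$observed_pic50[
                 match(ds$records$compound_id, lib$truth$molecules$compound_id)],
               tolerance = 1e-9)
})
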