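test_that("SALI follows its closed form including the identical-structure edge", {
  expect_equal(sali(9, 7, 0.8), 10)
  expect_equal(sali(7, 7, 0.5), 0)
  expect_identical(sali(9, 6, 1), Inf)
  expect_equal(sali(9, 9, 1), 0)
  expect_error(sali(9, 7, 1.2), "similarity")
  expect_error(sali(9, 7, -0.1), "similarity")
  expect_equal(sali(c(9, 7), c(7, 7), c(0.8, 0.5)), c(10, 0))
})

test_that("the mean + 2 SD similarity threshold is capped at 1", {
  expect_equal(similarity_threshold(rep(0.6, 5)), 0.6)
  expect_equal(similarity_threshold(c(0.5, 0.7)), 0.6 + 2 * stats::sd(c(0.5, 0.7)))
  expect_equal(similarity_threshold(c(0.9, 0.99, 0.95)), 1)
  expect_error(similarity_threshold(0.4), "at least 2")
})

test_that("landscapes enumerate all pairs and partition them into quadrants", {
  raw <- raw_activity_rows(
    c("c1ccccc1CCO", "c1ccccc1CCCO", "C1CCNCC1", "c1ccccc1CC(=O)NO"),
    c(6.0, 6.2, 6.1, 9.1))
  ds <- curate_activities(raw)
  fps <- compute_fingerprints(ds, "MACCS166")
  ls <- build_landscape(ds, fps, landscape_config(sim_threshold_rule = "fixed",
                                                  fixed_sim_threshold = 0.6))
  n <- nrow(ds$records)
  expect_equal(nrow(ls), n * (n - 1) / 2)
  expect_true(all(ls$id_a < ls$id_b))
  expect_false(anyNA(ls$quadrant))
  expect_equal(ls$is_cliff,
               ls$similarity >= 0.6 & ls$delta_activity >= 2)
  # quadrant assignment consistent with the two thresholds
  expect_equal(as.character(ls$quadrant),
               ifelse(ls$similarity >= 0.6 & ls$delta_activity >= 2, "cliff",
               ifelse(ls$similarity >= 0.6, "smooth",
               ifelse(ls$delta_activity >= 2, "nondescript", "scaffold_hop"))))

  # recomputation of SALI from the emitted columns
  expect_equal(ls$sali[is.finite(ls$sali)],
               (ls$delta_activity / (1 - ls$similarity))[is.finite(ls$sali)])

  # missing fingerprints are an error naming the compounds
  fps_cut <- fps
  keep <- fps$ids[-1]
  fps_cut$ids <- keep
  fps_cut$matrix <- fps_cut$matrix[keep, , drop = FALSE]
  expect_error(build_landscape(ds, fps_cut), ds$records$compound_id[1])
})

test_that("the data-driven threshold rule reproduces the mean + 2 SD statistic", {
  ds <- ref_dataset()
  fps <- ref_fingerprints("MACCS166")
  ls <- build_landscape(ds, fps)  # default mean_plus_2sd
  sims <- similarity_matrix(fps)
  expect_equal(attr(ls, "sim_threshold"),
               min(mean(sims[upper.tri(sims)]) + 2 * stats::sd(sims[upper.tri(sims)]), 1),
               tolerance = 1e-12)
})

test_that("consensus cliffs are the exact pair intersection and generators need min_cliffs", {
  mk <- function(pairs) {
    tibble::tibble(id_a = vapply(pairs, `[[`, "", 1),
                   id_b = vapply(pairs, `[[`, "", 2),
                   similarity = 0.9, delta_activity = 2.5, sali = 25,
                   quadrant = factor("cliff",
                     levels = c("smooth", "cliff", "nondescript", "scaffold_hop")),
                   is_cliff = TRUE)
  }
  a <- mk(list(c("x", "y"), c("x", "z")))
  b <- mk(list(c("x", "y"), c("w", "x")))
  out <- consensus_cliffs(list(A = a, B = b), min_cliffs = 2)
  expect_equal(nrow(out$cliffs), 1)
  expect_equal(out$cliffs$id_a, "x"); expect_equal(out$cliffs$id_b, "y")
  gens <- out$generators
  expect_equal(gens$compound_id[gens$consensus_generator], "x")

  same <- consensus_cliffs(list(A = a, B = a))
  expect_equal(nrow(same$cliffs), nrow(a))

  disj <- mk(list(c("p", "q")))
  expect_warning(empty <- consensus_cliffs(list(A = a, B = disj[0, ])), "empty cliff set")
  expect_equal(nrow(empty$cliffs), 0)
  none <- consensus_cliffs(list(A = a, B = disj))
  expect_equal(nrow(none$cliffs), 0)
  expect_error(consensus_cliffs(list(A = a)), "at least 2")
})

test_that("consensus size never exceeds any scheme's cliff count on real landscapes", {
  lss <- list(MACCS166 = ref_landscape("MACCS166"),
              PubChem881 = ref_landscape("PubChem881"))
  out <- consensus_cliffs(lss, min_cliffs = 2)
  expect_lte(nrow(out$cliffs), min(out$per_scheme_cliff_counts))
  counts <- out$generators[, c("n_cliffs_MACCS166", "n_cliffs_PubChem881")]
  flags <- out$generators[, c("generator_MACCS166", "generator_PubChem881")]
  expect_equal(flags$generator_MACCS166, counts$n_cliffs_MACCS166 >= 2)
  expect_equal(out$generators$consensus_generator,
               flags$generator_MACCS166 & flags$generator_PubChem881)
})
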