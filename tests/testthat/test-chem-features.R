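test_that("drug-likeness descriptors match hand-checkable molecules", {
  d <- compute_descriptors(c(benzene = "c1ccccc1", ethanol = "CCO",
                             hexane = "CCCCCC"))
  benz <- d[d$compound_id == "benzene", ]
  expect_equal(benz$nhd, 0L)
  expect_equal(benz$nha, 0L)
  expect_equal(benz$nrot, 0L)
  expect_equal(benz$tpsa, 0)
  eth <- d[d$compound_id == "ethanol", ]
  expect_equal(eth$nhd, 1L)
  expect_equal(eth$nha, 1L)
  hex <- d[d$compound_id == "hexane", ]
  expect_equal(hex$tpsa, 0)
  expect_gt(hex$logp, benz$logp - 10)  # populated
  expect_equal(round(benz$mw), 78)

  # deterministic
  expect_identical(d, compute_descriptors(c(benzene = "c1ccccc1", ethanol = "CCO",
                                            hexane = "CCCCCC")))
  expect_error(compute_descriptors(c(ok = "CCO", bad = "q((")), "bad")
})

test_that("fingerprint matrices have the published key counts and are deterministic", {
  smi <- c(a = "c1ccccc1", b = "CCO", m = "C",
           h = "Oc1ccc(-c2ccccc2)cc1C(=O)NO")
  fm <- compute_fingerprints(smi, "MACCS166")
  expect_equal(fm$n_bits, 166L)
  expect_equal(dim(fm$matrix), c(4L, 166L))
  expect_true(all(fm$matrix %in% c(0L, 1L)))
  fp <- compute_fingerprints(smi, "PubChem881")
  expect_equal(fp$n_bits, 881L)
  expect_equal(dim(fp$matrix), c(4L, 881L))

  # methane: no ring or aromatic keys (PubChem ring-count section is bits
  # 115-262 zero-based, columns 116-263)
  expect_equal(sum(fp$matrix["m", 116:263]), 0L)
  # benzene: an aromatic 6-ring is keyed
  expect_gt(sum(fp$matrix["a", 116:263]), 0L)
  # hydroxamate molecule sets the hydroxamic-acid substructure key
  hx_bit <- unname(sarscape:::pc_smarts_bits()[["[CX3](=O)[NX3][OX2]"]]) + 1L
  expect_equal(fp$matrix["h", hx_bit], 1L)
  expect_equal(fp$matrix["a", hx_bit], 0L)

  expect_identical(fp$matrix, compute_fingerprints(smi, "PubChem881")$matrix)
  expect_identical(fm$matrix, compute_fingerprints(smi, "MACCS166")$matrix)
})

test_that("Tanimoto similarity obeys its definition and bounds", {
  expect_equal(tanimoto(c(1, 1, 1, 0), c(1, 1, 1, 0)), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  a <- numeric(8); a[1:3] <- 1
  b <- numeric(8); b[2:4] <- 1
  expect_equal(tanimoto(a, b), 0.5)
  expect_error(tanimoto(numeric(4), numeric(4)), "all-zero")
  expect_error(tanimoto(c(1, 0), c(1, 0, 0)), "length")

  withr::with_seed(7, {
    for (i in 1:50) {
      x <- stats::rbinom(32, 1, 0.4)
      y <- stats::rbinom(32, 1, 0.4)
      if (sum(x) == 0 || sum(x | y) == 0) next
      expect_equal(tanimoto(x, x), 1)
      s <- tanimoto(x, y)
      expect_equal(s, tanimoto(y, x))
      expect_gte(s, 0)
      expect_lte(s, 1)
    }
  })
})

test_that("similarity matrices are symmetric with unit diagonal and handle empty rows", {
  fps <- compute_fingerprints(c(x = "c1ccccc1O", y = "CCOC", z = "c1ccncc1"),
                              "MACCS166")
  sm <- similarity_matrix(fps)
  expect_equal(sm, t(sm))
  expect_equal(unname(diag(sm)), rep(1, 3))
  off <- sm[upper.tri(sm)]
  expect_length(off, 3 * 2 / 2)
  expect_true(all(off >= 0 & off <= 1))

  m <- rbind(a = c(1L, 1L, 0L), b = c(0L, 0L, 0L), c = c(1L, 0L, 1L))
  expect_warning(sm2 <- similarity_matrix(m), "all-zero")
  expect_true(all(is.na(sm2["b", ])))
  expect_false(anyNA(sm2[c("a", "c"), c("a", "c")]))
})

test_that("canonicalization is stable and strips salts to the parent fragment", {
  two <- canonicalize_smiles(c("OCC", "CCO"))
  expect_equal(two[1], two[2])
  salt <- canonicalize_smiles("CC(=O)O.[Na+]", strip_salts = TRUE)
  expect_false(grepl(".", salt, fixed = TRUE))
  expect_true(grepl("C", salt))
  keep <- canonicalize_smiles("CC(=O)O.[Na+]", strip_salts = FALSE)
  expect_true(grepl(".", keep, fixed = TRUE))
  expect_true(is.na(canonicalize_smiles("C1CC")))  # unmatched ring bond
  mix <- canonicalize_smiles(c("CCO", "C1CC", "c1ccccc1"))
  expect_equal(is.na(mix), c(FALSE, TRUE, FALSE))
})
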