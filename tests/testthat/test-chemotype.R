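test_that("Murcko scaffolds drop side chains and keep rings, linkers, exocyclic doubles", {
  biphenyl <- canonicalize_smiles("c1ccc(-c2ccccc2)cc1")
  benzene <- canonicalize_smiles("c1ccccc1")
  got <- murcko_scaffold(c("Oc1ccc(-c2ccccc2)cc1",  # 4-hydroxybiphenyl
                           "Cc1ccccc1",             # toluene
                           "CCCCCC",                # hexane: acyclic
                           "CC(=O)c1ccccc1",        # acetophenone: chain removed
                           "O=C1CCCCC1CCN"))        # ring carbonyl retained
  expect_equal(got[1], biphenyl)
  expect_equal(got[2], benzene)
  expect_equal(got[3], "")
  expect_equal(got[4], benzene)
  expect_equal(got[5], canonicalize_smiles("O=C1CCCCC1"))

  # linkers between ring systems survive
  ether <- murcko_scaffold("COc1ccc(COc2ccc(N)cc2)cc1")
  expect_equal(ether, canonicalize_smiles("c1ccc(COc2ccccc2)cc1"))
})

test_that("murcko_scaffold is idempotent", {
  mols <- c("Oc1ccc(-c2ccccc2)cc1", "CC(=O)c1ccc(CN2CCOCC2)cc1",
            "O=C1C=C(c2ccccc2)C=CN1", "O1CCN=C1c1ccccc1Cl",
            "c1ccc(COc2ccc(-c3noc(C)n3)cc2)cc1")
  s1 <- murcko_scaffold(mols)
  s2 <- murcko_scaffold(s1)
  expect_equal(s2, s1)
})

test_that("scaffolds agree with an independent toolkit on reference molecules", {
  mols <- c("Oc1ccc(-c2ccccc2)cc1", "Cc1ccccc1", "CC(=O)c1ccccc1",
            "COc1ccc(COc2ccc(N)cc2)cc1", "O=C1C=C(c2ccccc2)C=CN1",
            "ClCC1COC(=N1)c1ccccc1")
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem.Scaffolds import MurckoScaffold",
    "for s in sys.argv[1:]:",
    "    m = Chem.MolFromSmiles(s)",
    "    print(Chem.MolToSmiles(MurckoScaffold.GetScaffoldForMol(m)))",
    sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(mols)), stdout = TRUE))
  skip_if(length(out) != length(mols), "reference toolkit unavailable")
  # both toolkits' scaffolds are compared through one canonicalizer
  expect_equal(murcko_scaffold(mols), canonicalize_smiles(out))
})

test_that("cyclic skeletons erase elements and bond orders and are idempotent", {
  cyclohexane <- canonicalize_smiles("C1CCCCC1")
  expect_equal(cyclic_skeleton("c1ccncc1"), cyclohexane)
  expect_equal(cyclic_skeleton("c1ccccc1"), cyclohexane)
  expect_equal(cyclic_skeleton(""), "")
  two_ring <- cyclic_skeleton("O=c1cc(-c2ccccc2)cc[nH]1")
  expect_equal(cyclic_skeleton(two_ring), two_ring)
  expect_false(grepl("[nNoO=]", two_ring))
})

test_that("scaffold tables report frequencies, diversity and favorability", {
  # ten molecules, one scaffold
  raw <- raw_activity_rows(paste0("c1ccccc1", vapply(1:10, function(k)
    paste(rep("C", k), collapse = ""), "")), seq(6, 7.8, length.out = 10))
  ds <- curate_activities(raw)
  st <- scaffold_table(ds, min_frequency = 5)
  expect_equal(nrow(st$scaffolds), 1)
  expect_equal(st$scaffolds$frequency, 10)
  div_all <- st$diversity[st$diversity$subset == "all", ]
  expect_equal(div_all$n_scaffolds, 1L)
  expect_equal(div_all$scaffold_per_molecule, 0.1)
  expect_equal(div_all$singleton_fraction, 0)

  # all-unique scaffolds
  raw2 <- raw_activity_rows(c("c1ccncc1C", "c1ccccc1C", "C1CCOC1C", "C1CCNC1C"),
                            c(6, 6.5, 7, 7.5))
  st2 <- scaffold_table(curate_activities(raw2), min_frequency = 1)
  d2 <- st2$diversity[st2$diversity$subset == "all", ]
  expect_equal(d2$scaffold_per_molecule, 1)
  expect_equal(d2$singleton_fraction, 1)

  # frequencies sum to the number of cyclic molecules
  lib <- ref_library()
  st3 <- scaffold_table(ref_dataset(), min_frequency = 10)
  expect_equal(sum(st3$scaffolds$frequency),
               nrow(ref_dataset()$records) - st3$n_acyclic)
  # planted frequency bookkeeping is recovered exactly
  truth_counts <- sort(as.integer(lib$truth$scaffold_counts), decreasing = TRUE)
  expect_equal(sort(st3$scaffolds$frequency, decreasing = TRUE), truth_counts)
  expect_true(all(st3$scaffolds$favorability %in%
                    c("favorable", "unfavorable", "neutral")))
})
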