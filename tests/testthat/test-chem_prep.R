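# Standardization and fingerprint contracts.

test_that("equivalent SMILES forms standardize to one canonical parent", {
  s <- standardize_smiles(c("c1ccccc1", "C1=CC=CC=C1", "c1ccccc1.[Na+].[Cl-]"))
  expect_false(anyNA(s))
  expect_length(unique(s), 1L)

  # salt invariance: appending counter-ions never changes the parent
  ions <- c("[Na+].[Cl-]", "[K+].[Br-]", "Cl", "[Ca+2].[Cl-].[Cl-]", "O")
  base <- "CC(=O)Nc1ccc(O)cc1"
  salted <- standardize_smiles(c(base, paste(base, ions, sep = ".")))
  expect_length(unique(salted), 1L)

  # neutralization maps deprotonated/protonated forms onto the neutral parent
  expect_equal(standardize_smiles("CC(=O)[O-].[Na+]"),
               standardize_smiles("CC(=O)O"), ignore_attr = TRUE)
  # permanently charged centers survive
  expect_true(grepl("\\+", standardize_smiles("C[N+](C)(C)C")))
})

test_that("isotope labels are stripped", {
  expect_equal(standardize_smiles("[13CH4]"), standardize_smiles("C"),
               ignore_attr = TRUE)
  # deuterium becomes plain (implicit) hydrogen
  expect_equal(standardize_smiles("OC([2H])([2H])C"),
               standardize_smiles("OCC"), ignore_attr = TRUE)
  expect_equal(standardize_smiles("[13CH3]OC"), standardize_smiles("COC"),
               ignore_attr = TRUE)
})

test_that("structure errors are collected, never thrown", {
  s <- standardize_smiles(c("CCO", "C1CC1xyz", "", "c1ccccc1"))
  expect_equal(is.na(s), c(FALSE, TRUE, TRUE, FALSE))
  err <- attr(s, "errors")
  expect_equal(err$index, c(2L, 3L))
  expect_equal(err$reason, c("unparseable SMILES", "empty SMILES"))
})

test_that("standardization is deterministic and order-invariant", {
  smi <- c("CC(=O)[O-].[Na+]", "c1ccncc1", "CCOC(=O)c1ccccc1", "C")
  a <- standardize_smiles(smi)
  b <- rev(standardize_smiles(rev(smi)))
  expect_equal(as.character(a), as.character(b))
})

test_that("fingerprints are deterministic, canonical and bounded", {
  fp <- compute_fingerprint(c("c1ccccc1", "C1=CC=CC=C1", "c1ccccc1"),
                            n_bits = 1024L, radius = 3L)
  expect_identical(fp[[1]], fp[[2]]) # Kekule vs aromatic input
  expect_identical(fp[[1]], fp[[3]])
  expect_true(all(fp[[1]] >= 0L & fp[[1]] < 1024L))
  expect_false(is.unsorted(fp[[1]], strictly = TRUE))

  # single heavy atom at radius 0: exactly one environment
  expect_length(compute_fingerprint("C", radius = 0L)[[1]], 1L)

  # radius widens the environment set
  f0 <- compute_fingerprint("CCOc1ccccc1", radius = 0L)[[1]]
  f3 <- compute_fingerprint("CCOc1ccccc1", radius = 3L)[[1]]
  expect_gt(length(f3), length(f0))
})

test_that("tanimoto similarity follows the set formula and conventions", {
  expect_equal(tanimoto_similarity(c(1L, 2L, 3L), c(2L, 3L, 4L)), 0.5)
  expect_equal(tanimoto_similarity(c(5L, 9L), c(5L, 9L)), 1.0)
  expect_equal(tanimoto_similarity(c(1L, 2L), c(3L, 4L)), 0.0)
  # degenerate convention: two empty fingerprints are identical
  expect_equal(tanimoto_similarity(integer(0), integer(0)), 1.0)
  expect_error(tanimoto_similarity(1L, 2L, n_bits_a = 64L, n_bits_b = 128L),
               "n_bits")
  # symmetry on random pairs
  fps <- random_fps(30, seed = 7)
  for (k in 1:20) {
    i <- sample.int(30, 2)
    expect_equal(tanimoto_similarity(fps[[i[1]]], fps[[i[2]]]),
                 tanimoto_similarity(fps[[i[2]]], fps[[i[1]]]))
  }
  # agreement with the independent set-based reference
  for (k in 1:20) {
    i <- sample.int(30, 2)
    expect_equal(tanimoto_similarity(fps[[i[1]]], fps[[i[2]]]),
                 ref_tanimoto(fps[[i[1]]], fps[[i[2]]]))
  }
})

test_that("prepare_molecules assembles compounds, fingerprints and errors", {
  mols <- prepare_molecules(c(a = "CCO", b = "OCC", c = "C1CC1xyz", d = "c1ccccc1"))
  expect_s3_class(mols, "mol_set")
  expect_equal(mols$compounds$compound_id, c("a", "b", "d"))
  # identical structures get identical canonical SMILES and fingerprints
  expect_equal(mols$compounds$canonical_smiles[1], mols$compounds$canonical_smiles[2])
  expect_identical(mols$fingerprints[["a"]], mols$fingerprints[["b"]])
  expect_equal(mols$errors$compound_id, "c")
  expect_error(prepare_molecules(c(x = "C", x = "CC")), "duplicated")
})
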