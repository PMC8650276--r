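# Scaffold network decomposition and scaffold-based fold split.

test_that("acyclic molecules carry the single empty scaffold", {
  s <- compute_scaffold_set("CCCCCC")
  expect_equal(nrow(s), 1L)
  expect_equal(s$scaffold_smiles, "")
  expect_equal(s$ring_count, 0L)
})

test_that("single-ring and linked-ring networks enumerate correctly", {
  benz <- compute_scaffold_set("c1ccccc1")
  expect_equal(nrow(benz), 1L)
  expect_equal(benz$ring_count, 1L)

  biphenyl <- compute_scaffold_set("c1ccc(-c2ccccc2)cc1")
  expect_equal(sort(biphenyl$ring_count), c(1L, 2L))
  # the 1-ring child of biphenyl is benzene itself
  expect_true(benz$scaffold_smiles %in% biphenyl$scaffold_smiles)

  # side chains are pruned: a decorated biphenyl has the same network
  decorated <- compute_scaffold_set("CCOc1ccc(-c2ccccc2CC(N)=O)cc1")
  expect_setequal(decorated$scaffold_smiles, biphenyl$scaffold_smiles)
})

test_that("fused ring systems are never dissected", {
  # naphthalene is one 2-ring system: no single-ring child scaffold
  naph <- compute_scaffold_set("c1ccc2ccccc2c1")
  expect_equal(nrow(naph), 1L)
  expect_equal(naph$ring_count, 2L)
  # spiro systems count as one unit too
  spiro <- compute_scaffold_set("C1CCC2(CC1)CCCC2")
  expect_equal(nrow(spiro), 1L)
  expect_equal(spiro$ring_count, 2L)
})

test_that("flucloxacillin's representative scaffold has three rings", {
  fluclox <- paste0("CC1=C(C(=NO1)C2=C(C=CC=C2Cl)F)C(=O)N[C@@H]3C(=O)N4",
                    "[C@H]3SC([C@@H]4C(=O)O)(C)C")
  can <- standardize_smiles(fluclox)
  sc <- compute_scaffold_set(can)
  expect_true(4L %in% sc$ring_count)  # full Murcko scaffold
  sel <- select_representative_scaffold(sc)
  expect_equal(sel$ring_count, 3L)
})

test_that("ring counts equidistant from three resolve to the smaller", {
  # two linked naphthalenes: network ring counts {4, 2}; |4-3| == |2-3|
  sc <- compute_scaffold_set("c1ccc2cc(CCc3ccc4ccccc4c3)ccc2c1")
  expect_setequal(sc$ring_count, c(4L, 2L))
  expect_equal(select_representative_scaffold(sc)$ring_count, 2L)
  expect_error(select_representative_scaffold(sc[0, ]), "non-empty")
})

test_that("the prioritization cascade is deterministic and documented", {
  # four linked ring systems: imidazole - benzene - pyridine - benzene;
  # two 3-ring sub-scaffolds exist, tied on linker bonds, separated by ring
  # heteroatom count (imidazole+pyridine: 3 vs pyridine alone: 1)
  smi <- "c1cnc([nH]1)CCc2ccc(CCc3ccc(CCc4ccccc4)cn3)cc2"
  can <- standardize_smiles(smi)
  sc <- compute_scaffold_set(can)
  three <- sc[sc$ring_count == 3L, ]
  expect_equal(nrow(three), 2L)
  sel <- select_representative_scaffold(sc)
  # manual cascade: equal linker bonds, so maximal ring heteroatoms wins
  expect_equal(unique(three$n_linker_bonds), unique(three$n_linker_bonds)[1])
  expect_equal(sel$n_ring_heteroatoms, max(three$n_ring_heteroatoms))
  expect_equal(sel$n_ring_heteroatoms, 3L)
  # full determinism across repeated calls
  expect_identical(sel, select_representative_scaffold(compute_scaffold_set(can)))
})

test_that("scaffold folds: shared scaffold, acyclic pooling, determinism", {
  mols <- prepare_molecules(c(
    hexane = "CCCCCC", ether = "CCOCC",              # acyclic
    a1 = "Cc1ccc(-c2ccccc2)cc1", a2 = "CCc1ccc(-c2ccccc2)cc1", # one series
    b1 = "c1ccc2ccccc2c1"), fingerprints = FALSE)
  fa <- assign_scaffold_folds(mols, 5)
  lk <- setNames(fa$fold, fa$compound_id)
  expect_equal(lk[["hexane"]], lk[["ether"]])  # all acyclic share one fold
  expect_equal(lk[["a1"]], lk[["a2"]])         # same representative scaffold
  scf <- attr(fa, "scaffolds")
  expect_equal(scf$scaffold_smiles[scf$compound_id == "hexane"], "")
  # input order invariance
  mols2 <- prepare_molecules(c(
    b1 = "c1ccc2ccccc2c1", a2 = "CCc1ccc(-c2ccccc2)cc1",
    hexane = "CCCCCC", ether = "CCOCC", a1 = "Cc1ccc(-c2ccccc2)cc1"),
    fingerprints = FALSE)
  fa2 <- assign_scaffold_folds(mols2, 5)
  lk2 <- setNames(fa2$fold, fa2$compound_id)
  expect_equal(lk[names(lk)], lk2[names(lk)])
  # atom-order invariance of the representative scaffold
  alt <- standardize_smiles("c1ccccc1-c1ccc(C)cc1") # a1 rewritten
  expect_equal(attr(assign_scaffold_folds(
    prepare_molecules(c(x = alt), fingerprints = FALSE), 5),
    "scaffolds")$scaffold_smiles,
    scf$scaffold_smiles[scf$compound_id == "a1"])
})

test_that("highly similar fingerprints can still split across scaffolds", {
  # ring-size extension: near-identical fingerprints, different scaffolds
  chain <- strrep("CC(C)CCO", 8)
  m <- prepare_molecules(c(x = paste0("C1CCCCC1", chain),
                           y = paste0("C1CCCCCC1", chain)))
  sim <- tanimoto_similarity(m$fingerprints[["x"]], m$fingerprints[["y"]])
  expect_gte(sim, 0.9)
  scf <- attr(assign_scaffold_folds(m, 5), "scaffolds")
  expect_false(scf$scaffold_smiles[1] == scf$scaffold_smiles[2])
})
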