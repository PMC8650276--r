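# Sphere exclusion clustering.

test_that("worked example: A joins B's cluster, C stands alone", {
  # dist(A,B) = 1 - 4/6 = 0.333 <= 0.6; dist(A,C) = dist(B,C) = 1
  fps <- list(A = c(1L, 2L, 3L, 4L, 5L), B = c(1L, 2L, 3L, 4L, 6L),
              C = c(10L, 11L, 12L, 13L, 14L))
  mols <- fake_mol_set(fps, ids = c("A", "B", "C"))
  cm <- run_sphere_exclusion(mols, t_tc = 0.6,
                             order_seed = identity_order_seed(3))
  expect_equal(length(cm$center_compound_ids), 2L)
  expect_equal(cm$center_compound_ids[1], "A")
  expect_equal(unname(cm$assignment[c("A", "B")]), c(1L, 1L))
  expect_equal(unname(cm$assignment["C"]), 2L)
})

test_that("degenerate inputs: single compound, t_tc = 1, empty set", {
  one <- fake_mol_set(list(c(1L, 2L)), ids = "solo")
  cm1 <- run_sphere_exclusion(one, 0.6, order_seed = 1)
  expect_equal(cm1$center_compound_ids, "solo")
  many <- fake_mol_set(random_fps(15, seed = 2))
  cm2 <- run_sphere_exclusion(many, t_tc = 1.0, order_seed = 3)
  expect_equal(length(cm2$center_compound_ids), 1L)
  empty <- fake_mol_set(list())
  expect_equal(length(run_sphere_exclusion(empty, 0.6, 1)$assignment), 0L)
  expect_error(run_sphere_exclusion(many, 0.6), "order_seed")
})

test_that("re-assignment is a nearest-center argmin and is idempotent", {
  fps <- random_fps(20, n_bits = 48L, density = 0.3, seed = 11)
  mols <- fake_mol_set(fps, n_bits = 48L)
  cm <- run_sphere_exclusion(mols, 0.6, order_seed = 5)
  cm2 <- reassign_to_nearest(cm, mols)
  # oracle: exhaustive distance matrix argmin
  for (i in seq_along(fps)) {
    d <- vapply(seq_along(cm2$center_compound_ids), function(j)
      1 - ref_tanimoto(fps[[i]], unclass(cm2$center_fps)[[j]]), numeric(1))
    expect_equal(unname(cm2$assignment[i]), which.min(d))
    expect_equal(unname(cm2$distance[i]), min(d))
  }
  cm3 <- reassign_to_nearest(cm2, mols)
  expect_equal(cm2$assignment, cm3$assignment)
})

test_that("ties in distance go to the earliest-created center", {
  # centers {1,2} and {3,4}; compound {1,3} is equidistant (d = 0.8) to both
  fps <- list(c(1L, 2L), c(3L, 4L), c(1L, 3L))
  mols <- fake_mol_set(fps)
  cm <- run_sphere_exclusion(mols, t_tc = 0.4,
                             order_seed = identity_order_seed(3))
  expect_equal(length(cm$center_compound_ids), 3L) # 0.8 > 0.4: all centers
  cm <- reassign_to_nearest(cm, mols)
  expect_equal(unname(cm$assignment[3]), 3L) # itself is at distance 0
  # remove its own center from the picture: nearest among the first two
  res <- molsplit:::.nearest_center_cpp(fps[3], fps[1:2])
  expect_equal(res$cluster, 1L)
})

test_that("model invariants hold on random instances", {
  for (s in 1:5) {
    fps <- random_fps(40, n_bits = 32L, density = 0.3, seed = 100 + s)
    mols <- fake_mol_set(fps, n_bits = 32L)
    cm <- reassign_to_nearest(run_sphere_exclusion(mols, 0.6, order_seed = s),
                              mols)
    k <- length(cm$center_compound_ids)
    # pairwise center separation > t_tc
    if (k > 1) {
      cf <- unclass(cm$center_fps)
      for (i in 1:(k - 1)) for (j in (i + 1):k)
        expect_gt(1 - ref_tanimoto(cf[[i]], cf[[j]]), 0.6)
    }
    # coverage: every compound within t_tc of its center
    expect_true(all(cm$distance <= 0.6 + 1e-12))
  }
})

test_that("full pipeline matches the brute-force reference implementation", {
  for (s in 1:10) {
    n <- 10 + (s * 7) %% 41
    fps <- random_fps(n, n_bits = 40L, density = 0.25, seed = 2000 + s)
    mols <- fake_mol_set(fps, n_bits = 40L)
    cm <- reassign_to_nearest(run_sphere_exclusion(mols, 0.6, order_seed = s),
                              mols)
    ord <- molsplit:::with_seed(s, sample.int(n))
    ref <- ref_sphere_pipeline(fps, ord, 0.6)
    expect_equal(unname(cm$assignment), ref$assignment)
    expect_equal(match(cm$center_compound_ids, names(cm$assignment)),
                 ref$centers)
  }
})

test_that("cluster-to-fold allocation is seeded, uniform and inherited", {
  fps <- random_fps(30, seed = 33)
  mols <- fake_mol_set(fps)
  cm <- run_sphere_exclusion(mols, 0.6, order_seed = 4)
  fa1 <- assign_cluster_folds(cm, 5, fold_seed = 9)
  fa2 <- assign_cluster_folds(cm, 5, fold_seed = 9)
  expect_identical(as.data.frame(fa1), as.data.frame(fa2))
  expect_error(assign_cluster_folds(cm, 5), "fold_seed")
  # members inherit the cluster fold
  lk <- setNames(fa1$fold, fa1$compound_id)
  expect_true(all(tapply(lk[names(cm$assignment)], cm$assignment,
                         function(x) length(unique(x))) == 1L))
  # all compounds in one cluster -> one fold
  cm1 <- run_sphere_exclusion(mols, 1.0, order_seed = 4)
  expect_length(unique(assign_cluster_folds(cm1, 5, 1)$fold), 1L)
  # empirical per-cluster fold frequency ~ 1/n_folds over many seeds
  k <- length(cm$center_compound_ids)
  draws <- vapply(1:1500, function(fs)
    molsplit:::with_seed(fs, sample.int(5L, k, replace = TRUE) - 1L),
    integer(k))
  freq <- rowMeans(draws == 0L) # fold 0 frequency per cluster
  expect_true(all(abs(freq - 0.2) < 4 * sqrt(0.2 * 0.8 / 1500)))
})

test_that("series land in single clusters on series-structured data", {
  fx <- series_fixture()
  cm <- reassign_to_nearest(
    run_sphere_exclusion(fx$mols, 0.6, order_seed = 42), fx$mols)
  caps <- tapply(cm$assignment[fx$mols$compounds$compound_id], fx$series,
                 function(x) length(unique(x)))
  expect_true(all(caps[grepl("^S", names(caps))] == 1L))
})
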