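# Evaluation metrics: pair sampling, intra-fold fractions, imbalance flags.

test_that("pair sampling is seeded, self-pair-free and balanced", {
  ids <- sprintf("C%03d", 1:100)
  p1 <- sample_pairs(ids, 1e4, seed = 3)
  p2 <- sample_pairs(ids, 1e4, seed = 3)
  expect_identical(p1, p2)
  expect_true(all(p1$id1 != p1$id2))
  expect_equal(nrow(p1), 1e4)
  # participation counts within binomial 4 sigma of expectation
  counts <- table(factor(c(p1$id1, p1$id2), levels = ids))
  expe <- 2e4 / 100
  expect_true(all(abs(counts - expe) < 4 * sqrt(2e4 * (1 / 100) * (99 / 100))))
  # two molecules: only one possible pair
  p3 <- sample_pairs(c("a", "b"), 50, seed = 1)
  expect_true(all((p3$id1 == "a" & p3$id2 == "b") |
                  (p3$id1 == "b" & p3$id2 == "a")))
  expect_error(sample_pairs("a", 5, seed = 1), "at least 2")
})

test_that("intra-fold fractions match a hand tally and bin conventions", {
  folds <- new_fold_assignment_for_test(
    ids = c("a", "b", "c", "d"), folds = c(0L, 0L, 1L, 2L), n_folds = 5L)
  pairs <- data.frame(id1 = c("a", "a", "a", "b", "c", "a"),
                      id2 = c("b", "c", "d", "c", "d", "b"))
  sims <- c(0.95, 0.95, 0.52, 0.52, 0.52, 0.05)
  r <- intra_fold_fraction(pairs, sims, folds)
  # top bin: pairs (a,b) same fold and (a,c) different -> 1/2
  expect_equal(r$intra_fold_fraction[10], 0.5)
  # [0.5, 0.6): (a,d), (b,c), (c,d) all different folds -> 0
  expect_equal(r$intra_fold_fraction[6], 0)
  # [0.0, 0.1): (a,b) same fold -> 1
  expect_equal(r$intra_fold_fraction[1], 1)
  expect_equal(sum(r$n_pairs), nrow(pairs))
  # empty bins are NA, never 0
  expect_true(all(is.na(r$intra_fold_fraction[c(2:5, 7:9)])))
  # similarity 1.0 lands in the closed top bin
  r2 <- intra_fold_fraction(pairs[1, ], 1.0, folds)
  expect_equal(r2$n_pairs[10], 1L)
  # unknown compound -> error
  expect_error(intra_fold_fraction(data.frame(id1 = "zz", id2 = "a"), 0.5, folds),
               "no fold")
})

test_that("task data imbalance flags tasks with any fold below five", {
  folds <- new_fold_assignment_for_test(
    ids = sprintf("m%02d", 1:60),
    folds = rep(0:4, each = 12), n_folds = 5L)
  # task A: 4 compounds (pigeonhole: some fold < 5) -> flagged
  # task B: exactly 5 in each of 5 folds -> NOT flagged (strict "below five")
  # task C: 12 compounds in one fold, none elsewhere -> flagged (empty folds)
  act <- rbind(
    data.frame(compound_id = sprintf("m%02d", 1:4), task_id = "A", label = 1L),
    data.frame(compound_id = sprintf("m%02d", c(1:5, 13:17, 25:29, 37:41, 49:53)),
               task_id = "B", label = rep(c(1L, 0L), length.out = 25)),
    data.frame(compound_id = sprintf("m%02d", 1:12), task_id = "C", label = 0L))
  r <- task_data_imbalance(act, folds)
  expect_equal(setNames(r$below5_flag, r$task_id),
               c(A = TRUE, B = FALSE, C = TRUE))
  expect_equal(r$n_compounds, c(4L, 25L, 12L))
  # fold counts conserve task size
  expect_equal(unname(rowSums(r[paste0("fold", 0:4)])), r$n_compounds)
  expect_equal(as.character(r$size_bin), c("<10", ">=10", ">=10"))
})

test_that("label imbalance uses population sd over populated folds, strict >", {
  folds <- new_fold_assignment_for_test(
    ids = sprintf("m%02d", 1:40), folds = rep(0:3, each = 10), n_folds = 4L)
  mk <- function(task, ids, labels)
    data.frame(compound_id = ids, task_id = task, label = labels)
  act <- rbind(
    # equal active fraction everywhere -> sd 0
    mk("flat", sprintf("m%02d", 1:40), rep(c(1L, 0L), 20)),
    # two populated folds with fractions 0 and 1 -> sd 0.5 -> flagged
    mk("split", sprintf("m%02d", 1:20), rep(c(0L, 1L), each = 10)),
    # fractions 0.5, 0.5, 0.6, 0.6 -> population sd exactly 0.05 -> NOT flagged
    mk("edge", sprintf("m%02d", 1:40),
       c(rep(c(1L, 0L), 10), rep(c(1L, 1L, 1L, 0L, 0L), 4))))
  r <- task_label_imbalance(act, folds)
  lk <- setNames(r$label_imbalance_flag, r$task_id)
  expect_false(lk[["flat"]])
  expect_true(lk[["split"]])
  expect_false(lk[["edge"]])
  sd_edge <- r$active_sd[r$task_id == "edge"]
  expect_equal(sd_edge, 0.05, tolerance = 1e-12)
  # empty folds are excluded from the sd (they have no active fraction)
  expect_equal(r$n_folds_populated[r$task_id == "split"], 2L)
})

test_that("aggregation reports flag fractions by task size bin", {
  folds <- new_fold_assignment_for_test(
    ids = sprintf("m%03d", 1:300), folds = rep(0:4, 60), n_folds = 5L)
  lib_ids <- sprintf("m%03d", 1:300)
  act <- rbind(
    data.frame(compound_id = lib_ids[1:8], task_id = "t1", label = 1L),
    data.frame(compound_id = lib_ids[1:50], task_id = "t2",
               label = rep(c(1L, 0L), 25)),
    data.frame(compound_id = lib_ids, task_id = "t3",
               label = rep(c(1L, 0L), 150)))
  agg <- aggregate_imbalance(task_data_imbalance(act, folds),
                             task_label_imbalance(act, folds))
  expect_s3_class(agg, "imbalance_report")
  expect_equal(sum(agg$n_tasks), 3L)
  expect_true(all(agg$fraction_below5 >= 0 & agg$fraction_below5 <= 1))
})

test_that("activity table validation rejects malformed input", {
  folds <- new_fold_assignment_for_test(c("a", "b"), c(0L, 1L), 2L)
  expect_error(task_data_imbalance(
    data.frame(compound_id = "a", task_id = "t", label = 2L), folds), "binary")
  expect_error(task_data_imbalance(
    data.frame(compound_id = c("a", "a"), task_id = c("t", "t"),
               label = c(0L, 1L)), folds), "one label")
})
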