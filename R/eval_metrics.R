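# Split-quality diagnostics: intra-fold pair fraction by similarity bin, and
# per-task data / label imbalance on a sparse binary activity table.

#' Sample random compound pairs
#'
#' Uniform sampling with replacement over unordered pairs of distinct
#' compound ids, seeded and reproducible. Self-pairs are excluded.
#'
#' @param ids character vector of compound ids (>= 2), or a
#'   [mol_set][prepare_molecules()].
#' @param n_pairs number of pairs to draw.
#' @param seed integer RNG seed.
#' @return data frame `id1`, `id2` with `n_pairs` rows; the attribute
#'   `"index"` holds the corresponding integer index matrix into `ids`.
#' @export
sample_pairs <- function(ids, n_pairs, seed) {
  if (inherits(ids, "mol_set")) ids <- ids$compounds$compound_id
  n <- length(ids)
  if (n < 2L) stop("need at least 2 compounds to sample pairs")
  stopifnot(n_pairs >= 1L)
  idx <- with_seed(seed, {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n, n_pairs, replace = TRUE)
    while (any(eq <- i == j))
      j[eq] <- sample.int(n, sum(eq), replace = TRUE)
    cbind(i, j)
  })
  out <- data.frame(id1 = ids[idx[, 1L]], id2 = ids[idx[, 2L]])
  attr(out, "index") <- idx
  out
}

# Tanimoto similarity for a sampled pair table against a mol_set.
pair_similarities <- function(mols, pairs) {
  fps <- mol_fps(mols)
  idx <- attr(pairs, "index")
  if (is.null(idx)) {
    idx <- cbind(match(pairs$id1, mols$compounds$compound_id),
                 match(pairs$id2, mols$compounds$compound_id))
    if (anyNA(idx)) stop("pair ids missing from mol_set")
  }
  tanimoto_pairs(unclass(fps), idx[, 1L], idx[, 2L])
}

#' Intra-fold pair fraction by similarity bin
#'
#' Groups sampled compound pairs into 10 equidistant Tanimoto similarity bins
#' (`[0,0.1), ..., [0.8,0.9), [0.9,1.0]`; the top bin is closed so identical
#' pairs are counted) and computes, per bin, the fraction of pairs whose two
#' members share a fold. Under a uniform random split the expected fraction
#' is `1/n_folds` in every bin; series-preserving splits push the top bins
#' toward 1. Empty bins are reported as `NA`, never as 0.
#'
#' @param pairs a pair table from [sample_pairs()] (or any data frame with
#'   `id1`, `id2`).
#' @param similarities numeric vector in `[0,1]` aligned with `pairs`.
#' @param folds a `fold_assignment` covering every paired compound.
#' @return a `pair_similarity_report`: data frame `bin_low`, `bin_high`,
#'   `n_pairs`, `intra_fold_fraction`.
#' @export
intra_fold_fraction <- function(pairs, similarities, folds) {
  stopifnot(nrow(pairs) == length(similarities),
            all(similarities >= 0 & similarities <= 1))
  lk <- fold_lookup(folds)
  f1 <- lk[pairs$id1]
  f2 <- lk[pairs$id2]
  if (anyNA(f1) || anyNA(f2))
    stop("some paired compounds have no fold assignment")
  bin <- pmin(floor(similarities * 10), 9) + 1L # [0.9, 1.0] closed
  same <- as.integer(f1 == f2)
  n <- tabulate(bin, nbins = 10L)
  hits <- vapply(1:10, function(b) sum(same[bin == b]), numeric(1))
  frac <- ifelse(n > 0L, hits / n, NA_real_)
  structure(data.frame(bin_low = seq(0, 0.9, by = 0.1),
                       bin_high = seq(0.1, 1.0, by = 0.1),
                       n_pairs = n,
                       intra_fold_fraction = frac),
            class = c("pair_similarity_report", "data.frame"))
}

#' @export
print.pair_similarity_report <- function(x, ...) {
  cat("<pair_similarity_report>", sum(x$n_pairs), "pairs\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

# validate a sparse binary activity table
check_activity <- function(activity) {
  stopifnot(is.data.frame(activity),
            all(c("compound_id", "task_id", "label") %in% names(activity)))
  if (!all(activity$label %in% c(0L, 1L)))
    stop("labels must be binary (0/1)")
  if (anyDuplicated(activity[c("compound_id", "task_id")]))
    stop("at most one label per (compound_id, task_id) pair")
  activity
}

# Task size bins of the imbalance summary: lower limits 10/100/1k/10k/100k,
# tasks below 10 compounds reported separately as "<10".
TASK_SIZE_LIMITS <- c(10, 100, 1000, 10000, 100000)

task_size_bin <- function(n) {
  cut(n, breaks = c(-Inf, TASK_SIZE_LIMITS, Inf),
      labels = c("<10", paste0(">=", TASK_SIZE_LIMITS)), right = FALSE)
}

#' Per-task data imbalance
#'
#' For every task, counts the task's compounds per fold (folds with no
#' compounds count 0) and flags the task when any fold holds fewer than 5 of
#' its compounds (strict: exactly 5 everywhere is not flagged). The flag is
#' the paper-style "fraction of tasks below five compounds in one or more
#' folds" measure once aggregated with [aggregate_imbalance()].
#'
#' @param activity data frame `compound_id`, `task_id`, `label` (sparse
#'   binary activity triplets).
#' @param folds a `fold_assignment` covering every activity compound.
#' @param n_folds number of folds; defaults to the assignment's.
#' @return data frame `task_id`, `n_compounds`, `size_bin`, per-fold counts
#'   `fold0..fold<k>`, `below5_flag`.
#' @export
task_data_imbalance <- function(activity, folds, n_folds = NULL) {
  activity <- check_activity(activity)
  if (is.null(n_folds)) n_folds <- attr(folds, "n_folds")
  lk <- fold_lookup(folds)
  f <- lk[activity$compound_id]
  if (anyNA(f)) stop("some activity compounds have no fold assignment")
  tasks <- split(f, activity$task_id)
  counts <- t(vapply(tasks, function(x) tabulate(x + 1L, nbins = n_folds),
                     integer(n_folds)))
  colnames(counts) <- paste0("fold", seq_len(n_folds) - 1L)
  n_comp <- rowSums(counts)
  out <- data.frame(task_id = names(tasks),
                    n_compounds = as.integer(n_comp),
                    size_bin = task_size_bin(n_comp),
                    row.names = NULL)
  out <- cbind(out, as.data.frame(counts, row.names = NULL))
  out$below5_flag <- apply(counts < 5L, 1L, any)
  out
}

#' Per-task label imbalance
#'
#' For every task, the fraction of active labels is computed per populated
#' fold (folds holding none of the task's compounds have no defined active
#' fraction and are excluded), and the population standard deviation of
#' those fractions is taken across folds. Tasks with a standard deviation
#' strictly greater than 0.05 are flagged "label imbalanced"; a standard
#' deviation of exactly 0.05 is not flagged (comparison uses a small relative
#' epsilon so the boundary survives floating-point roundoff).
#'
#' @inheritParams task_data_imbalance
#' @return data frame `task_id`, `n_folds_populated`, `active_sd`,
#'   `label_imbalance_flag`.
#' @export
task_label_imbalance <- function(activity, folds) {
  activity <- check_activity(activity)
  lk <- fold_lookup(folds)
  f <- lk[activity$compound_id]
  if (anyNA(f)) stop("some activity compounds have no fold assignment")
  key <- split(seq_len(nrow(activity)), activity$task_id)
  res <- lapply(key, function(ix) {
    fr <- vapply(split(activity$label[ix], f[ix]), mean, numeric(1))
    sdp <- sqrt(mean((fr - mean(fr))^2)) # population sd across populated folds
    c(k = length(fr), sd = sdp)
  })
  res <- do.call(rbind, res)
  data.frame(task_id = names(key),
             n_folds_populated = as.integer(res[, "k"]),
             active_sd = res[, "sd"],
             label_imbalance_flag = res[, "sd"] > 0.05 * (1 + 1e-9) + 1e-12,
             row.names = NULL)
}

#' Aggregate imbalance flags by task size bin
#'
#' Joins the per-task data- and label-imbalance tables and reports, per task
#' size bin (lower limits 10, 100, 1000, 10000, 100000; tasks under 10
#' compounds separately), the fraction of tasks flagged.
#'
#' @param data_imbalance output of [task_data_imbalance()].
#' @param label_imbalance output of [task_label_imbalance()].
#' @return an `imbalance_report`: data frame `size_bin`, `n_tasks`,
#'   `fraction_below5`, `fraction_label_imbalance`.
#' @export
aggregate_imbalance <- function(data_imbalance, label_imbalance) {
  m <- merge(data_imbalance[c("task_id", "size_bin", "below5_flag")],
             label_imbalance[c("task_id", "label_imbalance_flag")],
             by = "task_id")
  sp <- split(m, m$size_bin)
  out <- data.frame(size_bin = names(sp),
                    n_tasks = vapply(sp, nrow, integer(1)),
                    fraction_below5 = vapply(sp, function(d)
                      if (nrow(d)) mean(d$below5_flag) else NA_real_, numeric(1)),
                    fraction_label_imbalance = vapply(sp, function(d)
                      if (nrow(d)) mean(d$label_imbalance_flag) else NA_real_, numeric(1)),
                    row.names = NULL)
  structure(out[out$n_tasks > 0L | !is.na(out$fraction_below5), , drop = FALSE],
            class = c("imbalance_report", "data.frame"))
}

#' @export
print.imbalance_report <- function(x, ...) {
  cat("<imbalance_report>\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' One-stop pair similarity report for a split
#'
#' Convenience wrapper: samples pairs, computes their Tanimoto similarities
#' from the `mol_set` fingerprints and tallies the intra-fold fraction per
#' similarity bin.
#'
#' @param mols a [mol_set][prepare_molecules()] with fingerprints.
#' @param folds a `fold_assignment` for the same compounds.
#' @param n_pairs number of sampled pairs.
#' @param seed RNG seed for pair sampling.
#' @return a [pair_similarity_report][intra_fold_fraction()].
#' @export
pair_similarity_report <- function(mols, folds, n_pairs = 1e5, seed = 1L) {
  pairs <- sample_pairs(mols, n_pairs, seed)
  sims <- pair_similarities(mols, pairs)
  intra_fold_fraction(pairs, sims, folds)
}
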