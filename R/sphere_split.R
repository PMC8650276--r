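# Sphere exclusion (Taylor-Butina / leader-follower) clustering split.
#
# Compounds are processed in a seeded random order; each joins the closest
# existing cluster center within Tanimoto distance t_Tc or founds a new
# cluster. A single nearest-center re-assignment pass (the k-means-style
# step) follows, and every cluster is then allocated to one seeded random
# fold. Because cluster centers depend on the pooled library, this method is
# not locally computable per party: in a federation it must run as a joint
# protocol; this implementation is the centralized variant.

#' Sphere exclusion clustering
#'
#' Shuffles the compounds with `order_seed`, then processes them in that
#' order: a compound joins the closest existing center when its minimum
#' Tanimoto distance over centers is `<= t_tc` (ties to the earliest-created
#' center), otherwise it becomes a new center. By construction pairwise
#' center distances exceed `t_tc` and every compound lies within `t_tc` of
#' its center. Complexity O(N_clusters * N_compounds).
#'
#' @param mols a [mol_set][prepare_molecules()] with fingerprints.
#' @param t_tc Tanimoto distance cutoff in `[0, 1]` (default 0.6).
#' @param order_seed integer seed for the processing-order shuffle; required,
#'   so every clustering is reproducible.
#' @return an object of class `cluster_model`: list with `center_compound_ids`
#'   (creation order), `center_fps`, `assignment` (named integer vector
#'   compound_id -> 1-based cluster index), `distance` (to the assigned
#'   center), `t_tc`, `order_seed`, `reassigned`.
#' @export
run_sphere_exclusion <- function(mols, t_tc = 0.6, order_seed) {
  stopifnot(inherits(mols, "mol_set"), t_tc >= 0, t_tc <= 1)
  if (missing(order_seed)) stop("order_seed is required for reproducibility")
  fps <- mol_fps(mols)
  ids <- mols$compounds$compound_id
  n <- length(ids)
  if (n == 0L) {
    return(structure(list(center_compound_ids = character(),
                          center_fps = structure(list(), n_bits = attr(fps, "n_bits"),
                                                 class = "fp_set"),
                          assignment = integer(), distance = numeric(),
                          t_tc = t_tc, order_seed = order_seed,
                          reassigned = FALSE),
                     class = "cluster_model"))
  }
  ord <- with_seed(order_seed, sample.int(n))
  res <- .sphere_exclusion_cpp(unclass(fps), ord, t_tc)
  centers <- res$centers
  assignment <- stats::setNames(res$assignment, ids)
  center_fps <- structure(unclass(fps)[centers], n_bits = attr(fps, "n_bits"),
                          radius = attr(fps, "radius"), class = "fp_set")
  dist <- 1 - tanimoto_pairs(unclass(fps), seq_len(n), centers[res$assignment])
  structure(list(center_compound_ids = ids[centers],
                 center_fps = center_fps,
                 assignment = assignment,
                 distance = stats::setNames(dist, ids),
                 t_tc = t_tc, order_seed = order_seed, reassigned = FALSE),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d clusters over %d compounds, t_Tc = %g%s\n",
              length(x$center_compound_ids), length(x$assignment), x$t_tc,
              if (x$reassigned) " (re-assigned)" else ""))
  invisible(x)
}

#' Nearest-center re-assignment
#'
#' One pass mapping every compound to its minimum-distance center (ties to
#' the earliest-created center), with centers unchanged -- the analogue of
#' one k-means assignment step. Idempotent; assigned distances never
#' increase and stay `<= t_tc`.
#'
#' @param model a [cluster_model][run_sphere_exclusion()].
#' @param mols the same [mol_set][prepare_molecules()] the model was built on.
#' @return the updated `cluster_model` (`reassigned = TRUE`).
#' @export
reassign_to_nearest <- function(model, mols) {
  stopifnot(inherits(model, "cluster_model"), inherits(mols, "mol_set"))
  ids <- mols$compounds$compound_id
  if (!all(ids %in% names(model$assignment)) ||
      length(ids) != length(model$assignment))
    stop("mol_set does not match the compounds the model was built on")
  fps <- mol_fps(mols)
  res <- .nearest_center_cpp(unclass(fps), unclass(model$center_fps))
  model$assignment <- stats::setNames(res$cluster, ids)
  model$distance <- stats::setNames(res$distance, ids)
  model$reassigned <- TRUE
  model
}

#' Allocate sphere-exclusion clusters to folds
#'
#' Draws one fold per cluster from a seeded RNG, in cluster-creation order,
#' and lets every member inherit its cluster's fold. A seeded RNG (rather
#' than the SHA-256 key hash) is used because clusters have no canonical
#' cross-party key; consistent federated use requires running the clustering
#' jointly and sharing `fold_seed`.
#'
#' @param model a [cluster_model][run_sphere_exclusion()].
#' @param n_folds number of folds (default 5).
#' @param fold_seed integer seed for the per-cluster fold draw; required.
#' @return a `fold_assignment` (method `"sphere"`).
#' @export
assign_cluster_folds <- function(model, n_folds = 5L, fold_seed) {
  stopifnot(inherits(model, "cluster_model"))
  if (missing(fold_seed)) stop("fold_seed is required for reproducibility")
  k <- length(model$center_compound_ids)
  cluster_fold <- with_seed(fold_seed,
                            sample.int(as.integer(n_folds), k, replace = TRUE) - 1L)
  folds <- cluster_fold[model$assignment]
  new_fold_assignment(names(model$assignment), folds, n_folds, "sphere",
                      params = list(t_tc = model$t_tc,
                                    order_seed = model$order_seed,
                                    fold_seed = fold_seed,
                                    n_clusters = k))
}
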