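# Deterministic, party-independent mapping of text keys to folds.
#
# All locally computable split methods (random, LSH, scaffold) reduce to the
# same primitive: SHA-256 over `secret || 0x00 || key`, first 8 digest bytes
# read as a big-endian unsigned 64-bit integer, modulo n_folds. The single
# 0x00 separator removes the "ab"+"c" vs "a"+"bc" ambiguity; modulo bias is
# negligible for n_folds far below 2^64. Any two parties that agree on the
# standardization pipeline (and the optional shared secret) therefore assign
# identical structures to identical folds with no communication.

#' Map text keys to folds by keyed SHA-256 hashing
#'
#' @param key character vector of non-empty keys (e.g. canonical SMILES).
#' @param n_folds number of folds (>= 1).
#' @param secret optional shared secret; appended into the hash input so that
#'   only parties knowing it can reproduce the assignment. The empty string
#'   means no secret.
#' @return integer vector of 0-based fold indices in `[0, n_folds)`.
#' @examples
#' hash_to_fold("c1ccccc1", 5) # 4, reproducible everywhere
#' @export
hash_to_fold <- function(key, n_folds, secret = "") {
  stopifnot(is.character(key), length(secret) == 1L, !is.na(secret))
  if (!is.numeric(n_folds) || length(n_folds) != 1L || is.na(n_folds) ||
      n_folds < 1)
    stop("n_folds must be a positive integer")
  if (any(!is.na(key) & key == ""))
    stop("keys must be non-empty")
  .hash_to_fold_cpp(key, as.integer(n_folds), secret)
}

# ---------------------------------------------------------------------------
# fold_assignment container

new_fold_assignment <- function(compound_id, fold, n_folds, method,
                                params = list()) {
  stopifnot(length(compound_id) == length(fold))
  if (anyDuplicated(compound_id)) stop("duplicated compound_id in assignment")
  fold <- as.integer(fold)
  if (length(fold) && (anyNA(fold) || any(fold < 0L) || any(fold >= n_folds)))
    stop("fold indices must lie in [0, n_folds)")
  structure(
    data.frame(compound_id = as.character(compound_id), fold = fold,
               row.names = NULL),
    n_folds = as.integer(n_folds), method = method, params = params,
    class = c("fold_assignment", "data.frame"))
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> method '%s', %d compounds, %d folds\n",
              attr(x, "method"), nrow(x), attr(x, "n_folds")))
  if (nrow(x)) {
    tab <- tabulate(x$fold + 1L, nbins = attr(x, "n_folds"))
    names(tab) <- paste0("fold", seq_along(tab) - 1L)
    print(tab)
  }
  invisible(x)
}

#' @export
summary.fold_assignment <- function(object, ...) {
  tab <- tabulate(object$fold + 1L, nbins = attr(object, "n_folds"))
  data.frame(fold = seq_along(tab) - 1L, n = tab,
             fraction = if (nrow(object)) tab / nrow(object) else rep(NA_real_, length(tab)))
}

# named lookup fold[compound_id]
fold_lookup <- function(fa) {
  stats::setNames(fa$fold, fa$compound_id)
}

#' Random fold split by hashing canonical SMILES
#'
#' The federated random split: each compound's fold is the keyed hash
#' ([hash_to_fold()]) of its standardized canonical SMILES, so the split is
#' pseudo-random, uniform over folds, and reproducible by every party
#' independently. Duplicate structures (identical canonical SMILES under
#' different compound ids) always share a fold.
#'
#' @param mols a [mol_set][prepare_molecules()].
#' @param n_folds number of folds (default 5).
#' @param secret optional shared secret, see [hash_to_fold()].
#' @return a `fold_assignment`: data frame `compound_id`, `fold` with
#'   attributes `method`, `n_folds`, `params`.
#' @examples
#' \donttest{
#' mols <- prepare_molecules(c(a = "CCO", b = "OCC"), fingerprints = FALSE)
#' assign_random_folds(mols, n_folds = 5) # a and b share a fold
#' }
#' @export
assign_random_folds <- function(mols, n_folds = 5L, secret = "") {
  stopifnot(inherits(mols, "mol_set"))
  folds <- hash_to_fold(mols$compounds$canonical_smiles, n_folds, secret)
  new_fold_assignment(mols$compounds$compound_id, folds, n_folds, "random",
                      params = list(secret_fingerprint = secret_fingerprint(secret)))
}

# never store the secret itself in provenance metadata
secret_fingerprint <- function(secret) {
  if (identical(secret, "")) "" else substr(sha256_hex(secret), 1L, 12L)
}

#' Map folds to train/validation/test partitions
#'
#' Maps fold indices to named partitions by fold index order: with the
#' default `ratio = c(train = 3, valid = 1, test = 1)` and 5 folds, folds
#' 0-2 become training, fold 3 validation and fold 4 test (the 60-20-20
#' convention for nested cross-validation).
#'
#' @param fold integer vector of fold indices, or a `fold_assignment`.
#' @param ratio named integer vector of fold counts per partition; must sum
#'   to the number of folds.
#' @param n_folds total number of folds (taken from a `fold_assignment`
#'   automatically).
#' @return character vector of partition names aligned with `fold`.
#' @examples
#' partition_folds(c(0L, 2L, 3L, 4L), n_folds = 5L)
#' @export
partition_folds <- function(fold, ratio = c(train = 3L, valid = 1L, test = 1L),
                            n_folds = NULL) {
  if (inherits(fold, "fold_assignment")) {
    n_folds <- attr(fold, "n_folds")
    fold <- fold$fold
  }
  if (is.null(n_folds)) n_folds <- max(fold) + 1L
  if (is.null(names(ratio))) names(ratio) <- paste0("set", seq_along(ratio))
  if (sum(ratio) != n_folds)
    stop("partition ratio must sum to n_folds")
  map <- rep(names(ratio), times = ratio)
  map[fold + 1L]
}
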