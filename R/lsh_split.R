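# Locality-sensitive hashing split.
#
# Compounds are binned by the values of the N fingerprint bits whose
# frequency in a reference set is closest to 0.5 (for a binary feature,
# maximal entropy). Similar compounds agree on most bits and therefore tend
# to share a bin; every compound in a bin is hashed to the same fold. When
# the reference set is public, every party can reproduce the same bit
# selection and hence the same folds, with no communication.

#' Select the highest-entropy fingerprint bits from a reference set
#'
#' Picks the `n_select` bit indices whose frequency in the reference
#' fingerprints is closest to 0.5; for binary features this is the maximal
#' entropy criterion. Ties on `|frequency - 0.5|` are broken toward the lower
#' bit index; the result is sorted ascending.
#'
#' @param reference an [fp_set][compute_fingerprint()] (or plain list of
#'   sorted on-bit vectors) of reference fingerprints; non-empty.
#' @param n_select number of bits to select (default 16).
#' @param n_bits bit-space size; taken from the `fp_set` attribute when
#'   present.
#' @return an object of class `lsh_model`: list with `selected_bits`
#'   (0-based, strictly ascending), `reference_frequencies` (aligned),
#'   `n_select`, `n_bits`, `n_reference`.
#' @examples
#' fps <- structure(list(c(0L, 7L), 7L, 0L, integer(0)), n_bits = 8L)
#' select_high_entropy_bits(fps, n_select = 2)
#' @export
select_high_entropy_bits <- function(reference, n_select = 16L, n_bits = NULL) {
  reference <- Filter(Negate(is.null), unclass(reference))
  if (length(reference) == 0L) stop("reference set must be non-empty")
  if (is.null(n_bits)) n_bits <- attr(reference, "n_bits")
  if (is.null(n_bits)) n_bits <- 32768L
  n_select <- as.integer(n_select)
  stopifnot(n_select >= 1L, n_select <= n_bits)
  freq <- tabulate(unlist(reference) + 1L, nbins = n_bits) / length(reference)
  ord <- order(abs(freq - 0.5), seq_len(n_bits))[seq_len(n_select)]
  sel <- sort(ord) - 1L
  structure(list(selected_bits = sel,
                 reference_frequencies = freq[sel + 1L],
                 n_select = n_select,
                 n_bits = as.integer(n_bits),
                 n_reference = length(reference)),
            class = "lsh_model")
}

#' @export
print.lsh_model <- function(x, ...) {
  cat(sprintf("<lsh_model> %d selected bits of %d (reference: %d fingerprints)\n",
              x$n_select, x$n_bits, x$n_reference))
  cat("bits:", paste(x$selected_bits, collapse = " "), "\n")
  cat("freq:", paste(sprintf("%.3f", x$reference_frequencies), collapse = " "), "\n")
  invisible(x)
}

#' Compute LSH bin keys
#'
#' The bin key of a fingerprint is the string of '1'/'0' characters over the
#' model's selected bits in ascending index order; at most `2^n_select`
#' distinct keys can occur.
#'
#' @param fps an [fp_set][compute_fingerprint()], a plain list of on-bit
#'   vectors, or a single integer on-bit vector.
#' @param model an [lsh_model][select_high_entropy_bits()].
#' @return character vector of bin keys of length `n_select` each.
#' @examples
#' m <- structure(list(selected_bits = c(3L, 5L), n_select = 2L, n_bits = 8L),
#'                class = "lsh_model")
#' compute_bin(list(c(3L)), m) # "10"
#' @export
compute_bin <- function(fps, model) {
  stopifnot(inherits(model, "lsh_model"))
  if (is.numeric(fps)) fps <- list(as.integer(fps))
  nb <- attr(fps, "n_bits")
  if (!is.null(nb) && nb != model$n_bits)
    stop("fingerprint bit space does not match the LSH model (n_bits mismatch)")
  vapply(unclass(fps), function(fp) {
    if (is.null(fp)) return(NA_character_)
    paste(as.integer(model$selected_bits %in% fp), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' LSH fold split
#'
#' Bins every compound by its selected-bit pattern ([compute_bin()]) and
#' hashes the bin key to a fold with [hash_to_fold()], under the "LSH:" key
#' namespace so that bin keys can never collide with SMILES or scaffold keys
#' under a shared secret. All compounds in a bin share a fold.
#'
#' @param mols a [mol_set][prepare_molecules()] with fingerprints.
#' @param model an [lsh_model][select_high_entropy_bits()], typically built
#'   from a shared public reference set.
#' @param n_folds,secret see [hash_to_fold()].
#' @return a `fold_assignment` (method `"lsh"`).
#' @export
assign_lsh_folds <- function(mols, model, n_folds = 5L, secret = "") {
  stopifnot(inherits(mols, "mol_set"), inherits(model, "lsh_model"))
  bins <- compute_bin(mol_fps(mols), model)
  folds <- hash_to_fold(paste0("LSH:", bins), n_folds, secret)
  new_fold_assignment(mols$compounds$compound_id, folds, n_folds, "lsh",
                      params = list(n_select = model$n_select,
                                    selected_bits = model$selected_bits,
                                    secret_fingerprint = secret_fingerprint(secret)))
}

#' Persist / restore an LSH model
#'
#' The model is written as plain JSON (bit indices, reference frequencies,
#' sizes) so that it can be exchanged between parties and reused verbatim;
#' federated consistency requires every party to use the identical model.
#'
#' @param model an `lsh_model`.
#' @param path file path.
#' @return `read_lsh_model` returns the restored `lsh_model`;
#'   `write_lsh_model` returns `path` invisibly.
#' @export
write_lsh_model <- function(model, path) {
  stopifnot(inherits(model, "lsh_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lsh_model
#' @export
read_lsh_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(selected_bits = as.integer(x$selected_bits),
                 reference_frequencies = as.numeric(x$reference_frequencies),
                 n_select = as.integer(x$n_select),
                 n_bits = as.integer(x$n_bits),
                 n_reference = as.integer(x$n_reference)),
            class = "lsh_model")
}
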