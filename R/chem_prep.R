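# Structure standardization and folded circular fingerprints.
#
# All descriptor-based split methods share one representation: the
# standardized parent structure (largest organic fragment, simple charges
# neutralized, isotope labels stripped, canonical SMILES) and a folded
# ECFP-style circular fingerprint over that canonical SMILES. The central
# contract is that identical compounds -- including different salt forms and
# different input atom orderings -- yield an identical canonical SMILES and
# hence an identical fingerprint and fold.

#' Standardize SMILES to the canonical parent structure
#'
#' Applies a minimal standardization: isotope labels are stripped, simple
#' charges are neutralized where a neutral form exists (quaternary nitrogens
#' and other permanently charged centers are kept), counter-ions are removed
#' by keeping the largest organic fragment, and the result is converted to a
#' canonical SMILES (OpenBabel canonicalization). Deterministic: the same
#' input always yields the same output.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where the input could
#'   not be parsed; the attribute `"errors"` holds a data frame
#'   (`index`, `smiles`, `reason`) describing the failures so that callers
#'   can skip-and-log rather than abort.
#' @examples
#' \donttest{
#' standardize_smiles(c("C1=CC=CC=C1", "c1ccccc1.[Na+].[Cl-]"))
#' }
#' @export
standardize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  out <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  if (n == 0L) {
    attr(out, "errors") <- data.frame(index = integer(), smiles = character(),
                                      reason = character())
    return(out)
  }

  x <- trimws(smiles)
  empty <- is.na(x) | x == ""
  reason[empty] <- "empty SMILES"

  todo <- which(!empty)
  if (length(todo)) {
    stripped <- strip_isotopes(x[todo])
    can <- ob_canonical(stripped, neutralize = TRUE)
    failed <- is.na(can)
    reason[todo[failed]] <- "unparseable SMILES"
    ok <- todo[!failed]
    can <- can[!failed]
    if (length(ok)) {
      frag <- vapply(can, largest_organic_fragment, character(1), USE.NAMES = FALSE)
      multi <- frag != can
      if (any(multi)) {
        # re-canonicalize fragments cut out of a multi-component SMILES
        recan <- ob_canonical(frag[multi], neutralize = TRUE)
        frag[multi] <- recan
      }
      bad <- is.na(frag) | frag == ""
      reason[ok[bad]] <- "unparseable SMILES"
      out[ok[!bad]] <- frag[!bad]
    }
  }

  err <- which(is.na(out))
  attr(out, "errors") <- data.frame(index = err,
                                    smiles = smiles[err],
                                    reason = reason[err],
                                    row.names = NULL)
  out
}

# Remove isotope labels: digits opening a bracket atom, e.g. [13CH4] -> [CH4],
# [2H] -> [H].
strip_isotopes <- function(smiles) {
  gsub("\\[[0-9]+", "[", smiles)
}

# Batch OpenBabel SMILES -> canonical SMILES. Returns NA for molecules the
# parser rejects. Identity of each record is kept through the SMILES title.
# A parse error aborts OpenBabel's remaining input stream, so the batch is
# resumed past each failing record until every molecule has been attempted.
ob_canonical <- function(smiles, neutralize = FALSE) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  opts <- if (neutralize) data.frame(names = "neutralize", args = "") else
    data.frame(names = character(), args = character())
  pending <- seq_len(n)
  while (length(pending)) {
    src <- paste0(smiles[pending], " i", pending, collapse = "\n")
    txt <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(src, "\n"), options = opts),
      error = function(e) "")
    got <- integer(0)
    if (is.character(txt) && length(txt) == 1L && nzchar(txt)) {
      lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
      lines <- lines[nzchar(trimws(lines))]
      for (ln in lines) {
        parts <- strsplit(ln, "[ \t]+")[[1]]
        if (length(parts) < 2L) next
        idx <- suppressWarnings(as.integer(sub("^i", "", parts[length(parts)])))
        if (!is.na(idx) && idx %in% pending) {
          out[idx] <- parts[1L]
          got <- c(got, idx)
        }
      }
    }
    missing <- setdiff(pending, got)
    if (!length(missing)) break
    # the first missing record stopped the stream; skip it and resume
    pending <- missing[-1L]
  }
  out
}

# Pick the component with the most heavy atoms, preferring organic
# (carbon-containing) components; ties broken by SMILES sort order for
# determinism.
largest_organic_fragment <- function(canonical) {
  if (is.na(canonical)) return(NA_character_)
  frags <- strsplit(canonical, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1L) return(canonical)
  heavy <- vapply(frags, count_heavy_atoms, integer(1), USE.NAMES = FALSE)
  organic <- vapply(frags, fragment_is_organic, logical(1), USE.NAMES = FALSE)
  key <- order(-organic, -heavy, frags)
  frags[key[1L]]
}

fragment_is_organic <- function(frag) {
  bare <- gsub("\\[[^]]*\\]", "", frag)
  if (grepl("C|c", bare)) return(TRUE)
  brackets <- regmatches(frag, gregexpr("\\[[^]]*\\]", frag))[[1]]
  any(grepl("^\\[(C|c)(?![a-eg-z])", brackets, perl = TRUE))
}

count_heavy_atoms <- function(frag) {
  brackets <- regmatches(frag, gregexpr("\\[[^]]*\\]", frag))[[1]]
  n_br <- sum(!grepl("^\\[H", brackets)) # bracket H atoms are not heavy
  bare <- gsub("\\[[^]]*\\]", "", frag)
  n_two <- sum(lengths(regmatches(bare, gregexpr("Cl|Br", bare))))
  bare <- gsub("Cl|Br", "", bare)
  n_one <- sum(lengths(regmatches(bare, gregexpr("[BCNOPSFI]|[bcnops]", bare))))
  as.integer(n_br + n_two + n_one)
}

# ---------------------------------------------------------------------------
# molecular graphs

ELEMENTS <- c(H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Si = 14L,
              P = 15L, S = 16L, Cl = 17L, Br = 35L, I = 53L, Na = 11L,
              K = 19L, Li = 3L, Mg = 12L, Ca = 20L, Zn = 30L, Fe = 26L,
              Se = 34L, As = 33L)

# molfile atom-block charge codes (field 6 of a V2000 atom line)
CHARGE_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

# Parse SMILES (batch) into light molecular graphs: for each molecule a list
# with `element` (atomic numbers), `symbol`, `charge`, and `bonds` (matrix
# i, j, order; kekulized orders as written by OpenBabel). NULL where parsing
# failed. The conversion goes through V2000 molfile text without coordinate
# generation (2D layout is expensive and irrelevant for connectivity); as in
# ob_canonical(), the stream is resumed past records OpenBabel rejects.
parse_mol_graphs <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  noopt <- data.frame(names = character(), args = character())
  pending <- which(!is.na(smiles) & nzchar(smiles))
  while (length(pending)) {
    src <- paste0(smiles[pending], " i", pending, collapse = "\n")
    txt <- tryCatch(
      ChemmineOB::convertFormat("SMI", "SDF", paste0(src, "\n"), options = noopt),
      error = function(e) "")
    got <- integer(0)
    if (is.character(txt) && length(txt) == 1L && nzchar(txt)) {
      blocks <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
      for (bl in blocks) {
        lines <- strsplit(bl, "\n", fixed = TRUE)[[1]]
        lines <- lines[cumsum(nzchar(lines)) > 0L | nzchar(lines)]
        while (length(lines) && !nzchar(lines[1L])) lines <- lines[-1L]
        if (length(lines) < 4L) next
        idx <- suppressWarnings(as.integer(sub("^i", "", trimws(lines[1L]))))
        if (is.na(idx) || !(idx %in% pending)) next
        g <- parse_molfile_lines(lines)
        if (!is.null(g)) {
          out[[idx]] <- g
          got <- c(got, idx)
        }
      }
    }
    missing <- setdiff(pending, got)
    if (!length(missing)) break
    pending <- missing[-1L] # first missing record stopped the stream
  }
  out
}

# Single-molecule convenience wrapper.
molfile_graph <- function(smiles) {
  parse_mol_graphs(smiles)[[1L]]
}

# Parse one V2000 molfile block (vector of lines, title first).
parse_molfile_lines <- function(lines) {
  if (length(lines) < 4L) return(NULL)
  na <- suppressWarnings(as.integer(substr(lines[4L], 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(lines[4L], 4L, 6L)))
  if (is.na(na) || is.na(nb) || na < 1L) return(NULL)
  al <- lines[4L + seq_len(na)]
  sym <- trimws(substr(al, 32L, 34L))
  code <- suppressWarnings(as.integer(substr(al, 37L, 39L)))
  charge <- unname(CHARGE_CODE[as.character(code)])
  charge[is.na(charge)] <- 0L
  bonds <- matrix(integer(), ncol = 3L)
  if (nb > 0L) {
    bl <- lines[4L + na + seq_len(nb)]
    bonds <- cbind(as.integer(substr(bl, 1L, 3L)),
                   as.integer(substr(bl, 4L, 6L)),
                   pmin(pmax(as.integer(substr(bl, 7L, 9L)), 1L), 3L))
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
    n <- f[1L]
    for (q in seq_len(n)) charge[f[2L * q]] <- f[2L * q + 1L]
  }
  z <- unname(ELEMENTS[sym]); z[is.na(z)] <- 0L
  keep_h <- z != 1L
  if (!all(keep_h)) {
    map <- cumsum(keep_h)
    hb <- bonds[, 1L] %in% which(!keep_h) | bonds[, 2L] %in% which(!keep_h)
    bonds <- bonds[!hb, , drop = FALSE]
    bonds[, 1L] <- map[bonds[, 1L]]
    bonds[, 2L] <- map[bonds[, 2L]]
    z <- z[keep_h]; charge <- charge[keep_h]; sym <- sym[keep_h]
  }
  list(element = z, symbol = sym, charge = as.integer(charge), bonds = bonds)
}

# ---------------------------------------------------------------------------
# fingerprints

#' Folded circular fingerprint of one or more molecules
#'
#' Computes an ECFP-style circular fingerprint: iterative neighborhood
#' hashing up to `radius` bond steps (radius 3 corresponds to ECFP6), with
#' all identifiers folded into `n_bits` bits. The fingerprint is represented
#' as the strictly increasing integer vector of 0-based on-bit indices.
#' Identical canonical SMILES always yield identical fingerprints.
#'
#' @param smiles character vector of (ideally canonical) SMILES. Inputs are
#'   parsed with OpenBabel, so equivalent aromatic/Kekule forms of the same
#'   structure produce the same fingerprint.
#' @param n_bits size of the folded bit space (default 32768, "32k").
#' @param radius circular neighborhood radius in bonds (default 3, ECFP6).
#' @return an object of class `fp_set`: a named list (one element per input)
#'   of sorted integer on-bit vectors, `NULL` where parsing failed, with
#'   attributes `n_bits` and `radius`.
#' @examples
#' \donttest{
#' fp <- compute_fingerprint(c(a = "c1ccccc1", b = "CCO"))
#' lengths(fp)
#' }
#' @export
compute_fingerprint <- function(smiles, n_bits = 32768L, radius = 3L) {
  stopifnot(is.character(smiles), n_bits >= 2L, radius >= 0L)
  graphs <- parse_mol_graphs(smiles)
  fps <- lapply(graphs, function(g) {
    if (is.null(g)) return(NULL)
    .morgan_bits_cpp(cbind(g$element, g$charge), g$bonds,
                     as.integer(radius), as.integer(n_bits))
  })
  names(fps) <- names(smiles)
  structure(fps, n_bits = as.integer(n_bits), radius = as.integer(radius),
            class = "fp_set")
}

#' @export
print.fp_set <- function(x, ...) {
  cat(sprintf("<fp_set> %d fingerprints, %d bits, radius %d (%d parse failures)\n",
              length(x), attr(x, "n_bits"), attr(x, "radius"),
              sum(vapply(x, is.null, logical(1)))))
  invisible(x)
}

#' @export
`[.fp_set` <- function(x, i) {
  structure(unclass(x)[i], n_bits = attr(x, "n_bits"),
            radius = attr(x, "radius"), class = "fp_set")
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` on on-bit sets. Two empty fingerprints
#' compare as identical (similarity 1), so degenerate structures with no
#' features still satisfy "identical compounds, identical fold". The
#' Tanimoto distance is `1 - tanimoto_similarity(a, b)`.
#'
#' @param a,b sorted integer on-bit vectors (elements of an [fp_set][compute_fingerprint()]).
#' @param n_bits_a,n_bits_b optional bit-space sizes; when both are given they
#'   must agree.
#' @return similarity in `[0, 1]`.
#' @examples
#' tanimoto_similarity(c(1L, 2L, 3L), c(2L, 3L, 4L)) # 0.5
#' @export
tanimoto_similarity <- function(a, b, n_bits_a = NULL, n_bits_b = NULL) {
  if (!is.null(n_bits_a) && !is.null(n_bits_b) && n_bits_a != n_bits_b)
    stop("fingerprints live in different bit spaces (n_bits mismatch)")
  a <- as.integer(a); b <- as.integer(b)
  .tanimoto_pairs_cpp(list(a, b), 1L, 2L)[1L]
}

# Tanimoto similarities for aligned pairs of fingerprints in one fp list.
tanimoto_pairs <- function(fps, i, j) {
  .tanimoto_pairs_cpp(fps, as.integer(i), as.integer(j))
}

# ---------------------------------------------------------------------------
# the molecule container

#' Standardize a compound table and compute fingerprints
#'
#' The entry point of the preparation pipeline: standardizes every structure
#' ([standardize_smiles()]), computes folded circular fingerprints
#' ([compute_fingerprint()]) on the canonical SMILES, and collects parse
#' failures in an error table instead of aborting.
#'
#' @param smiles character vector of raw SMILES, or a data frame with columns
#'   `compound_id` and `smiles` (as read by [read_compounds()]).
#' @param compound_id identifiers aligned with `smiles`; defaults to names of
#'   `smiles` or `mol<i>`.
#' @param n_bits,radius fingerprint parameters, see [compute_fingerprint()].
#' @param fingerprints compute fingerprints (set `FALSE` when only hash-based
#'   splits are needed).
#' @return an object of class `mol_set`: list with `compounds` (data frame
#'   `compound_id`, `raw_smiles`, `canonical_smiles`), `fingerprints`
#'   ([fp_set][compute_fingerprint()] aligned with `compounds`), and `errors`
#'   (data frame `compound_id`, `smiles`, `reason` of skipped records).
#' @examples
#' \donttest{
#' mols <- prepare_molecules(c(a = "CCO", b = "OCC", c = "c1ccccc1"))
#' mols$compounds
#' }
#' @export
prepare_molecules <- function(smiles, compound_id = NULL, n_bits = 32768L,
                              radius = 3L, fingerprints = TRUE) {
  if (is.data.frame(smiles)) {
    stopifnot(all(c("compound_id", "smiles") %in% names(smiles)))
    compound_id <- as.character(smiles$compound_id)
    smiles <- as.character(smiles$smiles)
  }
  if (is.null(compound_id)) {
    compound_id <- if (!is.null(names(smiles))) names(smiles) else
      sprintf("mol%d", seq_along(smiles))
  }
  stopifnot(length(compound_id) == length(smiles))
  if (anyDuplicated(compound_id))
    stop("duplicated compound_id values")

  can <- standardize_smiles(smiles)
  errs <- attr(can, "errors")
  errors <- data.frame(compound_id = compound_id[errs$index],
                       smiles = errs$smiles, reason = errs$reason,
                       row.names = NULL)
  keep <- !is.na(can)
  compounds <- data.frame(compound_id = compound_id[keep],
                          raw_smiles = smiles[keep],
                          canonical_smiles = as.character(can)[keep],
                          row.names = NULL)

  fps <- NULL
  if (fingerprints) {
    # identical canonical SMILES get the identical fingerprint by
    # construction: compute once per distinct structure
    uniq <- unique(compounds$canonical_smiles)
    ufp <- compute_fingerprint(uniq, n_bits = n_bits, radius = radius)
    fps <- unclass(ufp)[match(compounds$canonical_smiles, uniq)]
    names(fps) <- compounds$compound_id
    fail <- vapply(fps, is.null, logical(1))
    if (any(fail)) {
      errors <- rbind(errors, data.frame(
        compound_id = compounds$compound_id[fail],
        smiles = compounds$raw_smiles[fail],
        reason = "fingerprint failure"))
      compounds <- compounds[!fail, , drop = FALSE]
      fps <- fps[!fail]
    }
    fps <- structure(fps, n_bits = as.integer(n_bits),
                     radius = as.integer(radius), class = "fp_set")
  }

  structure(list(compounds = compounds, fingerprints = fps, errors = errors),
            class = "mol_set")
}

#' @export
print.mol_set <- function(x, ...) {
  cat(sprintf("<mol_set> %d compounds (%d skipped)", nrow(x$compounds),
              nrow(x$errors)))
  if (!is.null(x$fingerprints))
    cat(sprintf(", fingerprints: %d bits / radius %d",
                attr(x$fingerprints, "n_bits"), attr(x$fingerprints, "radius")))
  cat("\n")
  if (nrow(x$compounds)) print(head(x$compounds, 4L))
  invisible(x)
}

mol_fps <- function(mols) {
  if (is.null(mols$fingerprints))
    stop("mol_set has no fingerprints; rerun prepare_molecules(fingerprints = TRUE)")
  mols$fingerprints
}
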