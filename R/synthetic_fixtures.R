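# Synthetic molecule libraries and sparse activity tables.
#
# Real QSAR libraries are dominated by chemical series: sets of analogues
# sharing a scaffold core and differing in small substituents, so that
# within-series fingerprint similarity is high and between-series similarity
# low. Two generators emulate the structures the split methods and metrics
# are sensitive to:
#
# * `generate_series_library()` -- distinct drug-like cores (1-4 rings)
#   decorated at two substitution points, plus structurally unrelated
#   singletons: the series/cluster structure the sphere-exclusion and
#   scaffold methods are supposed to capture.
# * `generate_ladder_library()` -- graded analogue ladders: chain molecules
#   derived from a few base sequences by increasing numbers of unit edits,
#   giving a pairwise-similarity continuum that populates every Tanimoto
#   similarity bin (needed to estimate per-bin intra-fold fractions with
#   tight Monte-Carlo error).
#
# All generators are deterministic given their seed, and every generated
# SMILES parses and standardizes.

# Drug-like scaffold cores, 18-26 heavy atoms, with two adjacent substitution
# points each. Cores are large relative to the substituents so that
# within-series Tanimoto distance stays below the sphere-exclusion cutoff
# (0.6) while distinct cores stay above it; ring counts 1-4 exercise both the
# three-ring preference and the closest-to-3 fallback of the scaffold split.
CORE_TEMPLATES <- c(
  # 1 ring system
  "CC(NC(=O)c1ccc(OCC(O)CNC(C)C)cc1)C(C%s)C%s",
  "CC(C)CC(NC(=O)C(N)CC(C)C)C(=O)NCCc1cc(C%s)c(C%s)cn1",
  "CCOC(=O)C(CCN(CC)CC)NC(=O)CNC(=O)C1(C%s)CCC(C%s)CC1",
  "CCN(CC)CCOC(=O)C(O)(CCCC)c1cc(C%s)c(C%s)s1",
  # 2 ring systems / fused bicycles
  "O=C(Nc1ccc(N2CCN(CC(C)O)CC2)cc1)C(CC(C)C)NC(C%s)C%s",
  "COc1ccc2cc(C(C)C(=O)OCCN(C)C)ccc2c1OCC(C%s)C%s",
  "O=C(NCc1ccc2c(c1)OCO2)C(CC(C)CC)NC(=O)NC(C%s)C%s",
  "CC(O)(CNC(=O)c1ccncc1)COc1ccc(Cl)cc1CNC(=O)C(C%s)C%s",
  "CC(C)(C)NCC(O)COc1ccc2[nH]c(=O)ccc2c1CC(C%s)C%s",
  "COC(=O)C1=C(C)NC(C)=C(C(=O)OCC)C1c1cccc(C%s)c1C%s",
  # 3 rings
  "CN(CCOc1ccc(CC2SC(=O)NC2=O)cc1)c1ccc(C%s)c(C%s)n1",
  "CC(C)N(CCCNC(=O)c1ccc2c(c1)oc1ccccc12)CC(O)C(C%s)C%s",
  "CN1CCN(CCCN2c3ccccc3Sc3ccc(C(F)(F)F)cc32)CC1CC(C%s)C%s",
  "O=C(NCCN1CCC(c2ccccc2)CC1)c1ccc(-c2ccc(C%s)cc2C%s)cc1",
  "COc1ccc(C(=O)Nc2ccc(N3CCOCC3)c(NC(=O)c3ccccc3C%s)c2)cc1C%s",
  "CCOC(=O)c1c(C)[nH]c2c1CC(C)(C)CC2=NNC(=O)c1ccc(C%s)cc1C%s",
  "O=C(CN1c2ccccc2CCc2ccccc21)NCCN1CCC(C(C%s)C%s)CC1",
  "c1ccc(-c2cc3c([nH]c4ccc(CN5CCOCC5)cc43)cc2CNC(C%s)C%s)cc1",
  "O=C(NCC1CCN(Cc2ccccc2)CC1)c1cc2cc3ccccc3nc2n1CC(C%s)C%s",
  "O=C1CCC(N2C(=O)c3ccccc3C2=O)C(=O)N1CCCCNC(C%s)C%s",
  "Cc1ccccc1N1CCN(CCCCOc2ccc3c(c2)NC(=O)CC3)CC1C(C%s)C%s",
  "O=c1[nH]c2ccccc2n1CCCN1CCC(NC(=O)c2ccccc2OC)CC1C(C%s)C%s",
  # 4 rings
  "CC12CCC3C(CCC4=CC(=O)CCC43C)C1CCC2OC(=O)CC(C%s)C%s"
)

# Small acyclic substituents: halogens, small alkyl/alkoxy, amine, nitrile,
# amide. All keep the series' representative scaffold unchanged.
SUBSTITUENT_ALPHABET <- c("C", "CC", "F", "Cl", "Br", "O", "OC", "N", "C#N",
                          "C(N)=O")

# Monovalent ring fragments and linker units for singleton molecules:
# singleton = ringA + linker + ringB, giving each singleton a scaffold of its
# own (distinct ring/linker combination).
SINGLETON_RINGS <- c("c1ccccc1", "c1ccncc1", "c1ccsc1", "c1ccoc1",
                     "C1CCCCC1", "C1CCNCC1")
SINGLETON_LINKS <- c("C", "CC", "CO", "CN", "CC(C)", "CCO", "CCN", "CCS")

# Backbone units for ladder chain molecules: each continues the chain at its
# last atom.
CHAIN_UNITS <- c("CC(C)", "CCO", "CCN", "CCS", "CC(F)(F)", "CCC", "CC(Cl)",
                 "CC(C)(C)")

#' Generate a synthetic chemical-series library
#'
#' Builds `n_series` series, each from its own scaffold core template
#' decorated at two substitution points with small substituents, plus
#' `n_singletons` structurally unrelated chain molecules. Within a series
#' Tanimoto similarity is high (shared core); between series and to
#' singletons it is low.
#'
#' @param n_series number of series (at most `length(core_templates)`).
#' @param series_size_range integer range (min, max) of members per series.
#' @param n_singletons number of singleton molecules.
#' @param core_templates character vector of `sprintf` templates with two
#'   `%s` substitution points.
#' @param substituent_alphabet substituent SMILES fragments.
#' @param seed integer RNG seed; the library is deterministic given the seed.
#' @return data frame `compound_id`, `smiles`, `series_id` (singletons carry
#'   their own `X...` series ids).
#' @examples
#' lib <- generate_series_library(n_series = 3, series_size_range = c(4, 4),
#'                                n_singletons = 2, seed = 1)
#' head(lib)
#' @export
generate_series_library <- function(n_series = 20L,
                                    series_size_range = c(25L, 25L),
                                    n_singletons = 100L,
                                    core_templates = CORE_TEMPLATES,
                                    substituent_alphabet = SUBSTITUENT_ALPHABET,
                                    seed = 1L) {
  stopifnot(n_series >= 0L, n_singletons >= 0L,
            length(series_size_range) == 2L,
            series_size_range[1] >= 1L,
            series_size_range[2] >= series_size_range[1])
  if (n_series > length(core_templates))
    stop("n_series exceeds the number of distinct core templates (",
         length(core_templates), ")")
  if (any(!grepl("%s.*%s", core_templates)))
    stop("every core template needs two substitution points")

  with_seed(seed, {
    cores <- sample(core_templates, n_series)
    smiles <- character(0)
    series <- character(0)
    sizes <- seq(series_size_range[1], series_size_range[2])
    for (s in seq_len(n_series)) {
      size <- sizes[sample.int(length(sizes), 1L)]
      combos <- expand.grid(a = substituent_alphabet, b = substituent_alphabet,
                            stringsAsFactors = FALSE)
      if (size > nrow(combos))
        stop("series size exceeds the number of distinct decorations")
      pick <- combos[sample.int(nrow(combos), size), , drop = FALSE]
      smiles <- c(smiles, sprintf(cores[s], pick$a, pick$b))
      series <- c(series, rep(sprintf("S%03d", s), size))
    }
    if (n_singletons > 0L) {
      seen <- character(0)
      sing <- character(0)
      while (length(sing) < n_singletons) {
        smi <- paste0(sample(SINGLETON_RINGS, 1L),
                      paste(sample(SINGLETON_LINKS, sample.int(3L, 1L) + 1L,
                                   replace = TRUE), collapse = ""),
                      sample(SINGLETON_RINGS, 1L))
        if (smi %in% seen) next
        seen <- c(seen, smi)
        sing <- c(sing, smi)
      }
      smiles <- c(smiles, sing)
      series <- c(series, sprintf("X%03d", seq_len(n_singletons)))
    }
    data.frame(compound_id = sprintf("CPD%05d", seq_along(smiles)),
               smiles = smiles, series_id = series, row.names = NULL)
  })
}

# Chain units of the ladder library (2-3 heavy atoms each, 2-valent).
LADDER_UNITS <- c("CC", "CO", "CN", "CS", "CCC", "COC", "CNC", "C(C)C",
                  "CC(F)(F)", "CC(Cl)")

# Ladder families: each family has a unit alphabet (indices into
# LADDER_UNITS) and a sampling weight. Alphabet overlaps are graded so that
# cross-family pair similarities cover the low and middle Tanimoto bins;
# family 7 shares the first third of family 1's base sequence ("common
# ancestry"), feeding the 0.5-0.7 bins.
LADDER_FAMILIES <- list(
  alphabets = list(c(1L, 2L, 3L, 4L, 5L), c(1L, 2L, 3L, 4L, 5L),
                   c(2L, 3L, 4L, 5L, 6L), c(4L, 5L, 6L, 7L, 8L),
                   c(8L, 9L, 10L), c(3L, 4L, 5L, 6L, 7L),
                   c(1L, 2L, 3L, 4L, 5L)),
  weights = c(0.27, 0.27, 0.08, 0.12, 0.12, 0.07, 0.07))

#' Generate a graded analogue-ladder library
#'
#' Chain molecules built as mutated prefixes of a few base unit sequences.
#' Every molecule copies the first `m` units (prefix length drawn with a bias
#' toward long prefixes) of its family's base sequence and mutates 0-2
#' positions. Pairs within a family are graded analogues whose similarity
#' tracks the prefix-length ratio (filling the high Tanimoto bins); pairs
#' across families range from moderately related (overlapping unit alphabets,
#' shared ancestry) to unrelated, filling the middle and low bins. The
#' resulting library populates all 10 similarity bins with substantial
#' mass -- which a plain series library (tight series, unrelated cores) does
#' not -- so per-bin intra-fold fractions can be estimated with tight
#' Monte-Carlo error.
#'
#' Structures are deduplicated during generation; all `n_molecules` SMILES
#' are distinct.
#'
#' @param n_molecules library size.
#' @param seed integer RNG seed.
#' @param min_units,max_units prefix length range (chain units; 2-3 heavy
#'   atoms each).
#' @return data frame `compound_id`, `smiles`, `series_id` (the base family).
#' @export
generate_ladder_library <- function(n_molecules = 10000L, seed = 1L,
                                    min_units = 26L, max_units = 54L) {
  stopifnot(n_molecules >= 1L, min_units >= 2L, max_units > min_units)
  alph <- LADDER_FAMILIES$alphabets
  w <- LADDER_FAMILIES$weights
  nb <- length(alph)
  with_seed(seed, {
    bases <- lapply(seq_len(nb), function(b)
      sample(alph[[b]], max_units, replace = TRUE))
    shared <- seq_len((min_units + max_units) %/% 3L)
    bases[[7L]][shared] <- bases[[1L]][shared]

    seen <- new.env(parent = emptyenv())
    smiles <- character(0)
    family <- integer(0)
    guard <- 0L
    while (length(smiles) < n_molecules && guard < 100L * n_molecules) {
      guard <- guard + 1L
      b <- sample.int(nb, 1L, prob = w)
      m <- round(min_units + (max_units - min_units) * stats::runif(1)^(1 / 3.5))
      u <- bases[[b]][seq_len(m)]
      d <- sample(0:2, 1L, prob = c(0.45, 0.35, 0.20))
      if (d > 0L) {
        pos <- sample.int(m, d)
        u[pos] <- sample(alph[[b]], d, replace = TRUE)
      }
      smi <- paste0("C", paste(LADDER_UNITS[u], collapse = ""), "C")
      if (!is.null(seen[[smi]])) next
      seen[[smi]] <- TRUE
      smiles <- c(smiles, smi)
      family <- c(family, b)
    }
    if (length(smiles) < n_molecules)
      stop("could not generate enough distinct molecules; widen the unit range")
    data.frame(compound_id = sprintf("LAD%05d", seq_along(smiles)),
               smiles = smiles, series_id = sprintf("B%02d", family),
               row.names = NULL)
  })
}

#' Generate a sparse binary activity table
#'
#' Emulates a sparse multi-task activity matrix in which the active label
#' concentrates in few chemical series: per task, a size is drawn
#' log-uniformly from `size_range`, that many compounds are sampled, and the
#' members of `n_active_series` series (drawn among the series present in the
#' task) are labeled active.
#'
#' @param library a library data frame with `compound_id` and `series_id`
#'   (from [generate_series_library()]).
#' @param n_tasks number of tasks.
#' @param size_range numeric range (min, max) of task sizes; capped at the
#'   library size.
#' @param n_active_series number of series whose members are active per task.
#' @param seed integer RNG seed.
#' @return data frame `compound_id`, `task_id`, `label` (sparse triplets, at
#'   most one label per compound/task pair).
#' @export
generate_activity_table <- function(library, n_tasks = 50L,
                                    size_range = c(10, 500),
                                    n_active_series = 2L, seed = 1L) {
  stopifnot(all(c("compound_id", "series_id") %in% names(library)),
            n_tasks >= 1L, length(size_range) == 2L,
            size_range[1] >= 1, size_range[2] >= size_range[1])
  n <- nrow(library)
  if (size_range[2] > n) stop("task size exceeds library size")
  with_seed(seed, {
    out <- vector("list", n_tasks)
    for (t in seq_len(n_tasks)) {
      size <- round(exp(stats::runif(1, log(size_range[1]), log(size_range[2]))))
      size <- max(min(size, n), 1L)
      rows <- sample.int(n, size)
      ser <- library$series_id[rows]
      present <- unique(ser)
      act <- sample(present, min(n_active_series, length(present)))
      out[[t]] <- data.frame(compound_id = library$compound_id[rows],
                             task_id = sprintf("T%04d", t),
                             label = as.integer(ser %in% act))
    }
    do.call(rbind, out)
  })
}
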