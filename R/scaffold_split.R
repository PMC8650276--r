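# Scaffold-network fold split.
#
# Each molecule is decomposed into its scaffold network: the side-chain-pruned
# core ("Murcko") scaffold plus every scaffold reachable by iteratively
# removing one peripheral ring system at a time. Fused, bridged and spiro
# ring systems are treated as indivisible units (never dissected), attachment
# points are not retained, and atoms/bonds are kept concrete (no generic
# abstraction). One representative scaffold per molecule is then selected --
# scaffolds with exactly three rings are preferred, otherwise the ring count
# closest to three -- and its canonical SMILES is hashed to a fold. Acyclic
# molecules have the empty scaffold and therefore all share one fold.

#' Scaffold network of a molecule
#'
#' Enumerates the scaffold network: the Murcko scaffold (all acyclic side
#' chains pruned; atoms double-bonded to retained atoms are kept) and every
#' scaffold obtained by recursively deleting one peripheral ring system,
#' where a ring system (fused, bridged or spiro set of rings) is never
#' dissected and deletions that would disconnect the scaffold are not
#' allowed. Ring counts are smallest-set-of-smallest-rings counts, so a fused
#' bicycle counts as 2 rings even though it is removed as one unit.
#'
#' @param smiles a single (ideally canonical) SMILES string.
#' @return a data frame of `ScaffoldRecord`s with columns `scaffold_smiles`
#'   (canonical; `""` for the empty scaffold of an acyclic molecule),
#'   `ring_count`, `n_linker_bonds` (acyclic bonds within the scaffold) and
#'   `n_ring_heteroatoms`.
#' @examples
#' \donttest{
#' compute_scaffold_set("c1ccc(-c2ccccc2)cc1") # biphenyl + benzene
#' compute_scaffold_set("CCCCCC")              # the empty scaffold
#' }
#' @export
compute_scaffold_set <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  res <- scaffold_sets_batch(smiles)[[1]]
  if (is.null(res)) stop("unparseable SMILES: ", smiles)
  res
}

# Batch scaffold networks: one OpenBabel parse for all molecules and one
# canonicalization call for all scaffold subgraphs. Returns a list of
# data frames (NULL where the molecule failed to parse).
scaffold_sets_batch <- function(smiles) {
  graphs <- parse_mol_graphs(smiles)
  sets <- lapply(graphs, function(g) if (is.null(g)) NULL else scaffold_atom_sets(g))

  # canonicalize all non-empty scaffold subgraphs in one call
  blocks <- list()
  where <- list()
  for (m in seq_along(sets)) {
    s <- sets[[m]]
    if (is.null(s)) next
    for (k in seq_along(s$atom_sets)) {
      atoms <- s$atom_sets[[k]]
      if (length(atoms) == 0L) next
      blocks[[length(blocks) + 1L]] <- graph_to_molfile(graphs[[m]], atoms,
                                                        sprintf("i%d_%d", m, k))
      where[[length(where) + 1L]] <- c(m, k)
    }
  }
  can_map <- list()
  if (length(blocks)) {
    txt <- paste0(paste(unlist(blocks), collapse = "\n"), "\n")
    out <- ChemmineOB::convertFormat("SDF", "CAN", txt)
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      parts <- strsplit(ln, "[ \t]+")[[1]]
      if (length(parts) >= 2L) can_map[[parts[2L]]] <- parts[1L]
    }
  }

  out <- vector("list", length(smiles))
  for (m in seq_along(sets)) {
    s <- sets[[m]]
    if (is.null(s)) next
    smi <- character(length(s$atom_sets))
    for (k in seq_along(s$atom_sets)) {
      if (length(s$atom_sets[[k]]) == 0L) { smi[k] <- ""; next }
      v <- can_map[[sprintf("i%d_%d", m, k)]]
      smi[k] <- if (is.null(v)) NA_character_ else v
    }
    df <- data.frame(scaffold_smiles = smi,
                     ring_count = s$ring_count,
                     n_linker_bonds = s$n_linker_bonds,
                     n_ring_heteroatoms = s$n_ring_heteroatoms,
                     row.names = NULL)
    df <- df[!is.na(df$scaffold_smiles), , drop = FALSE]
    # symmetric molecules can reach the same scaffold via different atom sets
    df <- df[!duplicated(df$scaffold_smiles), , drop = FALSE]
    rownames(df) <- NULL
    out[[m]] <- df
  }
  out
}

# Enumerate scaffold atom subsets of one molecular graph, with per-scaffold
# ring counts and tie-break features. Returns list(atom_sets, ring_count,
# n_linker_bonds, n_ring_heteroatoms); the empty scaffold is an integer(0)
# atom set.
scaffold_atom_sets <- function(g) {
  n <- length(g$element)
  bonds <- g$bonds
  m <- nrow(bonds)
  empty <- list(atom_sets = list(integer(0)), ring_count = 0L,
                n_linker_bonds = 0L, n_ring_heteroatoms = 0L)
  if (n == 0L || m == 0L) return(empty)

  ig <- igraph::make_graph(edges = as.vector(t(bonds[, 1:2, drop = FALSE])),
                           n = n, directed = FALSE)
  bridge_ids <- igraph::bridges(ig)
  ring_edge <- !(seq_len(m) %in% as.integer(bridge_ids))
  if (!any(ring_edge)) return(empty)
  ring_atom <- rep(FALSE, n)
  ring_atom[unique(as.vector(bonds[ring_edge, 1:2]))] <- TRUE

  adj <- vector("list", n)
  for (e in seq_len(m)) {
    i <- bonds[e, 1L]; j <- bonds[e, 2L]
    adj[[i]] <- rbind(adj[[i]], c(j, bonds[e, 3L]))
    adj[[j]] <- rbind(adj[[j]], c(i, bonds[e, 3L]))
  }

  murcko <- function(S) {
    inS <- rep(FALSE, n); inS[S] <- TRUE
    repeat {
      drop <- integer(0)
      for (a in which(inS)) {
        if (ring_atom[a]) next
        deg <- if (is.null(adj[[a]])) 0L else sum(inS[adj[[a]][, 1L]])
        if (deg <= 1L) drop <- c(drop, a)
      }
      if (!length(drop)) break
      inS[drop] <- FALSE
    }
    # re-attach atoms multiple-bonded to the retained core (e.g. exocyclic =O)
    for (a in S) {
      if (inS[a] || is.null(adj[[a]])) next
      nb <- adj[[a]]
      if (any(inS[nb[, 1L]] & nb[, 2L] >= 2L)) inS[a] <- TRUE
    }
    which(inS)
  }

  connected <- function(S) {
    if (length(S) <= 1L) return(TRUE)
    inS <- rep(FALSE, n); inS[S] <- TRUE
    seen <- rep(FALSE, n)
    stack <- S[1L]; seen[S[1L]] <- TRUE
    while (length(stack)) {
      a <- stack[[1L]]; stack <- stack[-1L]
      nb <- adj[[a]]
      if (!is.null(nb)) {
        nxt <- nb[inS[nb[, 1L]] & !seen[nb[, 1L]], 1L]
        seen[nxt] <- TRUE
        stack <- c(stack, nxt)
      }
    }
    all(seen[S])
  }

  # ring systems within S: connected components over ring edges
  ring_systems <- function(S) {
    inS <- rep(FALSE, n); inS[S] <- TRUE
    es <- which(ring_edge & inS[bonds[, 1L]] & inS[bonds[, 2L]])
    if (!length(es)) return(list())
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (e in es) {
      a <- find(bonds[e, 1L]); b <- find(bonds[e, 2L])
      if (a != b) parent[a] <- b
    }
    members <- unique(as.vector(bonds[es, 1:2]))
    split(members, vapply(members, find, integer(1)))
  }

  props <- function(S) {
    inS <- rep(FALSE, n); inS[S] <- TRUE
    es <- which(inS[bonds[, 1L]] & inS[bonds[, 2L]])
    rc <- length(es) - length(S) + 1L # cyclomatic number of a connected scaffold
    list(ring_count = as.integer(rc),
         n_linker_bonds = as.integer(sum(!ring_edge[es])),
         n_ring_heteroatoms = as.integer(sum(ring_atom[S] & g$element[S] != 6L)))
  }

  top <- murcko(seq_len(n))
  key <- function(S) paste(S, collapse = ",")
  seen <- new.env(parent = emptyenv())
  queue <- list(top)
  assign(key(top), TRUE, envir = seen)
  atom_sets <- list()
  ring_count <- integer(0)
  n_linker <- integer(0)
  n_hetero <- integer(0)

  while (length(queue)) {
    S <- queue[[1L]]; queue <- queue[-1L]
    p <- props(S)
    atom_sets[[length(atom_sets) + 1L]] <- S
    ring_count <- c(ring_count, p$ring_count)
    n_linker <- c(n_linker, p$n_linker_bonds)
    n_hetero <- c(n_hetero, p$n_ring_heteroatoms)
    systems <- ring_systems(S)
    if (length(systems) < 2L) next # a lone ring system is never dissected
    for (sys in systems) {
      S2 <- murcko(setdiff(S, sys))
      if (!length(S2) || !connected(S2)) next
      k2 <- key(S2)
      if (!isTRUE(get0(k2, envir = seen))) {
        assign(k2, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <- S2
      }
    }
  }
  list(atom_sets = atom_sets, ring_count = ring_count,
       n_linker_bonds = n_linker, n_ring_heteroatoms = n_hetero)
}

# V2000 molfile text (vector of lines) for an induced subgraph.
graph_to_molfile <- function(g, atoms, title) {
  idx <- match(seq_along(g$element), atoms)
  es <- which(!is.na(idx[g$bonds[, 1L]]) & !is.na(idx[g$bonds[, 2L]]))
  na <- length(atoms); nb <- length(es)
  lines <- c(title, " molsplit", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
             sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     g$symbol[atoms]))
  if (nb) {
    b <- g$bonds[es, , drop = FALSE]
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              idx[b[, 1L]], idx[b[, 2L]], b[, 3L]))
  }
  chg <- which(g$charge[atoms] != 0L)
  while (length(chg)) {
    take <- chg[seq_len(min(8L, length(chg)))]
    chg <- chg[-seq_along(take)]
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(take)),
                             paste0(sprintf("%4d%4d", take, g$charge[atoms][take]),
                                    collapse = "")))
  }
  c(lines, "M  END", "$$$$")
}

#' Select the representative scaffold of a molecule
#'
#' From a scaffold network ([compute_scaffold_set()]): scaffolds with exactly
#' 3 rings are candidates; if none exist, those with ring count closest to 3
#' (counts equidistant from 3 resolve toward the smaller, more generic
#' count). Remaining ties go through a deterministic prioritization cascade:
#' fewer acyclic linker bonds, then more ring heteroatoms, then the
#' lexicographically smallest canonical SMILES.
#'
#' @param scaffolds a non-empty scaffold data frame as returned by
#'   [compute_scaffold_set()].
#' @return the selected single-row scaffold data frame.
#' @export
select_representative_scaffold <- function(scaffolds) {
  if (!is.data.frame(scaffolds) || nrow(scaffolds) == 0L)
    stop("scaffold set must be non-empty (acyclic molecules carry the empty scaffold)")
  d <- abs(scaffolds$ring_count - 3L)
  cand <- scaffolds[d == min(d), , drop = FALSE]
  if (nrow(cand) > 1L)
    cand <- cand[cand$ring_count == min(cand$ring_count), , drop = FALSE]
  if (nrow(cand) > 1L)
    cand <- cand[cand$n_linker_bonds == min(cand$n_linker_bonds), , drop = FALSE]
  if (nrow(cand) > 1L)
    cand <- cand[cand$n_ring_heteroatoms == max(cand$n_ring_heteroatoms), , drop = FALSE]
  if (nrow(cand) > 1L) {
    smi <- cand$scaffold_smiles
    cand <- cand[order(smi)[1L], , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}

#' Scaffold-network fold split
#'
#' Computes each compound's representative scaffold
#' ([select_representative_scaffold()]) and hashes its canonical SMILES to a
#' fold with [hash_to_fold()] under the "SCF:" key namespace. All molecules
#' sharing a representative scaffold share a fold; all acyclic molecules
#' (empty scaffold) share one fold. Fully deterministic and locally
#' computable, hence federated-consistent by construction.
#'
#' @param mols a [mol_set][prepare_molecules()].
#' @param n_folds,secret see [hash_to_fold()].
#' @return a `fold_assignment` (method `"scaffold"`) with attribute
#'   `scaffolds`: data frame `compound_id`, `scaffold_smiles`, `ring_count`,
#'   `fold`.
#' @export
assign_scaffold_folds <- function(mols, n_folds = 5L, secret = "") {
  stopifnot(inherits(mols, "mol_set"))
  can <- mols$compounds$canonical_smiles
  uniq <- unique(can)
  sets <- scaffold_sets_batch(uniq)
  rep_smi <- character(length(uniq))
  rep_rings <- integer(length(uniq))
  for (k in seq_along(uniq)) {
    if (is.null(sets[[k]]) || nrow(sets[[k]]) == 0L)
      stop("scaffold decomposition failed for: ", uniq[k])
    sel <- select_representative_scaffold(sets[[k]])
    rep_smi[k] <- sel$scaffold_smiles
    rep_rings[k] <- sel$ring_count
  }
  i <- match(can, uniq)
  folds <- hash_to_fold(paste0("SCF:", rep_smi[i]), n_folds, secret)
  fa <- new_fold_assignment(mols$compounds$compound_id, folds, n_folds,
                            "scaffold",
                            params = list(secret_fingerprint = secret_fingerprint(secret)))
  attr(fa, "scaffolds") <- data.frame(compound_id = mols$compounds$compound_id,
                                      scaffold_smiles = rep_smi[i],
                                      ring_count = rep_rings[i],
                                      fold = folds, row.names = NULL)
  fa
}
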