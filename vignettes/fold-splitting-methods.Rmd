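---
title: "Whole-compound-domain fold splitting: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-compound-domain fold splitting: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molsplit)
```

## The problem

Cross-validated performance of QSAR models is notoriously optimistic when
folds are drawn at random: compound libraries are dominated by *chemical
series* — sets of close analogues around a shared core — and a random split
places members of the same series on both sides of the train/test boundary.
The model is then rewarded for memorizing series, not for generalizing to new
chemistry (the "series effect", or Kubinyi paradox). The remedy is to split
in the *whole compound domain*: a compound, with all of its measurements
across all assays, belongs to exactly one fold, and entire groups of similar
compounds should move together.

Federated multi-task modelling adds a second constraint: several parties
hold private libraries that may overlap, and an identical structure must
receive the identical fold at every party without the parties exchanging
structures. `molsplit` implements four split methods under these
constraints, the diagnostics to compare them, and synthetic data generators
that make everything testable without proprietary compounds.

## Shared representation

All methods operate on a standardized structure table
(`prepare_molecules()`):

* **Standardization** (`standardize_smiles()`): isotope labels are stripped,
  simple charges neutralized where a neutral form exists (OpenBabel's
  neutralize operation; permanently charged centers such as quaternary
  nitrogen are kept), counter-ions removed by keeping the largest organic
  component, and the parent canonicalized with OpenBabel. This is a minimal
  contract — tautomer canonicalization, stereochemistry normalization and
  sanity filters of full production pipelines are intentionally out of scope
  — but it guarantees the property every split method relies on: salt forms
  and input atom orderings of the same parent map to one canonical SMILES.
  Unparseable records are collected in an error table and never abort a run.
* **Fingerprints** (`compute_fingerprint()`): a folded circular fingerprint
  (Morgan algorithm) with radius 3 (ECFP6-style) folded into 32,768 bits, the
  "32k folded" convention of large-scale multi-task pipelines. The
  implementation hashes per-atom invariants (atomic number, heavy degree,
  formal charge, total bond order) and iteratively rehashes each atom with
  its sorted neighbor identifiers; identifiers from all iterations are folded
  modulo `n_bits`. Because it is computed from the canonical SMILES with
  deterministic hashing, identical compounds always yield identical
  fingerprints on every machine. Bit values are *not* interchangeable with
  any other toolkit's ECFP — no result in this package depends on a specific
  bit vocabulary, only on identity and Tanimoto geometry.
* **Tanimoto similarity**: $T(A,B) = |A \cap B| / |A \cup B|$ on on-bit
  sets; distance is $1 - T$. Two empty fingerprints compare as identical
  ($T = 1$): degenerate featureless structures must still satisfy
  "identical compound, identical fold".

## The four split methods

### Random split by keyed hashing

`hash_to_fold(key, n_folds, secret)` computes SHA-256 over
`secret || 0x00 || key` and reduces the first 8 digest bytes, read as a
big-endian unsigned 64-bit integer, modulo `n_folds`. The single zero byte
separates secret from key unambiguously; modulo bias is negligible for any
practical fold count. `assign_random_folds()` keys on the canonical SMILES,
so the split is uniform, pseudo-random, and bit-for-bit reproducible across
parties, processes and languages — the federated replacement for a shared
RNG. A shared secret restricts reproducibility to the consortium. Folds are
0-based internally; "fold 1..N" displays are a presentation convention.

### Locality-sensitive hashing (LSH)

`select_high_entropy_bits()` picks the `N = 16` fingerprint bits whose
frequency in a reference set is closest to 0.5 — for binary features, the
maximum-entropy criterion stated operationally (no log-entropy computation is
needed; the ordering is identical). Ties break toward lower bit indices.
Compounds are binned by their 16-bit pattern (`compute_bin()`, at most
$2^{16} = 65536$ bins) and each bin key is hashed to a fold under the
`"LSH:"` key namespace. Similar compounds agree on most bits, so series tend
to share bins. Federated use requires a *shared* model built from a public
reference library (`write_lsh_model()`/`read_lsh_model()`); each party then
bins its own compounds locally. The overlap between bits selected from a
public reference and from a private library is a diagnostic, not a
guarantee, and the package reports frequencies so it can be inspected.

### Sphere exclusion clustering

`run_sphere_exclusion()` is the Taylor–Butina / leader–follower procedure: in
a seeded random processing order, each compound joins the nearest existing
cluster center within Tanimoto distance `t_tc = 0.6`, or founds a new
cluster. One nearest-center re-assignment pass follows
(`reassign_to_nearest()`), the analogue of a single k-means assignment step —
exactly one pass, no iteration to convergence. By construction centers are
pairwise farther than `t_tc` apart and every compound lies within `t_tc` of
its (re-assigned) center; both invariants are asserted in the test suite.
`assign_cluster_folds()` draws one fold per cluster from a seeded RNG in
cluster-creation order. Because centers depend on the pooled library, this
method is not locally computable: consistent federated use requires a joint
(cryptographic) execution, and the package implements the centralized
variant with explicit `order_seed`/`fold_seed` so runs are reproducible.
Distance ties go to the earliest-created center; the threshold comparison is
"join when distance ≤ t_tc".

### Scaffold-network binning

`compute_scaffold_set()` decomposes a molecule into its scaffold network:
the side-chain-pruned core scaffold (atoms double-bonded to retained atoms,
e.g. carbonyl oxygens, are kept) plus every scaffold reachable by
iteratively deleting one peripheral ring system, where fused, bridged and
spiro systems are indivisible units and deletions that would disconnect the
scaffold are not allowed. Attachment points and generic-atom abstraction are
both disabled. Ring counts are SSSR (cyclomatic) counts, so a fused bicycle
counts as two rings even though it is never dissected.

`select_representative_scaffold()` prefers scaffolds with exactly **three
rings** (a practical granularity for medicinal chemistry series); if none
exist, the ring count closest to three wins, with the 2-vs-4 tie resolved
toward the *smaller* count — more generic scaffolds merge more of a series
into one fold, which is the method's purpose. Remaining ties pass through a
deterministic cascade: fewer acyclic linker bonds, more ring heteroatoms,
then the lexicographically smallest canonical SMILES. The historical
scaffold-tree rule list is longer and partly subjective; this package fixes
a documented, reproducible subset instead of guessing the original order, so
selections are stable even where they might differ from other
implementations. `assign_scaffold_folds()` hashes the representative
scaffold's canonical SMILES under the `"SCF:"` namespace; all acyclic
molecules carry the empty scaffold and therefore share one fold. The method
is fully deterministic and locally computable, hence federated-consistent by
construction. Its known failure mode is real: ring-size or linker changes
can flip the scaffold while barely moving the fingerprint, so highly similar
pairs *can* land in different folds; the test suite demonstrates the
possibility rather than treating it as a defect.

## Evaluation metrics

* **Intra-fold pair fraction by similarity bin**
  (`sample_pairs()`, `intra_fold_fraction()`): compound pairs are sampled
  uniformly with replacement over unordered distinct-id pairs (self-pairs
  excluded; at the ~10^6 scale sampling, not enumeration, is the only
  practical estimator), binned into ten equidistant Tanimoto bins — the top
  bin closed, `[0.9, 1.0]`, so identical pairs are counted — and the
  fraction of same-fold pairs reported per bin. A uniform random split gives
  `1/n_folds` everywhere; series-preserving methods should rise toward 1 in
  the high bins. Empty bins are `NA`, never 0.
* **Data imbalance** (`task_data_imbalance()`): a task is flagged when any
  fold — including empty folds — holds fewer than five of its compounds
  (strict "below five": exactly five everywhere is not flagged).
* **Label imbalance** (`task_label_imbalance()`): per task, the fraction of
  actives per populated fold; folds with none of the task's compounds have
  no defined active fraction and are excluded, while they do count for the
  below-five flag. The *population* standard deviation across those
  fractions is compared against 0.05 with a strict `>`; the comparison adds
  a relative epsilon (~1e-9) so that a standard deviation of exactly 0.05 —
  representable only approximately in binary floating point — stays
  unflagged. Tasks are aggregated by size bins with lower limits 10, 100,
  1000, 10000, 100000 (`aggregate_imbalance()`), tasks under 10 compounds
  reported separately.

## Synthetic data

Two generators produce text-only, seed-deterministic libraries:

* `generate_series_library()` (default: 20 series × 25 members + 100
  singletons) emulates a series-dominated screening library: each series is
  one drug-like core (18–26 heavy atoms, 1–4 rings, all cores with distinct
  ring systems) decorated at two substitution points with small substituents
  (halogens, small alkyl/alkoxy, amine, nitrile, amide). The cores are large
  relative to the substituents so that *every* within-series Tanimoto
  distance is below the sphere-exclusion cutoff 0.6 and every between-series
  distance above it — the construction the series-capture analyses assume.
  Singletons are ring–linker–ring compounds, each with its own scaffold.
  With 10 substituents at 2 sites, series up to 100 members are possible;
  the 25-member default exercises the generators far from that ceiling.
* `generate_ladder_library()` (default 10,000 molecules) produces graded
  analogue ladders: mutated prefixes of a few base chains built from 2–3
  atom units, with graded alphabet overlaps across families. Its purpose is
  statistical: pairwise similarities cover *all ten* Tanimoto bins with
  substantial mass (every non-identity bin receives at least ~3.5% of sampled pairs),
  so per-bin intra-fold fractions can be estimated with a Monte-Carlo
  standard error near 0.002 from 10^6 pairs. A plain series library cannot
  do this — its similarity distribution is bimodal (within-series high,
  between-series near zero) and the middle bins would hold too few pairs for
  any per-bin assertion to be meaningful.
* `generate_activity_table()` emulates the sparse multi-task activity
  matrix: per task a log-uniform size, uniformly sampled compounds, and all
  actives concentrated in a configurable number of series — the situation
  that makes series-preserving splits label-imbalanced by design.

What the generators do **not** emulate: real substructure frequency
distributions, activity cliffs, assay noise, tautomer-rich chemistry, or
inter-series similarity gradients of real collections. Tests passing on
synthetic data therefore validate the algorithms and their invariants, not
field performance on any particular corporate library.

## Numerical and statistical choices

* All randomness is explicitly seeded (`order_seed`, `fold_seed`, generator
  and pair-sampling seeds); there is no wall-clock seeding anywhere, and the
  sphere method refuses to run without seeds. RNG state of the caller is
  always restored.
* The hash reduction (first 8 bytes, big-endian, modulo) is pinned so that
  any SHA-256 implementation in any language reproduces the folds exactly;
  the package's own SHA-256 is verified against published test vectors and
  externally computed fold constants.
* Test problem sizes: the per-bin random-split check uses 10,000 molecules
  and 10^6 pairs (standard error ≈ 0.0019 in the thinnest bin); the
  series-level analyses use the 600-compound series library with 10^5
  pairs; sphere-exclusion correctness is checked exactly against a
  brute-force reference on 100 instances of up to 50 compounds.
* For the series library, the *lowest-bin* intra-fold fraction of the
  sphere and scaffold methods is reported as the average over 10 replicate
  fold randomizations (fresh `fold_seed`s, fresh hash secrets). A single
  draw allocates only ~20 series-level groups to folds, so its lowest-bin
  fraction carries an irreducible group-level standard error of about 0.02;
  averaging over the method's own randomization estimates the expected
  fraction (the quantity the 1/N_folds baseline refers to) at ~0.006
  standard error. The top-bin assertions hold for every replicate
  individually.
* Scaffold canonicalization round-trips subgraphs through V2000 molfiles and
  OpenBabel canonical SMILES; scaffolds reached via different removal orders
  or symmetric atom sets are deduplicated on the canonical SMILES.

## Known limitations

* Standardization is deliberately minimal; libraries that differ in
  tautomer or stereo conventions should be normalized upstream.
* Fingerprint bits are package-specific (deterministic, but not RDKit's);
  LSH models are therefore only exchangeable between parties running this
  package — which is the federated contract anyway.
* The scaffold prioritization cascade is a documented subset of the
  original scaffold-tree rules; on multi-candidate molecules it may select
  a different (equally deterministic) scaffold than other toolkits.
* Sphere exclusion is O(clusters × compounds) in C++, adequate into the
  10^5 range on one core, but no approximate-neighbor acceleration is
  provided.
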