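// Fingerprint and clustering kernels. Fingerprints are represented
// throughout as strictly increasing integer vectors of on-bit indices
// (0-based) in a folded bit space.
#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

// 64-bit mix (splitmix64 finalizer); deterministic across platforms.
inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ull;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ull;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebull;
  return x ^ (x >> 31);
}

inline uint64_t hash_combine(uint64_t h, uint64_t v) {
  return mix64(h ^ (v + 0x9e3779b97f4a7c15ull + (h << 6) + (h >> 2)));
}

inline double tanimoto_sorted(const int *a, int na, const int *b, int nb) {
  if (na == 0 && nb == 0) return 1.0; // degenerate: two empty fingerprints
  int i = 0, j = 0, inter = 0;
  while (i < na && j < nb) {
    if (a[i] == b[j]) { ++inter; ++i; ++j; }
    else if (a[i] < b[j]) ++i;
    else ++j;
  }
  return double(inter) / double(na + nb - inter);
}

} // namespace

// Folded circular (Morgan-style) fingerprint of one molecule.
// atoms: matrix with columns (atomic number, formal charge); bonds: matrix
// with columns (atom i, atom j, order), 1-based atom indices, kekulized
// orders. Initial atom identifiers hash (Z, heavy degree, charge, sum of
// bond orders); each iteration rehashes an atom id with its sorted
// (bond order, neighbor id) list. Identifiers from iterations 0..radius are
// folded modulo n_bits.
// [[Rcpp::export(name = ".morgan_bits_cpp")]]
IntegerVector morgan_bits_cpp(IntegerMatrix atoms, IntegerMatrix bonds,
                              int radius, int n_bits) {
  const int n = atoms.nrow();
  if (n_bits < 2) stop("n_bits must be >= 2");
  if (n == 0) return IntegerVector(0);

  std::vector<std::vector<std::pair<int, int>>> nbr(n); // (neighbor, order)
  for (int e = 0; e < bonds.nrow(); ++e) {
    int i = bonds(e, 0) - 1, j = bonds(e, 1) - 1, o = bonds(e, 2);
    nbr[i].push_back({j, o});
    nbr[j].push_back({i, o});
  }

  std::vector<uint64_t> id(n), next(n);
  for (int a = 0; a < n; ++a) {
    int sumord = 0;
    for (auto &p : nbr[a]) sumord += p.second;
    uint64_t h = mix64(0x4543465036ull); // domain constant
    h = hash_combine(h, uint64_t(atoms(a, 0)));
    h = hash_combine(h, uint64_t(int64_t(atoms(a, 1)) + 16));
    h = hash_combine(h, uint64_t(nbr[a].size()));
    h = hash_combine(h, uint64_t(sumord));
    id[a] = h;
  }

  std::vector<uint64_t> ids;
  ids.reserve(size_t(n) * (radius + 1));
  for (int a = 0; a < n; ++a) ids.push_back(id[a]);

  std::vector<std::pair<uint64_t, uint64_t>> env;
  for (int r = 1; r <= radius; ++r) {
    for (int a = 0; a < n; ++a) {
      env.clear();
      for (auto &p : nbr[a])
        env.push_back({uint64_t(p.second), id[p.first]});
      std::sort(env.begin(), env.end());
      uint64_t h = mix64(uint64_t(r));
      h = hash_combine(h, id[a]);
      for (auto &e : env) {
        h = hash_combine(h, e.first);
        h = hash_combine(h, e.second);
      }
      next[a] = h;
      ids.push_back(h);
    }
    id.swap(next);
  }

  std::vector<int> bits;
  bits.reserve(ids.size());
  for (uint64_t v : ids) bits.push_back(int(v % uint64_t(n_bits)));
  std::sort(bits.begin(), bits.end());
  bits.erase(std::unique(bits.begin(), bits.end()), bits.end());
  return IntegerVector(bits.begin(), bits.end());
}

// Tanimoto similarity for aligned index pairs (1-based into fps).
// [[Rcpp::export(name = ".tanimoto_pairs_cpp")]]
NumericVector tanimoto_pairs_cpp(List fps, IntegerVector i, IntegerVector j) {
  if (i.size() != j.size()) stop("index vectors must be aligned");
  NumericVector out(i.size());
  for (R_xlen_t k = 0; k < i.size(); ++k) {
    IntegerVector a = fps[i[k] - 1], b = fps[j[k] - 1];
    out[k] = tanimoto_sorted(INTEGER(a), a.size(), INTEGER(b), b.size());
  }
  return out;
}

// Full cross matrix of Tanimoto similarities (rows x, cols y).
// [[Rcpp::export(name = ".tanimoto_cross_cpp")]]
NumericMatrix tanimoto_cross_cpp(List x, List y) {
  NumericMatrix out(x.size(), y.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    IntegerVector a = x[i];
    for (R_xlen_t j = 0; j < y.size(); ++j) {
      IntegerVector b = y[j];
      out(i, j) = tanimoto_sorted(INTEGER(a), a.size(), INTEGER(b), b.size());
    }
  }
  return out;
}

// Sphere exclusion (leader-follower) pass over fps in the given processing
// order (1-based permutation). A compound joins the closest existing center
// when its Tanimoto distance is <= t_tc (ties to the earliest-created
// center), otherwise founds a new cluster. Returns 1-based center indices
// (into fps, creation order) and per-compound cluster assignment.
// [[Rcpp::export(name = ".sphere_exclusion_cpp")]]
List sphere_exclusion_cpp(List fps, IntegerVector order, double t_tc) {
  const R_xlen_t n = fps.size();
  std::vector<int> centers;
  std::vector<int> assign(n, NA_INTEGER);
  for (R_xlen_t k = 0; k < order.size(); ++k) {
    int c = order[k] - 1;
    IntegerVector fc = fps[c];
    double best = 2.0;
    int best_j = -1;
    for (size_t j = 0; j < centers.size(); ++j) {
      IntegerVector ctr = fps[centers[j]];
      double d = 1.0 - tanimoto_sorted(INTEGER(fc), fc.size(),
                                       INTEGER(ctr), ctr.size());
      if (d < best) { best = d; best_j = int(j); } // strict <: earliest wins ties
    }
    if (best_j >= 0 && best <= t_tc) {
      assign[c] = best_j + 1;
    } else {
      centers.push_back(c);
      assign[c] = int(centers.size());
    }
  }
  return List::create(_["centers"] = IntegerVector(centers.begin(), centers.end()) + 1,
                      _["assignment"] = IntegerVector(assign.begin(), assign.end()));
}

// Nearest-center re-assignment: argmin Tanimoto distance over centers,
// ties to the lowest-index (earliest-created) center.
// [[Rcpp::export(name = ".nearest_center_cpp")]]
List nearest_center_cpp(List fps, List center_fps) {
  const R_xlen_t n = fps.size(), m = center_fps.size();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    IntegerVector a = fps[i];
    double best = 2.0;
    int best_j = 0;
    for (R_xlen_t j = 0; j < m; ++j) {
      IntegerVector b = center_fps[j];
      double d = 1.0 - tanimoto_sorted(INTEGER(a), a.size(), INTEGER(b), b.size());
      if (d < best) { best = d; best_j = int(j) + 1; }
    }
    idx[i] = best_j;
    dist[i] = best;
  }
  return List::create(_["cluster"] = idx, _["distance"] = dist);
}
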