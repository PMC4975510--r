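#include <Rcpp.h>
#include <random>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Greedy two-phase (Louvain-style) maximisation of the set-partition quality
//   Q(P) = sum_{c} sum_{i,j in c} B_ij
// for a symmetric matrix B.  With B the symmetrised time-dependent
// autocovariance of the teleported diffusion this maximises Markov Stability;
// with B a modularity matrix it reduces to ordinary modularity maximisation.
//
// Conventions: node visit order is shuffled once per level from the seeded
// RNG; a node moves only on a strictly positive gain (ties keep the current
// community), so the algorithm is deterministic given the seed.

static const double GAIN_EPS = 1e-12;

// one level of local moves + aggregation; returns assignment into communities
static std::vector<int> local_moves(const std::vector<double>& B, int n,
                                    std::mt19937& rng, bool& improved) {
  std::vector<int> comm(n);
  for (int i = 0; i < n; ++i) comm[i] = i;
  int n_comm = n;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);

  std::vector<double> w2c(n, 0.0); // accumulated weight from node i to each community
  improved = false;
  bool moved = true;
  int pass = 0;
  while (moved && pass < 200) {
    moved = false;
    ++pass;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      // weights from i to every community (excluding self weight B_ii,
      // which is invariant under moves)
      std::fill(w2c.begin(), w2c.begin() + n_comm, 0.0);
      const double* Bi = &B[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        w2c[comm[j]] += Bi[j];
      }
      int ci = comm[i];
      double base = w2c[ci];
      double best_gain = 0.0;
      int best_c = ci;
      for (int c = 0; c < n_comm; ++c) {
        if (c == ci) continue;
        // factor 2 from symmetry of B; constant across candidates, kept for clarity
        double gain = 2.0 * (w2c[c] - base);
        if (gain > best_gain + GAIN_EPS) {
          best_gain = gain;
          best_c = c;
        }
      }
      if (best_c != ci) {
        comm[i] = best_c;
        moved = true;
        improved = true;
      }
    }
  }

  // relabel contiguous
  std::vector<int> map(n_comm, -1);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = k++;
    comm[i] = map[comm[i]];
  }
  return comm;
}

// [[Rcpp::export(name = ".louvain_cpp")]]
List louvain_cpp(NumericMatrix Bmat, int seed) {
  int n0 = Bmat.nrow();
  std::mt19937 rng((unsigned int)seed);

  std::vector<double> B((size_t)n0 * n0);
  for (int j = 0; j < n0; ++j)
    for (int i = 0; i < n0; ++i)
      B[(size_t)i * n0 + j] = Bmat(i, j);

  std::vector<int> assign(n0);
  for (int i = 0; i < n0; ++i) assign[i] = i;

  int n = n0;
  bool improved = true;
  while (improved && n > 1) {
    std::vector<int> comm = local_moves(B, n, rng, improved);
    int m = 0;
    for (int i = 0; i < n; ++i) m = std::max(m, comm[i] + 1);
    if (!improved && m == n) break;
    // compose with current assignment
    for (int i = 0; i < n0; ++i) assign[i] = comm[assign[i]];
    if (m == n) break;
    // aggregate B into community-level matrix
    std::vector<double> Bn((size_t)m * m, 0.0);
    for (int i = 0; i < n; ++i) {
      const double* Bi = &B[(size_t)i * n];
      int ci = comm[i];
      for (int j = 0; j < n; ++j)
        Bn[(size_t)ci * m + comm[j]] += Bi[j];
    }
    B.swap(Bn);
    n = m;
  }

  // quality of final assignment on the original matrix
  int m = 0;
  for (int i = 0; i < n0; ++i) m = std::max(m, assign[i] + 1);
  // B has been aggregated to community level, so Q = trace of the aggregate
  double q = 0.0;
  for (int i = 0; i < n; ++i) q += B[(size_t)i * n + i];

  IntegerVector out(n0);
  for (int i = 0; i < n0; ++i) out[i] = assign[i] + 1;
  return List::create(_["assignment"] = out, _["quality"] = q,
                      _["n_communities"] = m);
}

// normalised variation of information between two partitions (natural log,
// normalised by log n so the value lies in [0, 1])
// [[Rcpp::export(name = ".vi_cpp")]]
double vi_cpp(IntegerVector a, IntegerVector b, bool normalise = true) {
  int n = a.size();
  if (n != b.size()) stop("partitions have different lengths");
  if (n <= 1) return 0.0;
  std::unordered_map<long long, int> joint;
  std::unordered_map<int, int> ca, cb;
  for (int i = 0; i < n; ++i) {
    ca[a[i]]++;
    cb[b[i]]++;
    joint[(long long)a[i] * 1000003LL + b[i]]++;
  }
  double Ha = 0.0, Hb = 0.0, Hab = 0.0;
  for (auto& kv : ca) { double p = (double)kv.second / n; Ha -= p * std::log(p); }
  for (auto& kv : cb) { double p = (double)kv.second / n; Hb -= p * std::log(p); }
  for (auto& kv : joint) { double p = (double)kv.second / n; Hab -= p * std::log(p); }
  double vi = 2.0 * Hab - Ha - Hb;
  if (vi < 0) vi = 0; // guard numerical noise
  if (normalise) vi /= std::log((double)n);
  return vi;
}

// mean pairwise normalised VI over an ensemble (list of integer vectors);
// equals the ordered-pair average since VI is symmetric
// [[Rcpp::export(name = ".ensemble_vi_cpp")]]
double ensemble_vi_cpp(List ensemble) {
  int l = ensemble.size();
  if (l < 2) return 0.0;
  double s = 0.0;
  int np = 0;
  for (int i = 0; i < l; ++i) {
    IntegerVector pi = ensemble[i];
    for (int j = i + 1; j < l; ++j) {
      IntegerVector pj = ensemble[j];
      s += vi_cpp(pi, pj, true);
      ++np;
    }
  }
  return s / np;
}
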