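#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Nucleotide codes: 0 = A, 1 = C, 2 = G, 3 = U.
// Pair energies are additive per base pair; no stacking or loop terms.
static inline double pair_energy(int a, int b, double e_gc, double e_au,
                                 double e_gu) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return e_gc;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return e_au;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return e_gu;
  return NA_REAL;
}

// Minimum free energy over all nested structures with hairpin loops of at
// least min_loop unpaired bases. Deterministic traceback: at each interval,
// pairing the left end is preferred over leaving it unpaired, and the
// smallest partner index wins among co-optimal pairings.
// [[Rcpp::export]]
List fold_mfe_cpp(IntegerVector codes, double e_gc, double e_au, double e_gu,
                  int min_loop) {
  const int n = codes.size();
  const double eps = 1e-9;
  IntegerVector partner(n, 0);
  if (n == 0) return List::create(_["mfe"] = 0.0, _["partner"] = partner);

  std::vector<double> E((size_t)n * n, 0.0);
  auto Eat = [&](int i, int j) -> double {
    return (i > j) ? 0.0 : E[(size_t)i * n + j];
  };

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = Eat(i + 1, j);
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double q = pair_energy(codes[i], codes[k], e_gc, e_au, e_gu);
        if (ISNA(q)) continue;
        double cand = q + Eat(i + 1, k - 1) + Eat(k + 1, j);
        if (cand < best) best = cand;
      }
      E[(size_t)i * n + j] = best;
    }
  }

  // traceback
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    double target = Eat(i, j);
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      double q = pair_energy(codes[i], codes[k], e_gc, e_au, e_gu);
      if (ISNA(q)) continue;
      double cand = q + Eat(i + 1, k - 1) + Eat(k + 1, j);
      if (cand <= target + eps) {
        partner[i] = k + 1;  // 1-based
        partner[k] = i + 1;
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }

  return List::create(_["mfe"] = Eat(0, n - 1), _["partner"] = partner);
}

// Partition function Z = sum over all legal nested structures of
// exp(-E/RT), with inside-outside base-pair probabilities. The grammar
// decomposes each interval on the leftmost position (unpaired, or paired
// with some k), so every structure is counted exactly once.
// Plain double precision suffices for hairpin-scale inputs; overflow is
// detected and reported rather than silently propagated.
// [[Rcpp::export]]
List partition_function_cpp(IntegerVector codes, double e_gc, double e_au,
                            double e_gu, int min_loop, double rt) {
  const int n = codes.size();
  NumericMatrix bp_probs(n, n);
  if (n == 0)
    return List::create(_["z"] = 1.0, _["bp_probs"] = bp_probs);

  std::vector<double> Z((size_t)n * n, 1.0);
  auto Zat = [&](int i, int j) -> double {
    return (i > j) ? 1.0 : Z[(size_t)i * n + j];
  };
  auto boltz = [&](int i, int k) -> double {
    double q = pair_energy(codes[i], codes[k], e_gc, e_au, e_gu);
    return ISNA(q) ? 0.0 : std::exp(-q / rt);
  };

  // inside
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double z = Zat(i + 1, j);
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double w = boltz(i, k);
        if (w > 0.0) z += w * Zat(i + 1, k - 1) * Zat(k + 1, j);
      }
      if (!R_finite(z))
        stop("partition function overflow: sequence too long for the "
             "double-precision engine");
      Z[(size_t)i * n + j] = z;
    }
  }
  double z_total = Zat(0, n - 1);

  // outside
  std::vector<double> O((size_t)n * n, 0.0);
  O[(size_t)0 * n + (n - 1)] = 1.0;
  for (int len = n; len >= min_loop + 2; --len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double o = O[(size_t)i * n + j];
      if (o == 0.0) continue;
      if (i + 1 <= j) O[(size_t)(i + 1) * n + j] += o;
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double w = boltz(i, k);
        if (w == 0.0) continue;
        double zin = Zat(i + 1, k - 1);
        double zout = Zat(k + 1, j);
        bp_probs(i, k) += o * w * zin * zout;
        if (i + 1 <= k - 1) O[(size_t)(i + 1) * n + (k - 1)] += o * w * zout;
        if (k + 1 <= j) O[(size_t)(k + 1) * n + j] += o * w * zin;
      }
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = i + 1; k < n; ++k) bp_probs(i, k) /= z_total;

  return List::create(_["z"] = z_total, _["bp_probs"] = bp_probs);
}
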