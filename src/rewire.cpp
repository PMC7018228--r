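#include <Rcpp.h>
#include <vector>
#include <random>
#include <unordered_set>
using namespace Rcpp;

static inline long long ekey(int a, int b, int n) {
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return (long long)lo * n + hi;
}

// Degree-preserving double-edge swaps (a-b, c-d) -> (a-c, b-d) on four
// distinct nodes, rejecting self-loops and duplicate edges. When
// `cost_constrained`, a swap is additionally accepted only if
// |(d_ab + d_cd) - (d_ac + d_bd)| < eps_D (strict), with eps_D = eps * D
// computed once on the input graph. Runs until `target_swaps` acceptances
// or `max_attempts` attempts.
// [[Rcpp::export]]
List rewire_cpp(IntegerMatrix edges0, int n, double target_swaps,
                double max_attempts, bool cost_constrained,
                NumericMatrix dist, double eps_D, bool keep_log, int seed) {
  int L = edges0.nrow();
  std::vector<int> u(L), v(L);
  std::unordered_set<long long> eset;
  eset.reserve(L * 2);
  for (int e = 0; e < L; ++e) {
    u[e] = edges0(e, 0);
    v[e] = edges0(e, 1);
    eset.insert(ekey(u[e], v[e], n));
  }
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_int_distribution<int> pick(0, L - 1);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  double attempts = 0, accepted = 0;
  std::vector<int> log_a, log_b, log_c, log_d;

  while (accepted < target_swaps && attempts < max_attempts && L >= 2) {
    ++attempts;
    int e1 = pick(rng), e2 = pick(rng);
    if (e1 == e2) continue;
    int a = u[e1], b = v[e1], c = u[e2], d = v[e2];
    if (unif(rng) < 0.5) std::swap(c, d); // orientation of the pairing
    if (a == c || a == d || b == c || b == d) continue; // need 4 distinct
    long long k1 = ekey(a, c, n), k2 = ekey(b, d, n);
    if (eset.count(k1) || eset.count(k2)) continue;
    if (cost_constrained) {
      double delta = (dist(a, b) + dist(c, d)) - (dist(a, c) + dist(b, d));
      if (!(std::fabs(delta) < eps_D)) continue;
    }
    eset.erase(ekey(a, b, n));
    eset.erase(ekey(c, d, n));
    eset.insert(k1);
    eset.insert(k2);
    u[e1] = a; v[e1] = c;
    u[e2] = b; v[e2] = d;
    ++accepted;
    if (keep_log) {
      log_a.push_back(a); log_b.push_back(b);
      log_c.push_back(c); log_d.push_back(d);
    }
  }
  IntegerMatrix out(L, 2);
  for (int e = 0; e < L; ++e) {
    out(e, 0) = u[e];
    out(e, 1) = v[e];
  }
  List res = List::create(Named("edges") = out,
                          Named("attempts") = attempts,
                          Named("accepted") = accepted);
  if (keep_log) {
    IntegerMatrix lg(log_a.size(), 4);
    for (size_t k = 0; k < log_a.size(); ++k) {
      lg(k, 0) = log_a[k]; lg(k, 1) = log_b[k];
      lg(k, 2) = log_c[k]; lg(k, 3) = log_d[k];
    }
    res["swap_log"] = lg;
  }
  return res;
}
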