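#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Greedy next hop: the neighbor of `cur` closest to `tgt` under `dist`,
// ties broken by the smallest lexicographic rank.
static int next_hop(const std::vector<std::vector<int> > &adj,
                    const NumericMatrix &dist, const IntegerVector &rank,
                    int cur, int tgt) {
  const std::vector<int> &nb = adj[cur];
  int best = -1;
  double bd = 0.0;
  for (size_t k = 0; k < nb.size(); ++k) {
    int v = nb[k];
    double d = dist(v, tgt);
    if (best < 0 || d < bd || (d == bd && rank[v] < rank[best])) {
      best = v;
      bd = d;
    }
  }
  return best;
}

static std::vector<std::vector<int> > as_adj(const List &adj_list) {
  int n = adj_list.size();
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj_list[i];
    adj[i] = std::vector<int>(nb.begin(), nb.end());
  }
  return adj;
}

// [[Rcpp::export]]
List greedy_route_cpp(List adj_list, NumericMatrix dist, IntegerVector rank,
                      int source, int target, int max_hops) {
  std::vector<std::vector<int> > adj = as_adj(adj_list);
  int n = adj.size();
  std::vector<bool> visited(n, false);
  std::vector<int> path;
  path.push_back(source);
  visited[source] = true;
  bool success = (source == target);
  double glen = 0.0;
  int cur = source;
  while (!success) {
    int nxt = next_hop(adj, dist, rank, cur, target);
    if (nxt < 0) break; // dead end: no neighbors
    glen += dist(cur, nxt);
    path.push_back(nxt);
    if (nxt == target) {
      success = true;
      break;
    }
    if (visited[nxt]) break; // loop detected: failure
    visited[nxt] = true;
    cur = nxt;
    if ((int)path.size() - 1 >= max_hops) break; // hop-cap backstop
  }
  return List::create(
      Named("success") = success,
      Named("path") = IntegerVector(path.begin(), path.end()),
      Named("geometric_length") = glen);
}

// Full navigability sweep over every ordered intra-component pair.
// For each source: BFS hop counts plus, over the BFS level DAG, the minimal
// geometric length among hop-minimal paths (layered relaxation); then the
// greedy protocol towards every target in the same component.
// [[Rcpp::export]]
List navigability_cpp(List route_adj_list, List undirected_adj_list,
                      NumericMatrix dist, IntegerVector rank,
                      IntegerVector comp) {
  std::vector<std::vector<int> > radj = as_adj(route_adj_list);
  std::vector<std::vector<int> > uadj = as_adj(undirected_adj_list);
  int n = radj.size();

  long pair_count = 0, successes = 0;
  std::vector<double> tstretch, gstretch;
  IntegerVector out_succ(n), out_tot(n), in_succ(n), in_tot(n);

  std::vector<int> hop(n), order;
  std::vector<double> geo(n);
  std::vector<int> stamp(n, -1);
  order.reserve(n);

  for (int s = 0; s < n; ++s) {
    // BFS from s on the undirected graph
    std::fill(hop.begin(), hop.end(), -1);
    order.clear();
    hop[s] = 0;
    geo[s] = 0.0;
    order.push_back(s);
    for (size_t qi = 0; qi < order.size(); ++qi) {
      int u = order[qi];
      for (size_t k = 0; k < uadj[u].size(); ++k) {
        int v = uadj[u][k];
        if (hop[v] < 0) {
          hop[v] = hop[u] + 1;
          order.push_back(v);
        }
      }
    }
    // layered relaxation: minimal geometric length over hop-minimal paths
    for (size_t qi = 1; qi < order.size(); ++qi) {
      int v = order[qi];
      double best = R_PosInf;
      for (size_t k = 0; k < uadj[v].size(); ++k) {
        int u = uadj[v][k];
        if (hop[u] == hop[v] - 1) {
          double cand = geo[u] + dist(u, v);
          if (cand < best) best = cand;
        }
      }
      geo[v] = best;
    }
    // greedy routes to all reachable targets in the same component
    for (int t = 0; t < n; ++t) {
      if (t == s || comp[t] != comp[s]) continue;
      ++pair_count;
      ++out_tot[s];
      ++in_tot[t];
      // greedy walk; stamp == 1 marks nodes visited for this pair
      int cur = s;
      bool success = false;
      double glen = 0.0;
      int hops = 0;
      std::vector<int> touched;
      touched.push_back(s);
      stamp[s] = 1;
      while (true) {
        int nxt = next_hop(radj, dist, rank, cur, t);
        if (nxt < 0) break;
        glen += dist(cur, nxt);
        ++hops;
        if (nxt == t) {
          success = true;
          break;
        }
        if (stamp[nxt] == 1) break;
        stamp[nxt] = 1;
        touched.push_back(nxt);
        cur = nxt;
        if (hops >= n) break;
      }
      for (size_t k = 0; k < touched.size(); ++k) stamp[touched[k]] = -1;
      if (success) {
        ++successes;
        ++out_succ[s];
        ++in_succ[t];
        tstretch.push_back((double)hops / (double)hop[t]);
        double denom = geo[t];
        gstretch.push_back(denom > 0.0 ? glen / denom
                                       : (glen == 0.0 ? 1.0 : R_PosInf));
      }
    }
  }
  return List::create(
      Named("pair_count") = (double)pair_count,
      Named("successes") = (double)successes,
      Named("topological_stretch") = NumericVector(tstretch.begin(), tstretch.end()),
      Named("geometric_stretch") = NumericVector(gstretch.begin(), gstretch.end()),
      Named("out_succ") = out_succ, Named("out_tot") = out_tot,
      Named("in_succ") = in_succ, Named("in_tot") = in_tot);
}
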