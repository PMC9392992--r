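// Exact heterogeneous-fleet CVRP by dynamic programming.
//
// Two nested DPs over customer subsets:
//   1. Held-Karp: optimal open path depot -> ... -> j for every (subset, j),
//      giving the optimal closed-tour length per subset.
//   2. Set partition: optimal split of the customer set into feasible tours,
//      each tour priced with the cheapest vehicle type whose range and
//      capacity admit it.
// Exact for the exact-mode ceiling (n <= 15); memory ~ O(2^n * n).

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List cvrp_exact_dp(NumericMatrix d, IntegerVector nodes, NumericVector q,
                   NumericVector type_cost, NumericVector type_cap,
                   NumericVector type_range) {
  const int n = nodes.size();          // customers
  const int K = type_cost.size();      // vehicle types
  if (n < 1) stop("no customers to route");
  if (n > 20) stop("exact DP limited to 20 customers");
  const uint32_t NS = 1u << n;

  // distances: dep[i] = depot->i, dd[i][j] between customers (0-based here)
  std::vector<double> dep(n);
  std::vector<std::vector<double>> dd(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i) {
    dep[i] = d(0, nodes[i]);
    for (int j = 0; j < n; ++j) dd[i][j] = d(nodes[i], nodes[j]);
  }

  // Held-Karp open paths
  std::vector<std::vector<double>> path(NS, std::vector<double>(n, INF));
  std::vector<std::vector<int>> prev(NS, std::vector<int>(n, -1));
  for (int i = 0; i < n; ++i) path[1u << i][i] = dep[i];
  for (uint32_t S = 1; S < NS; ++S) {
    for (int j = 0; j < n; ++j) {
      if (!(S & (1u << j))) continue;
      double pj = path[S][j];
      if (pj == INF) continue;
      for (int k = 0; k < n; ++k) {
        if (S & (1u << k)) continue;
        uint32_t S2 = S | (1u << k);
        double cand = pj + dd[j][k];
        if (cand < path[S2][k] - 1e-12) {
          path[S2][k] = cand;
          prev[S2][k] = j;
        }
      }
    }
  }

  // optimal tour length, load and cheapest feasible type per subset
  std::vector<double> tourlen(NS, INF), load(NS, 0.0), rcost(NS, INF);
  std::vector<int> last(NS, -1), rtype(NS, -1);
  for (uint32_t S = 1; S < NS; ++S) {
    double best = INF; int bj = -1;
    for (int j = 0; j < n; ++j) {
      if (!(S & (1u << j))) continue;
      if (path[S][j] == INF) continue;
      double c = path[S][j] + dep[j];
      if (c < best - 1e-12) { best = c; bj = j; }
    }
    tourlen[S] = best; last[S] = bj;
    double ld = 0;
    for (int i = 0; i < n; ++i) if (S & (1u << i)) ld += q[i];
    load[S] = ld;
    double bc = INF; int bt = -1;
    for (int k = 0; k < K; ++k) {
      if (ld <= type_cap[k] + 1e-9 && best <= type_range[k] + 1e-9) {
        double c = type_cost[k] * best;
        if (c < bc - 1e-12) { bc = c; bt = k; }
      }
    }
    rcost[S] = bc; rtype[S] = bt;
  }

  // single-customer feasibility check gives the infeasibility report
  for (int i = 0; i < n; ++i) {
    if (rcost[1u << i] == INF) {
      return List::create(_["feasible"] = false,
                          _["infeasible_customer"] = nodes[i]);
    }
  }

  // set-partition DP; fix the lowest unrouted customer into the new tour so
  // each partition is enumerated once
  std::vector<double> best(NS, INF);
  std::vector<uint32_t> choice(NS, 0);
  best[0] = 0.0;
  for (uint32_t S = 1; S < NS; ++S) {
    uint32_t low = S & (~S + 1u);
    // iterate over submasks of S containing `low`
    for (uint32_t T = S; T; T = (T - 1) & S) {
      if (!(T & low)) continue;
      if (rcost[T] == INF || best[S ^ T] == INF) continue;
      double c = rcost[T] + best[S ^ T];
      if (c < best[S] - 1e-12) { best[S] = c; choice[S] = T; }
    }
  }

  uint32_t FULL = NS - 1;
  if (best[FULL] == INF) {
    return List::create(_["feasible"] = false,
                        _["infeasible_customer"] = NA_INTEGER);
  }

  // reconstruct
  List routes; IntegerVector types; NumericVector lengths;
  uint32_t S = FULL;
  while (S) {
    uint32_t T = choice[S];
    std::vector<int> stops;
    int j = last[T]; uint32_t R = T;
    while (j >= 0) {
      stops.push_back(nodes[j]);
      int pj = prev[R][j];
      R ^= (1u << j);
      j = pj;
    }
    std::reverse(stops.begin(), stops.end());
    routes.push_back(wrap(stops));
    types.push_back(rtype[T] + 1);   // 1-based type index
    lengths.push_back(tourlen[T]);
    S ^= T;
  }
  return List::create(_["feasible"] = true, _["routes"] = routes,
                      _["types"] = types, _["lengths"] = lengths,
                      _["objective"] = best[FULL]);
}
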