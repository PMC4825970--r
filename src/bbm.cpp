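#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler over ancestral per-area presence bits on a rooted bifurcating
// tree. Each area evolves as an independent 2-state chain with stationary
// presence frequency pi[a] and rate mu[a]; transition probability over a
// branch of duration t is P(i -> j) = pi_j + (delta_ij - pi_j) * exp(-mu t).
// One generation = one full sweep over the internal nodes in random order.
// root_mode: 0 = stationary prior on the root state, 1 = root fixed to
// all-present, 2 = root fixed to custom_bits.
//
// Returns per-internal-node per-area posterior mean presence and the count of
// each sampled root bit pattern (index = bitmask over areas).
// [[Rcpp::export]]
List bbm_gibbs_cpp(IntegerVector parent, IntegerVector child_left,
                   IntegerVector child_right, NumericVector edge_time,
                   int n_tip, IntegerMatrix tip_states,
                   NumericVector pi, NumericVector mu,
                   int n_sweeps, int n_burnin,
                   int root_mode, IntegerVector custom_bits) {
  const int n_area = pi.size();
  const int n_node = parent.size();          // 1-based ape numbering, size n
  const int root = n_tip + 1;
  const int n_internal = n_node - n_tip;

  // current states, 1-based node index
  std::vector<std::vector<int>> x(n_node + 1, std::vector<int>(n_area, 0));
  for (int t = 1; t <= n_tip; ++t)
    for (int a = 0; a < n_area; ++a) x[t][a] = tip_states(t - 1, a);

  // initialize internal states
  for (int v = n_tip + 1; v <= n_node; ++v)
    for (int a = 0; a < n_area; ++a)
      x[v][a] = (unif_rand() < pi[a]) ? 1 : 0;
  if (root_mode == 1)
    for (int a = 0; a < n_area; ++a) x[root][a] = 1;
  if (root_mode == 2)
    for (int a = 0; a < n_area; ++a) x[root][a] = custom_bits[a];

  // per-edge decay exp(-mu t) cached per node per area
  std::vector<std::vector<double>> decay(n_node + 1, std::vector<double>(n_area, 1.0));
  for (int v = 1; v <= n_node; ++v) {
    if (v == root) continue;
    for (int a = 0; a < n_area; ++a)
      decay[v][a] = std::exp(-mu[a] * edge_time[v - 1]);
  }

  NumericMatrix sums(n_internal, n_area);
  std::vector<double> root_counts(1 << n_area, 0.0);
  std::vector<int> order(n_internal);
  for (int i = 0; i < n_internal; ++i) order[i] = n_tip + 1 + i;

  auto ptrans = [&](int from, int to, int node, int a) -> double {
    // transition prob along the branch leading to `node`
    double p1 = pi[a] + ((from == 1 ? 1.0 : 0.0) - pi[a]) * decay[node][a];
    return to == 1 ? p1 : 1.0 - p1;
  };

  int n_kept = 0;
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    // Fisher-Yates shuffle of update order
    for (int i = n_internal - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int oi = 0; oi < n_internal; ++oi) {
      int v = order[oi];
      bool is_root = (v == root);
      if (is_root && root_mode != 0) continue;  // fixed root state
      int cl = child_left[v - 1], cr = child_right[v - 1];
      for (int a = 0; a < n_area; ++a) {
        double w1, w0;
        if (is_root) { w1 = pi[a]; w0 = 1.0 - pi[a]; }
        else {
          int xp = x[parent[v - 1]][a];
          w1 = ptrans(xp, 1, v, a);
          w0 = ptrans(xp, 0, v, a);
        }
        w1 *= ptrans(1, x[cl][a], cl, a) * ptrans(1, x[cr][a], cr, a);
        w0 *= ptrans(0, x[cl][a], cl, a) * ptrans(0, x[cr][a], cr, a);
        double z = w1 + w0;
        double p1 = (z > 0) ? w1 / z : 0.5;
        x[v][a] = (unif_rand() < p1) ? 1 : 0;
      }
    }
    if (sweep >= n_burnin) {
      ++n_kept;
      for (int v = n_tip + 1; v <= n_node; ++v)
        for (int a = 0; a < n_area; ++a)
          sums(v - n_tip - 1, a) += x[v][a];
      int rmask = 0;
      for (int a = 0; a < n_area; ++a)
        if (x[root][a]) rmask |= (1 << a);
      root_counts[rmask] += 1.0;
    }
  }
  for (int i = 0; i < n_internal; ++i)
    for (int a = 0; a < n_area; ++a) sums(i, a) /= n_kept;
  return List::create(_["marginals"] = sums,
                      _["root_counts"] = NumericVector(root_counts.begin(),
                                                       root_counts.end()),
                      _["n_kept"] = n_kept);
}
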