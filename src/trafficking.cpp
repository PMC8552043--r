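// Sankoff minimum-transition ancestral state reconstruction (unit costs)
// and the within-tree label permutation engine for the trafficking test.
//
// Trees arrive as postorder edge matrices (0-based node ids, each child's
// subtree edges before the edge to its parent). Node states: 0..S-1 for
// observed (constrained) nodes, -1 for unconstrained nodes (internal nodes
// and the germline root). Ties among minimum-cost states are resolved
// uniformly at random (R's RNG), and transition-type counts are averaged
// over R independent resolutions.

#include <Rcpp.h>
using namespace Rcpp;

static const double BIG = 1e18;

// Up-pass; fills cost (nNodes x S, row-major) and returns the root index.
static int sankoff_up(const IntegerMatrix& edge, int nNodes,
                      const std::vector<int>& state, int S,
                      std::vector<double>& cost) {
  std::fill(cost.begin(), cost.end(), 0.0);
  std::vector<bool> isChild(nNodes, false);
  for (int v = 0; v < nNodes; ++v)
    if (state[v] >= 0)
      for (int s = 0; s < S; ++s)
        cost[(size_t)v * S + s] = (s == state[v]) ? 0.0 : BIG;
  for (int e = 0; e < edge.nrow(); ++e) {
    int p = edge(e, 0), c = edge(e, 1);
    isChild[c] = true;
    double cmin = BIG;
    for (int s = 0; s < S; ++s)
      cmin = std::min(cmin, cost[(size_t)c * S + s]);
    for (int s = 0; s < S; ++s) {
      double best = std::min(cost[(size_t)c * S + s], cmin + 1.0);
      cost[(size_t)p * S + s] += best;
    }
  }
  for (int v = 0; v < nNodes; ++v)
    if (!isChild[v]) return v;
  return 0;
}

static double min_cost(const std::vector<double>& cost, int node, int S) {
  double m = BIG;
  for (int s = 0; s < S; ++s) m = std::min(m, cost[(size_t)node * S + s]);
  return m;
}

// Uniform draw among indices attaining the minimum of vals.
static int pick_argmin(const double* vals, int S) {
  double m = BIG;
  for (int s = 0; s < S; ++s) m = std::min(m, vals[s]);
  int cnt = 0;
  for (int s = 0; s < S; ++s) if (vals[s] <= m + 1e-9) ++cnt;
  int k = (int)(unif_rand() * cnt);
  if (k >= cnt) k = cnt - 1;
  for (int s = 0; s < S; ++s)
    if (vals[s] <= m + 1e-9 && k-- == 0) return s;
  return 0;
}

// One random minimum-cost resolution; adds transition counts into counts
// (S x S) and optionally records node states.
static void resolve_once(const IntegerMatrix& edge, int nNodes, int root,
                         const std::vector<double>& cost, int S,
                         double* counts, int* statesOut) {
  std::vector<int> assign(nNodes, -1);
  std::vector<double> vals(S);
  for (int s = 0; s < S; ++s) vals[s] = cost[(size_t)root * S + s];
  assign[root] = pick_argmin(vals.data(), S);
  for (int e = edge.nrow() - 1; e >= 0; --e) {  // preorder
    int p = edge(e, 0), c = edge(e, 1);
    int sp = assign[p];
    for (int s = 0; s < S; ++s)
      vals[s] = cost[(size_t)c * S + s] + (s == sp ? 0.0 : 1.0);
    int sc = pick_argmin(vals.data(), S);
    assign[c] = sc;
    if (sc != sp) counts[sp * S + sc] += 1.0;
  }
  if (statesOut)
    for (int v = 0; v < nNodes; ++v) statesOut[v] = assign[v];
}

// [[Rcpp::export(name = ".cppSankoff")]]
List cppSankoff(IntegerMatrix edge, int nNodes, IntegerVector state, int S,
                int R) {
  std::vector<int> st(state.begin(), state.end());
  std::vector<double> cost((size_t)nNodes * S);
  int root = sankoff_up(edge, nNodes, st, S, cost);
  double mc = min_cost(cost, root, S);
  NumericMatrix counts(S, S);
  IntegerVector states(nNodes);
  std::vector<double> acc((size_t)S * S, 0.0);
  std::vector<int> stOut(nNodes);
  for (int r = 0; r < R; ++r)
    resolve_once(edge, nNodes, root, cost, S, acc.data(),
                 r == R - 1 ? stOut.data() : (int*)nullptr);
  for (int a = 0; a < S; ++a)
    for (int b = 0; b < S; ++b) counts(a, b) = acc[a * S + b] / R;
  for (int v = 0; v < nNodes; ++v) states[v] = stOut[v];
  return List::create(_["cost"] = mc, _["counts"] = counts,
                      _["states"] = states);
}

// Shuffle the constrained labels of st in place (Fisher-Yates).
static void shuffle_states(std::vector<int>& st,
                           const std::vector<int>& constrained) {
  int n = constrained.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(st[constrained[i]], st[constrained[j]]);
  }
}

// Observed and permuted per-direction proportion statistics over a set of
// trees. Returns the observed summed count and proportion matrices, the
// per-tree minimal costs, and per-permutation statistics.
// [[Rcpp::export(name = ".cppTraffickingPerm")]]
List cppTraffickingPerm(List edges, List states, IntegerVector nNodes, int S,
                        int nPerm, int R) {
  int nTree = edges.size();
  NumericMatrix obsCounts(S, S), obsProp(S, S);
  NumericVector obsCost(nTree);
  NumericMatrix nullProp(nPerm, S * S);
  NumericVector nullTotal(nPerm);

  std::vector<std::vector<int>> st(nTree), constrained(nTree);
  for (int t = 0; t < nTree; ++t) {
    IntegerVector sv = states[t];
    st[t].assign(sv.begin(), sv.end());
    for (int v = 0; v < (int)st[t].size(); ++v)
      if (st[t][v] >= 0) constrained[t].push_back(v);
  }

  std::vector<double> cost, acc((size_t)S * S);
  for (int t = 0; t < nTree; ++t) {
    IntegerMatrix edge = edges[t];
    cost.assign((size_t)nNodes[t] * S, 0.0);
    int root = sankoff_up(edge, nNodes[t], st[t], S, cost);
    double mc = min_cost(cost, root, S);
    obsCost[t] = mc;
    if (mc <= 0) continue;
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int r = 0; r < R; ++r)
      resolve_once(edge, nNodes[t], root, cost, S, acc.data(), nullptr);
    for (int a = 0; a < S; ++a)
      for (int b = 0; b < S; ++b) {
        double avg = acc[a * S + b] / R;
        obsCounts(a, b) += avg;
        obsProp(a, b) += avg / mc;
      }
  }

  for (int p = 0; p < nPerm; ++p) {
    double totalSum = 0.0;
    int totalTrees = 0;
    for (int t = 0; t < nTree; ++t) {
      IntegerMatrix edge = edges[t];
      std::vector<int> perm = st[t];
      shuffle_states(perm, constrained[t]);
      cost.assign((size_t)nNodes[t] * S, 0.0);
      int root = sankoff_up(edge, nNodes[t], perm, S, cost);
      double mc = min_cost(cost, root, S);
      totalSum += mc;
      ++totalTrees;
      if (mc <= 0) continue;
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int r = 0; r < R; ++r)
        resolve_once(edge, nNodes[t], root, cost, S, acc.data(), nullptr);
      for (int a = 0; a < S; ++a)
        for (int b = 0; b < S; ++b)
          nullProp(p, a * S + b) += (acc[a * S + b] / R) / mc;
    }
    nullTotal[p] = totalTrees > 0 ? totalSum / totalTrees : 0.0;
  }

  return List::create(_["obs_counts"] = obsCounts, _["obs_prop"] = obsProp,
                      _["obs_cost"] = obsCost, _["null_prop"] = nullProp,
                      _["null_total"] = nullTotal);
}
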