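#include <Rcpp.h>
using namespace Rcpp;

// Fitch small-parsimony counting for binary characters on a rooted binary
// tree whose ancestor is fixed in the all-zero state.
//
// Tree encoding: tips are nodes 1..n_tips, internal nodes n_tips+1..2n-1.
// `edge` is a 2-column integer matrix (parent, child) listing every edge;
// children of a node may appear in any order, but the matrix must be in
// postorder (every child edge listed before the edge to its parent), which
// the R-side tree builders guarantee. `tip_states` is an n_tips x n_events
// 0/1 integer matrix. Returns the per-event minimum number of state changes,
// counting the forced transition at the root when its Fitch set excludes 0.
//
// State sets are bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}.

// [[Rcpp::export(name = ".fitch_counts")]]
IntegerVector fitch_counts(IntegerMatrix edge, int n_tips,
                           IntegerMatrix tip_states) {
  const int n_events = tip_states.ncol();
  const int n_nodes = 2 * n_tips - 1 > n_tips ? 2 * n_tips - 1 : n_tips;
  IntegerVector changes(n_events);

  std::vector<std::vector<unsigned char>> sets(
      n_nodes + 1, std::vector<unsigned char>(n_events, 0));
  std::vector<bool> seen(n_nodes + 1, false);

  for (int t = 1; t <= n_tips; ++t) {
    for (int e = 0; e < n_events; ++e)
      sets[t][e] = tip_states(t - 1, e) ? 2 : 1;
    seen[t] = true;
  }

  int root = n_tips == 1 ? 1 : n_tips + 1;
  for (int i = 0; i < edge.nrow(); ++i) {
    int parent = edge(i, 0), child = edge(i, 1);
    if (parent > n_nodes || child > n_nodes)
      stop("edge matrix references a node outside the expected range");
    if (!seen[child]) stop("edge matrix is not in postorder");
    if (!seen[parent]) {
      sets[parent] = sets[child];
      seen[parent] = true;
    } else {
      for (int e = 0; e < n_events; ++e) {
        unsigned char inter = sets[parent][e] & sets[child][e];
        if (inter) {
          sets[parent][e] = inter;
        } else {
          sets[parent][e] = sets[parent][e] | sets[child][e];
          changes[e] += 1;
        }
      }
    }
  }
  // root anchored at the unaberrated (all-zero) ancestor
  for (int e = 0; e < n_events; ++e)
    if (!(sets[root][e] & 1)) changes[e] += 1;
  return changes;
}
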