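#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
#include <functional>
using namespace Rcpp;

// Transportation simplex with MODI (u-v) pricing.
//
// Minimizes sum_ij cost(i,j) * f(i,j) subject to
//   rowSums(f) = supply, colSums(f) = demand, f >= 0,
// with sum(supply) == sum(demand). The basis is a spanning tree of the
// bipartite supply/demand graph holding exactly m + n - 1 cells (zero-flow
// cells are kept to handle degeneracy). Entering variable: most negative
// reduced cost, switching to Bland's rule (first negative) after a run of
// degenerate pivots to guard against cycling.

struct Basis {
  int m, n;
  std::vector<int> brow, bcol;      // basic cell endpoints
  std::vector<double> bflow;        // basic cell flows
  std::vector<std::vector<int>> adj; // node -> indices into brow/bcol
  Basis(int m_, int n_) : m(m_), n(n_), adj(m_ + n_) {}
  void add(int i, int j, double x) {
    int id = brow.size();
    brow.push_back(i); bcol.push_back(j); bflow.push_back(x);
    adj[i].push_back(id); adj[m + j].push_back(id);
  }
  void remove(int id) { // swap-with-last removal, fix adjacency
    int last = brow.size() - 1;
    detach(id);
    if (id != last) {
      detach(last);
      brow[id] = brow[last]; bcol[id] = bcol[last]; bflow[id] = bflow[last];
      adj[brow[id]].push_back(id); adj[m + bcol[id]].push_back(id);
    }
    brow.pop_back(); bcol.pop_back(); bflow.pop_back();
  }
  void detach(int id) {
    drop(adj[brow[id]], id);
    drop(adj[m + bcol[id]], id);
  }
  static void drop(std::vector<int>& v, int id) {
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == id) { v[k] = v.back(); v.pop_back(); return; }
  }
};

// [[Rcpp::export(name = ".transport_simplex_cpp")]]
List transport_simplex_cpp(NumericVector supply, NumericVector demand,
                           NumericMatrix cost, int max_iter = 0,
                           double tol = 1e-10) {
  const int m = supply.size(), n = demand.size();
  if (cost.nrow() != m || cost.ncol() != n)
    stop("cost matrix dimensions do not match supply/demand");
  if (max_iter <= 0) max_iter = 2000 + 100 * (m + n);

  Basis B(m, n);
  { // matrix-minimum initial solution: allocate cells in increasing cost
    // order (forms a forest), then close the basis into a spanning tree
    // with zero-flow cells, again preferring cheap cells
    std::vector<int> ord(m * (size_t)n);
    for (size_t k = 0; k < ord.size(); ++k) ord[k] = k;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return cost[a] < cost[b]; // column-major linear indexing
    });
    std::vector<double> s(supply.begin(), supply.end());
    std::vector<double> d(demand.begin(), demand.end());
    std::vector<int> uf(m + n);
    for (int k = 0; k < m + n; ++k) uf[k] = k;
    std::function<int(int)> find = [&](int x) {
      while (uf[x] != x) { uf[x] = uf[uf[x]]; x = uf[x]; }
      return x;
    };
    double remaining = 0.0;
    for (int i = 0; i < m; ++i) remaining += s[i];
    for (int k : ord) {
      if (remaining <= 0) break;
      int i = k % m, j = k / m;
      if (s[i] > 0 && d[j] > 0) {
        double x = std::min(s[i], d[j]);
        B.add(i, j, x);
        s[i] -= x; d[j] -= x; remaining -= x;
        uf[find(i)] = find(m + j);
      }
    }
    for (int k : ord) {
      if ((int)B.brow.size() >= m + n - 1) break;
      int i = k % m, j = k / m;
      int ri = find(i), rj = find(m + j);
      if (ri != rj) { B.add(i, j, 0.0); uf[ri] = rj; }
    }
  }

  std::vector<double> u(m), v(n);
  std::vector<char> seen(m + n);
  std::vector<int> parent_cell(m + n), parent_node(m + n);
  int iter = 0, degen_run = 0;
  bool converged = false;

  while (iter < max_iter) {
    ++iter;
    // duals: u[i] + v[j] = c[i][j] on basic cells; tree BFS from row 0
    std::fill(seen.begin(), seen.end(), 0);
    u[0] = 0.0; seen[0] = 1;
    std::queue<int> q; q.push(0);
    while (!q.empty()) {
      int node = q.front(); q.pop();
      for (int id : B.adj[node]) {
        int i = B.brow[id], j = B.bcol[id];
        int other = (node == i) ? m + j : i;
        if (!seen[other]) {
          if (other >= m) v[j] = cost(i, j) - u[i];
          else u[i] = cost(i, j) - v[j];
          seen[other] = 1;
          q.push(other);
        }
      }
    }

    // entering cell
    const bool bland = degen_run > m + n;
    int ei = -1, ej = -1;
    double best = -tol;
    for (int i = 0; i < m && (ei < 0 || !bland); ++i) {
      const double ui = u[i];
      for (int j = 0; j < n; ++j) {
        double rc = cost(i, j) - ui - v[j];
        if (rc < best) {
          best = rc; ei = i; ej = j;
          if (bland) break;
        }
      }
    }
    if (ei < 0) { converged = true; break; }

    // cycle: path from row node ei to col node m+ej through the tree
    std::fill(seen.begin(), seen.end(), 0);
    seen[ei] = 1; parent_node[ei] = -1;
    std::queue<int> q2; q2.push(ei);
    int target = m + ej;
    while (!q2.empty() && !seen[target]) {
      int node = q2.front(); q2.pop();
      for (int id : B.adj[node]) {
        int other = (node == B.brow[id]) ? m + B.bcol[id] : B.brow[id];
        if (!seen[other]) {
          seen[other] = 1;
          parent_node[other] = node;
          parent_cell[other] = id;
          q2.push(other);
        }
      }
    }
    if (!seen[target]) stop("internal error: basis is not a spanning tree");

    // walk back: cells on the path alternate -,+,-,... starting with "-"
    // (the entering cell itself is "+")
    double theta = R_PosInf; int leave = -1;
    {
      int node = target; int sign = -1; // first tree cell is a "-" cell
      while (parent_node[node] != -1) {
        int id = parent_cell[node];
        if (sign < 0 && B.bflow[id] < theta) { theta = B.bflow[id]; leave = id; }
        node = parent_node[node];
        sign = -sign;
      }
    }
    if (leave < 0) stop("internal error: no leaving variable");
    degen_run = (theta <= tol) ? degen_run + 1 : 0;

    // apply the pivot
    {
      int node = target; int sign = -1;
      while (parent_node[node] != -1) {
        int id = parent_cell[node];
        B.bflow[id] += sign * theta;
        if (B.bflow[id] < 0) B.bflow[id] = 0;
        node = parent_node[node];
        sign = -sign;
      }
    }
    B.remove(leave);
    B.add(ei, ej, theta);
  }

  NumericMatrix flow(m, n);
  for (size_t k = 0; k < B.brow.size(); ++k)
    flow(B.brow[k], B.bcol[k]) += B.bflow[k];
  double total = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) total += flow(i, j) * cost(i, j);

  return List::create(_["flow"] = flow, _["cost"] = total,
                      _["iterations"] = iter, _["converged"] = converged);
}
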