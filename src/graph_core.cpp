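#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Relative tolerance for declaring two path lengths equal; alternative
// equal-length shortest paths then share the flow fractionally.
static const double REL_TOL = 1e-12;

static inline bool close_eq(double a, double b) {
  return std::fabs(a - b) <= REL_TOL * std::max(1.0, std::fabs(b));
}

struct Adj {
  std::vector<std::vector<std::pair<int, int>>> nbr; // (neighbour, edge index)
  Adj(int n, const IntegerVector &from, const IntegerVector &to) : nbr(n) {
    for (int e = 0; e < from.size(); ++e) {
      int a = from[e] - 1, b = to[e] - 1;
      nbr[a].push_back(std::make_pair(b, e));
      nbr[b].push_back(std::make_pair(a, e));
    }
  }
};

// Weighted betweenness of every node and edge of an undirected graph with
// strictly positive edge lengths (Brandes' dependency accumulation, one
// Dijkstra per source). Counts are per unordered node pair; endpoints are
// excluded from node scores. Unreachable pairs contribute nothing.
// [[Rcpp::export]]
List brandes_betweenness(int n, IntegerVector from, IntegerVector to,
                         NumericVector len) {
  int m = from.size();
  Adj adj(n, from, to);
  NumericVector node_bt(n), edge_bt(m);
  std::vector<double> dist(n), sigma(n), delta(n);
  std::vector<char> done(n);
  std::vector<std::vector<std::pair<int, int>>> preds(n); // (pred node, edge)
  std::vector<int> order;
  order.reserve(n);

  typedef std::pair<double, int> QE;
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(done.begin(), done.end(), 0);
    for (int i = 0; i < n; ++i) preds[i].clear();
    order.clear();

    dist[s] = 0.0;
    sigma[s] = 1.0;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
    pq.push(std::make_pair(0.0, s));
    while (!pq.empty()) {
      int u = pq.top().second;
      pq.pop();
      if (done[u]) continue;
      done[u] = 1;
      order.push_back(u);
      for (size_t k = 0; k < adj.nbr[u].size(); ++k) {
        int v = adj.nbr[u][k].first, e = adj.nbr[u][k].second;
        if (done[v]) continue;
        double nd = dist[u] + len[e];
        if (std::isfinite(dist[v]) && close_eq(nd, dist[v])) {
          sigma[v] += sigma[u];
          preds[v].push_back(std::make_pair(u, e));
        } else if (nd < dist[v]) {
          dist[v] = nd;
          sigma[v] = sigma[u];
          preds[v].clear();
          preds[v].push_back(std::make_pair(u, e));
          pq.push(std::make_pair(nd, v));
        }
      }
    }

    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int w = order[i];
      for (size_t k = 0; k < preds[w].size(); ++k) {
        int v = preds[w][k].first, e = preds[w][k].second;
        double c = sigma[v] / sigma[w] * (1.0 + delta[w]);
        edge_bt[e] += c;
        delta[v] += c;
      }
      if (w != s) node_bt[w] += delta[w];
    }
  }
  // each unordered pair was counted from both endpoints
  for (int i = 0; i < n; ++i) node_bt[i] /= 2.0;
  for (int e = 0; e < m; ++e) edge_bt[e] /= 2.0;
  return List::create(_["node"] = node_bt, _["edge"] = edge_bt);
}

// Connected-component membership (union-find); component ids renumbered
// 1, 2, ... in order of first appearance over nodes 1..n.
// [[Rcpp::export]]
IntegerVector connected_components(int n, IntegerVector from,
                                   IntegerVector to) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  struct UF {
    std::vector<int> &p;
    int find(int x) {
      while (p[x] != x) {
        p[x] = p[p[x]];
        x = p[x];
      }
      return x;
    }
  } uf{parent};
  for (int e = 0; e < from.size(); ++e) {
    int ra = uf.find(from[e] - 1), rb = uf.find(to[e] - 1);
    if (ra != rb) parent[rb] = ra;
  }
  IntegerVector memb(n);
  std::vector<int> label(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (label[r] == 0) label[r] = ++next;
    memb[i] = label[r];
  }
  return memb;
}

// All-sources shortest-path lengths (rows = sources, in order 1..n);
// unreachable pairs are Inf.
// [[Rcpp::export]]
NumericMatrix dijkstra_distances(int n, IntegerVector from, IntegerVector to,
                                 NumericVector len) {
  Adj adj(n, from, to);
  NumericMatrix D(n, n);
  std::vector<double> dist(n);
  std::vector<char> done(n);
  typedef std::pair<double, int> QE;
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(done.begin(), done.end(), 0);
    dist[s] = 0.0;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
    pq.push(std::make_pair(0.0, s));
    while (!pq.empty()) {
      int u = pq.top().second;
      pq.pop();
      if (done[u]) continue;
      done[u] = 1;
      for (size_t k = 0; k < adj.nbr[u].size(); ++k) {
        int v = adj.nbr[u][k].first, e = adj.nbr[u][k].second;
        if (done[v]) continue;
        double nd = dist[u] + len[e];
        if (nd < dist[v]) {
          dist[v] = nd;
          pq.push(std::make_pair(nd, v));
        }
      }
    }
    for (int v = 0; v < n; ++v) D(s, v) = dist[v];
  }
  return D;
}
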