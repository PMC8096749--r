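// Degree-preserving null models and the graph statistics needed for
// small-world normalization. Hot path: 100 nulls x ~25 sparsities per
// subject, so the swap loop, clustering and Dijkstra live here.
#include <Rcpp.h>
#include <queue>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

static inline long long ekey(int a, int b, int n) {
  if (a > b) std::swap(a, b);
  return (long long)a * n + b;
}

// Maslov-Sneppen double-edge swaps on a 1-based edge list; weights stay
// attached to their (rewired) edge slots. Uses R's RNG.
static void ms_swap(std::vector<int>& ei, std::vector<int>& ej,
                    std::unordered_set<long long>& edges, int n,
                    int nswap) {
  int m = (int)ei.size();
  for (int it = 0; it < nswap; ++it) {
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    // propose (a,d) and (c,b)
    if (a == d || c == b) continue;
    if (a == c || b == d) continue;  // would duplicate or self-pair
    long long k1 = ekey(a, d, n), k2 = ekey(c, b, n);
    if (edges.count(k1) || edges.count(k2)) continue;
    edges.erase(ekey(a, b, n));
    edges.erase(ekey(c, d, n));
    edges.insert(k1);
    edges.insert(k2);
    ej[e1] = d;
    ei[e2] = c; ej[e2] = b;
  }
}

// [[Rcpp::export(name = ".ms_swap_cpp")]]
List ms_swap_cpp(IntegerVector ei, IntegerVector ej, NumericVector w,
                 int n, int nswap) {
  std::vector<int> vi(ei.begin(), ei.end()), vj(ej.begin(), ej.end());
  std::unordered_set<long long> edges;
  for (size_t e = 0; e < vi.size(); ++e)
    edges.insert(ekey(vi[e], vj[e], n));
  GetRNGstate();
  ms_swap(vi, vj, edges, n, nswap);
  PutRNGstate();
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj),
                      _["w"] = w);
}

struct Net {
  int n;
  std::vector<std::vector<std::pair<int, double> > > adj;  // 0-based
  Net(int n_) : n(n_), adj(n_) {}
  void add(int a, int b, double w) {
    adj[a].push_back(std::make_pair(b, w));
    adj[b].push_back(std::make_pair(a, w));
  }
};

// mean clustering coefficient; weighted = Onnela geometric-mean variant
// with weights scaled by the maximum, binary = 2t/(k(k-1))
static double mean_clustering(const Net& net, bool weighted) {
  int n = net.n;
  double maxw = 0.0;
  std::vector<std::vector<double> > W(n, std::vector<double>(n, 0.0));
  std::vector<int> deg(n, 0);
  for (int a = 0; a < n; ++a) {
    deg[a] = (int)net.adj[a].size();
    for (size_t t = 0; t < net.adj[a].size(); ++t) {
      W[a][net.adj[a][t].first] = net.adj[a][t].second;
      if (net.adj[a][t].second > maxw) maxw = net.adj[a][t].second;
    }
  }
  double total = 0.0;
  for (int a = 0; a < n; ++a) {
    if (deg[a] < 2) continue;
    double t2 = 0.0;
    const std::vector<std::pair<int, double> >& nb = net.adj[a];
    for (size_t x = 0; x < nb.size(); ++x) {
      for (size_t y = x + 1; y < nb.size(); ++y) {
        int j = nb[x].first, k = nb[y].first;
        double wjk = W[j][k];
        if (wjk <= 0) continue;
        if (weighted) {
          t2 += std::cbrt(nb[x].second / maxw) *
                std::cbrt(nb[y].second / maxw) * std::cbrt(wjk / maxw);
        } else {
          t2 += 1.0;
        }
      }
    }
    total += 2.0 * t2 / ((double)deg[a] * (deg[a] - 1));
  }
  return total / n;
}

// characteristic path length: mean Dijkstra distance (edge length =
// 1/weight; binary: 1) over connected ordered pairs
static double char_path_length(const Net& net, bool weighted) {
  int n = net.n;
  double sum = 0.0;
  long long cnt = 0;
  typedef std::pair<double, int> QE;
  std::vector<double> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    dist[s] = 0.0;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    pq.push(std::make_pair(0.0, s));
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      if (top.first > dist[top.second]) continue;
      int u = top.second;
      for (size_t t = 0; t < net.adj[u].size(); ++t) {
        int v = net.adj[u][t].first;
        double len = weighted ? 1.0 / net.adj[u][t].second : 1.0;
        double nd = top.first + len;
        if (nd < dist[v]) {
          dist[v] = nd;
          pq.push(std::make_pair(nd, v));
        }
      }
    }
    for (int v = 0; v < n; ++v) {
      if (v != s && R_FINITE(dist[v])) { sum += dist[v]; ++cnt; }
    }
  }
  return cnt > 0 ? sum / cnt : NA_REAL;
}

// per-node local efficiency: global efficiency of each node's
// neighbourhood subgraph (node removed); < 2 neighbours -> 0
// [[Rcpp::export(name = ".local_efficiency_cpp")]]
NumericVector local_efficiency_cpp(IntegerVector ei, IntegerVector ej,
                                   NumericVector w, int n,
                                   bool weighted) {
  Net net(n);
  int m = ei.size();
  for (int e = 0; e < m; ++e) net.add(ei[e] - 1, ej[e] - 1, w[e]);
  NumericVector out(n);
  std::vector<int> idx(n, -1);
  for (int i = 0; i < n; ++i) {
    const std::vector<std::pair<int, double> >& nb = net.adj[i];
    int k = (int)nb.size();
    if (k < 2) { out[i] = 0.0; continue; }
    for (int x = 0; x < k; ++x) idx[nb[x].first] = x;
    Net sub(k);
    for (int x = 0; x < k; ++x) {
      int u = nb[x].first;
      for (size_t t = 0; t < net.adj[u].size(); ++t) {
        int v = net.adj[u][t].first;
        if (idx[v] > x)  // each subgraph edge once
          sub.add(x, idx[v], net.adj[u][t].second);
      }
    }
    // global efficiency of the subgraph
    double sum = 0.0;
    typedef std::pair<double, int> QE;
    std::vector<double> dist(k);
    for (int s = 0; s < k; ++s) {
      std::fill(dist.begin(), dist.end(), R_PosInf);
      dist[s] = 0.0;
      std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
      pq.push(std::make_pair(0.0, s));
      while (!pq.empty()) {
        QE top = pq.top(); pq.pop();
        if (top.first > dist[top.second]) continue;
        int u = top.second;
        for (size_t t = 0; t < sub.adj[u].size(); ++t) {
          int v = sub.adj[u][t].first;
          double len = weighted ? 1.0 / sub.adj[u][t].second : 1.0;
          double nd = top.first + len;
          if (nd < dist[v]) {
            dist[v] = nd;
            pq.push(std::make_pair(nd, v));
          }
        }
      }
      for (int v = 0; v < k; ++v)
        if (v != s && R_FINITE(dist[v])) sum += 1.0 / dist[v];
    }
    out[i] = sum / ((double)k * (k - 1));
    for (int x = 0; x < k; ++x) idx[nb[x].first] = -1;
  }
  return out;
}

// Cp and Lp averaged over n_null degree-preserving rewired references
// [[Rcpp::export(name = ".null_reference_cpp")]]
NumericVector null_reference_cpp(IntegerVector ei, IntegerVector ej,
                                 NumericVector w, int n, int n_null,
                                 int nswap, bool weighted) {
  int m = ei.size();
  double cp_sum = 0.0, lp_sum = 0.0;
  GetRNGstate();
  for (int b = 0; b < n_null; ++b) {
    std::vector<int> vi(ei.begin(), ei.end()), vj(ej.begin(), ej.end());
    std::unordered_set<long long> edges;
    for (int e = 0; e < m; ++e) edges.insert(ekey(vi[e], vj[e], n));
    ms_swap(vi, vj, edges, n, nswap);
    Net net(n);
    for (int e = 0; e < m; ++e) net.add(vi[e] - 1, vj[e] - 1, w[e]);
    cp_sum += mean_clustering(net, weighted);
    lp_sum += char_path_length(net, weighted);
  }
  PutRNGstate();
  return NumericVector::create(cp_sum / n_null, lp_sum / n_null);
}
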