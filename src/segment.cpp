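#include <Rcpp.h>
#include <queue>
#include <set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Greedy hierarchical region merging on a pixel grid.
//
// Every valid pixel starts as its own region; adjacent regions (4- or
// 8-connected) are merged in order of increasing Ward cost
//   sqrt(2 n1 n2 / (n1 + n2)) * ||mean1 - mean2||
// (the square root of twice the within-segment sum-of-squares increase;
// for two single pixels this is just their feature distance) until the
// cheapest remaining merge exceeds `threshold`. The size factor makes
// thin boundary strips cheap to absorb into large homogeneous fields
// while keeping large dissimilar regions expensive, which suppresses
// chaining across field borders. Ties break on the smaller (then
// larger) region id, so the result is fully deterministic, and because
// the greedy merge sequence is identical for any two thresholds up to
// the smaller one, the number of segments is monotone non-increasing in
// the threshold.
//
// feat: pixels x F matrix (column-major pixel order, row index
//       p = r + c*nr); valid: length-P flags. Invalid pixels receive
//       label 0 and are resolved by the caller.
// Returns 1-based region labels (not yet densely relabeled).

struct Edge {
  double cost;
  int a, b;        // region reps at push time (a < b)
  long va, vb;     // region versions at push time
};
struct EdgeCmp {
  bool operator()(const Edge& x, const Edge& y) const {
    if (x.cost != y.cost) return x.cost > y.cost;
    if (x.a != y.a) return x.a > y.a;
    return x.b > y.b;
  }
};

class DSU {
 public:
  explicit DSU(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  std::vector<int> parent;
};

// [[Rcpp::export]]
IntegerVector merge_segments_cpp(NumericMatrix feat, LogicalVector valid,
                                 int nr, int nc, double threshold,
                                 bool eight) {
  const int P = nr * nc;
  const int F = feat.ncol();
  DSU dsu(P);
  std::vector<long> version(P, 0);
  std::vector<double> sum(static_cast<size_t>(P) * F, 0.0);
  std::vector<int> count(P, 0);
  std::vector<std::set<int> > adj(P);

  for (int p = 0; p < P; ++p) {
    if (!valid[p]) continue;
    count[p] = 1;
    for (int f = 0; f < F; ++f) sum[(size_t)p * F + f] = feat(p, f);
  }

  auto cost_between = [&](int ra, int rb) -> double {
    double s = 0.0;
    for (int f = 0; f < F; ++f) {
      double d = sum[(size_t)ra * F + f] / count[ra] -
                 sum[(size_t)rb * F + f] / count[rb];
      s += d * d;
    }
    double n1 = count[ra], n2 = count[rb];
    return std::sqrt(s * 2.0 * n1 * n2 / (n1 + n2));
  };

  std::priority_queue<Edge, std::vector<Edge>, EdgeCmp> heap;
  auto push_edge = [&](int ra, int rb) {
    if (ra == rb) return;
    int a = std::min(ra, rb), b = std::max(ra, rb);
    heap.push(Edge{cost_between(a, b), a, b, version[a], version[b]});
  };

  // initial grid adjacency
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int p = r + c * nr;
      if (!valid[p]) continue;
      const int dr4[2] = {1, 0}, dc4[2] = {0, 1};
      const int dr8[2] = {1, -1}, dc8[2] = {1, 1};
      for (int k = 0; k < 2; ++k) {
        int rr = r + dr4[k], cc = c + dc4[k];
        if (rr < nr && cc < nc) {
          int q = rr + cc * nr;
          if (valid[q]) { adj[p].insert(q); adj[q].insert(p); push_edge(p, q); }
        }
      }
      if (eight) {
        for (int k = 0; k < 2; ++k) {
          int rr = r + dr8[k], cc = c + dc8[k];
          if (rr >= 0 && rr < nr && cc < nc) {
            int q = rr + cc * nr;
            if (valid[q]) { adj[p].insert(q); adj[q].insert(p); push_edge(p, q); }
          }
        }
      }
    }
  }

  while (!heap.empty()) {
    Edge e = heap.top();
    heap.pop();
    int ra = dsu.find(e.a), rb = dsu.find(e.b);
    if (ra == rb) continue;
    bool current = (ra == e.a && rb == e.b &&
                    version[ra] == e.va && version[rb] == e.vb);
    if (!current) {
      // still adjacent? re-push with the up-to-date cost
      int a = std::min(ra, rb), b = std::max(ra, rb);
      if (adj[a].count(b)) {
        heap.push(Edge{cost_between(a, b), a, b, version[a], version[b]});
      }
      continue;
    }
    if (e.cost > threshold) break;  // heap min: nothing cheaper remains
    // merge rb into ra (ra < rb by construction)
    for (int f = 0; f < F; ++f)
      sum[(size_t)ra * F + f] += sum[(size_t)rb * F + f];
    count[ra] += count[rb];
    dsu.parent[rb] = ra;
    version[ra] += 1;
    adj[ra].erase(rb);
    adj[rb].erase(ra);
    for (int nb : adj[rb]) {
      adj[nb].erase(rb);
      adj[nb].insert(ra);
      adj[ra].insert(nb);
    }
    adj[rb].clear();
    for (int nb : adj[ra]) push_edge(ra, nb);
  }

  IntegerVector out(P, 0);
  for (int p = 0; p < P; ++p) {
    if (valid[p]) out[p] = dsu.find(p) + 1;
  }
  return out;
}
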