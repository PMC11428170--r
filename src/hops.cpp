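// All-pairs shortest contact hops by breadth-first search from every bead.
// Disconnected pairs receive the cap value (the map size by convention).
// This sits in the inner loop of the sequence search, hence compiled.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".hop_matrix_cpp")]]
IntegerMatrix hop_matrix_cpp(IntegerMatrix G, int cap) {
  int n = G.nrow();
  IntegerMatrix S(n, n);
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (G(i, j) == 1) adj[i].push_back(j);
  std::vector<int> dist(n), queue(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int head = 0, tail = 0;
    queue[tail++] = s;
    while (head < tail) {
      int u = queue[head++];
      for (int v : adj[u]) {
        if (dist[v] < 0) {
          dist[v] = dist[u] + 1;
          queue[tail++] = v;
        }
      }
    }
    for (int j = 0; j < n; ++j)
      S(s, j) = dist[j] < 0 ? cap : dist[j];
  }
  return S;
}

// SCH distance from two hop matrices (upper triangle), compiled for the
// same reason.
// [[Rcpp::export(name = ".sch_from_hops_cpp")]]
double sch_from_hops_cpp(IntegerMatrix SA, IntegerMatrix SB) {
  int n = SA.nrow();
  double s = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int a = SA(i, j), b = SB(i, j);
      if (a != b) s += std::abs(a - b) / (double)std::max(a, b);
    }
  return 2.0 * s / ((double)n * (n - 1));
}
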