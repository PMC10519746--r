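// 2D phase unwrapping by reliability sorting with region merging
// (Herraez-style quality-guided algorithm). Pixels are joined along
// horizontal/vertical edges in decreasing order of reliability; each merge
// shifts one region by an integer multiple of 2*pi, so the output differs
// from the wrapped input by an exact multiple of 2*pi at every pixel.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double wrap2pi(double x) {
  const double tp = 2.0 * M_PI;
  return x - tp * std::round(x / tp);
}

// [[Rcpp::export(name = ".unwrap2d_cpp")]]
NumericMatrix unwrap2d_cpp(NumericMatrix wrapped) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol();
  const int n = nr * nc;
  const double tp = 2.0 * M_PI;
  const double* w = wrapped.begin();

  // pixel reliability: inverse of second-difference magnitude
  std::vector<double> rel(n, 0.0);
  for (int j = 1; j < nc - 1; ++j) {
    for (int i = 1; i < nr - 1; ++i) {
      const int id = i + j * nr;
      double H = wrap2pi(w[id - 1] - w[id]) - wrap2pi(w[id] - w[id + 1]);
      double V = wrap2pi(w[id - nr] - w[id]) - wrap2pi(w[id] - w[id + nr]);
      double D1 = wrap2pi(w[id - nr - 1] - w[id]) - wrap2pi(w[id] - w[id + nr + 1]);
      double D2 = wrap2pi(w[id - nr + 1] - w[id]) - wrap2pi(w[id] - w[id + nr - 1]);
      double d = std::sqrt(H * H + V * V + D1 * D1 + D2 * D2);
      rel[id] = 1.0 / (d + 1e-12);
    }
  }
  // borders: low reliability (d large) -> small rel; keep 0 => processed last

  struct Edge { float rel; int a, b; };
  std::vector<Edge> edges;
  edges.reserve(2 * n);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr - 1; ++i) {
      int id = i + j * nr;
      edges.push_back({(float)(rel[id] + rel[id + 1]), id, id + 1});
    }
  for (int j = 0; j < nc - 1; ++j)
    for (int i = 0; i < nr; ++i) {
      int id = i + j * nr;
      edges.push_back({(float)(rel[id] + rel[id + nr]), id, id + nr});
    }
  std::sort(edges.begin(), edges.end(),
            [](const Edge& x, const Edge& y) { return x.rel > y.rel; });

  // region bookkeeping: head/next linked lists, sizes, per-pixel wrap count
  std::vector<int> group(n), next(n, -1), head(n), tail(n), size(n, 1);
  std::vector<int> k(n, 0);
  for (int i = 0; i < n; ++i) { group[i] = i; head[i] = i; tail[i] = i; }

  for (const Edge& e : edges) {
    int ga = group[e.a], gb = group[e.b];
    if (ga == gb) continue;
    // unwrapped values with current wrap counts
    double va = w[e.a] + tp * k[e.a];
    double vb = w[e.b] + tp * k[e.b];
    int m = (int)std::lround((va - vb) / tp);  // shift for b's region
    if (size[ga] < size[gb]) {
      // merge a's region into b's: shift a's region by -m
      for (int p = head[ga]; p != -1; p = next[p]) { k[p] -= m; group[p] = gb; }
      next[tail[gb]] = head[ga]; tail[gb] = tail[ga];
      size[gb] += size[ga];
    } else {
      for (int p = head[gb]; p != -1; p = next[p]) { k[p] += m; group[p] = ga; }
      next[tail[ga]] = head[gb]; tail[ga] = tail[gb];
      size[ga] += size[gb];
    }
  }

  NumericMatrix out(nr, nc);
  for (int i = 0; i < n; ++i) out[i] = w[i] + tp * k[i];
  return out;
}
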