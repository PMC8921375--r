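// 3-D voxel morphology, region growing, marker watershed and the 1-D optimal
// k-means dynamic program. Arrays are column-major with dim = (n1, n2, n3);
// linear index = i + n1*(j + n2*k). Out-of-bounds voxels are treated as
// background everywhere, so erosion always removes border voxels.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int n1, n2, n3;
  Grid(const IntegerVector& dim) : n1(dim[0]), n2(dim[1]), n3(dim[2]) {}
  inline int idx(int i, int j, int k) const { return i + n1 * (j + n2 * k); }
  inline void coords(int v, int& i, int& j, int& k) const {
    i = v % n1; j = (v / n1) % n2; k = v / (n1 * n2);
  }
  inline bool inside(int i, int j, int k) const {
    return i >= 0 && i < n1 && j >= 0 && j < n2 && k >= 0 && k < n3;
  }
};

// neighbor offsets for 6- or 26-connectivity, deterministic order
std::vector<std::array<int, 3>> neighbor_deltas(int connectivity) {
  std::vector<std::array<int, 3>> d;
  if (connectivity == 6) {
    d = {{{-1,0,0}},{{1,0,0}},{{0,-1,0}},{{0,1,0}},{{0,0,-1}},{{0,0,1}}};
  } else {
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di)
          if (di || dj || dk) d.push_back({{di, dj, dk}});
  }
  return d;
}

} // namespace

// Connected components; labels assigned in raster-scan order (deterministic).
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  Grid g(dim);
  auto nb = neighbor_deltas(connectivity);
  int n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int v = 0; v < n; ++v) {
    if (!mask[v] || lab[v]) continue;
    ++next;
    lab[v] = next;
    stack.push_back(v);
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      int i, j, k; g.coords(u, i, j, k);
      for (auto& d : nb) {
        int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (!g.inside(ii, jj, kk)) continue;
        int w = g.idx(ii, jj, kk);
        if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// Flood fill from seed voxels through `include`; returns grown mask.
// [[Rcpp::export(name = ".grow_from_seeds_cpp")]]
LogicalVector grow_from_seeds_cpp(LogicalVector include, IntegerVector seeds,
                                  IntegerVector dim, int connectivity) {
  Grid g(dim);
  auto nb = neighbor_deltas(connectivity);
  LogicalVector out(include.size(), false);
  std::vector<int> stack;
  for (int s = 0; s < seeds.size(); ++s) {
    int v = seeds[s];
    if (v < 0 || v >= include.size()) stop("seed index out of range");
    if (include[v] && !out[v]) { out[v] = true; stack.push_back(v); }
  }
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    int i, j, k; g.coords(u, i, j, k);
    for (auto& d : nb) {
      int ii = i + d[0], jj = j + d[1], kk = k + d[2];
      if (!g.inside(ii, jj, kk)) continue;
      int w = g.idx(ii, jj, kk);
      if (include[w] && !out[w]) { out[w] = true; stack.push_back(w); }
    }
  }
  return out;
}

// One erosion step; survive iff all structuring-element neighbors are set.
// [[Rcpp::export(name = ".erode_cpp")]]
LogicalVector erode_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  Grid g(dim);
  auto nb = neighbor_deltas(connectivity);
  LogicalVector out(mask.size(), false);
  for (int v = 0; v < mask.size(); ++v) {
    if (!mask[v]) continue;
    int i, j, k; g.coords(v, i, j, k);
    bool keep = true;
    for (auto& d : nb) {
      int ii = i + d[0], jj = j + d[1], kk = k + d[2];
      if (!g.inside(ii, jj, kk) || !mask[g.idx(ii, jj, kk)]) { keep = false; break; }
    }
    out[v] = keep;
  }
  return out;
}

// [[Rcpp::export(name = ".dilate_cpp")]]
LogicalVector dilate_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  Grid g(dim);
  auto nb = neighbor_deltas(connectivity);
  LogicalVector out = clone(mask);
  for (int v = 0; v < mask.size(); ++v) {
    if (!mask[v]) continue;
    int i, j, k; g.coords(v, i, j, k);
    for (auto& d : nb) {
      int ii = i + d[0], jj = j + d[1], kk = k + d[2];
      if (g.inside(ii, jj, kk)) out[g.idx(ii, jj, kk)] = true;
    }
  }
  return out;
}

// Erosion depth: number of 3^3 erosion iterations a voxel survives
// (boundary voxels 0, background -1). Iterates until the mask is empty.
// [[Rcpp::export(name = ".erosion_depth_cpp")]]
IntegerVector erosion_depth_cpp(LogicalVector mask, IntegerVector dim) {
  IntegerVector depth(mask.size(), -1);
  LogicalVector cur = clone(mask);
  int d = 0;
  bool any = false;
  for (int v = 0; v < mask.size(); ++v) if (cur[v]) { depth[v] = 0; any = true; }
  while (any) {
    LogicalVector nxt = erode_cpp(cur, dim, 26);
    any = false;
    for (int v = 0; v < cur.size(); ++v) {
      if (nxt[v]) { depth[v] = d + 1; any = true; }
    }
    cur = nxt;
    ++d;
    if (d > 10000) stop("erosion depth runaway");
  }
  return depth;
}

// Marker-based watershed on -depth: descending-depth region growth from
// labeled markers. Deterministic: pop highest depth first, FIFO within depth.
// [[Rcpp::export(name = ".watershed_desc_cpp")]]
IntegerVector watershed_desc_cpp(IntegerVector depth, IntegerVector markers,
                                 LogicalVector mask, IntegerVector dim,
                                 int connectivity) {
  Grid g(dim);
  auto nb = neighbor_deltas(connectivity);
  int n = mask.size();
  IntegerVector lab(n, 0);
  typedef std::tuple<int, long long, int> QE; // (depth, -order, voxel)
  std::priority_queue<QE> pq;
  long long order = 0;
  for (int v = 0; v < n; ++v) {
    if (markers[v] > 0 && mask[v]) {
      lab[v] = markers[v];
      pq.push(QE(depth[v], -(order++), v));
    }
  }
  while (!pq.empty()) {
    int u = std::get<2>(pq.top()); pq.pop();
    int i, j, k; g.coords(u, i, j, k);
    for (auto& d : nb) {
      int ii = i + d[0], jj = j + d[1], kk = k + d[2];
      if (!g.inside(ii, jj, kk)) continue;
      int w = g.idx(ii, jj, kk);
      if (mask[w] && lab[w] == 0) {
        lab[w] = lab[u];
        pq.push(QE(depth[w], -(order++), w));
      }
    }
  }
  return lab;
}

// Multi-source BFS label propagation inside a mask (geodesic nearest seed).
// [[Rcpp::export(name = ".geodesic_label_cpp")]]
IntegerVector geodesic_label_cpp(LogicalVector mask, IntegerVector seed_labels,
                                 IntegerVector dim, int connectivity) {
  Grid g(dim);
  auto nb = neighbor_deltas(connectivity);
  int n = mask.size();
  IntegerVector lab(n, 0);
  std::queue<int> q;
  for (int v = 0; v < n; ++v) {
    if (seed_labels[v] > 0 && mask[v]) { lab[v] = seed_labels[v]; q.push(v); }
  }
  while (!q.empty()) {
    int u = q.front(); q.pop();
    int i, j, k; g.coords(u, i, j, k);
    for (auto& d : nb) {
      int ii = i + d[0], jj = j + d[1], kk = k + d[2];
      if (!g.inside(ii, jj, kk)) continue;
      int w = g.idx(ii, jj, kk);
      if (mask[w] && lab[w] == 0) { lab[w] = lab[u]; q.push(w); }
    }
  }
  return lab;
}

// Separable 1-D convolution along one axis with replicate padding.
// [[Rcpp::export(name = ".conv_axis_cpp")]]
NumericVector conv_axis_cpp(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis) {
  Grid g(dim);
  int half = (kernel.size() - 1) / 2;
  NumericVector out(vol.size());
  int n[3] = {g.n1, g.n2, g.n3};
  int len = n[axis];
  for (int v = 0; v < vol.size(); ++v) {
    int c[3]; g.coords(v, c[0], c[1], c[2]);
    double acc = 0.0;
    for (int t = -half; t <= half; ++t) {
      int p = c[axis] + t;
      if (p < 0) p = 0;
      if (p >= len) p = len - 1;
      int cc[3] = {c[0], c[1], c[2]};
      cc[axis] = p;
      acc += kernel[t + half] * vol[g.idx(cc[0], cc[1], cc[2])];
    }
    out[v] = acc;
  }
  return out;
}

namespace {
// within-cluster sum of squares of sorted, centered x over [i, j] inclusive
struct SSQ {
  std::vector<double> s1, s2;
  SSQ(const NumericVector& x) {
    int n = x.size();
    double mean = 0.0;
    for (int i = 0; i < n; ++i) mean += x[i];
    mean /= n;
    s1.resize(n + 1, 0.0); s2.resize(n + 1, 0.0);
    for (int i = 0; i < n; ++i) {
      double c = x[i] - mean;
      s1[i + 1] = s1[i] + c;
      s2[i + 1] = s2[i] + c * c;
    }
  }
  inline double operator()(int i, int j) const {
    double s = s1[j + 1] - s1[i];
    int m = j - i + 1;
    double v = (s2[j + 1] - s2[i]) - s * s / m;
    return v > 0 ? v : 0.0;
  }
};

} // namespace

// Optimal univariate k-means on sorted values: dynamic program with
// divide-and-conquer (monotone argmin). Returns 1-based cluster assignment.
// [[Rcpp::export(name = ".ckmeans_dp_cpp")]]
IntegerVector ckmeans_dp_cpp(NumericVector x_sorted, int k) {
  int n = x_sorted.size();
  if (k < 1 || k > n) stop("require 1 <= k <= n");
  SSQ ssq(x_sorted);
  std::vector<double> prev(n + 1), cur(n + 1);
  // arg[q][j]: start index of cluster q ending at j (0-based values, 1..j)
  std::vector<std::vector<int>> arg(k + 1, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) { prev[j + 1] = ssq(0, j); arg[1][j] = 0; }
  prev[0] = 0.0;
  for (int q = 2; q <= k; ++q) {
    std::vector<double> row(n + 1, R_PosInf);
    // prev[i] = optimal cost of the first i values in q-1 clusters; cluster q
    // covers sorted values i..j (0-based) with i >= q-1 so clusters are nonempty
    std::vector<double> pc(n + 1);
    for (int i = 0; i <= n; ++i) pc[i] = prev[i];
    std::vector<double> curj(n, R_PosInf);
    std::vector<int> argq(n, 0);
    // reuse dc_fill with prev[i-1] meaning cost of values 0..i-1
    struct Local {
      const std::vector<double>& pc; const SSQ& ssq;
      std::vector<double>& curj; std::vector<int>& argq;
      void fill(int jlo, int jhi, int ilo, int ihi) {
        if (jlo > jhi) return;
        int jm = (jlo + jhi) / 2;
        double best = R_PosInf; int besti = ilo;
        int hi = std::min(jm, ihi);
        for (int i = ilo; i <= hi; ++i) {
          double c = pc[i] + ssq(i, jm);
          if (c < best) { best = c; besti = i; }
        }
        curj[jm] = best; argq[jm] = besti;
        fill(jlo, jm - 1, ilo, besti);
        fill(jm + 1, jhi, besti, ihi);
      }
    } loc{pc, ssq, curj, argq};
    loc.fill(q - 1, n - 1, q - 1, n - 1);
    for (int j = 0; j < n; ++j) arg[q][j] = argq[j];
    for (int j = 0; j < n; ++j) row[j + 1] = curj[j];
    row[0] = 0.0;
    prev = row;
  }
  IntegerVector assign(n);
  int j = n - 1;
  for (int q = k; q >= 1; --q) {
    int i = arg[q][j];
    for (int t = i; t <= j; ++t) assign[t] = q;
    j = i - 1;
  }
  return assign;
}
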