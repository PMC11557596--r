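// 3D Euclidean distance transform (Felzenszwalb-Huttenlocher separable
// squared-distance transform) and marker-based priority-flood watershed
// with saddle-height basin merging, for mesoscale-domain segmentation of
// LAC volumes.

#include <Rcpp.h>
#include <queue>
#include <map>
#include <cmath>
#include <functional>
using namespace Rcpp;

static const double EDT_INF = 1e20;

// 1D squared distance transform of sampled function f -> d
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -EDT_INF;
  z[1] = EDT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = EDT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector fg, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // 0 on background, INF on foreground; voxels outside the array count as
  // background (distance to the array boundary is respected)
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] ? EDT_INF : 0.0;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nx * ny];
      dt1d(f, d, nz, v, z);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nx * ny] = d[k];
    }
  out.attr("dim") = dims;
  return out;  // squared Euclidean distance in voxel units
}

// Local maxima of dt over the 26-neighbourhood with greedy minimum-
// separation suppression (stronger peaks win).
// [[Rcpp::export]]
IntegerMatrix local_maxima_cpp(NumericVector dt, IntegerVector dims,
                               double min_sep) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<R_xlen_t> cand;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
        double v = dt[idx];
        if (v <= 0) continue;
        bool is_max = true;
        for (int dk = -1; dk <= 1 && is_max; ++dk)
          for (int dj = -1; dj <= 1 && is_max; ++dj)
            for (int di = -1; di <= 1 && is_max; ++di) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                  kk >= nz)
                continue;
              if (dt[(R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii] > v)
                is_max = false;
            }
        if (is_max) cand.push_back(idx);
      }
  // sort candidates by decreasing dt
  std::sort(cand.begin(), cand.end(),
            [&](R_xlen_t a, R_xlen_t b) { return dt[a] > dt[b]; });
  std::vector<R_xlen_t> kept;
  const double sep2 = min_sep * min_sep;
  for (R_xlen_t idx : cand) {
    int i = idx % nx, j = (idx / nx) % ny, k = idx / ((R_xlen_t)nx * ny);
    bool ok = true;
    for (R_xlen_t kidx : kept) {
      int i2 = kidx % nx, j2 = (kidx / nx) % ny,
          k2 = kidx / ((R_xlen_t)nx * ny);
      double d2 = (double)(i - i2) * (i - i2) + (double)(j - j2) * (j - j2) +
                  (double)(k - k2) * (k - k2);
      if (d2 <= sep2) { ok = false; break; }
    }
    if (ok) kept.push_back(idx);
  }
  IntegerMatrix out(kept.size(), 4);  // i, j, k (1-based), linear index
  for (size_t m = 0; m < kept.size(); ++m) {
    R_xlen_t idx = kept[m];
    out(m, 0) = idx % nx + 1;
    out(m, 1) = (idx / nx) % ny + 1;
    out(m, 2) = idx / ((R_xlen_t)nx * ny) + 1;
    out(m, 3) = idx + 1;
  }
  return out;
}

struct QItem {
  double prio;
  R_xlen_t idx;
  int label;
  bool operator<(const QItem& o) const { return prio < o.prio; }
};

// Marker watershed on -dt (flood from high distance downwards) over the
// foreground, then merge basins whose saddle height is >= merge_level *
// min(peak heights). Returns relabelled basins (small ones dropped).
// [[Rcpp::export]]
IntegerVector watershed_merge_cpp(NumericVector dt, LogicalVector fg,
                                  IntegerVector dims, IntegerVector markers,
                                  double merge_level, int min_voxels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int nm = markers.size();
  std::vector<double> peak(nm + 1, 0.0);
  std::priority_queue<QItem> pq;
  for (int m = 0; m < nm; ++m) {
    R_xlen_t idx = markers[m] - 1;
    lab[idx] = m + 1;
    peak[m + 1] = dt[idx];
    pq.push({dt[idx], idx, m + 1});
  }
  // saddle height per adjacent label pair
  std::map<std::pair<int, int>, double> saddle;
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    int i = it.idx % nx, j = (it.idx / nx) % ny,
        k = it.idx / ((R_xlen_t)nx * ny);
    for (int d = 0; d < 6; ++d) {
      int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t nidx = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
      if (!fg[nidx]) continue;
      if (lab[nidx] == 0) {
        lab[nidx] = it.label;
        pq.push({dt[nidx], nidx, it.label});
      } else if (lab[nidx] != it.label) {
        int a = std::min(lab[nidx], it.label), b = std::max(lab[nidx], it.label);
        double h = std::min(dt[nidx], dt[it.idx]);
        auto key = std::make_pair(a, b);
        auto f = saddle.find(key);
        if (f == saddle.end() || f->second < h) saddle[key] = h;
      }
    }
  }
  // union-find merge
  std::vector<int> parent(nm + 1);
  for (int m = 0; m <= nm; ++m) parent[m] = m;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) a = parent[a] = parent[parent[a]];
    return a;
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (auto& kv : saddle) {
      int a = find(kv.first.first), b = find(kv.first.second);
      if (a == b) continue;
      double pmin = std::min(peak[a], peak[b]);
      if (kv.second >= merge_level * pmin) {
        parent[std::max(a, b)] = std::min(a, b);
        peak[std::min(a, b)] = std::max(peak[a], peak[b]);
        changed = true;
      }
    }
  }
  // relabel, drop small regions
  std::vector<R_xlen_t> count(nm + 1, 0);
  for (R_xlen_t i = 0; i < n; ++i)
    if (lab[i]) lab[i] = find(lab[i]);
  for (R_xlen_t i = 0; i < n; ++i)
    if (lab[i]) ++count[lab[i]];
  std::vector<int> newlab(nm + 1, 0);
  int next = 0;
  for (int m = 1; m <= nm; ++m)
    if (count[m] >= (R_xlen_t)min_voxels && find(m) == m) newlab[m] = ++next;
  for (R_xlen_t i = 0; i < n; ++i)
    lab[i] = lab[i] ? newlab[lab[i]] : 0;
  lab.attr("dim") = dims;
  return lab;
}
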