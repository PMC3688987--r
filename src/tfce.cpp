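#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Union-find with cluster sizes
struct UF {
  std::vector<int> parent, size;
  UF(int n) : parent(n, -1), size(n, 0) {}
  void activate(int i) { parent[i] = i; size[i] = 1; }
  bool active(int i) const { return parent[i] >= 0; }
  int find(int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

// 26-connected neighbour offsets within bounds, linear indexing x fastest
static inline void tfce_one(const double *stat, int nx, int ny, int nz,
                            double E, double H, double dh_in, int nsteps_default,
                            double *out,
                            std::vector<int> &order, UF &uf,
                            std::vector<int> &active) {
  const int v = nx * ny * nz;
  double maxv = 0.0;
  for (int i = 0; i < v; ++i) {
    out[i] = 0.0;
    if (stat[i] > maxv) maxv = stat[i];
  }
  if (maxv <= 0.0) return;
  double dh = dh_in > 0 ? dh_in : maxv / nsteps_default;
  int nsteps = (int)std::floor(maxv / dh + 1e-12);
  if (nsteps < 1) return;

  // voxels with positive stat, sorted descending
  order.clear();
  for (int i = 0; i < v; ++i) if (stat[i] > 0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });

  std::fill(uf.parent.begin(), uf.parent.end(), -1);
  std::fill(uf.size.begin(), uf.size.end(), 0);
  active.clear();

  size_t next = 0;
  for (int step = nsteps; step >= 1; --step) {
    double h = dh * step;
    // activate voxels with stat >= h and union with active neighbours
    while (next < order.size() && stat[order[next]] >= h) {
      int i = order[next++];
      uf.activate(i);
      active.push_back(i);
      int z = i / (nx * ny), rem = i % (nx * ny);
      int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            int j = (zz * ny + yy) * nx + xx;
            if (j != i && uf.active(j)) uf.unite(i, j);
          }
        }
      }
    }
    double hH = std::pow(h, H) * dh;
    for (int idx : active) {
      int root = uf.find(idx);
      out[idx] += std::pow((double)uf.size[root], E) * hH;
    }
  }
}

// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims, double E,
                       double H, double dh, int nsteps_default = 100) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int v = nx * ny * nz;
  if (stat.size() != v) stop("stat length does not match dims");
  NumericVector out(v);
  std::vector<double> s(v);
  for (int i = 0; i < v; ++i) s[i] = stat[i] > 0 ? stat[i] : 0.0;
  std::vector<int> order; order.reserve(v);
  UF uf(v);
  std::vector<int> active; active.reserve(v);
  tfce_one(s.data(), nx, ny, nz, E, H, dh, nsteps_default, REAL(out), order,
           uf, active);
  return out;
}

// Max TFCE statistic per permutation, both signs.
// maps: n x v (subjects x voxels, full grid, out-of-mask columns zero);
// bperm: n x nperm matrix of permuted behaviour vectors.
// Returns nperm x 2 matrix of (max TFCE of +t map, max TFCE of -t map).
// [[Rcpp::export]]
NumericMatrix perm_max_tfce_cpp(NumericMatrix maps, NumericMatrix bperm,
                                IntegerVector dims, double E, double H,
                                int nsteps = 100) {
  int n = maps.nrow(), v = maps.ncol(), nperm = bperm.ncol();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  if (v != nx * ny * nz) stop("maps width does not match dims");

  // centre columns, precompute norms
  std::vector<double> M(n * (size_t)v);
  std::vector<double> cnorm(v);
  for (int j = 0; j < v; ++j) {
    double m = 0;
    for (int i = 0; i < n; ++i) m += maps(i, j);
    m /= n;
    double ss = 0;
    for (int i = 0; i < n; ++i) {
      double c = maps(i, j) - m;
      M[(size_t)j * n + i] = c;
      ss += c * c;
    }
    cnorm[j] = std::sqrt(ss);
  }

  NumericMatrix out(nperm, 2);
  std::vector<double> tmap(v), tneg(v), enh(v);
  std::vector<int> order; order.reserve(v);
  UF uf(v);
  std::vector<int> active; active.reserve(v);
  std::vector<double> b(n);

  for (int p = 0; p < nperm; ++p) {
    double bm = 0;
    for (int i = 0; i < n; ++i) bm += bperm(i, p);
    bm /= n;
    double bss = 0;
    for (int i = 0; i < n; ++i) { b[i] = bperm(i, p) - bm; bss += b[i] * b[i]; }
    double bn = std::sqrt(bss);
    for (int j = 0; j < v; ++j) {
      double dot = 0;
      const double *col = &M[(size_t)j * n];
      for (int i = 0; i < n; ++i) dot += col[i] * b[i];
      double denom = cnorm[j] * bn;
      double t = 0;
      if (denom > 0) {
        double r = dot / denom;
        if (r > 0.999999999) r = 0.999999999;
        if (r < -0.999999999) r = -0.999999999;
        t = r * std::sqrt((n - 2) / (1.0 - r * r));
      }
      tmap[j] = t > 0 ? t : 0.0;
      tneg[j] = t < 0 ? -t : 0.0;
    }
    tfce_one(tmap.data(), nx, ny, nz, E, H, 0.0, nsteps, enh.data(), order, uf, active);
    double mx = 0;
    for (int j = 0; j < v; ++j) if (enh[j] > mx) mx = enh[j];
    out(p, 0) = mx;
    tfce_one(tneg.data(), nx, ny, nz, E, H, 0.0, nsteps, enh.data(), order, uf, active);
    mx = 0;
    for (int j = 0; j < v; ++j) if (enh[j] > mx) mx = enh[j];
    out(p, 1) = mx;
    if (p % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
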