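#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays with dim = (nz, ny, nx); linear index (0-based here)
// is i = z + nz*(y + ny*x), i.e. R's column-major order.

struct Offsets {
  std::vector<int> dz, dy, dx;
};

// Neighbor stencils: 6 = faces, 18 = faces + edges, 26 = full cube shell.
static Offsets make_offsets(int conn) {
  Offsets o;
  for (int x = -1; x <= 1; ++x)
    for (int y = -1; y <= 1; ++y)
      for (int z = -1; z <= 1; ++z) {
        int l1 = std::abs(x) + std::abs(y) + std::abs(z);
        if (l1 == 0) continue;
        if ((conn == 6 && l1 > 1) || (conn == 18 && l1 > 2)) continue;
        o.dz.push_back(z); o.dy.push_back(y); o.dx.push_back(x);
      }
  return o;
}

struct UF {
  std::vector<int> parent;
  int make() { parent.push_back((int)parent.size()); return (int)parent.size() - 1; }
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  void link(int a, int b) { parent[find(a)] = find(b); } // a absorbed into b
};

// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector fg, IntegerVector dim, int conn) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = fg.size();
  Offsets off = make_offsets(conn);
  const int no = (int)off.dz.size();
  IntegerVector lab(n, 0);
  UF uf;
  std::vector<int> comp(n, -1);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (!fg[i]) continue;
        int own = -1;
        for (int k = 0; k < no; ++k) {
          int zz = z + off.dz[k], yy = y + off.dy[k], xx = x + off.dx[k];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
          if (!fg[j] || comp[j] < 0) continue;
          if (own < 0) own = uf.find(comp[j]);
          else uf.link(comp[j], own);
        }
        if (own < 0) own = uf.make();
        comp[i] = own;
      }
  // relabel 1..K in order of first appearance along the linear index
  std::vector<int> newlab(uf.parent.size(), 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (comp[i] < 0) continue;
    int r = uf.find(comp[i]);
    if (newlab[r] == 0) newlab[r] = ++next;
    lab[i] = newlab[r];
  }
  return lab;
}

// 1D squared-distance transform (lower envelope of parabolas), spacing s.
// Infinite parabolas (no source on this line yet) never enter the envelope.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double sq = (double)q * s;
    double inter = -INF;
    while (k >= 0) {
      double sp = (double)v[k] * s;
      inter = ((f[q] + sq * sq) - (f[v[k]] + sp * sp)) / (2 * sq - 2 * sp);
      if (k >= 1 && inter <= zb[k]) --k; else break;
    }
    if (k < 0) { k = 0; v[0] = q; zb[0] = -INF; zb[1] = INF; }
    else { ++k; v[k] = q; zb[k] = inter; zb[k + 1] = INF; }
  }
  if (k < 0) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (zb[j + 1] < sq) ++j;
    double sp = (double)v[j] * s;
    d[q] = (sq - sp) * (sq - sp) + f[v[j]];
  }
}

// Exact squared Euclidean distance to the nearest background voxel.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector fg, IntegerVector dim, NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  R_xlen_t n = fg.size();
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = fg[i] ? INF : 0.0;
  std::vector<double> f, g;
  // pass along z (stride 1)
  f.resize(nz); g.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) f[z] = d[base + z];
      dt1d(f, g, nz, spacing[0]);
      for (int z = 0; z < nz; ++z) d[base + z] = g[z];
    }
  // pass along y
  f.resize(ny); g.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = d[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
      dt1d(f, g, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) d[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = g[y];
    }
  // pass along x
  f.resize(nx); g.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = d[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
      dt1d(f, g, nx, spacing[2]);
      for (int x = 0; x < nx; ++x) d[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = g[x];
    }
  return d;
}

// Contour-tree region growing with persistence merging.
// Sweep foreground voxels in decreasing value order (ties: ascending linear
// index). A voxel with no labeled neighbor founds a region recording its peak;
// at a saddle every adjacent region with (peak - value) < thr — or with zero
// persistence, which marks plateau fragments — is merged into the adjacent
// region of globally highest peak; the voxel joins the surviving adjacent
// region of highest peak.
// [[Rcpp::export]]
IntegerVector ct_sweep_cpp(NumericVector val, LogicalVector fg, IntegerVector dim,
                           int conn, double thr) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = fg.size();
  Offsets off = make_offsets(conn);
  const int no = (int)off.dz.size();

  std::vector<int> idx;
  idx.reserve(n / 2);
  for (R_xlen_t i = 0; i < n; ++i) if (fg[i]) idx.push_back((int)i);
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (val[a] != val[b]) return val[a] > val[b];
    return a < b;
  });

  UF uf;
  std::vector<double> peak;
  std::vector<int> comp(n, -1);
  std::vector<int> roots; roots.reserve(32);

  for (size_t s = 0; s < idx.size(); ++s) {
    int i = idx[s];
    int z = i % nz, rem = i / nz, y = rem % ny, x = rem / ny;
    roots.clear();
    for (int k = 0; k < no; ++k) {
      int zz = z + off.dz[k], yy = y + off.dy[k], xx = x + off.dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (comp[j] < 0) continue;
      int r = uf.find(comp[j]);
      bool seen = false;
      for (int q = 0; q < (int)roots.size(); ++q) if (roots[q] == r) { seen = true; break; }
      if (!seen) roots.push_back(r);
    }
    if (roots.empty()) {
      int r = uf.make();
      peak.push_back(val[i]);
      comp[i] = r;
    } else if (roots.size() == 1) {
      comp[i] = roots[0];
    } else {
      // target: adjacent region with highest peak; ties -> earliest-created id
      int tgt = roots[0];
      for (int q = 1; q < (int)roots.size(); ++q) {
        int r = roots[q];
        if (peak[r] > peak[tgt] || (peak[r] == peak[tgt] && r < tgt)) tgt = r;
      }
      double v = val[i];
      for (int q = 0; q < (int)roots.size(); ++q) {
        int r = roots[q];
        if (r == tgt) continue;
        double pers = peak[r] - v;
        if (pers < thr || pers == 0.0) uf.link(r, tgt);
      }
      comp[i] = tgt;
    }
  }
  IntegerVector lab(n, 0);
  std::vector<int> newlab(uf.parent.size(), 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (comp[i] < 0) continue;
    int r = uf.find(comp[i]);
    if (newlab[r] == 0) newlab[r] = ++next;
    lab[i] = newlab[r];
  }
  return lab;
}

// Plateau-aware local maxima: connected sets of equal value (within the
// foreground) none of whose members has a strictly greater neighbor.
// [[Rcpp::export]]
int local_max_count_cpp(NumericVector val, LogicalVector fg, IntegerVector dim, int conn) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = fg.size();
  Offsets off = make_offsets(conn);
  const int no = (int)off.dz.size();
  UF uf;
  std::vector<int> comp(n, -1);
  std::vector<char> bad; // component has a strictly greater neighbor
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (!fg[i]) continue;
        int own = -1;
        bool greater = false;
        for (int k = 0; k < no; ++k) {
          int zz = z + off.dz[k], yy = y + off.dy[k], xx = x + off.dx[k];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
          double vj = fg[j] ? val[j] : 0.0; // background counts as value 0
          if (vj > val[i]) greater = true;
          if (fg[j] && vj == val[i] && comp[j] >= 0) {
            int r = uf.find(comp[j]);
            if (own < 0) own = r;
            else if (own != r) {
              char b = (bad[own] || bad[r]) ? 1 : 0;
              uf.link(own, r);
              own = uf.find(r);
              bad[own] = b;
            }
          }
        }
        if (own < 0) { own = uf.make(); bad.push_back(0); }
        if (greater) bad[uf.find(own)] = 1;
        comp[i] = uf.find(own);
      }
  // propagate badness to roots
  std::vector<char> rootbad(uf.parent.size(), 0);
  for (size_t r = 0; r < uf.parent.size(); ++r)
    if (bad[r]) rootbad[uf.find((int)r)] = 1;
  std::vector<char> counted(uf.parent.size(), 0);
  int cnt = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (comp[i] < 0) continue;
    int r = uf.find(comp[i]);
    if (!counted[r]) { counted[r] = 1; if (!rootbad[r]) ++cnt; }
  }
  return cnt;
}

// Simulated absorbing walks from one start voxel; returns the step count of
// each walk. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
NumericVector mc_walk_cpp(LogicalVector fg, IntegerVector dim, int conn,
                          bool reflecting, int start, int n_walks, double step_cap) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  Offsets off = make_offsets(conn);
  const int no = (int)off.dz.size();
  NumericVector steps(n_walks);
  RNGScope scope;
  std::vector<int> nbrs(no);
  for (int w = 0; w < n_walks; ++w) {
    int z = start % nz, rem = start / nz, y = rem % ny, x = rem / ny;
    double t = 0;
    while (true) {
      if (t >= step_cap) stop("walk exceeded step cap; background may be unreachable");
      int m = 0;
      int zz = 0, yy = 0, xx = 0;
      if (reflecting) {
        for (int k = 0; k < no; ++k) {
          int az = z + off.dz[k], ay = y + off.dy[k], ax = x + off.dx[k];
          if (az < 0 || az >= nz || ay < 0 || ay >= ny || ax < 0 || ax >= nx) continue;
          nbrs[m++] = k;
        }
        int k = nbrs[(int)std::floor(unif_rand() * m)];
        zz = z + off.dz[k]; yy = y + off.dy[k]; xx = x + off.dx[k];
      } else {
        int k = (int)std::floor(unif_rand() * no);
        zz = z + off.dz[k]; yy = y + off.dy[k]; xx = x + off.dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) {
          steps[w] = t + 1; break; // outside counts as background
        }
      }
      t += 1;
      R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (!fg[j]) { steps[w] = t; break; }
      z = zz; y = yy; x = xx;
    }
  }
  return steps;
}

// Separable Gaussian blur with mirrored boundaries; sigma in voxels.
static void blur_axis(std::vector<double>& a, int n, const std::vector<double>& ker) {
  int r = ((int)ker.size() - 1) / 2;
  std::vector<double> out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int k = -r; k <= r; ++k) {
      int j = i + k;
      if (j < 0) j = -j - 1;           // mirror
      if (j >= n) j = 2 * n - j - 1;
      if (j < 0) j = 0; if (j >= n) j = n - 1; // tiny-n guard
      s += ker[k + r] * a[j];
    }
    out[i] = s;
  }
  a = out;
}

// [[Rcpp::export]]
NumericVector gauss_blur_cpp(NumericVector x, IntegerVector dim, double sigma) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  int r = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> ker(2 * r + 1);
  double tot = 0;
  for (int k = -r; k <= r; ++k) { ker[k + r] = std::exp(-0.5 * k * k / (sigma * sigma)); tot += ker[k + r]; }
  for (auto& v : ker) v /= tot;
  NumericVector d = clone(x);
  std::vector<double> line;
  line.resize(nz);
  for (int xx = 0; xx < nx; ++xx)
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      for (int z = 0; z < nz; ++z) line[z] = d[base + z];
      blur_axis(line, nz, ker);
      for (int z = 0; z < nz; ++z) d[base + z] = line[z];
    }
  line.resize(ny);
  for (int xx = 0; xx < nx; ++xx)
    for (int z = 0; z < nz; ++z) {
      for (int yy = 0; yy < ny; ++yy) line[yy] = d[z + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
      blur_axis(line, ny, ker);
      for (int yy = 0; yy < ny; ++yy) d[z + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)] = line[yy];
    }
  line.resize(nx);
  for (int yy = 0; yy < ny; ++yy)
    for (int z = 0; z < nz; ++z) {
      for (int xx = 0; xx < nx; ++xx) line[xx] = d[z + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
      blur_axis(line, nx, ker);
      for (int xx = 0; xx < nx; ++xx) d[z + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)] = line[xx];
    }
  return d;
}
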