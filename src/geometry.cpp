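#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// Exact nearest-neighbor search between point sets using a uniform grid
// (spatial hash) with expanding-shell scanning. Reference points must be
// supplied sorted by the desired tie-break order (lowest filament rank,
// then lowest point index); on exact distance ties the lowest row wins,
// which reproduces an exhaustive scan in that same order.
//
// qgroup / rgroup are integer group ids; a reference point is ignored when
// its group equals the query's group (self-filament exclusion). Use a
// query group absent from rgroup to disable exclusion.
// [[Rcpp::export]]
List cpp_nn_points(NumericMatrix q, IntegerVector qgroup,
                   NumericMatrix r, IntegerVector rgroup) {
  const int nq = q.nrow(), nr = r.nrow();
  NumericVector dist(nq);
  IntegerVector idx(nq);
  if (nr == 0) {
    std::fill(dist.begin(), dist.end(), NA_REAL);
    std::fill(idx.begin(), idx.end(), NA_INTEGER);
    return List::create(_["distance"] = dist, _["index"] = idx);
  }

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = std::numeric_limits<double>::infinity();
    hi[d] = -std::numeric_limits<double>::infinity();
  }
  for (int i = 0; i < nr; ++i)
    for (int d = 0; d < 3; ++d) {
      if (r(i, d) < lo[d]) lo[d] = r(i, d);
      if (r(i, d) > hi[d]) hi[d] = r(i, d);
    }
  // target ~2 points per cell, using only axes with real extent (points may
  // be coplanar or collinear); cap the total grid size
  double ext[3], vol = 1.0;
  int ndim = 0;
  for (int d = 0; d < 3; ++d) {
    ext[d] = hi[d] - lo[d];
    if (ext[d] > 1e-9) {
      vol *= ext[d];
      ++ndim;
    }
  }
  double cell = (ndim > 0) ? std::pow(2.0 * vol / nr, 1.0 / ndim) : 1.0;
  if (!(cell > 0) || !std::isfinite(cell)) cell = 1.0;
  int nc[3];
  for (;;) {
    double ncell_d = 1.0;
    for (int d = 0; d < 3; ++d) {
      nc[d] = std::max(1, std::min(256, (int)std::floor(ext[d] / cell) + 1));
      ncell_d *= nc[d];
    }
    if (ncell_d <= 2097152.0) break;
    cell *= 2.0;
  }
  // effective cell size per axis must cover the extent; the shell-distance
  // bound can only use axes along which the grid actually extends
  double cs[3];
  for (int d = 0; d < 3; ++d) cs[d] = std::max(ext[d] / nc[d], 1e-12);
  double csmin = std::numeric_limits<double>::infinity();
  for (int d = 0; d < 3; ++d)
    if (nc[d] > 1) csmin = std::min(csmin, cs[d]);
  bool single_cell = !std::isfinite(csmin);

  auto cellof = [&](double x, int d) {
    int c = (int)std::floor((x - lo[d]) / cs[d]);
    if (c < 0) c = 0;
    if (c >= nc[d]) c = nc[d] - 1;
    return c;
  };
  const int ncell = nc[0] * nc[1] * nc[2];
  std::vector<std::vector<int> > bins(ncell);
  for (int i = 0; i < nr; ++i) {
    int cx = cellof(r(i, 0), 0), cy = cellof(r(i, 1), 1), cz = cellof(r(i, 2), 2);
    bins[cx + nc[0] * (cy + nc[1] * cz)].push_back(i);
  }
  const int maxshell = std::max(nc[0], std::max(nc[1], nc[2]));

  for (int i = 0; i < nq; ++i) {
    const double px = q(i, 0), py = q(i, 1), pz = q(i, 2);
    const int g = qgroup[i];
    int cx = cellof(px, 0), cy = cellof(py, 1), cz = cellof(pz, 2);
    double best = std::numeric_limits<double>::infinity();
    int besti = -1;
    for (int s = 0; s <= maxshell; ++s) {
      // stop once every unscanned cell is strictly farther than the best hit
      if (s > 0 && single_cell) break;
      if (besti >= 0 && (double)(s - 1) * csmin > std::sqrt(best)) break;
      bool any = false;
      int x0 = cx - s, x1 = cx + s, y0 = cy - s, y1 = cy + s, z0 = cz - s, z1 = cz + s;
      for (int x = x0; x <= x1; ++x) {
        if (x < 0 || x >= nc[0]) continue;
        for (int y = y0; y <= y1; ++y) {
          if (y < 0 || y >= nc[1]) continue;
          for (int z = z0; z <= z1; ++z) {
            if (z < 0 || z >= nc[2]) continue;
            // only the new shell surface
            if (s > 0 && x != x0 && x != x1 && y != y0 && y != y1 && z != z0 && z != z1)
              continue;
            any = true;
            const std::vector<int>& b = bins[x + nc[0] * (y + nc[1] * z)];
            for (size_t k = 0; k < b.size(); ++k) {
              int j = b[k];
              if (rgroup[j] == g) continue;
              double dx = r(j, 0) - px, dy = r(j, 1) - py, dz = r(j, 2) - pz;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best || (d2 == best && j < besti)) {
                best = d2;
                besti = j;
              }
            }
          }
        }
      }
      if (!any && s > 0 && (x0 < 0 || x1 >= nc[0]) && (y0 < 0 || y1 >= nc[1]) &&
          (z0 < 0 || z1 >= nc[2]) && besti >= 0)
        break;
    }
    if (besti < 0) {
      dist[i] = NA_REAL;
      idx[i] = NA_INTEGER;
    } else {
      dist[i] = std::sqrt(best);
      idx[i] = besti + 1;  // 1-based for R
    }
  }
  return List::create(_["distance"] = dist, _["index"] = idx);
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), helper for
// the separable 3D transform below. f holds squared distances, INF where
// no feature; d receives the transformed values.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  // lower envelope of parabolas rooted at positions with finite f
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform of a 3D foreground mask: for every
// voxel, squared distance (in voxel units) to the nearest foreground voxel
// center. Returns distances in voxel units (caller scales by voxel size).
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector fg, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = fg[i] ? 0.0 : INF;

  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (fastest-varying)
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      R_xlen_t base = (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
      for (int i = 0; i < d1; ++i) f[i] = g[base + i];
      dt1d(f, dd, d1, v, z);
      for (int i = 0; i < d1; ++i) g[base + i] = dd[i];
    }
  // axis 2
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = i + (R_xlen_t)d1 * d2 * k;
      for (int j = 0; j < d2; ++j) f[j] = g[base + (R_xlen_t)d1 * j];
      dt1d(f, dd, d2, v, z);
      for (int j = 0; j < d2; ++j) g[base + (R_xlen_t)d1 * j] = dd[j];
    }
  // axis 3
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = i + (R_xlen_t)d1 * j;
      R_xlen_t stride = (R_xlen_t)d1 * d2;
      for (int k = 0; k < d3; ++k) f[k] = g[base + stride * k];
      dt1d(f, dd, d3, v, z);
      for (int k = 0; k < d3; ++k) g[base + stride * k] = dd[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// 26-connected component labeling of a 3D mask (BFS flood fill).
// Labels are assigned in raster-scan order of the first voxel encountered.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector fg, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!fg[s] || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = cur % d1, j = (cur / d1) % d2, k = cur / ((R_xlen_t)d1 * d2);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
            R_xlen_t t = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
            if (fg[t] && lab[t] == 0) {
              lab[t] = next;
              stack.push_back(t);
            }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Foreground voxels that touch background via a 6-neighbor (or the array
// edge): the mask's surface voxels. Returns 0-based (i, j, k) indices.
// [[Rcpp::export]]
IntegerMatrix cpp_boundary_voxels(LogicalVector fg, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  std::vector<int> out;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t s = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        if (!fg[s]) continue;
        bool b = (i == 0 || i == d1 - 1 || j == 0 || j == d2 - 1 || k == 0 || k == d3 - 1);
        if (!b) {
          if (!fg[s - 1] || !fg[s + 1] || !fg[s - d1] || !fg[s + d1] ||
              !fg[s - (R_xlen_t)d1 * d2] || !fg[s + (R_xlen_t)d1 * d2])
            b = true;
        }
        if (b) {
          out.push_back(i);
          out.push_back(j);
          out.push_back(k);
        }
      }
  int m = out.size() / 3;
  IntegerMatrix res(m, 3);
  for (int i = 0; i < m; ++i) {
    res(i, 0) = out[3 * i];
    res(i, 1) = out[3 * i + 1];
    res(i, 2) = out[3 * i + 2];
  }
  return res;
}

// Zhang-Suen morphological thinning of a binary matrix to a 1-pixel
// skeleton (8-connectivity preserved).
// [[Rcpp::export]]
LogicalMatrix cpp_thin2d(LogicalMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix a = clone(img);
  std::vector<std::pair<int, int> > kill;
  bool changed = true;
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return a(r, c) ? 1 : 0;
  };
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int r = 0; r < nr; ++r)
        for (int c = 0; c < nc; ++c) {
          if (!a(r, c)) continue;
          int p[8] = {at(r - 1, c), at(r - 1, c + 1), at(r, c + 1), at(r + 1, c + 1),
                      at(r + 1, c), at(r + 1, c - 1), at(r, c - 1), at(r - 1, c - 1)};
          int B = 0;
          for (int t = 0; t < 8; ++t) B += p[t];
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int t = 0; t < 8; ++t)
            if (p[t] == 0 && p[(t + 1) % 8] == 1) ++A;
          if (A != 1) continue;
          if (step == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      if (!kill.empty()) changed = true;
      for (size_t t = 0; t < kill.size(); ++t) a(kill[t].first, kill[t].second) = false;
    }
  }
  return a;
}

// Gaussian product-kernel density evaluated at each data point (and at
// optional probe points), after the caller has standardized the axes.
// h is the common bandwidth on the standardized scale.
// [[Rcpp::export]]
NumericVector cpp_kde2d_at(NumericVector x, NumericVector y,
                           NumericVector px, NumericVector py, double h) {
  const int n = x.size(), m = px.size();
  NumericVector out(m);
  const double norm = 1.0 / (n * 2.0 * M_PI * h * h);
  const double inv2h2 = 1.0 / (2.0 * h * h);
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      double dx = px[i] - x[j], dy = py[i] - y[j];
      s += std::exp(-(dx * dx + dy * dy) * inv2h2);
    }
    out[i] = s * norm;
  }
  return out;
}
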