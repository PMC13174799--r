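// Low-level volumetric kernels. All 3D arrays use R's column-major layout
// with dim = c(nz, ny, nx): linear index = z + nz*(y + ny*x), 0-based here.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// Connected-component labeling of a binary volume (BFS flood fill).
// connectivity: 6 (faces) or 26 (faces+edges+corners). Labels are assigned
// in scan order; relabeling by size happens on the R side.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);

  std::vector<std::array<int,3>> nbr;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        nbr.push_back({dz, dy, dx});
      }

  int next = 0;
  std::queue<std::array<int,3>> q;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!mask[i] || labels[i]) continue;
        labels[i] = ++next;
        q.push({z, y, x});
        while (!q.empty()) {
          auto p = q.front(); q.pop();
          for (auto &d : nbr) {
            int zz = p[0] + d[0], yy = p[1] + d[1], xx = p[2] + d[2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t j = idx3(zz, yy, xx, nz, ny);
            if (mask[j] && !labels[j]) { labels[j] = next; q.push({zz, yy, xx}); }
          }
        }
      }
  return labels;
}

// Naive surface nets iso-surfacing. One vertex per grid cell crossed by the
// iso-surface, placed at the centroid of the cell's edge crossings; one quad
// (two triangles) per sign-changing grid edge, wound so that, after the
// caller's global orientation fix, the enclosed volume is positive. The
// caller must zero-pad the volume so no crossing touches the array border;
// the mesh is then closed by construction.
// Vertex coordinates are in 0-based sample-index units (z, y, x).
// [[Rcpp::export]]
List cpp_surface_nets(NumericVector vol, IntegerVector dims, double level) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int cz = nz - 1, cy = ny - 1, cx = nx - 1;

  auto inside = [&](int z, int y, int x) {
    return vol[idx3(z, y, x, nz, ny)] >= level;
  };

  // cube corners as (dz, dy, dx) and the 12 cube edges between them
  static const int CORN[8][3] = {
    {0,0,0},{0,0,1},{0,1,0},{0,1,1},{1,0,0},{1,0,1},{1,1,0},{1,1,1}};
  static const int EDGE[12][2] = {
    {0,1},{0,2},{0,4},{1,3},{1,5},{2,3},{2,6},{3,7},{4,5},{4,6},{5,7},{6,7}};

  std::vector<int> cellv((R_xlen_t)cz * cy * cx, -1);
  std::vector<double> vz, vy, vx;
  auto cidx = [&](int z, int y, int x) {
    return (R_xlen_t)z + (R_xlen_t)cz * ((R_xlen_t)y + (R_xlen_t)cy * (R_xlen_t)x);
  };

  for (int x = 0; x < cx; ++x)
    for (int y = 0; y < cy; ++y)
      for (int z = 0; z < cz; ++z) {
        double cv[8];
        int nin = 0;
        for (int k = 0; k < 8; ++k) {
          cv[k] = vol[idx3(z + CORN[k][0], y + CORN[k][1], x + CORN[k][2], nz, ny)];
          if (cv[k] >= level) ++nin;
        }
        if (nin == 0 || nin == 8) continue;
        double sz = 0, sy = 0, sx = 0; int m = 0;
        for (int e = 0; e < 12; ++e) {
          int a = EDGE[e][0], b = EDGE[e][1];
          bool ia = cv[a] >= level, ib = cv[b] >= level;
          if (ia == ib) continue;
          double t = (level - cv[a]) / (cv[b] - cv[a]);
          sz += z + CORN[a][0] + t * (CORN[b][0] - CORN[a][0]);
          sy += y + CORN[a][1] + t * (CORN[b][1] - CORN[a][1]);
          sx += x + CORN[a][2] + t * (CORN[b][2] - CORN[a][2]);
          ++m;
        }
        cellv[cidx(z, y, x)] = (int)vz.size();
        vz.push_back(sz / m); vy.push_back(sy / m); vx.push_back(sx / m);
      }

  // (axis, o1, o2) right-handed in (z,y,x) index space
  static const int OTH[3][2] = {{1,2},{2,0},{0,1}};
  std::vector<int> f1, f2, f3;
  int dimn[3] = {nz, ny, nx};
  for (int axis = 0; axis < 3; ++axis) {
    int d[3] = {0,0,0}; d[axis] = 1;
    int o1[3] = {0,0,0}; o1[OTH[axis][0]] = 1;
    int o2[3] = {0,0,0}; o2[OTH[axis][1]] = 1;
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          int p[3] = {z, y, x};
          int q[3] = {z + d[0], y + d[1], x + d[2]};
          if (q[0] >= dimn[0] || q[1] >= dimn[1] || q[2] >= dimn[2]) continue;
          bool v0 = inside(p[0], p[1], p[2]);
          bool v1 = inside(q[0], q[1], q[2]);
          if (v0 == v1) continue;
          int ids[4]; bool ok = true;
          int cells[4][3];
          for (int k = 0; k < 3; ++k) {
            cells[0][k] = p[k];
            cells[1][k] = p[k] - o1[k];
            cells[2][k] = p[k] - o1[k] - o2[k];
            cells[3][k] = p[k] - o2[k];
          }
          for (int c = 0; c < 4; ++c) {
            int* cc = cells[c];
            if (cc[0] < 0 || cc[1] < 0 || cc[2] < 0 ||
                cc[0] >= cz || cc[1] >= cy || cc[2] >= cx) { ok = false; break; }
            ids[c] = cellv[cidx(cc[0], cc[1], cc[2])];
            if (ids[c] < 0) { ok = false; break; }
          }
          if (!ok) continue;  // crossing at border: caller failed to pad
          if (v0) { std::swap(ids[0], ids[3]); std::swap(ids[1], ids[2]); }
          f1.push_back(ids[0] + 1); f2.push_back(ids[1] + 1); f3.push_back(ids[2] + 1);
          f1.push_back(ids[0] + 1); f2.push_back(ids[2] + 1); f3.push_back(ids[3] + 1);
        }
  }

  int nv = (int)vz.size(), nf = (int)f1.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i,0) = vz[i]; V(i,1) = vy[i]; V(i,2) = vx[i]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) { F(i,0) = f1[i]; F(i,1) = f2[i]; F(i,2) = f3[i]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Separable 1D convolution along one axis (0 = z, 1 = y, 2 = x) with
// reflected (mirror) boundary, so a normalized kernel preserves constants.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector arr, IntegerVector dims,
                                NumericVector kernel, int axis) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int nk = kernel.size(), half = nk / 2;
  int n[3] = {nz, ny, nx};
  int na = n[axis];
  NumericVector out((R_xlen_t)nz * ny * nx);

  auto reflect = [&](int i) {
    while (i < 0 || i >= na) {
      if (i < 0) i = -i - 1;
      if (i >= na) i = 2 * na - i - 1;
    }
    return i;
  };

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int p[3] = {z, y, x};
        double s = 0;
        for (int k = 0; k < nk; ++k) {
          int q[3] = {p[0], p[1], p[2]};
          q[axis] = reflect(p[axis] + k - half);
          s += kernel[k] * arr[idx3(q[0], q[1], q[2], nz, ny)];
        }
        out[idx3(z, y, x, nz, ny)] = s;
      }
  return out;
}

// Felzenszwalb-Huttenlocher 1D squared distance transform
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact 2D squared Euclidean distance transform (in pixel units) to the
// nearest FALSE pixel; pixels outside the image count as FALSE only if the
// caller pads. Input/output are nr x nc matrices.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq_2d(LogicalMatrix inside) {
  int nr = inside.nrow(), nc = inside.ncol();
  const double INF = 1e20;
  NumericMatrix D(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      D(i, j) = inside(i, j) ? INF : 0.0;

  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {           // along rows (within a column)
    for (int i = 0; i < nr; ++i) f[i] = D(i, j);
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) D(i, j) = d[i];
  }
  for (int i = 0; i < nr; ++i) {           // along columns
    for (int j = 0; j < nc; ++j) f[j] = D(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) D(i, j) = d[j];
  }
  return D;
}

// Grayscale erosion (dilate = false) or dilation (dilate = true) with an
// arbitrary structuring element given as K x 3 integer offsets (dz, dy, dx).
// Out-of-bounds neighbors are ignored (structuring element clipped at the
// border).
// [[Rcpp::export]]
NumericVector cpp_gray_morph(NumericVector arr, IntegerVector dims,
                             IntegerMatrix offsets, bool dilate) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int K = offsets.nrow();
  NumericVector out((R_xlen_t)nz * ny * nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double best = dilate ? -std::numeric_limits<double>::infinity()
                             :  std::numeric_limits<double>::infinity();
        for (int k = 0; k < K; ++k) {
          int zz = z + offsets(k, 0), yy = y + offsets(k, 1), xx = x + offsets(k, 2);
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          double v = arr[idx3(zz, yy, xx, nz, ny)];
          if (dilate ? (v > best) : (v < best)) best = v;
        }
        out[idx3(z, y, x, nz, ny)] = best;
      }
  return out;
}
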