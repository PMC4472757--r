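#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Voxel grids are column-major (R order): linear = i + nx*(j + ny*k), 0-based here.

// Partial-volume occupancy of a tube with varying radius along a densely
// sampled centerline (arc step <= half voxel). The solid is the generalized
// surface of revolution: a point is inside when its distance to the nearest
// centerline sample (the foot point) is within that sample's radius. A
// union-of-spheres model would bulge at stenoses, where wide neighbouring
// spheres poke into the throat. Voxels deeper than half the voxel diagonal
// are classified whole; boundary voxels are supersampled 3x3x3.
// [[Rcpp::export]]
NumericVector cpp_fill_occupancy(IntegerVector dim, NumericVector spacing,
                                 NumericVector origin, NumericMatrix cl,
                                 NumericVector rad, int win) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  const int ns = cl.nrow();
  const double hd = 0.5 * std::sqrt(sx * sx + sy * sy + sz * sz);
  const double margin = 2.0 * hd + std::max(sx, std::max(sy, sz));

  std::vector<double> sd(nv, std::numeric_limits<double>::infinity());
  std::vector<int> ni(nv, -1);

  // stamp: record min distance to the centerline samples and the foot index
  for (int s = 0; s < ns; ++s) {
    const double cx = cl(s, 0), cy = cl(s, 1), cz = cl(s, 2), r = rad[s];
    const double rr = r + margin;
    int i0 = (int)std::ceil((cx - rr - ox) / sx), i1 = (int)std::floor((cx + rr - ox) / sx);
    int j0 = (int)std::ceil((cy - rr - oy) / sy), j1 = (int)std::floor((cy + rr - oy) / sy);
    int k0 = (int)std::ceil((cz - rr - oz) / sz), k1 = (int)std::floor((cz + rr - oz) / sz);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    for (int k = k0; k <= k1; ++k) {
      const double dz = oz + k * sz - cz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = oy + j * sy - cy;
        const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          const double dx = ox + i * sx - cx;
          const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d < sd[base + i]) { sd[base + i] = d; ni[base + i] = s; }
        }
      }
    }
  }

  NumericVector occ(nv);
  const double sub[3] = {-1.0 / 3.0, 0.0, 1.0 / 3.0};
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t v = base + i;
        if (ni[v] < 0) { occ[v] = 0.0; continue; }
        const double d = sd[v] - rad[ni[v]]; // signed radial distance at the foot
        if (d >= hd) { occ[v] = 0.0; continue; }
        if (d <= -hd) { occ[v] = 1.0; continue; }
        // boundary voxel: supersample; foot searched near the stamped index
        const int lo = std::max(0, ni[v] - win), hi = std::min(ns - 1, ni[v] + win);
        const double px = ox + i * sx, py = oy + j * sy, pz = oz + k * sz;
        int inside = 0;
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b)
            for (int c = 0; c < 3; ++c) {
              const double qx = px + sub[a] * sx, qy = py + sub[b] * sy, qz = pz + sub[c] * sz;
              double best = std::numeric_limits<double>::infinity();
              int foot = lo;
              for (int s = lo; s <= hi; ++s) {
                const double dx = qx - cl(s, 0), dy = qy - cl(s, 1), dz = qz - cl(s, 2);
                const double dd = std::sqrt(dx * dx + dy * dy + dz * dz);
                if (dd < best) { best = dd; foot = s; }
              }
              if (best <= rad[foot]) ++inside;
            }
        occ[v] = inside / 27.0;
      }
    }
  }
  occ.attr("dim") = dim;
  return occ;
}

// 1D lower-envelope squared distance transform (Felzenszwalb & Huttenlocher)
// over sites at real coordinates x[], values f[]. Writes d[] at the same sites.
static void dt1d(const std::vector<double> &x, const std::vector<double> &f,
                 std::vector<double> &d) {
  const int n = (int)x.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int q = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int i = 1; i < n; ++i) {
    if (!std::isfinite(f[i]) && f[i] > 0) continue; // +inf sites never dominate
    double s;
    while (true) {
      const int vi = v[q];
      if (!std::isfinite(f[vi]) && f[vi] > 0) { --q; continue; }
      s = ((f[i] + x[i] * x[i]) - (f[vi] + x[vi] * x[vi])) / (2.0 * x[i] - 2.0 * x[vi]);
      if (s <= z[q]) { --q; } else break;
    }
    ++q; v[q] = i; z[q] = s; z[q + 1] = std::numeric_limits<double>::infinity();
  }
  // handle all-infinite rows
  if (!std::isfinite(f[v[0]]) && q == 0 && f[v[0]] > 0) {
    for (int i = 0; i < n; ++i) d[i] = f[i];
    return;
  }
  int j = 0;
  for (int i = 0; i < n; ++i) {
    while (z[j + 1] < x[i]) ++j;
    const double dx = x[i] - x[v[j]];
    d[i] = dx * dx + f[v[j]];
  }
}

// Anisotropy-aware Euclidean distance (mm) from each foreground voxel to the
// nearest background voxel center; voxels beyond the grid count as background.
// Zero on background voxels.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(nv);
  for (R_xlen_t v = 0; v < nv; ++v) g[v] = mask[v] ? INF : 0.0;

  const int n_ax[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const int n = n_ax[ax];
    const double s = sp[ax];
    // sites: virtual background at -s and n*s emulate out-of-grid background
    std::vector<double> x(n + 2), f(n + 2), d(n + 2);
    x[0] = -s; x[n + 1] = n * s;
    for (int i = 0; i < n; ++i) x[i + 1] = i * s;
    const int a1 = (ax + 1) % 3, a2 = (ax + 2) % 3;
    for (int u = 0; u < n_ax[a1]; ++u)
      for (int w = 0; w < n_ax[a2]; ++w) {
        const R_xlen_t base = (R_xlen_t)u * stride[a1] + (R_xlen_t)w * stride[a2];
        f[0] = 0.0; f[n + 1] = 0.0;
        for (int i = 0; i < n; ++i) f[i + 1] = g[base + (R_xlen_t)i * stride[ax]];
        dt1d(x, f, d);
        for (int i = 0; i < n; ++i) g[base + (R_xlen_t)i * stride[ax]] = d[i + 1];
      }
  }
  NumericVector out(nv);
  for (R_xlen_t v = 0; v < nv; ++v) out[v] = mask[v] ? std::sqrt(g[v]) : 0.0;
  out.attr("dim") = dim;
  return out;
}

// Radius-weighted shortest path over 26-connected mask voxels.
// Edge cost u->v: |step in mm| * (1/r_u + 1/r_v) / 2, symmetric.
// start/end are 0-based linear indices. Ties broken toward smaller voxel index.
// [[Rcpp::export]]
List cpp_trace_path(LogicalVector mask, IntegerVector dim, NumericVector spacing,
                    NumericVector radius, double start_idx, double end_idx) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  const R_xlen_t s0 = (R_xlen_t)start_idx, s1 = (R_xlen_t)end_idx;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(nv, INF);
  std::vector<R_xlen_t> pred(nv, -1);
  std::vector<char> done(nv, 0);
  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[s0] = 0.0;
  pq.push(QE(0.0, s0));

  // precompute neighbor offsets
  int di[26], dj[26], dk[26]; double step[26]; R_xlen_t doff[26];
  int m = 0;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        di[m] = a; dj[m] = b; dk[m] = c;
        step[m] = std::sqrt(a * a * sx * sx + b * b * sy * sy + c * c * sz * sz);
        doff[m] = (R_xlen_t)a + (R_xlen_t)nx * ((R_xlen_t)b + (R_xlen_t)ny * (R_xlen_t)c);
        ++m;
      }

  while (!pq.empty()) {
    const QE top = pq.top(); pq.pop();
    const R_xlen_t u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    if (u == s1) break;
    const int ui = (int)(u % nx), uj = (int)((u / nx) % ny), uk = (int)(u / ((R_xlen_t)nx * ny));
    const double iru = 1.0 / radius[u];
    for (int e = 0; e < 26; ++e) {
      const int vi = ui + di[e], vj = uj + dj[e], vk = uk + dk[e];
      if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz) continue;
      const R_xlen_t v = u + doff[e];
      if (!mask[v] || done[v]) continue;
      const double w = step[e] * 0.5 * (iru + 1.0 / radius[v]);
      const double nd = dist[u] + w;
      if (nd < dist[v] - 1e-15 ||
          (std::abs(nd - dist[v]) <= 1e-15 && pred[v] >= 0 && u < pred[v])) {
        dist[v] = nd; pred[v] = u;
        pq.push(QE(nd, v));
      }
    }
  }

  if (!std::isfinite(dist[s1]))
    return List::create(_["reached"] = false);
  std::vector<double> path;
  for (R_xlen_t v = s1; v != -1; v = pred[v]) path.push_back((double)v);
  std::reverse(path.begin(), path.end());
  return List::create(_["reached"] = true, _["path"] = wrap(path),
                      _["cost"] = dist[s1]);
}

// Separable 1D convolution along one axis (0,1,2) with replicate padding.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector vol, IntegerVector dim,
                                NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n_ax[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int n = n_ax[axis];
  const int kn = kernel.size(), half = kn / 2;
  const int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  NumericVector out(vol.size());
  std::vector<double> line(n);
  for (int u = 0; u < n_ax[a1]; ++u)
    for (int w = 0; w < n_ax[a2]; ++w) {
      const R_xlen_t base = (R_xlen_t)u * stride[a1] + (R_xlen_t)w * stride[a2];
      for (int i = 0; i < n; ++i) line[i] = vol[base + (R_xlen_t)i * stride[axis]];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int t = 0; t < kn; ++t) {
          int j = i + t - half;
          if (j < 0) j = 0; else if (j >= n) j = n - 1;
          acc += kernel[t] * line[j];
        }
        out[base + (R_xlen_t)i * stride[axis]] = acc;
      }
    }
  out.attr("dim") = dim;
  return out;
}

// 26-connected component containing the seed voxel (0-based linear index).
// [[Rcpp::export]]
LogicalVector cpp_flood_fill(LogicalVector mask, IntegerVector dim, double seed_idx) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  LogicalVector out(nv, false);
  std::vector<R_xlen_t> stack;
  const R_xlen_t s = (R_xlen_t)seed_idx;
  if (!mask[s]) return out;
  out[s] = true;
  stack.push_back(s);
  while (!stack.empty()) {
    const R_xlen_t u = stack.back(); stack.pop_back();
    const int ui = (int)(u % nx), uj = (int)((u / nx) % ny), uk = (int)(u / ((R_xlen_t)nx * ny));
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          const int vi = ui + a, vj = uj + b, vk = uk + c;
          if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz) continue;
          const R_xlen_t v = vi + (R_xlen_t)nx * (vj + (R_xlen_t)ny * vk);
          if (mask[v] && !out[v]) { out[v] = true; stack.push_back(v); }
        }
  }
  out.attr("dim") = dim;
  return out;
}

// Sub-voxel elastic-sphere radius: for each path point, slide the sphere
// center over a grid in the plane perpendicular to the local tangent and
// inflate it against background voxel centers. radius = max over centers of
// (distance to nearest background voxel center).
// [[Rcpp::export]]
NumericVector cpp_sphere_radius(LogicalVector mask, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix pts, NumericMatrix tangents,
                                NumericVector r_hint, double max_shift,
                                double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int np = pts.nrow();
  NumericVector out(np);
  std::vector<double> cxs, cys, czs;

  for (int p = 0; p < np; ++p) {
    const double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    const double rup = r_hint[p] + 2.0 * std::max(sx, std::max(sy, sz)) + max_shift;
    // collect background voxel centers within rup of the point
    cxs.clear(); cys.clear(); czs.clear();
    int i0 = std::max(0, (int)std::floor((px - rup - ox) / sx));
    int i1 = std::min(nx - 1, (int)std::ceil((px + rup - ox) / sx));
    int j0 = std::max(0, (int)std::floor((py - rup - oy) / sy));
    int j1 = std::min(ny - 1, (int)std::ceil((py + rup - oy) / sy));
    int k0 = std::max(0, (int)std::floor((pz - rup - oz) / sz));
    int k1 = std::min(nz - 1, (int)std::ceil((pz + rup - oz) / sz));
    const double rup2 = rup * rup;
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j) {
        const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          if (mask[base + i]) continue;
          const double dx = ox + i * sx - px, dy = oy + j * sy - py, dz = oz + k * sz - pz;
          if (dx * dx + dy * dy + dz * dz <= rup2) {
            cxs.push_back(ox + i * sx); cys.push_back(oy + j * sy); czs.push_back(oz + k * sz);
          }
        }
      }
    // grid borders also bound the sphere: clamp rup to distance out of grid
    double border = rup;
    border = std::min(border, (px - (ox - sx)));
    border = std::min(border, ((ox + nx * sx) - px));
    border = std::min(border, (py - (oy - sy)));
    border = std::min(border, ((oy + ny * sy) - py));
    border = std::min(border, (pz - (oz - sz)));
    border = std::min(border, ((oz + nz * sz) - pz));

    // orthonormal basis of the perpendicular plane
    double tx = tangents(p, 0), ty = tangents(p, 1), tz = tangents(p, 2);
    double tn = std::sqrt(tx * tx + ty * ty + tz * tz);
    if (tn < 1e-12) { tx = 1; ty = 0; tz = 0; tn = 1; }
    tx /= tn; ty /= tn; tz /= tn;
    double ax = 0, ay = 0, az = 1;
    if (std::abs(tz) > 0.9) { ax = 1; az = 0; }
    double e1x = ty * az - tz * ay, e1y = tz * ax - tx * az, e1z = tx * ay - ty * ax;
    double e1n = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
    e1x /= e1n; e1y /= e1n; e1z /= e1n;
    const double e2x = ty * e1z - tz * e1y, e2y = tz * e1x - tx * e1z, e2z = tx * e1y - ty * e1x;

    double best = 0.0;
    const int ng = (int)std::floor(max_shift / step + 1e-9);
    for (int ga = -ng; ga <= ng; ++ga)
      for (int gb = -ng; gb <= ng; ++gb) {
        const double a = ga * step, b = gb * step;
        const double qx = px + a * e1x + b * e2x;
        const double qy = py + a * e1y + b * e2y;
        const double qz = pz + a * e1z + b * e2z;
        double rmin = border - std::sqrt(a * a + b * b); // grid-edge bound
        if (rmin < 0) rmin = 0;
        for (size_t c = 0; c < cxs.size(); ++c) {
          const double dx = cxs[c] - qx, dy = cys[c] - qy, dz = czs[c] - qz;
          const double dd = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (dd < rmin) rmin = dd;
          if (rmin <= best) break;
        }
        if (rmin > best) best = rmin;
      }
    out[p] = best;
  }
  return out;
}
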