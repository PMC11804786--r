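// Voxel utilities: 6-connected flood fill (pore reachability from the domain
// boundary) and RK4 streamline tracing with trilinear velocity interpolation.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
LogicalVector flood_from_boundary_cpp(LogicalVector open, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ncell = (R_xlen_t)nx * ny * nz;
  std::vector<char> vis(ncell, 0);
  std::queue<R_xlen_t> q;
  auto idx = [nx, ny](int x, int y, int z) -> R_xlen_t {
    return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
  };
  auto push = [&](int x, int y, int z) {
    R_xlen_t c = idx(x, y, z);
    if (open[c] && !vis[c]) { vis[c] = 1; q.push(c); }
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) { push(0, y, z); push(nx-1, y, z); }
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) { push(x, 0, z); push(x, ny-1, z); }
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) { push(x, y, 0); push(x, y, nz-1); }
  const int DX[6] = {1,-1,0,0,0,0}, DY[6] = {0,0,1,-1,0,0}, DZ[6] = {0,0,0,0,1,-1};
  while (!q.empty()) {
    R_xlen_t c = q.front(); q.pop();
    int z = (int)(c / ((R_xlen_t)nx*ny));
    int r = (int)(c % ((R_xlen_t)nx*ny));
    int y = r / nx, x = r % nx;
    for (int k = 0; k < 6; ++k) {
      int xn = x + DX[k], yn = y + DY[k], zn = z + DZ[k];
      if (xn < 0 || xn >= nx || yn < 0 || yn >= ny || zn < 0 || zn >= nz) continue;
      push(xn, yn, zn);
    }
  }
  LogicalVector out(ncell);
  for (R_xlen_t c = 0; c < ncell; ++c) out[c] = (vis[c] != 0);
  return out;
}

// Trilinear interpolation of a vector field stored at voxel centres
// (integer coordinates 0..n-1); outside the grid the velocity is zero.
static inline void interp3(const double* ux, const double* uy, const double* uz,
                           int nx, int ny, int nz,
                           double px, double py, double pz, double* out) {
  out[0] = out[1] = out[2] = 0.0;
  if (px < 0 || py < 0 || pz < 0 || px > nx-1 || py > ny-1 || pz > nz-1) return;
  int x0 = (int)std::floor(px); if (x0 > nx-2) x0 = nx-2;
  int y0 = (int)std::floor(py); if (y0 > ny-2) y0 = ny-2;
  int z0 = (int)std::floor(pz); if (z0 > nz-2) z0 = nz-2;
  double fx = px - x0, fy = py - y0, fz = pz - z0;
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        double w = (dx ? fx : 1-fx) * (dy ? fy : 1-fy) * (dz ? fz : 1-fz);
        if (w == 0.0) continue;
        R_xlen_t c = (R_xlen_t)(x0+dx) + (R_xlen_t)nx*((R_xlen_t)(y0+dy) + (R_xlen_t)ny*(z0+dz));
        out[0] += w * ux[c]; out[1] += w * uy[c]; out[2] += w * uz[c];
      }
}

// Fixed-arc-length RK4 streamline integration through a steady field.
// Positions are in voxel coordinates; velocities keep the field's units.
// Termination codes: 1 left domain, 2 stagnation, 3 max steps.
// [[Rcpp::export]]
List trace_streamlines_cpp(NumericVector ux, NumericVector uy, NumericVector uz,
                           IntegerVector dims, NumericMatrix starts,
                           double step, int max_steps, double stag_speed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* pux = REAL(ux); const double* puy = REAL(uy);
  const double* puz = REAL(uz);
  const int nstart = starts.nrow();
  List paths(nstart);
  IntegerVector code(nstart);
  for (int s = 0; s < nstart; ++s) {
    std::vector<double> rec; rec.reserve(600);
    double p[3] = {starts(s,0), starts(s,1), starts(s,2)};
    int why = 3;
    double v[3], k1[3], k2[3], k3[3], k4[3];
    for (int it = 0; it < max_steps; ++it) {
      interp3(pux, puy, puz, nx, ny, nz, p[0], p[1], p[2], v);
      double spd = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
      rec.push_back(p[0]); rec.push_back(p[1]); rec.push_back(p[2]);
      rec.push_back(v[0]); rec.push_back(v[1]); rec.push_back(v[2]);
      if (spd < stag_speed) { why = 2; break; }
      for (int d = 0; d < 3; ++d) k1[d] = v[d] / spd;
      double q[3];
      bool out = false, stalled = false;
      auto stage = [&](const double* kin, double frac, double* kout) {
        for (int d = 0; d < 3; ++d) q[d] = p[d] + frac*step*kin[d];
        if (q[0] < 0 || q[1] < 0 || q[2] < 0 ||
            q[0] > nx-1 || q[1] > ny-1 || q[2] > nz-1) { out = true; return; }
        interp3(pux, puy, puz, nx, ny, nz, q[0], q[1], q[2], v);
        double s = std::sqrt(v[0]*v[0]+v[1]*v[1]+v[2]*v[2]);
        if (s < stag_speed) { stalled = true; return; }
        for (int d = 0; d < 3; ++d) kout[d] = v[d] / s;
      };
      stage(k1, 0.5, k2);
      if (!out && !stalled) stage(k2, 0.5, k3);
      if (!out && !stalled) stage(k3, 1.0, k4);
      if (out) { why = 1; break; }
      if (stalled) { why = 2; break; }
      for (int d = 0; d < 3; ++d)
        p[d] += step * (k1[d] + 2*k2[d] + 2*k3[d] + k4[d]) / 6.0;
      if (p[0] < 0 || p[1] < 0 || p[2] < 0 ||
          p[0] > nx-1 || p[1] > ny-1 || p[2] > nz-1) { why = 1; break; }
    }
    const int npt = (int)(rec.size() / 6);
    NumericMatrix m(npt, 6);
    for (int r = 0; r < npt; ++r)
      for (int ccol = 0; ccol < 6; ++ccol) m(r, ccol) = rec[(size_t)r*6 + ccol];
    paths[s] = m;
    code[s] = why;
  }
  return List::create(_["paths"] = paths, _["code"] = code);
}
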