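// D3Q19 single-relaxation-time (BGK) lattice-Boltzmann kernel.
//
// Lattice units: dx = dt = 1, c_s^2 = 1/3.  The R layer owns the conversion
// to physical units.  Two boundary set-ups are supported:
//   bc_mode = 0  fully periodic box (solid voxels still bounce back)
//   bc_mode = 1  "seabed channel": inlet velocity profile at x = 0, fixed
//                density outlet at x = nx-1, periodic in y, half-way
//                bounce-back seabed below z = 0, specular free-slip
//                reflection above z = nz-1.
//   bc_mode = 2  like 1 in z (seabed + free surface) but periodic in x,
//                no inlet/outlet; flow driven by the body force.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int EX[19] = {0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0};
static const int EY[19] = {0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1};
static const int EZ[19] = {0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1};
static const double WT[19] = {
  1.0/3,
  1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36};
static const int OPP[19]   = {0, 2, 1, 4, 3, 6, 5, 8, 7,10, 9,12,11,14,13,16,15,18,17};
// direction index after specular reflection about a horizontal (z) plane
static const int FLIPZ[19] = {0, 1, 2, 3, 4, 6, 5, 7, 8, 9,10,13,14,11,12,17,18,15,16};

static inline double feq_i(int i, double rho, double ux, double uy, double uz) {
  double eu = EX[i]*ux + EY[i]*uy + EZ[i]*uz;
  double u2 = ux*ux + uy*uy + uz*uz;
  return WT[i]*rho*(1.0 + 3.0*eu + 4.5*eu*eu - 1.5*u2);
}

static inline double inlet_u(double umax, int z, int nz, int profile) {
  double zeta = (z + 0.5) / nz;           // seabed plane at z = -0.5
  if (profile == 0) return umax;
  if (profile == 2) return umax * std::pow(zeta, 1.0/7.0);
  return umax * (2.0*zeta - zeta*zeta);   // half-Poiseuille open-channel profile
}

// [[Rcpp::export]]
List lbm_run_cpp(IntegerVector solid, IntegerVector dims, double tau,
                 int bc_mode, double u_inlet, int inlet_profile,
                 double gx, double gy, double gz,
                 NumericVector f0, NumericVector ux0, NumericVector uy0,
                 NumericVector uz0,
                 int max_steps, int check_every, double conv_tol, int conv_consec,
                 int ramp_steps, IntegerMatrix probes,
                 bool record_mass, bool keep_f) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ncell = (R_xlen_t)nx * ny * nz;
  const double omega = 1.0 / tau;
  const bool forced = (gx != 0.0 || gy != 0.0 || gz != 0.0);

  std::vector<double> f((size_t)ncell * 19, 0.0), fn((size_t)ncell * 19, 0.0);

  // initialise: supplied f, or equilibrium at rho = 1 with optional velocity
  const bool have_f0 = (f0.size() == (R_xlen_t)ncell * 19);
  const bool have_u0 = (ux0.size() == ncell);
  for (R_xlen_t c = 0; c < ncell; ++c) {
    if (solid[c]) continue;
    if (have_f0) {
      for (int i = 0; i < 19; ++i) f[(size_t)c*19 + i] = f0[c*19 + i];
    } else {
      double vx = have_u0 ? ux0[c] : 0.0;
      double vy = have_u0 ? uy0[c] : 0.0;
      double vz = have_u0 ? uz0[c] : 0.0;
      for (int i = 0; i < 19; ++i) f[(size_t)c*19 + i] = feq_i(i, 1.0, vx, vy, vz);
    }
  }

  const int nprobe = probes.nrow();
  std::vector<double> ke_trace, mass_trace, probe_trace;
  std::vector<int> ke_steps;
  bool converged = false, stable = true;
  double ke_prev = -1.0;
  int consec = 0, step = 0;

  auto idx = [nx, ny](int x, int y, int z) -> R_xlen_t {
    return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
  };

  for (step = 0; step < max_steps; ++step) {
    const bool check = ((step + 1) % check_every == 0) || (step + 1 == max_steps);
    double ke = 0.0, mass = 0.0, rho_min = 1e300;
    double ramp = (ramp_steps > 0 && step < ramp_steps)
                    ? (double)(step + 1) / ramp_steps : 1.0;

    std::fill(fn.begin(), fn.end(), 0.0);

    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const R_xlen_t c = idx(x, y, z);
          if (solid[c]) continue;
          const double* fc = &f[(size_t)c*19];
          double rho = 0.0, mx = 0.0, my = 0.0, mz = 0.0;
          for (int i = 0; i < 19; ++i) {
            rho += fc[i];
            mx += fc[i]*EX[i]; my += fc[i]*EY[i]; mz += fc[i]*EZ[i];
          }
          const double ux = mx/rho, uy = my/rho, uz = mz/rho;
          if (check) {
            ke += 0.5*rho*(ux*ux + uy*uy + uz*uz);
            mass += rho;
            if (rho < rho_min) rho_min = rho;
          }
          double fpost[19];
          for (int i = 0; i < 19; ++i) {
            double fe = feq_i(i, rho, ux, uy, uz);
            fpost[i] = fc[i] + omega*(fe - fc[i]);
            if (forced)
              fpost[i] += 3.0*WT[i]*rho*(EX[i]*gx + EY[i]*gy + EZ[i]*gz);
          }
          // push streaming with boundary rules
          for (int i = 0; i < 19; ++i) {
            int xd = x + EX[i], yd = y + EY[i], zd = z + EZ[i], id = i;
            if (yd < 0) yd += ny; else if (yd >= ny) yd -= ny;
            if (bc_mode == 0) {
              if (xd < 0) xd += nx; else if (xd >= nx) xd -= nx;
              if (zd < 0) zd += nz; else if (zd >= nz) zd -= nz;
            } else {
              if (zd < 0) {            // seabed: half-way bounce-back
                fn[(size_t)c*19 + OPP[i]] += fpost[i];
                continue;
              }
              if (zd >= nz) {          // free surface: specular reflection
                id = FLIPZ[i];
                zd = nz - 1;
              }
              if (xd < 0 || xd >= nx) {
                if (bc_mode == 2) { xd = (xd < 0) ? xd + nx : xd - nx; }
                else continue;       // replaced by inlet/outlet layers below
              }
            }
            const R_xlen_t d = idx(xd, yd, zd);
            if (solid[d])
              fn[(size_t)c*19 + OPP[id]] += fpost[i];
            else
              fn[(size_t)d*19 + id] += fpost[i];
          }
        }

    if (bc_mode == 1) {
      // outlet: fixed density, zero-gradient velocity from the neighbour layer
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
          const R_xlen_t co = idx(nx-1, y, z), cn = idx(nx-2, y, z);
          if (solid[co]) continue;
          double vx = 0.0, vy = 0.0, vz = 0.0;
          if (!solid[cn]) {
            const double* fb = &fn[(size_t)cn*19];
            double rho = 0.0, mx = 0.0, my = 0.0, mz = 0.0;
            for (int i = 0; i < 19; ++i) {
              rho += fb[i];
              mx += fb[i]*EX[i]; my += fb[i]*EY[i]; mz += fb[i]*EZ[i];
            }
            if (rho > 0) { vx = mx/rho; vy = my/rho; vz = mz/rho; }
          }
          for (int i = 0; i < 19; ++i)
            fn[(size_t)co*19 + i] = feq_i(i, 1.0, vx, vy, vz);
        }
      // inlet: prescribed open-channel velocity profile at unit density
      for (int z = 0; z < nz; ++z) {
        const double up = ramp * inlet_u(u_inlet, z, nz, inlet_profile);
        for (int y = 0; y < ny; ++y) {
          const R_xlen_t ci = idx(0, y, z);
          if (solid[ci]) continue;
          for (int i = 0; i < 19; ++i)
            fn[(size_t)ci*19 + i] = feq_i(i, 1.0, up, 0.0, 0.0);
        }
      }
    }

    f.swap(fn);

    if (check) {
      if (!std::isfinite(ke) || rho_min <= 0.0) { stable = false; break; }
      ke_trace.push_back(ke);
      ke_steps.push_back(step + 1);
      if (record_mass) mass_trace.push_back(mass);
      for (int pidx = 0; pidx < nprobe; ++pidx) {
        const R_xlen_t c = idx(probes(pidx,0), probes(pidx,1), probes(pidx,2));
        const double* fc = &f[(size_t)c*19];
        double rho = 0.0, mx = 0.0, my = 0.0, mz = 0.0;
        for (int i = 0; i < 19; ++i) {
          rho += fc[i];
          mx += fc[i]*EX[i]; my += fc[i]*EY[i]; mz += fc[i]*EZ[i];
        }
        probe_trace.push_back(step + 1);
        probe_trace.push_back(pidx + 1);
        probe_trace.push_back(rho > 0 ? mx/rho : 0.0);
        probe_trace.push_back(rho > 0 ? my/rho : 0.0);
        probe_trace.push_back(rho > 0 ? mz/rho : 0.0);
        probe_trace.push_back(rho);
      }
      // quasi-steady criterion: windowed relative change of domain KE
      if (step + 1 > ramp_steps && ke_prev >= 0.0) {
        double rel = std::fabs(ke - ke_prev) / std::max(ke, 1e-300);
        consec = (rel < conv_tol) ? consec + 1 : 0;
        if (consec >= conv_consec && conv_tol > 0) { converged = true; }
      }
      ke_prev = ke;
      if (converged) { ++step; break; }
    }
  }

  // final macroscopic fields
  NumericVector rho_out(ncell), ux_out(ncell), uy_out(ncell), uz_out(ncell);
  for (R_xlen_t c = 0; c < ncell; ++c) {
    if (solid[c]) { rho_out[c] = NA_REAL; continue; }
    const double* fc = &f[(size_t)c*19];
    double rho = 0.0, mx = 0.0, my = 0.0, mz = 0.0;
    for (int i = 0; i < 19; ++i) {
      rho += fc[i];
      mx += fc[i]*EX[i]; my += fc[i]*EY[i]; mz += fc[i]*EZ[i];
    }
    rho_out[c] = rho;
    ux_out[c] = mx/rho; uy_out[c] = my/rho; uz_out[c] = mz/rho;
  }

  List out = List::create(
    _["ux"] = ux_out, _["uy"] = uy_out, _["uz"] = uz_out, _["rho"] = rho_out,
    _["steps"] = std::min(step, max_steps), _["converged"] = converged,
    _["stable"] = stable,
    _["ke_steps"] = wrap(ke_steps), _["ke"] = wrap(ke_trace),
    _["mass"] = wrap(mass_trace), _["probe"] = wrap(probe_trace));
  if (keep_f) {
    NumericVector ff((R_xlen_t)ncell * 19);
    for (R_xlen_t c = 0; c < ncell; ++c)
      for (int i = 0; i < 19; ++i) ff[c*19 + i] = f[(size_t)c*19 + i];
    out["f"] = ff;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector lbm_weights_cpp() {
  return NumericVector(WT, WT + 19);
}

// [[Rcpp::export]]
IntegerMatrix lbm_velocities_cpp() {
  IntegerMatrix e(19, 3);
  for (int i = 0; i < 19; ++i) { e(i,0) = EX[i]; e(i,1) = EY[i]; e(i,2) = EZ[i]; }
  return e;
}
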