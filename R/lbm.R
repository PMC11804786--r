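#' D3Q19 lattice constants
#'
#' Discrete velocity set and quadrature weights of the D3Q19 lattice
#' (rest direction, 6 axis directions of weight 1/18, 12 edge-diagonal
#' directions of weight 1/36).
#'
#' @return `lbm_velocities()`: a 19 x 3 integer matrix of lattice velocities;
#'   `lbm_weights()`: the 19 quadrature weights.
#' @export
lbm_velocities <- function() lbm_velocities_cpp()

#' @rdname lbm_velocities
#' @export
lbm_weights <- function() lbm_weights_cpp()

#' Equilibrium distribution function
#'
#' Second-order (low-Mach) Maxwell-Boltzmann expansion on the D3Q19 lattice:
#' \deqn{f_i^{eq} = \omega_i \rho \left(1 + \frac{3 e_i \cdot u}{C^2}
#'   + \frac{9 (e_i \cdot u)^2}{2 C^4} - \frac{3 u^2}{2 C^2}\right)}
#' with \eqn{C} the characteristic lattice velocity. By construction the
#' zeroth moment recovers \eqn{\rho} and the first moment \eqn{\rho u}.
#'
#' @param rho fluid density (lattice units).
#' @param u velocity 3-vector (same units as `C`).
#' @param C characteristic lattice velocity (default 1: pure lattice units).
#' @return Numeric vector of the 19 equilibrium populations.
#' @export
equilibrium <- function(rho, u, C = 1) {
  stopifnot(length(u) == 3L)
  e <- lbm_velocities()
  w <- lbm_weights()
  eu <- as.numeric(e %*% u)
  u2 <- sum(u^2)
  w * rho * (1 + 3 * eu / C^2 + 4.5 * eu^2 / C^4 - 1.5 * u2 / C^2)
}

#' Macroscopic moments of a distribution state
#'
#' Density, velocity and pressure from the populations:
#' \eqn{\rho = \sum_i f_i}, \eqn{u = \sum_i f_i e_i / \rho},
#' \eqn{p = C^2 \rho / 3}.
#'
#' @param f numeric matrix (cells x 19) or vector of 19 populations.
#' @param C characteristic lattice velocity.
#' @return A list with `rho`, `u` (cells x 3) and `p`.
#' @export
macroscopics <- function(f, C = 1) {
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  stopifnot(ncol(f) == 19L)
  e <- lbm_velocities()
  rho <- rowSums(f)
  if (any(rho <= 0)) stopf("non-positive density: lattice state is unstable")
  u <- (f %*% e) / rho * C
  list(rho = rho, u = u, p = C^2 * rho / 3)
}

#' Kinematic viscosity of the BGK scheme
#'
#' \eqn{\nu = C^2 \delta t (\tau - 1/2) / 3}: the macroscopic viscosity
#' recovered by the single-relaxation-time collision operator.
#'
#' @param tau relaxation time (lattice units, > 0.5).
#' @param C characteristic lattice velocity `dl/dt` (m/s).
#' @param dt time step (s).
#' @return Kinematic viscosity (m^2/s for physical `C`, lattice units for
#'   `C = dt = 1`).
#' @export
lbm_viscosity <- function(tau, C = 1, dt = 1) C^2 * dt * (tau - 0.5) / 3

#' Reynolds number of the ambient flow
#'
#' \eqn{Re = |u_{inlet}| W / \nu} with `u_inlet` the maximum inlet velocity,
#' `W` the coral branch width and `nu` the kinematic viscosity of seawater.
#'
#' @param u_inlet maximum inlet velocity (m/s).
#' @param W coral width (m).
#' @param nu kinematic viscosity (m^2/s; default 1.0e-6).
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds(0.0009, 0.012)   # ~ 10.8
#' @export
reynolds <- function(u_inlet, W, nu = 1.0e-6) abs(u_inlet) * W / nu

#' Flow-simulation configuration
#'
#' Collects the physical flow conditions and derives the lattice
#' discretization. Given the voxel spacing `dl`, the relaxation time `tau`
#' fixes the lattice viscosity \eqn{\nu_{lat} = (\tau - 1/2)/3} and hence the
#' time step \eqn{\delta t = \nu_{lat} \delta l^2 / \nu}; the lattice inlet
#' velocity follows as \eqn{u_{lat} = u_{inlet} \delta t / \delta l}. If the
#' implied lattice Mach number exceeds `max_mach`, `tau` is reduced (down to
#' 0.55) to restore the low-Mach contract; an infeasible combination is a
#' configuration error.
#'
#' @param u_inlet maximum inlet velocity (m/s).
#' @param width coral branch width (m), used for the Reynolds number.
#' @param spacing voxel edge length `dl` (m).
#' @param nu physical kinematic viscosity (m^2/s; default 1.0e-6, seawater).
#' @param tau target BGK relaxation time (lattice units; accuracy window
#'   0.55--1.2).
#' @param max_mach cap on `u_lat / c_s` implied Mach proxy: maximum admitted
#'   lattice inlet velocity as a fraction of the lattice speed (default 0.1).
#' @param max_steps,check_every,tol,consec quasi-steady iteration controls:
#'   hard step cap, cadence of kinetic-energy checks, windowed relative
#'   KE-change tolerance, and the number of consecutive quiet windows
#'   required.
#' @param ramp_steps inlet ramp-up duration in steps (avoids initialization
#'   pressure shocks).
#' @param profile inlet profile: `"half_poiseuille"` (zero at the seabed,
#'   maximum and zero shear at the free surface), `"uniform"`, or
#'   `"power_law"` (1/7 exponent).
#' @param monitors optional integer matrix (n x 3) of 0-based voxel
#'   coordinates to record velocity/pressure traces at.
#' @return An object of class `flow_config`.
#' @export
flow_config <- function(u_inlet, width, spacing, nu = 1.0e-6, tau = 0.9,
                        max_mach = 0.1, max_steps = 6000L, check_every = 100L,
                        tol = 2e-4, consec = 3L, ramp_steps = 400L,
                        profile = c("half_poiseuille", "uniform", "power_law"),
                        monitors = NULL) {
  profile <- match.arg(profile)
  stopifnot(u_inlet >= 0, width > 0, spacing > 0, nu > 0)
  nu_lat <- (tau - 0.5) / 3
  dt <- nu_lat * spacing^2 / nu
  u_lat <- u_inlet * dt / spacing
  if (u_lat > max_mach) {
    dt <- max_mach * spacing / u_inlet
    nu_lat <- nu * dt / spacing^2
    tau <- 0.5 + 3 * nu_lat
    u_lat <- max_mach
    if (tau < 0.55)
      stopf("infeasible discretization: tau = %.3f < 0.55 at the low-Mach cap; refine the grid", tau)
  }
  structure(list(
    u_inlet = u_inlet, width = width, spacing = spacing, nu = nu,
    tau = tau, dt = dt, u_lat = u_lat, C = spacing / dt,
    re = reynolds(u_inlet, width, nu), mach = u_lat / sqrt(1 / 3),
    max_steps = as.integer(max_steps), check_every = as.integer(check_every),
    tol = tol, consec = as.integer(consec), ramp_steps = as.integer(ramp_steps),
    profile = profile, monitors = monitors), class = "flow_config")
}

#' @export
print.flow_config <- function(x, ...) {
  cat(sprintf("<flow_config> Re = %.3g  u_inlet = %.3g m/s  nu = %.3g m2/s\n",
              x$re, x$u_inlet, x$nu))
  cat(sprintf("  lattice: tau = %.3f  dt = %.4g s  dl = %.4g m  u_lat = %.4f (Ma %.3f)\n",
              x$tau, x$dt, x$spacing, x$u_lat, x$mach))
  invisible(x)
}

profile_code <- function(profile)
  switch(profile, uniform = 0L, half_poiseuille = 1L, power_law = 2L)

# shared low-level driver around the compiled kernel
lbm_drive <- function(solid, dims, tau, bc_mode, u_inlet_lat = 0,
                      profile = 1L, g = c(0, 0, 0), f0 = numeric(0),
                      u0 = NULL, max_steps, check_every = 100L, tol = 0,
                      consec = 3L, ramp_steps = 0L, probes = NULL,
                      record_mass = FALSE, keep_f = FALSE) {
  if (is.null(probes)) probes <- matrix(0L, 0, 3)
  storage.mode(probes) <- "integer"
  ux0 <- if (is.null(u0)) numeric(0) else as.vector(u0[[1]])
  uy0 <- if (is.null(u0)) numeric(0) else as.vector(u0[[2]])
  uz0 <- if (is.null(u0)) numeric(0) else as.vector(u0[[3]])
  res <- lbm_run_cpp(as.integer(solid), as.integer(dims), tau, as.integer(bc_mode),
                     u_inlet_lat, as.integer(profile), g[1], g[2], g[3],
                     f0, ux0, uy0, uz0,
                     as.integer(max_steps), as.integer(check_every), tol,
                     as.integer(consec), as.integer(ramp_steps), probes,
                     record_mass, keep_f)
  if (!res$stable)
    stopf("LBM instability detected (NaN or non-positive density); check tau (= %.3f) and the lattice Mach number", tau)
  res
}

#' Advance a lattice state by collide-and-stream steps
#'
#' Low-level access to the BGK collision + propagation update on a fully
#' periodic box (solid voxels, if any, bounce back). Mass is conserved
#' exactly in a solid-free periodic domain. Intended for small verification
#' domains; full runs go through [run_to_quasi_steady()].
#'
#' @param f numeric array of populations, dimensions `c(nx, ny, nz, 19)`,
#'   or `NULL` to start from equilibrium at rest.
#' @param dims grid dimensions (required if `f` is `NULL`).
#' @param tau relaxation time (> 0.5).
#' @param steps number of time steps.
#' @param solid optional logical array of solid voxels.
#' @param g constant body force per unit mass, length-3 (lattice units).
#' @param u0 optional list of three arrays (initial velocity field); the
#'   state is initialised at equilibrium with this field and unit density.
#' @return A list with the final populations `f` (nx x ny x nz x 19 array),
#'   per-check total `mass`, and the final macroscopic fields `ux`, `uy`,
#'   `uz`, `rho` as arrays.
#' @export
collide_and_stream <- function(f = NULL, dims = NULL, tau, steps,
                               solid = NULL, g = c(0, 0, 0), u0 = NULL) {
  if (is.null(f) && is.null(dims)) stopf("give either `f` or `dims`")
  if (!is.null(f)) {
    stopifnot(length(dim(f)) == 4L, dim(f)[4] == 19L)
    dims <- dim(f)[1:3]
    f0 <- as.vector(aperm(f, c(4, 1, 2, 3)))   # kernel stores f cell-major
  } else f0 <- numeric(0)
  if (is.null(solid)) solid <- array(FALSE, dims)
  res <- lbm_drive(solid, dims, tau, bc_mode = 0L, f0 = f0, u0 = u0,
                   max_steps = steps, check_every = max(1L, steps %/% 50L),
                   record_mass = TRUE, keep_f = TRUE)
  fout <- aperm(array(res$f, c(19, dims)), c(2, 3, 4, 1))
  shape <- function(v) array(v, dims)
  list(f = fout, mass = res$mass,
       ux = shape(res$ux), uy = shape(res$uy), uz = shape(res$uz),
       rho = shape(res$rho))
}

#' Body-force-driven seabed channel flow
#'
#' Periodic-in-x/y channel bounded by a no-slip seabed below the first cell
#' layer (half-way bounce-back, wall plane half a cell below the first
#' centre) and a free-slip (specular) sea surface half a cell above the last
#' layer, driven by a constant body force. The steady solution is the
#' analytic half-Poiseuille profile \eqn{u(\zeta) = g(H\zeta - \zeta^2/2)/\nu}
#' with \eqn{\zeta} the height above the wall plane and \eqn{H} the full
#' channel depth, which makes this the standard wall-boundary verification
#' case.
#'
#' @param dims grid dimensions (z is the resolved transverse direction).
#' @param tau relaxation time.
#' @param g body force per unit mass along x (lattice units).
#' @param steps number of time steps.
#' @param solid optional logical array of additional solid voxels.
#' @return List of final `ux`, `uy`, `uz`, `rho` arrays (lattice units) plus
#'   the kinetic-energy trace.
#' @export
run_channel_force <- function(dims, tau, g, steps, solid = NULL) {
  if (is.null(solid)) solid <- array(FALSE, dims)
  res <- lbm_drive(solid, dims, tau, bc_mode = 2L, g = c(g, 0, 0),
                   max_steps = steps, check_every = max(1L, steps %/% 20L))
  shape <- function(v) { v[is.na(v)] <- 0; array(v, dims) }
  list(ux = shape(res$ux), uy = shape(res$uy), uz = shape(res$uz),
       rho = shape(res$rho), ke = res$ke)
}

#' Simulate flow to a quasi-steady state
#'
#' Runs the D3Q19 BGK solver on a voxel geometry under the five seabed-channel
#' boundary conditions (inlet open-channel velocity profile, constant-pressure
#' outlet, periodic transverse sides, free-slip sea surface, no-slip seabed
#' and solid surfaces) until the windowed relative change of the
#' domain-average kinetic energy falls below tolerance, or the step cap is
#' reached. The inlet is ramped up over `config$ramp_steps` steps.
#'
#' @param geometry a [voxel_geometry()] (any non-solid label is fluid).
#' @param config a [flow_config()].
#' @return An object of class `coral_flow` holding the velocity field in m/s
#'   (`ux`, `uy`, `uz`, zero on solid voxels), lattice density `rho` and
#'   pressure `p` (Eq. of state \eqn{p = C^2 \rho / 3}), the kinetic-energy
#'   convergence trace, monitor-point traces, and the unit-conversion record.
#' @export
run_to_quasi_steady <- function(geometry, config) {
  stopifnot(inherits(geometry, "voxel_geometry"), inherits(config, "flow_config"))
  d <- dim(geometry$labels)
  m <- label_masks(geometry)
  res <- lbm_drive(m$solid, d, config$tau, bc_mode = 1L,
                   u_inlet_lat = config$u_lat,
                   profile = profile_code(config$profile),
                   max_steps = config$max_steps,
                   check_every = config$check_every, tol = config$tol,
                   consec = config$consec, ramp_steps = config$ramp_steps,
                   probes = config$monitors)
  if (!res$converged)
    warnf("quasi-steady state not reached within %d steps (KE still drifting); returning the final field flagged unconverged",
          config$max_steps)
  Cfac <- config$C
  shape <- function(v, fill = 0) { v[is.na(v)] <- fill; array(v, d) }
  probes <- NULL
  if (length(res$probe)) {
    pm <- matrix(res$probe, ncol = 6, byrow = TRUE)
    probes <- tibble(step = pm[, 1], point = pm[, 2],
                     time = pm[, 1] * config$dt,
                     ux = pm[, 3] * Cfac, uy = pm[, 4] * Cfac,
                     uz = pm[, 5] * Cfac, p = Cfac^2 * pm[, 6] / 3)
  }
  structure(list(
    ux = shape(res$ux) * Cfac, uy = shape(res$uy) * Cfac,
    uz = shape(res$uz) * Cfac,
    rho = shape(res$rho, fill = NA), p = Cfac^2 * shape(res$rho, fill = NA) / 3,
    spacing = geometry$spacing, dims = d,
    solid = m$solid, config = config,
    steps = res$steps, converged = res$converged,
    ke_trace = tibble(step = res$ke_steps, time = res$ke_steps * config$dt,
                      ke = res$ke),
    probes = probes,
    conversion = list(dl = config$spacing, dt = config$dt, C = Cfac,
                      tau = config$tau, u_lat = config$u_lat)),
    class = "coral_flow")
}

#' @export
print.coral_flow <- function(x, ...) {
  cat(sprintf("<coral_flow> %d x %d x %d grid, %d steps (%s), Re = %.3g\n",
              x$dims[1], x$dims[2], x$dims[3], x$steps,
              if (x$converged) "quasi-steady" else "NOT converged",
              x$config$re))
  cat(sprintf("  max |u| = %.3g m/s  dt = %.3g s  tau = %.3f\n",
              max(sqrt(x$ux^2 + x$uy^2 + x$uz^2)), x$conversion$dt,
              x$conversion$tau))
  invisible(x)
}

#' @describeIn run_to_quasi_steady one-row run summary (broom-style).
#' @param x a `coral_flow` object.
#' @param ... unused.
#' @export
glance.coral_flow <- function(x, ...) {
  tibble(re = x$config$re, steps = x$steps, converged = x$converged,
         tau = x$conversion$tau, dt = x$conversion$dt,
         mach = x$config$mach, ke_final = tail(x$ke_trace$ke, 1),
         u_max = max(sqrt(x$ux^2 + x$uy^2 + x$uz^2)))
}

#' Interior-to-ambient speed ratio at monitor points
#'
#' Compares the local speed (averaged over a small ball) at a monitor point
#' inside the skeleton pore space against a free-stream reference point,
#' quantifying how strongly the skeleton shelters its interior from the
#' ambient current.
#'
#' @param field a `coral_flow` object.
#' @param interior,ambient 0-based voxel coordinates (length 3).
#' @param ball_radius averaging radius in voxels.
#' @return A list with mean speeds `interior`, `ambient` and their `ratio`.
#' @export
speed_ratio <- function(field, interior, ambient, ball_radius = 1.5) {
  spd <- sqrt(field$ux^2 + field$uy^2 + field$uz^2)
  d <- field$dims
  ball_mean <- function(cen) {
    xs <- clampi(cen[1] - ball_radius, 0L, d[1] - 1L):clampi(cen[1] + ball_radius, 0L, d[1] - 1L)
    ys <- clampi(cen[2] - ball_radius, 0L, d[2] - 1L):clampi(cen[2] + ball_radius, 0L, d[2] - 1L)
    zs <- clampi(cen[3] - ball_radius, 0L, d[3] - 1L):clampi(cen[3] + ball_radius, 0L, d[3] - 1L)
    sub <- spd[xs + 1, ys + 1, zs + 1]
    keep <- !field$solid[xs + 1, ys + 1, zs + 1]
    if (!any(keep)) stopf("monitor ball contains no fluid voxels")
    mean(sub[keep])
  }
  si <- ball_mean(interior); sa <- ball_mean(ambient)
  list(interior = si, ambient = sa, ratio = si / sa)
}
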