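# fitted aragonite dissolution rate law: -r = RATE_A * (exp(RATE_B * C) - 1),
# C in mol/m^3, r in mol m^-3 s^-1 (fit to published aragonite dissolution data)
RATE_A <- 2.5e-7
RATE_B <- 1.98e5

#' Seconds in a Julian year
#' @export
JULIAN_YEAR <- 3.15576e7

#' Proton concentration from pH
#'
#' \eqn{C[H^+] = 10^{3 - pH}} in mol m\eqn{^{-3}} (the factor 10^3 converts
#' the conventional mol/L definition of pH).
#'
#' @param pH seawater pH.
#' @return Proton concentration (mol m^-3).
#' @examples
#' proton_concentration(8)     # 1e-5
#' proton_concentration(7.87)  # 2100 open-ocean projection, ~1.35e-5
#' @export
proton_concentration <- function(pH) 10^(3 - pH)

#' Aragonite dissolution rate law
#'
#' Exponential dependence of the dissolution rate on proton concentration,
#' \deqn{-r_{H^+} = 2.5\times10^{-7}\,(e^{1.98\times10^5 C} - 1)}
#' (mol m\eqn{^{-3}} s\eqn{^{-1}}), strictly increasing in `C`. The fit is
#' valid in the near-neutral regime (roughly pH > 6); far outside it the
#' exponential overflows and a domain error is raised.
#'
#' @param C proton concentration (mol m^-3), non-negative.
#' @return Dissolution rate (mol m^-3 s^-1).
#' @export
rate_law <- function(C) {
  if (any(C < 0)) stopf("proton concentration must be non-negative")
  if (any(RATE_B * C > 700))
    stopf("rate law evaluated outside its validity range (C = %.3g mol m^-3; the fit holds for roughly pH > 6)",
          max(C))
  RATE_A * expm1(RATE_B * C)
}

#' Analytic steady proton profile along the tube
#'
#' Closed-form (method of characteristics) steady solution of the
#' advection-reaction transport of protons through the carbonate tube with
#' the exponential rate law and no diffusion:
#' \deqn{C(x) = -\ln\!\left(1 - e^{-\lambda x / u}\,(1 - e^{-b C_0})\right)/b}
#' with \eqn{b = 1.98\times10^5} and \eqn{\lambda = a b \approx 0.0495}
#' s\eqn{^{-1}} derived from the two rate-law coefficients. The profile
#' recovers \eqn{C(0) = C_0} exactly and decreases monotonically in `x`.
#'
#' @param x distance from the tube entrance (m); vectorized.
#' @param u pore-water velocity (m/s), > 0.
#' @param C0 inlet proton concentration (mol m^-3).
#' @return Proton concentration (mol m^-3) at `x`.
#' @export
analytic_proton_profile <- function(x, u, C0) {
  stopifnot(u > 0, C0 >= 0, all(x >= 0))
  if (C0 == 0) return(rep(0, length(x)))
  lam <- RATE_A * RATE_B
  arg <- exp(-lam * x / u) * (-expm1(-RATE_B * C0))
  if (any(arg >= 1)) stopf("numerical guard: log argument <= 0")
  -log1p(-arg) / RATE_B
}

#' Upwind transport-reaction solver (independent numerical route)
#'
#' First-order upwind finite-difference solution of
#' \eqn{\partial C/\partial t + u\,\partial C/\partial x = -r(C)} on a
#' uniform grid with fixed inlet concentration, serving as the independent
#' numerical check of [analytic_proton_profile()]. Two modes:
#' * `steady = TRUE` (default): solves the steady discrete upwind balance
#'   \eqn{u (C_i - C_{i-1})/\Delta x = -r(C_i)} by a per-cell Newton march in
#'   `x` (the fixed point of the time-marched scheme, without time stepping);
#' * `steady = FALSE`: explicit time marching to `t_end` with an internally
#'   chosen CFL- and reaction-stable step, returning the final profile.
#'
#' @param u advection velocity (m/s).
#' @param C0 inlet concentration (mol m^-3).
#' @param L domain length (m).
#' @param nx number of grid cells.
#' @param steady see above.
#' @param t_end physical horizon for the time-marched mode (s).
#' @param react if `FALSE` the rate law is disabled (pure advection), useful
#'   for verifying the transport limit.
#' @param C_init optional initial profile for the time-marched mode.
#' @return A list with `x` (cell coordinates, m) and `C` (mol m^-3).
#' @export
solve_transport_numeric <- function(u, C0, L, nx = 1e4, steady = TRUE,
                                    t_end = NULL, react = TRUE, C_init = NULL) {
  stopifnot(u > 0, L > 0, nx >= 2)
  nx <- as.integer(nx)
  dx <- L / nx
  x <- (seq_len(nx) - 0.5) * dx
  rate <- if (react) rate_law else function(C) 0 * C
  if (steady) {
    C <- numeric(nx)
    a <- dx / u
    prev <- C0
    for (i in seq_len(nx)) {
      ci <- prev
      for (it in 1:60) {                 # Newton on g(c) = c + a r(c) - prev
        g <- ci + a * rate(ci) - prev
        gp <- 1 + if (react) a * RATE_A * RATE_B * exp(RATE_B * ci) else 0
        step <- g / gp
        ci <- max(ci - step, 0)
        if (abs(step) < 1e-16 * max(ci, 1e-30)) break
      }
      C[i] <- ci
      prev <- ci
    }
    return(list(x = x, C = C))
  }
  stopifnot(!is.null(t_end))
  C <- if (is.null(C_init)) numeric(nx) else C_init
  # CFL and explicit-reaction stability
  dt <- 0.9 * dx / u
  if (react && C0 > 0)
    dt <- min(dt, 0.2 / (RATE_A * RATE_B * exp(RATE_B * C0)))
  t <- 0
  while (t < t_end) {
    h <- min(dt, t_end - t)
    upwind <- u * (C - c(C0, C[-nx])) / dx
    C <- pmax(C - h * (upwind + rate(C)), 0)
    t <- t + h
  }
  list(x = x, C = C)
}

#' Equivalent carbonate tube model
#'
#' The coral branch reduced to a homogeneous aragonite (CaCO3) tube of outer
#' radius `R_O`, inner radius `R_I`, length `H`, initial porosity `n0`,
#' mineral density `rho_s` (2700 kg/m^3) and molar mass `M` (0.100 kg/mol).
#'
#' @param R_O,R_I,H tube geometry (m), with `0 < R_I < R_O`.
#' @param n0 initial skeletal porosity, in (0, 1]; by default the
#'   conventional pore/total fraction (a pore/solid ratio from
#'   [porosity()] can be supplied instead, documented by `n0_convention`).
#' @param rho_s mineral particle density (kg/m^3).
#' @param M molar mass of CaCO3 (kg/mol).
#' @param n0_convention `"fraction"` (pore/total) or `"ratio"` (pore/solid);
#'   bookkeeping only.
#' @return An object of class `pipe_model`.
#' @export
pipe_model <- function(R_O, R_I, H, n0, rho_s = 2700, M = 0.100,
                       n0_convention = c("fraction", "ratio")) {
  n0_convention <- match.arg(n0_convention)
  stopifnot(R_O > 0, R_I > 0, R_I < R_O, H > 0, n0 > 0, rho_s > 0, M > 0)
  structure(list(R_O = R_O, R_I = R_I, H = H, n0 = n0, rho_s = rho_s, M = M,
                 n0_convention = n0_convention), class = "pipe_model")
}

#' @export
print.pipe_model <- function(x, ...) {
  cat(sprintf("<pipe_model> R_O %.3g m  R_I %.3g m  H %.3g m  n0 %.3g (%s)\n",
              x$R_O, x$R_I, x$H, x$n0, x$n0_convention))
  invisible(x)
}

#' Scenario 1: average dissolution rate from an outside acid source
#'
#' Acid produced outside the skeleton is advected in and consumed completely
#' near the entrance, so the tube-averaged rate is the proton supply rate,
#' \deqn{r_{oe} = \frac{u}{H} C_0 = \frac{Q}{H \pi R_I^2}\, 10^{3 - pH}.}
#' When `check = TRUE`, the complete-consumption assumption is verified
#' against the analytic profile (\eqn{C(H)/C(0) < 10^{-3}}); if it fails,
#' the exact in/out concentration difference is used instead and a warning
#' issued.
#'
#' @param Q pore-water volume flux through the tube (m^3/s).
#' @param H tube length (m).
#' @param R_I inner radius (m).
#' @param pH_inlet pH of the incoming acidified water.
#' @param check verify the complete-consumption assumption (default TRUE).
#' @return Average dissolution rate (mol m^-3 s^-1).
#' @export
scenario1_average_rate <- function(Q, H, R_I, pH_inlet, check = TRUE) {
  stopifnot(Q >= 0, H > 0, R_I > 0)
  if (Q == 0) return(0)
  u <- Q / (pi * R_I^2)
  C0 <- proton_concentration(pH_inlet)
  if (check) {
    CH <- analytic_proton_profile(H, u, C0)
    if (CH / C0 >= 1e-3) {
      warnf("incomplete proton consumption at the outlet (C(H)/C(0) = %.2g); using the exact concentration difference",
            CH / C0)
      return(u / H * (C0 - CH))
    }
  }
  u / H * C0
}

#' Scenario 2: constant dissolution rate in a low-pH microenvironment
#'
#' Acid produced inside the skeleton maintains a stable local pH, so the
#' dissolution proceeds at the constant rate given by the rate law evaluated
#' at that pH.
#'
#' @param pH_local the sustained local pore-water pH.
#' @return Dissolution rate (mol m^-3 s^-1).
#' @export
scenario2_average_rate <- function(pH_local)
  rate_law(proton_concentration(pH_local))

#' Inner-radius growth under dissolution
#'
#' \deqn{R_I(t) = R_I(0)\, e^{r M t / 2\rho_s} \approx R_I(0)\,(1 + r M t / 2\rho_s)}
#' The linearization is accurate because \eqn{r M t / 2\rho_s} stays of order
#' \eqn{10^{-2}} even over a century at projected rates.
#'
#' @param pipe a [pipe_model()].
#' @param r dissolution rate (mol m^-3 s^-1).
#' @param t elapsed time (s).
#' @param mode `"exact"` (exponential) or `"linearized"` (first order).
#' @return Inner radius at time `t` (m).
#' @export
evolve_inner_radius <- function(pipe, r, t, mode = c("exact", "linearized")) {
  mode <- match.arg(mode)
  stopifnot(r >= 0, t >= 0)
  g <- r * pipe$M * t / (2 * pipe$rho_s)
  RI <- if (mode == "exact") pipe$R_I * exp(g) else pipe$R_I * (1 + g)
  if (RI >= pipe$R_O)
    stopf("tube fully dissolved: R_I(t) = %.3g m reaches R_O = %.3g m", RI, pipe$R_O)
  RI
}

#' Porosity change ratio under dissolution
#'
#' Percent increase of skeletal porosity relative to the initial porosity,
#' \deqn{N = \frac{R_I(0)^2}{R_O^2} \left(\frac{r M t}{\rho_s}
#'   + \left(\frac{r M t}{2\rho_s}\right)^2\right) / n_0 \times 100\%.}
#' Algebraically identical to the skeleton-volume difference
#' \eqn{(V_{sk}(0) - V_{sk}(t)) / (V_{total}\, n_0)} with
#' \eqn{V_{sk} = \pi (R_O^2 - R_I^2) H} under the linearized radius.
#'
#' @inheritParams evolve_inner_radius
#' @return Porosity change ratio N in percent.
#' @export
porosity_change_ratio <- function(pipe, r, t) {
  stopifnot(r >= 0, t >= 0)
  a <- r * pipe$M * t / pipe$rho_s
  (pipe$R_I^2 / pipe$R_O^2) * (a + (a / 2)^2) / pipe$n0 * 100
}

# 3D volume ~ (2D area)^1.4728 allometry of branching-coral skeletons, taken
# as given; flexural rigidity EI scales with area^2, hence volume^(2/1.4728)
RIGIDITY_EXPONENT <- 2 / 1.4728

#' Flexural rigidity reduction from skeletal volume loss
#'
#' The bending stiffness EI of a branch scales with the square of its
#' cross-sectional area; with the measured area-volume allometry
#' \eqn{\log V = 1.4728 \log A - 1.5275} of branching-coral skeletons this
#' gives
#' \deqn{G = \frac{V_0^{e} - V_t^{e}}{V_0^{e}} \times 100\%, \quad
#'   e = 2 / 1.4728 = 1.358.}
#'
#' @param V0 initial remaining-skeleton volume (m^3).
#' @param Vt remaining-skeleton volume after dissolution (m^3), `0 < Vt <= V0`.
#' @return Rigidity reduction G in percent.
#' @export
rigidity_reduction <- function(V0, Vt) {
  stopifnot(V0 > 0)
  if (any(Vt > V0)) stopf("Vt > V0: accretion is outside this model's scope")
  if (any(Vt <= 0)) stopf("Vt must be positive")
  (V0^RIGIDITY_EXPONENT - Vt^RIGIDITY_EXPONENT) / V0^RIGIDITY_EXPONENT * 100
}

#' Acidification scenario description
#'
#' @param scenario `"outside-acid"` (scenario 1: acid advected in from an
#'   external source, consumed completely near the entrance) or
#'   `"inside-acid"` (scenario 2: sustained low-pH microenvironment inside
#'   the skeleton).
#' @param pH boundary pH (scenario 1: at the tube entrance; scenario 2: the
#'   constant local pH).
#' @param Q pore-water flux (m^3/s; scenario 1 only; e.g. from
#'   [volume_flux()]).
#' @param t_years projection horizon in Julian years.
#' @param label optional scenario label (e.g. the projection year).
#' @return An object of class `acid_scenario`.
#' @export
acid_scenario <- function(scenario = c("outside-acid", "inside-acid"),
                          pH, Q = NULL, t_years = 1, label = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(pH > 0, pH < 14, t_years >= 0)
  if (scenario == "outside-acid" && is.null(Q))
    stopf("scenario \"outside-acid\" needs the pore-water flux Q")
  structure(list(scenario = scenario, pH = pH, Q = Q, t_years = t_years,
                 label = label %||% scenario), class = "acid_scenario")
}

#' Project skeletal dissolution for a scenario
#'
#' Chains the scenario's average dissolution rate through the inner-radius
#' trajectory to the porosity change ratio N and the flexural rigidity
#' reduction G.
#'
#' @param pipe a [pipe_model()].
#' @param scenario an [acid_scenario()] or list of them.
#' @return A tibble of class `dissolution_projection`, one row per scenario:
#'   `label`, `scenario`, `pH`, `Q`, `t_years`, `rate`, `R_I_t`,
#'   `N_percent`, `G_percent`.
#' @export
project_scenario <- function(pipe, scenario) {
  if (inherits(scenario, "acid_scenario")) scenario <- list(scenario)
  rows <- lapply(scenario, function(sc) {
    r <- if (sc$scenario == "outside-acid")
      scenario1_average_rate(sc$Q, pipe$H, pipe$R_I, sc$pH)
    else scenario2_average_rate(sc$pH)
    t <- sc$t_years * JULIAN_YEAR
    RIt <- evolve_inner_radius(pipe, r, t, mode = "exact")
    V0 <- pi * (pipe$R_O^2 - pipe$R_I^2) * pipe$H
    Vt <- pi * (pipe$R_O^2 - RIt^2) * pipe$H
    tibble(label = sc$label, scenario = sc$scenario, pH = sc$pH,
           Q = sc$Q %||% NA_real_, t_years = sc$t_years, rate = r,
           R_I_t = RIt, N_percent = porosity_change_ratio(pipe, r, t),
           G_percent = rigidity_reduction(V0, Vt))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dissolution_projection", class(out))
  out
}
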