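test_that("proton concentration and rate law evaluate as printed", {
  expect_equal(proton_concentration(3), 1)
  expect_equal(proton_concentration(8), 1e-5)
  expect_equal(proton_concentration(7.87), 10^(-4.87), tolerance = 1e-12)
  expect_equal(rate_law(0), 0)
  expect_equal(rate_law(1e-5), 2.5e-7 * (exp(1.98) - 1), tolerance = 1e-12)
  expect_gt(rate_law(proton_concentration(7.87)), rate_law(proton_concentration(8)))
  expect_error(rate_law(-1), "non-negative")
  expect_error(rate_law(0.01), "validity")
})

test_that("the analytic profile recovers the boundary and decays monotonically", {
  # exact boundary recovery over a log-spaced concentration grid
  for (C0 in 10^seq(-8, -4, length.out = 9)) {
    expect_equal(analytic_proton_profile(0, 1e-6, C0), C0,
                 tolerance = 1e-9)
  }
  expect_equal(analytic_proton_profile(c(0, 0.01, 0.02), 1e-6, 0), rep(0, 3))
  prof <- analytic_proton_profile(seq(0, 1e-4, length.out = 50), 1e-6, 1e-5)
  expect_true(all(diff(prof) < 0))
})

test_that("the upwind transport solver agrees with the closed form", {
  lam <- 2.5e-7 * 1.98e5
  # compare beyond the reaction entrance layer (first 1% of cells), scaled
  # by the inlet concentration
  for (u in c(1e-8, 1e-6, 1e-4)) for (pH in c(6, 7.5, 9)) {
    C0 <- proton_concentration(pH)
    L <- 10 * u / lam
    num <- solve_transport_numeric(u, C0, L, nx = 1e4)
    ana <- analytic_proton_profile(num$x, u, C0)
    keep <- -(1:100)
    expect_lt(max(abs(num$C[keep] - ana[keep])) / C0, 0.01)
  }
})

test_that("time-marched transport reduces to pure advection without reaction", {
  nx <- 200; L <- 1e-3; u <- 1e-5
  init <- ifelse(seq_len(nx) <= 20, 1e-5, 0)
  out <- solve_transport_numeric(u, 0, L, nx = nx, steady = FALSE, t_end = 50,
                                 react = FALSE, C_init = init)
  # front initially at cell 20 moves u * t / dx = 100 cells
  expect_equal(max(which(out$C > 0.5e-5)), 120, tolerance = 2)
  expect_equal(solve_transport_numeric(u, 0, L, nx = 50, steady = FALSE,
                                       t_end = 10)$C, rep(0, 50))
  # time marching converges to the steady x-march fixed point
  C0 <- proton_concentration(8)
  Lr <- 10 * u / (2.5e-7 * 1.98e5)
  tm <- solve_transport_numeric(u, C0, Lr, nx = 300, steady = FALSE,
                                t_end = 5 * Lr / u)
  st <- solve_transport_numeric(u, C0, Lr, nx = 300)
  expect_lt(max(abs(tm$C - st$C)) / C0, 1e-6)
})

test_that("scenario rates follow the printed proportionalities", {
  expect_equal(scenario1_average_rate(0, 0.04, 1e-3, 8), 0)
  r1 <- scenario1_average_rate(1e-10, 0.04, 1e-3, 8)
  expect_equal(r1, 1e-10 / (0.04 * pi * 1e-6) * 1e-5, tolerance = 1e-10)
  expect_equal(scenario1_average_rate(2e-10, 0.04, 1e-3, 8), 2 * r1)
  expect_equal(scenario1_average_rate(1e-10, 0.08, 1e-3, 8), r1 / 2)
  # fast flow violates complete consumption: warned, exact difference used
  expect_warning(rfast <- scenario1_average_rate(1e-5, 0.04, 1e-3, 8),
                 "incomplete")
  expect_lt(rfast, 1e-5 / (pi * 1e-6) / 0.04 * 1e-5)
  # scenario 2 is the rate law at the local pH, monotone in acidity
  expect_equal(scenario2_average_rate(8), rate_law(1e-5))
  expect_equal(scenario2_average_rate(14), 2.5e-7 * expm1(1.98e5 * 1e-11),
               tolerance = 1e-12)
  pHs <- seq(7.5, 8.5, by = 0.25)
  expect_true(all(diff(vapply(pHs, scenario2_average_rate, 1)) < 0))
})

test_that("inner-radius evolution bounds its linearization", {
  pipe <- pipe_model(R_O = 6e-3, R_I = 1.5e-3, H = 0.04, n0 = 0.3)
  expect_equal(evolve_inner_radius(pipe, 0, 1e9), pipe$R_I)
  expect_equal(evolve_inner_radius(pipe, 0, 1e9, "linearized"), pipe$R_I)
  r <- 1e-6; t <- JULIAN_YEAR
  g <- r * pipe$M * t / (2 * pipe$rho_s)
  expect_equal(g, 1e-6 * 0.1 * JULIAN_YEAR / 5400, tolerance = 1e-12)
  ex <- evolve_inner_radius(pipe, r, t)
  li <- evolve_inner_radius(pipe, r, t, "linearized")
  expect_gte(ex, li)
  expect_lt(abs(ex - li) / pipe$R_I, g^2)
  # a century keeps the growth factor at the 1e-2 scale, where the
  # exact/linearized gap is ~ e^g - (1 + g)
  g100 <- r * pipe$M * 100 * JULIAN_YEAR / (2 * pipe$rho_s)
  expect_lt(g100, 0.1)
  expect_error(evolve_inner_radius(pipe, 1, 1e12), "fully dissolved")
})

test_that("porosity change ratio equals the skeleton-volume difference route", {
  pipe <- pipe_model(R_O = 6e-3, R_I = 1.5e-3, H = 0.04, n0 = 0.3)
  expect_equal(porosity_change_ratio(pipe, 0, 1e9), 0)
  r <- 3e-6; t <- JULIAN_YEAR
  N1 <- porosity_change_ratio(pipe, r, t)
  RIt <- evolve_inner_radius(pipe, r, t, mode = "linearized")
  Vsk <- function(RI) pi * (pipe$R_O^2 - RI^2) * pipe$H
  Vtot <- pi * pipe$R_O^2 * pipe$H
  N2 <- (Vsk(pipe$R_I) - Vsk(RIt)) / (Vtot * pipe$n0) * 100
  expect_equal(N1, N2, tolerance = 1e-12)
  # doubling the initial porosity halves the ratio
  pipe2 <- pipe_model(R_O = 6e-3, R_I = 1.5e-3, H = 0.04, n0 = 0.6)
  expect_equal(porosity_change_ratio(pipe2, r, t), N1 / 2, tolerance = 1e-12)
})

test_that("flexural rigidity reduction uses the allometric exponent", {
  expect_equal(rigidity_reduction(1e-6, 1e-6), 0)
  expect_equal(rigidity_reduction(1, 0.5), (1 - 0.5^(2 / 1.4728)) * 100,
               tolerance = 1e-12)
  expect_equal(round(rigidity_reduction(1, 0.5)), 61)
  expect_equal(round(2 / 1.4728, 3), 1.358)
  expect_error(rigidity_reduction(1, 1.5), "accretion")
  expect_error(rigidity_reduction(1, 0), "positive")
})

test_that("scenario projection chains rate, radius, porosity and rigidity", {
  pipe <- pipe_model(R_O = 6e-3, R_I = 1.5e-3, H = 0.04, n0 = 0.3)
  # negligible acid: nothing happens
  mild <- project_scenario(pipe, acid_scenario("inside-acid", pH = 13.5))
  expect_lt(mild$N_percent, 1e-6)
  expect_lt(mild$G_percent, 1e-6)
  # porosity damage grows with the horizon
  ts <- c(1, 5, 20)
  proj <- project_scenario(pipe, lapply(ts, function(t)
    acid_scenario("inside-acid", pH = 7.87, t_years = t)))
  expect_true(all(diff(proj$N_percent) > 0))
  expect_true(all(diff(proj$G_percent) > 0))
  # damage is monotone in acidity across a pH sweep
  sweep <- project_scenario(pipe, lapply(seq(7.5, 8.2, by = 0.1), function(p)
    acid_scenario("inside-acid", pH = p)))
  expect_true(all(diff(sweep$G_percent) < 0))
  expect_true(all(diff(sweep$N_percent) < 0))
  # outside-acid scenario consumes the supplied flux
  p1 <- project_scenario(pipe, acid_scenario("outside-acid", pH = 8,
                                             Q = 1e-10, t_years = 1))
  expect_equal(p1$rate, scenario1_average_rate(1e-10, pipe$H, pipe$R_I, 8))
  expect_s3_class(p1, "tbl_df")
})
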