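# small helper: build a flow-field list from velocity component functions
# defined on 0-based voxel coordinates
make_field <- function(dims, fux, fuy, fuz, spacing = 1e-3) {
  X <- array(rep(0:(dims[1] - 1), times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(0:(dims[2] - 1), each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(0:(dims[3] - 1), each = dims[1] * dims[2]), dims)
  Xp <- X * spacing; Yp <- Y * spacing; Zp <- Z * spacing
  list(ux = fux(Xp, Yp, Zp), uy = fuy(Xp, Yp, Zp), uz = fuz(Xp, Yp, Zp),
       rho = array(1, dims), p = array(1 / 3, dims),
       spacing = spacing, dims = dims, solid = array(FALSE, dims))
}
zero_fun <- function(x, y, z) 0 * x

test_that("vorticity and enstrophy reproduce closed-form fields", {
  d <- c(12L, 12L, 12L)
  # uniform flow: no rotation
  f <- vorticity_enstrophy(make_field(d, function(x, y, z) 1 + 0 * x,
                                      zero_fun, zero_fun))
  expect_equal(max(abs(f$enstrophy)), 0)
  # rigid rotation about z: omega = (0, 0, 2 Omega), E = 2 Omega^2
  Om <- 3
  cen <- 5.5e-3
  f <- vorticity_enstrophy(make_field(d, function(x, y, z) -Om * (y - cen),
                                      function(x, y, z) Om * (x - cen), zero_fun))
  inn <- 2:11
  expect_equal(f$wz[inn, inn, inn], array(2 * Om, c(10, 10, 10)), tolerance = 1e-12)
  expect_equal(f$enstrophy[inn, inn, inn], array(2 * Om^2, c(10, 10, 10)),
               tolerance = 1e-12)
  # simple shear u = (gamma z, 0, 0): E = gamma^2 / 2
  gam <- 2
  f <- vorticity_enstrophy(make_field(d, function(x, y, z) gam * z,
                                      zero_fun, zero_fun))
  expect_equal(f$enstrophy[inn, inn, inn], array(gam^2 / 2, c(10, 10, 10)),
               tolerance = 1e-12)
})

test_that("particle seeding is deterministic, pore-restricted and centred", {
  g <- generate_coral(small_coral_params())
  reg <- region_box(c(8, 24), c(8, 24), c(10, 30))
  s1 <- seed_particles(g, reg, n = 200, radius = 6, seed = 5)
  s2 <- seed_particles(g, reg, n = 200, radius = 6, seed = 5)
  expect_identical(s1, s2)
  s3 <- seed_particles(g, reg, n = 200, radius = 6, seed = 6)
  expect_false(identical(s1, s3))
  v <- round(s1) + 1L
  expect_true(all(g$labels[cbind(v[, 1], v[, 2], v[, 3])] != 0L))
  # all-pore sphere: empirical centroid within 3 sigma of the sphere centre
  open <- voxel_geometry(array(2L, c(21, 21, 21)), spacing = 1)
  regall <- region_box(c(0, 20), c(0, 20), c(0, 20))
  n <- 1e4; r <- 6
  s <- seed_particles(open, regall, n = n, radius = r, seed = 1)
  expect_true(all(abs(colMeans(s) - 10) < 3 * r / sqrt(5 * n)))
  # a single-voxel pore region seeds onto that voxel
  one <- array(1L, c(7, 7, 7)); one[4, 4, 4] <- 2L
  gone <- label_inner_pores(voxel_geometry(one, spacing = 1))
  sone <- seed_particles(gone, NULL, n = 5, radius = 0.4, seed = 2)
  expect_true(all(round(sone) == 3))
  # solid-only sphere errors out
  expect_error(seed_particles(gone, region_box(c(0, 1), c(0, 1), c(0, 1)),
                              n = 1, radius = 1, seed = 1), "no pore")
})

test_that("streamlines follow uniform and rotational analytic fields", {
  d <- c(40L, 20L, 20L)
  uni <- make_field(d, function(x, y, z) 2e-3 + 0 * x, zero_fun, zero_fun)
  sl <- trace_streamlines(uni, matrix(c(2, 10, 10), 1), step = 0.5,
                          max_steps = 500)
  pos <- sl$lines[[1]]$positions
  expect_equal(sl$lines[[1]]$termination, "left_domain")
  expect_true(all(abs(pos[, 2] - 10) < 1e-10))
  expect_true(all(abs(diff(pos[, 1]) - 0.5) < 1e-10))
  # rigid rotation: circular orbit with small radius drift per revolution
  rot <- make_field(c(40L, 40L, 5L), function(x, y, z) -(y - 19.5e-3),
                    function(x, y, z) (x - 19.5e-3), zero_fun)
  r0 <- 10
  sl <- trace_streamlines(rot, matrix(c(19.5 + r0, 19.5, 2), 1), step = 0.25,
                          max_steps = ceiling(2 * pi * r0 / 0.25) + 2)
  pos <- sl$lines[[1]]$positions
  rad <- sqrt((pos[, 1] - 19.5)^2 + (pos[, 2] - 19.5)^2)
  expect_lt(abs(rad[length(rad)] - r0) / r0, 0.001)
  # starting on solid voxels is rejected
  uni$solid[4, 11, 11] <- TRUE
  expect_error(trace_streamlines(uni, matrix(c(2.9, 10.4, 10.2), 1)), "solid")
})

test_that("residence time equals L/u for uniform flow and the trimmed mean otherwise", {
  d <- c(40L, 8L, 8L)
  u0 <- 2e-3; sp <- 1e-3
  uni <- make_field(d, function(x, y, z) u0 + 0 * x, zero_fun, zero_fun, spacing = sp)
  starts <- cbind(2, c(3, 4, 5), 4)
  sl <- trace_streamlines(uni, starts, step = 0.25, max_steps = 400)
  reg <- region_box(c(10, 20), c(0, 7), c(0, 7))   # 10 voxels span inside
  rt <- residence_time(sl, reg, confidence = 1)
  expect_equal(rt$t_bar, 10 * sp / u0, tolerance = 1e-10)
  expect_equal(rt$times, rep(10 * sp / u0, 3), tolerance = 1e-10)
  expect_equal(sum(rt$histogram$frequency), 1)
  # trimmed mean over synthetic times {1, 3}: confidence 1 keeps both
  fake <- structure(list(
    lines = list(), step = 0.25, spacing = sp, stagnation = 1e-12),
    class = "streamline_set")
  mk_line <- function(t_tot) {
    n <- 21
    pos <- cbind(seq(10, 20, length.out = n), 4, 4)
    spd <- rep(10 * sp / t_tot, n)
    list(positions = pos, velocity = cbind(spd, 0, 0), speed = spd,
         termination = "left_domain")
  }
  fake$lines <- list(mk_line(1), mk_line(3))
  reg2 <- region_box(c(9.9, 20.1), c(0, 7), c(0, 7))
  rt2 <- residence_time(fake, reg2, confidence = 1)
  expect_equal(rt2$t_bar, 2, tolerance = 1e-9)
  expect_error(residence_time(sl, region_box(c(0, 1), c(6, 7), c(6, 7))),
               "no streamline")
})

test_that("residence times scale inversely with field magnitude and flux linearly", {
  d <- c(40L, 8L, 8L)
  sp <- 1e-3
  reg <- region_box(c(10, 20), c(0, 7), c(0, 7))
  starts <- cbind(2, 3:5, 4)
  t_at <- function(k) {
    f <- make_field(d, function(x, y, z) k * 2e-3 + 0 * x, zero_fun, zero_fun,
                    spacing = sp)
    residence_time(trace_streamlines(f, starts, max_steps = 600), reg,
                   confidence = 1)$t_bar
  }
  expect_equal(t_at(3), t_at(1) / 3, tolerance = 1e-9)
  expect_equal(volume_flux(1e-9, 10), 1e-10)
  expect_equal(volume_flux(1e-9, 20), volume_flux(1e-9, 10) / 2)
  expect_error(volume_flux(1e-9, 0), "positive")
})

test_that("brute-force advection matches streamline residence on analytic fields", {
  d <- c(40L, 8L, 8L)
  sp <- 1e-3; u0 <- 2e-3
  uni <- make_field(d, function(x, y, z) u0 + 0 * x, zero_fun, zero_fun, spacing = sp)
  reg <- region_box(c(10, 20), c(0, 7), c(0, 7))
  starts <- cbind(2, 3:5, 4)
  t_euler <- advect_particles(uni, starts, reg, dt = 0.005, max_steps = 20000)
  expect_equal(mean(t_euler), 10 * sp / u0, tolerance = 0.01)
})

test_that("asymmetry differences vanish for identical slices and negate under mirroring", {
  d <- c(20L, 10L, 10L)
  set.seed(2)
  f <- make_field(d, function(x, y, z) 1e-3 + 0 * x, zero_fun, zero_fun)
  f$ux <- f$ux + array(rnorm(prod(d), sd = 1e-4), d)
  f$p <- array(runif(prod(d)), d)
  same <- list(list(name = "same",
                    upstream = region_box(c(2, 5), c(0, 9), c(0, 9)),
                    downstream = region_box(c(2, 5), c(0, 9), c(0, 9))))
  rep0 <- asymmetry_differences(f, same)
  expect_equal(rep0$difference, rep(0, 3))
  pair <- list(list(name = "p",
                    upstream = region_box(c(2, 5), c(0, 9), c(0, 9)),
                    downstream = region_box(c(14, 17), c(0, 9), c(0, 9))))
  a1 <- asymmetry_differences(f, pair)
  fm <- f
  fm$ux <- f$ux[d[1]:1, , ]; fm$uy <- f$uy[d[1]:1, , ]; fm$uz <- f$uz[d[1]:1, , ]
  fm$p <- f$p[d[1]:1, , ]
  a2 <- asymmetry_differences(fm, pair)
  expect_equal(a2$difference, -a1$difference, tolerance = 1e-10)
  expect_error(asymmetry_differences(f, list(list(name = "x",
    upstream = region_box(c(2, 5), c(0, 9), c(0, 9)),
    downstream = region_box(c(2, 5), c(0, 9), c(0, 9)))),
    mask = array(FALSE, d)), "empty slice")
})

test_that("axial decomposition reports the vertical-velocity fraction", {
  d <- c(10L, 10L, 30L)
  vert <- make_field(d, zero_fun, zero_fun, function(x, y, z) 1e-3 + 0 * x)
  horiz <- make_field(d, function(x, y, z) 1e-3 + 0 * x, zero_fun, zero_fun)
  mask <- array(TRUE, d)
  sects <- list(low = region_box(c(0, 9), c(0, 9), c(0, 14)),
                high = region_box(c(0, 9), c(0, 9), c(15, 29)))
  av <- axial_decomposition(vert, sects, mask)
  expect_equal(av$uz_ratio, c(1, 1))
  ah <- axial_decomposition(horiz, sects, mask)
  expect_equal(ah$uz_ratio, c(0, 0))
  expect_error(axial_decomposition(vert, sects, array(FALSE, d)), "empty")
})
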