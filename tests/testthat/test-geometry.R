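test_that("degenerate geometry is a plain annular tube with exact channel volume", {
  p <- coral_params(dims = c(32, 32, 48), radius = 8, height = 36,
                    channel_radius = 2, channel_base = 4, n_bends = 0,
                    n_corallites = 0, bump_amplitude = 0, apical_radius = 2,
                    seed = 3)
  g <- generate_coral(p)
  # independent rasterization oracle: centre-of-voxel inclusion per slice
  cx <- (32 - 1) / 2
  circle <- 0L
  for (i in 0:31) for (j in 0:31)
    if ((i - cx)^2 + (j - cx)^2 <= 2^2) circle <- circle + 1L
  expect_identical(sum(g$labels == 1L), circle * (36L - 4L))
  # solid voxels form the annulus only
  expect_true(all(g$labels[1, , ] != 0L))
})

test_that("generation is a pure function of the parameter set", {
  g1 <- generate_coral(small_coral_params())
  g2 <- generate_coral(small_coral_params())
  expect_identical(g1$labels, g2$labels)
  g3 <- generate_coral(small_coral_params(seed = 12L))
  expect_false(identical(g1$labels, g3$labels))
  # generation does not disturb the caller's RNG stream
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(generate_coral(small_coral_params())); b <- runif(1)
  expect_identical(a, b)
})

test_that("infeasible parameter combinations raise explicit errors", {
  expect_error(coral_params(channel_radius = 20, radius = 16), "channel radius")
  expect_error(coral_params(dims = c(40, 40, 128), radius = 18), "half-width")
  expect_error(coral_params(dims = c(64, 64, 80), height = 96), "does not fit")
})

test_that("external-pore labelling agrees with a BFS reachability oracle", {
  g <- generate_coral(small_coral_params())
  lab2 <- g$labels
  lab2[lab2 == 1L] <- 2L   # forget the inner labels
  lab2[lab2 == 0L] <- 1L   # back to the raw 2-label scheme
  raw <- voxel_geometry(lab2, spacing = g$spacing)
  strict <- label_inner_pores(raw)
  oracle_ext <- bfs_reachable(lab2 == 2L)
  expect_identical(strict$labels == 2L, oracle_ext)
  # open mouths mean strict reachability leaves no inner pores ...
  expect_identical(sum(strict$labels == 1L), 0L)
  # ... while capping the declared openings recovers the interior
  raw$openings <- g$openings
  capped <- label_inner_pores(raw, cap_openings = TRUE)
  expect_identical(capped$labels, g$labels)
  expect_gt(sum(capped$labels == 1L), 0L)
})

test_that("the channel reaches every corallite cavity and mouth", {
  g <- generate_coral(small_coral_params())
  pore <- g$labels != 0L
  ax <- attr(g, "axis")
  seed <- c(round(ax[20, "x"]), round(ax[20, "y"]), 19) + 1L
  reach <- bfs_from(pore, seed)
  for (zc in attr(g, "corallite_heights")) {
    ring <- which(g$labels[, , zc + 1] != 0L, arr.ind = TRUE)
    expect_true(all(reach[, , zc + 1][ring]),
                info = sprintf("ring at z=%d fully reachable", zc))
  }
  for (op in g$openings) {
    v <- pmin(pmax(round(op$center), 0), dim(g$labels) - 1L) + 1L
    expect_true(reach[v[1], v[2], v[3]],
                info = sprintf("%s mouth reachable", op$kind))
  }
})

test_that("labelling is idempotent and conserves voxel counts", {
  g <- generate_coral(small_coral_params())
  once <- label_inner_pores(g, cap_openings = TRUE)
  twice <- label_inner_pores(once, cap_openings = TRUE)
  expect_identical(once$labels, twice$labels)
  expect_identical(length(once$labels), length(g$labels))
  expect_identical(sum(once$labels == 0L), sum(g$labels == 0L))
})

test_that("sealed cavities and degenerate volumes are classified per definition", {
  cube <- sealed_cavity_cube()
  out <- label_inner_pores(cube)
  expect_identical(sum(out$labels == 1L), 27L)           # 3x3x3 cavity
  expect_true(all(out$labels[1, , ] == 2L))
  openbox <- voxel_geometry(array(2L, c(5, 5, 5)), spacing = 1)
  expect_identical(unique(as.vector(label_inner_pores(openbox)$labels)), 2L)
  allsolid <- voxel_geometry(array(1L, c(4, 4, 4)), spacing = 1)
  expect_warning(res <- label_inner_pores(allsolid), "no pore")
  expect_true(all(res$labels == 0L))
})

test_that("porosity variants match brute-force voxel counting", {
  set.seed(7)
  lab <- array(sample(0:2, 20^3, replace = TRUE, prob = c(.5, .2, .3)), c(20, 20, 20))
  g <- voxel_geometry(lab, spacing = 1e-4)
  pore <- 0L; solid <- 0L
  for (i in 1:20) for (j in 1:20) for (k in 1:20) {
    if (lab[i, j, k] == 0L) solid <- solid + 1L else pore <- pore + 1L
  }
  expect_equal(porosity(g), pore / solid)
  expect_equal(porosity(g, variant = "fraction"), pore / (pore + solid))
  # the printed pore/solid ratio exceeds 1 when pores dominate
  mostly_pore <- voxel_geometry(array(c(0L, rep(2L, 26)), c(3, 3, 3)), spacing = 1)
  expect_gt(porosity(mostly_pore), 1)
  # region restriction and the zero-denominator guard
  reg <- region_box(c(0, 9), c(0, 19), c(0, 19))
  sub <- lab[1:10, , ]
  expect_equal(porosity(g, region = reg), sum(sub != 0L) / sum(sub == 0L))
  nosolid <- voxel_geometry(array(2L, c(4, 4, 4)), spacing = 1)
  expect_error(porosity(nosolid), "denominator")
})

test_that("whole-sample porosity uses the pore-filled reference as printed", {
  g <- generate_coral(small_coral_params())
  gf <- fill_internal_pores(g)
  n <- porosity(g, variant = "whole", filled_reference = gf)
  expect_equal(n, sum(g$labels == 1L) / sum(g$labels == 0L))
  # a geometry identical to its filled reference has no internal pores
  expect_equal(porosity(gf, variant = "whole", filled_reference = gf), 0)
  expect_error(porosity(g, variant = "whole"), "filled_reference")
})

test_that("filling internal pores solidifies exactly the inner space", {
  cube <- label_inner_pores(sealed_cavity_cube())
  filled <- fill_internal_pores(cube)
  expect_identical(sum(filled$labels == 1L), 0L)
  expect_identical(sum(filled$labels == 0L), sum(cube$labels == 0L) + 27L)
  expect_identical(sum(filled$labels == 2L), sum(cube$labels == 2L))
  # volumes without inner pores pass through unchanged
  openbox <- label_inner_pores(voxel_geometry(array(2L, c(5, 5, 5)), spacing = 1))
  expect_identical(fill_internal_pores(openbox)$labels, openbox$labels)
})

test_that("half-turn rotation is an index-mapped involution", {
  g <- generate_coral(small_coral_params())
  r2 <- rotate_half_turn(rotate_half_turn(g))
  expect_identical(r2$labels, g$labels)
  expect_identical(sum(rotate_half_turn(g)$labels == 0L), sum(g$labels == 0L))
  marker <- array(2L, c(6, 5, 4)); marker[1, 1, 1] <- 0L   # solid marker at (0,0,0)
  gm <- voxel_geometry(marker, spacing = 1)
  rot <- rotate_half_turn(gm)
  expect_identical(rot$labels[6, 5, 1], 0L)                # maps to (Nx-1, Ny-1, 0)
  expect_identical(sum(rot$labels == 0L), 1L)
})

test_that("block downsampling takes the majority with solid preference", {
  lab <- array(2L, c(4, 4, 4))
  lab[1:2, 1:2, 1:2] <- 0L     # 8 solid of 8 in block (1,1,1)
  lab[3:4, 1:2, 1:2] <- 1L     # 8 inner
  lab[1, 3, 1] <- 0L           # 1 solid, 7 external: external wins
  g <- voxel_geometry(lab, spacing = 2e-4)
  ds <- downsample_geometry(g, 2)
  expect_identical(dim(ds$labels), c(2L, 2L, 2L))
  expect_identical(ds$labels[1, 1, 1], 0L)
  expect_identical(ds$labels[2, 1, 1], 1L)
  expect_identical(ds$labels[1, 2, 1], 2L)
  expect_equal(ds$spacing, 4e-4)
  # solid wins ties against pore labels (thin-wall preservation)
  tie <- array(c(rep(0L, 4), rep(2L, 4)), c(2, 2, 2))
  gt <- downsample_geometry(voxel_geometry(tie, spacing = 1), 2)
  expect_identical(as.integer(gt$labels), 0L)
})
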