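# Independent oracles used across tests. These deliberately use naive
# R-level algorithms (flat-queue BFS, per-voxel loops) so they share no code
# path with the package implementation.

# BFS over a logical open-set from given 1-based seed voxels (n x 3 matrix);
# returns the reachable logical array (6-connectivity)
bfs_open <- function(open, seeds) {
  d <- dim(open)
  idx <- function(v) v[, 1] + d[1] * (v[, 2] - 1) + d[1] * d[2] * (v[, 3] - 1)
  vis <- array(FALSE, d)
  queue <- matrix(0L, nrow = sum(open) + 1L, ncol = 3)
  head <- 1L; tailp <- 0L
  seeds <- seeds[open[idx(seeds)] & !duplicated(idx(seeds)), , drop = FALSE]
  if (nrow(seeds)) {
    vis[idx(seeds)] <- TRUE
    queue[seq_len(nrow(seeds)), ] <- seeds
    tailp <- nrow(seeds)
  }
  moves <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  while (head <= tailp) {
    v <- queue[head, ]; head <- head + 1L
    for (m in 1:6) {
      w <- v + moves[m, ]
      if (all(w >= 1L) && all(w <= d)) {
        if (open[w[1], w[2], w[3]] && !vis[w[1], w[2], w[3]]) {
          vis[w[1], w[2], w[3]] <- TRUE
          tailp <- tailp + 1L
          queue[tailp, ] <- w
        }
      }
    }
  }
  vis
}

# reachability from all six faces of the bounding box
bfs_reachable <- function(open) {
  d <- dim(open)
  f <- expand.grid
  seeds <- rbind(
    as.matrix(f(x = c(1L, d[1]), y = 1:d[2], z = 1:d[3])),
    as.matrix(f(x = 1:d[1], y = c(1L, d[2]), z = 1:d[3])),
    as.matrix(f(x = 1:d[1], y = 1:d[2], z = c(1L, d[3]))))
  bfs_open(open, seeds)
}

bfs_from <- function(open, seed) bfs_open(open, matrix(seed, ncol = 3))

# a small coral parameter set that keeps per-test generation cheap
small_coral_params <- function(...) {
  args <- list(dims = c(32L, 32L, 48L), radius = 8, height = 36,
               channel_radius = 2, channel_base = 4, n_bends = 2,
               bend_amplitude = 1, n_corallites = 3, corallite_radius = 1,
               mouths_per_corallite = 2, bump_amplitude = 1,
               apical_radius = 3, seed = 11L)
  do.call(coral_params, utils::modifyList(args, list(...)))
}

# hollow cube with a sealed interior cavity, raw 2-label scheme
sealed_cavity_cube <- function(n = 10L, cav = 4:6) {
  lab <- array(2L, c(n, n, n))
  lab[2:(n - 1), 2:(n - 1), 2:(n - 1)] <- 1L
  lab[cav, cav, cav] <- 2L
  voxel_geometry(lab, spacing = 1e-4, provenance = "synthetic sealed-cavity cube")
}
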