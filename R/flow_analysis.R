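# central differences interior, one-sided at the domain boundary
deriv_axis <- function(arr, axis, h) {
  d <- dim(arr)
  n <- d[axis]
  if (n < 2L) return(array(0, d))
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  idx_p <- switch(axis, list(ip, TRUE, TRUE), list(TRUE, ip, TRUE), list(TRUE, TRUE, ip))
  idx_m <- switch(axis, list(im, TRUE, TRUE), list(TRUE, im, TRUE), list(TRUE, TRUE, im))
  diffs <- do.call(`[`, c(list(arr), idx_p)) - do.call(`[`, c(list(arr), idx_m))
  sweep(diffs, axis, (ip - im) * h, `/`)
}

#' Vorticity and enstrophy of a flow field
#'
#' Computes \eqn{\omega = \nabla \times u} by finite differences (central in
#' the interior, one-sided at the domain boundary) and the pointwise
#' enstrophy \eqn{E = |\omega|^2 / 2}, the standard measure of local
#' rotational intensity. Velocity is zero on solid voxels, so near-wall
#' stencils see the no-slip condition; statistics should mask solid cells.
#'
#' @param field a `coral_flow` object, or any list with `ux`, `uy`, `uz`
#'   arrays and a `spacing` (m).
#' @return The input with arrays `wx`, `wy`, `wz` (1/s) and `enstrophy`
#'   (1/s^2) attached.
#' @export
vorticity_enstrophy <- function(field) {
  h <- field$spacing
  dudy <- deriv_axis(field$ux, 2L, h); dudz <- deriv_axis(field$ux, 3L, h)
  dvdx <- deriv_axis(field$uy, 1L, h); dvdz <- deriv_axis(field$uy, 3L, h)
  dwdx <- deriv_axis(field$uz, 1L, h); dwdy <- deriv_axis(field$uz, 2L, h)
  field$wx <- dwdy - dvdz
  field$wy <- dudz - dwdx
  field$wz <- dvdx - dudy
  field$enstrophy <- (field$wx^2 + field$wy^2 + field$wz^2) / 2
  field
}

#' Seed tracer particles in a region's pore space
#'
#' Draws `n` positions uniformly from the sphere of the given radius about
#' the geometric centre of the region's pore space (the centroid of its pore
#' voxels), rejecting draws that land on solid voxels. Deterministic given
#' the seed. This emulates the tracer-release protocol of seeding each
#' analysed sub-volume from its geometric centre area.
#'
#' @param geometry a [voxel_geometry()].
#' @param region a [region_box()] or logical mask.
#' @param n number of particles.
#' @param radius seeding-sphere radius in voxels (the full-resolution
#'   protocol in the source data used 150 lattice cells; scale with the
#'   grid).
#' @param seed integer RNG seed.
#' @param max_tries resampling cap per batch before erroring.
#' @return An `n x 3` matrix of 0-based continuous voxel coordinates.
#' @export
seed_particles <- function(geometry, region, n, radius, seed = 1L,
                           max_tries = 200L) {
  m <- label_masks(geometry)
  keep <- m$pore & region_mask(region, dim(geometry$labels))
  if (!any(keep)) stopf("region contains no pore voxels")
  idx <- which(keep, arr.ind = TRUE) - 1L
  cen <- colMeans(idx)
  d <- dim(geometry$labels)
  pore_at <- function(p) {
    v <- clampi(round(p), 0L, matrix(rep(d - 1L, each = nrow(p)), ncol = 3))
    m$pore[cbind(v[, 1] + 1L, v[, 2] + 1L, v[, 3] + 1L)]
  }
  with_seed(seed, {
    out <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(out) < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stopf("seeding sphere contains too little pore space (radius %g)", radius)
      k <- max(n - nrow(out), 1L) * 2L
      dir <- matrix(stats::rnorm(3 * k), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
      r <- radius * stats::runif(k)^(1 / 3)
      cand <- sweep(dir * r, 2, cen, `+`)
      inside <- cand[, 1] >= 0 & cand[, 1] <= d[1] - 1 &
        cand[, 2] >= 0 & cand[, 2] <= d[2] - 1 &
        cand[, 3] >= 0 & cand[, 3] <= d[3] - 1
      cand <- cand[inside, , drop = FALSE]
      if (nrow(cand)) cand <- cand[pore_at(cand), , drop = FALSE]
      out <- rbind(out, cand)
    }
    out[seq_len(n), , drop = FALSE]
  })
}

#' Trace streamlines through a steady flow field
#'
#' Integrates \eqn{dx/ds = u(x)/|u(x)|} with fixed-step RK4 in arc length and
#' trilinear velocity interpolation (zero inside solid voxels, which enforces
#' the no-slip wall). A streamline terminates on leaving the domain, on
#' stagnation (speed below `stagnation`), or at `max_steps`.
#'
#' @param field a `coral_flow` object (or list with `ux`, `uy`, `uz`,
#'   `spacing`, `dims`, `solid`).
#' @param starts n x 3 matrix of 0-based voxel coordinates (e.g. from
#'   [seed_particles()]); starts on solid voxels are an error.
#' @param step arc-length step in voxel units (default 0.25).
#' @param max_steps per-streamline step cap.
#' @param stagnation speed floor (m/s); defaults to 1e-6 x the field maximum.
#' @return An object of class `streamline_set`: a list of streamlines, each
#'   with `positions` (voxel coords), `velocity` (m/s), `speed`, and a
#'   `termination` code (`"left_domain"`, `"stagnation"`, `"max_steps"`).
#' @export
trace_streamlines <- function(field, starts, step = 0.25, max_steps = 5000L,
                              stagnation = NULL) {
  starts <- matrix(starts, ncol = 3)
  d <- field$dims %||% dim(field$ux)
  if (!is.null(field$solid)) {
    v <- clampi(round(starts), 0L, matrix(rep(d - 1L, each = nrow(starts)), ncol = 3))
    on_solid <- field$solid[cbind(v[, 1] + 1L, v[, 2] + 1L, v[, 3] + 1L)]
    if (any(on_solid))
      stopf("%d start position(s) lie on solid voxels", sum(on_solid))
  }
  if (is.null(stagnation))
    stagnation <- 1e-6 * max(sqrt(field$ux^2 + field$uy^2 + field$uz^2))
  res <- trace_streamlines_cpp(as.vector(field$ux), as.vector(field$uy),
                               as.vector(field$uz), as.integer(d), starts,
                               step, as.integer(max_steps), stagnation)
  why <- c("left_domain", "stagnation", "max_steps")
  lines <- lapply(seq_along(res$paths), function(i) {
    m <- res$paths[[i]]
    list(positions = m[, 1:3, drop = FALSE],
         velocity = m[, 4:6, drop = FALSE],
         speed = sqrt(rowSums(m[, 4:6, drop = FALSE]^2)),
         termination = why[res$code[i]])
  })
  structure(list(lines = lines, step = step, spacing = field$spacing,
                 stagnation = stagnation),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  n <- length(x$lines)
  term <- table(vapply(x$lines, `[[`, "", "termination"))
  cat(sprintf("<streamline_set> %d streamlines (arc step %.3g voxels)\n", n, x$step))
  cat("  termination:", paste(names(term), term, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Residence time of streamlines in a region
#'
#' For each streamline the residence time inside the region is the sum of
#' segment length over speed, \eqn{t = \sum_i |l_{i+1} - l_i| / |u_i|}, with
#' the speed taken at the segment's first point; segments are counted when
#' their midpoint lies in the region. The summary retains streamlines up to
#' the `confidence` quantile of residence time (trimming never-exiting or
#' near-stagnant paths) before averaging; the untrimmed mean is also
#' reported. The normalized frequency histogram sums to 1.
#'
#' @param streamlines a [trace_streamlines()] result.
#' @param region a [region_box()], or a logical voxel mask (e.g. the inner
#'   pore space) for non-rectangular regions.
#' @param confidence retained quantile (default 0.95).
#' @param bins histogram bin count.
#' @return An object of class `residence_stats` with fields `t_bar` (s),
#'   `t_bar_raw`, `times` (per retained streamline), `times_raw`,
#'   `histogram` (tibble: `mid`, `frequency`), `n_streamline`, `confidence`.
#' @export
residence_time <- function(streamlines, region, confidence = 0.95, bins = 24L) {
  stopifnot(inherits(streamlines, "streamline_set"))
  times <- streamline_region_times(streamlines, region)
  crossed <- times > 0
  if (!any(crossed)) stopf("no streamline crosses the region")
  tr <- times[crossed]
  cut <- quantile(tr, confidence, names = FALSE, type = 7)
  kept <- tr[tr <= cut]
  h <- graphics::hist(kept, breaks = bins, plot = FALSE)
  structure(list(
    t_bar = mean(kept), t_bar_raw = mean(tr),
    times = kept, times_raw = tr,
    histogram = tibble(mid = h$mids, frequency = h$counts / sum(h$counts)),
    n_streamline = length(tr), n_retained = length(kept),
    confidence = confidence, region = region),
    class = "residence_stats")
}

#' @export
print.residence_stats <- function(x, ...) {
  cat(sprintf("<residence_stats> %d streamlines through region (%d retained at %.0f%%)\n",
              x$n_streamline, x$n_retained, 100 * x$confidence))
  cat(sprintf("  mean residence time: %.4g s (untrimmed %.4g s)\n",
              x$t_bar, x$t_bar_raw))
  invisible(x)
}

#' @describeIn residence_time per-streamline residence times as a tibble.
#' @param x a `residence_stats` object.
#' @param ... unused.
#' @export
tidy.residence_stats <- function(x, ...) {
  tibble(time = x$times_raw,
         retained = x$times_raw <= max(x$times, -Inf))
}

#' @describeIn residence_time one-row summary.
#' @export
glance.residence_stats <- function(x, ...) {
  tibble(t_bar = x$t_bar, t_bar_raw = x$t_bar_raw,
         n_streamline = x$n_streamline, n_retained = x$n_retained,
         confidence = x$confidence)
}

#' Per-streamline residence times in a region
#'
#' The residence-time vector underlying [residence_time()], one entry per
#' streamline in input order (0 for streamlines that never cross the
#' region). Useful for matched-pair comparisons against an independent
#' integrator on the same start positions.
#'
#' @inheritParams residence_time
#' @return Numeric vector, one residence time (s) per streamline.
#' @export
streamline_region_times <- function(streamlines, region) {
  sp <- streamlines$spacing
  vapply(streamlines$lines, function(l) {
    pos <- l$positions
    if (nrow(pos) < 2L) return(0)
    a <- pos[-nrow(pos), , drop = FALSE]
    b <- pos[-1L, , drop = FALSE]
    mid <- (a + b) / 2
    inside <- points_in_region(region, mid)
    if (!any(inside)) return(0)
    seg <- sqrt(rowSums((b - a)^2)) * sp
    spd <- l$speed[-length(l$speed)]
    sum((seg / pmax(spd, streamlines$stagnation))[inside])
  }, numeric(1))
}

#' Brute-force particle advection (independent reference integrator)
#'
#' Advects particles through the steady field with fixed-time-step forward
#' Euler, \eqn{x_{n+1} = x_n + u(x_n)\,\Delta t}, recording time spent inside
#' a region. Deliberately a different scheme from the arc-length RK4 used by
#' [trace_streamlines()], so the two can cross-check each other's residence
#' times.
#'
#' @param field a `coral_flow` object.
#' @param starts n x 3 matrix of 0-based voxel start coordinates.
#' @param region a [region_box()] or logical voxel mask.
#' @param dt time step (s); default resolves the fastest cell in a quarter
#'   voxel.
#' @param max_steps step cap.
#' @param stagnation speed floor (m/s).
#' @return Numeric vector of per-particle residence times (s).
#' @export
advect_particles <- function(field, starts, region, dt = NULL,
                             max_steps = 200000L, stagnation = NULL) {
  d <- field$dims %||% dim(field$ux)
  sp <- field$spacing
  umax <- max(sqrt(field$ux^2 + field$uy^2 + field$uz^2))
  if (is.null(dt)) dt <- 0.25 * sp / umax
  if (is.null(stagnation)) stagnation <- 1e-6 * umax
  p <- matrix(starts, ncol = 3)
  n <- nrow(p)
  active <- rep(TRUE, n)
  tin <- numeric(n)
  interp <- function(pts) {
    # vectorized trilinear interpolation at voxel-centre nodes
    i0 <- pmin(pmax(floor(pts), 0), matrix(rep(d - 2L, each = nrow(pts)), ncol = 3))
    fr <- pts - i0
    acc <- matrix(0, nrow(pts), 3)
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (dx * fr[, 1] + (1 - dx) * (1 - fr[, 1])) *
           (dy * fr[, 2] + (1 - dy) * (1 - fr[, 2])) *
           (dz * fr[, 3] + (1 - dz) * (1 - fr[, 3]))
      ci <- cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)
      acc <- acc + w * cbind(field$ux[ci], field$uy[ci], field$uz[ci])
    }
    acc
  }
  for (it in seq_len(max_steps)) {
    if (!any(active)) break
    ia <- which(active)
    u <- interp(p[ia, , drop = FALSE])
    spd <- sqrt(rowSums(u^2))
    stalled <- spd < stagnation
    inside <- points_in_region(region, p[ia, , drop = FALSE])
    tin[ia[inside & !stalled]] <- tin[ia[inside & !stalled]] + dt
    p[ia, ] <- p[ia, , drop = FALSE] + u / sp * dt
    out <- p[ia, 1] < 0 | p[ia, 2] < 0 | p[ia, 3] < 0 |
      p[ia, 1] > d[1] - 1 | p[ia, 2] > d[2] - 1 | p[ia, 3] > d[3] - 1
    active[ia[out | stalled]] <- FALSE
  }
  tin
}

#' Average volume flow flux through a pore system
#'
#' \eqn{Q = V_{pore} / \bar t}: the inner-pore volume divided by the mean
#' particle residence time.
#'
#' @param inner_pore_volume pore volume (m^3).
#' @param t_bar mean residence time (s).
#' @return Flux in m^3/s.
#' @export
volume_flux <- function(inner_pore_volume, t_bar) {
  stopifnot(inner_pore_volume > 0)
  if (t_bar <= 0) stopf("mean residence time must be positive")
  inner_pore_volume / t_bar
}

#' Upstream/downstream asymmetry of pressure, velocity and enstrophy
#'
#' For each paired slice, reports the mean over pore voxels of pressure,
#' velocity magnitude and enstrophy on the upstream and downstream sides and
#' their difference (upstream minus downstream) with standard errors.
#' Positive differences indicate upstream flow dominance.
#'
#' @param field a `coral_flow` object (enstrophy is computed on the fly if
#'   absent).
#' @param slice_pairs list of pairs, each a list with `name`, `upstream` and
#'   `downstream` [region_box()]es (e.g. `coral_regions()$slice_pairs`).
#' @param mask optional logical array restricting the statistics (e.g. inner
#'   pore space); defaults to all non-solid voxels.
#' @return A tibble of class `asymmetry_report`: one row per pair x quantity
#'   with columns `pair`, `quantity`, `upstream`, `downstream`, `difference`,
#'   `se`.
#' @export
asymmetry_differences <- function(field, slice_pairs, mask = NULL) {
  if (is.null(field$enstrophy)) field <- vorticity_enstrophy(field)
  d <- field$dims
  if (is.null(mask)) mask <- !field$solid
  qty <- list(pressure = field$p,
              velocity = sqrt(field$ux^2 + field$uy^2 + field$uz^2),
              enstrophy = field$enstrophy)
  rows <- list()
  for (pr in slice_pairs) {
    up <- region_mask(pr$upstream, d) & mask
    dn <- region_mask(pr$downstream, d) & mask
    if (!any(up) || !any(dn)) stopf("empty slice in pair '%s'", pr$name)
    for (qn in names(qty)) {
      vu <- qty[[qn]][up]; vd <- qty[[qn]][dn]
      vu <- vu[is.finite(vu)]; vd <- vd[is.finite(vd)]
      rows[[length(rows) + 1]] <- tibble(
        pair = pr$name, quantity = qn,
        upstream = mean(vu), downstream = mean(vd),
        difference = mean(vu) - mean(vd),
        se = sqrt(sd(vu)^2 / length(vu) + sd(vd)^2 / length(vd)))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("asymmetry_report", class(out))
  out
}

#' Axial-channel velocity decomposition
#'
#' Per channel section, the mean velocity magnitude and the mean ratio of the
#' vertical velocity component to the total magnitude, \eqn{u_z/|u|}, over
#' pore voxels in the axial channel. Cells below a speed floor are excluded
#' from the ratio (their direction is noise). A ratio near 1 indicates
#' longitudinal (vertical) flow; near 0, transverse flow.
#'
#' @param field a `coral_flow` object.
#' @param sections named list of [region_box()]es partitioning the channel
#'   height (e.g. `coral_regions()$axial_sections`).
#' @param channel_mask logical array selecting channel pore voxels.
#' @param speed_floor minimum speed (m/s) for the ratio; defaults to 1e-6 x
#'   the field maximum.
#' @return A tibble with columns `section`, `mean_speed`, `uz_ratio`,
#'   `n_voxels`.
#' @export
axial_decomposition <- function(field, sections, channel_mask,
                                speed_floor = NULL) {
  spd <- sqrt(field$ux^2 + field$uy^2 + field$uz^2)
  if (is.null(speed_floor)) speed_floor <- 1e-6 * max(spd)
  d <- field$dims
  rows <- lapply(names(sections), function(nm) {
    sel <- region_mask(sections[[nm]], d) & channel_mask
    if (!any(sel)) stopf("axial section '%s' is empty", nm)
    s <- spd[sel]
    ok <- s > speed_floor
    tibble(section = nm, mean_speed = mean(s),
           uz_ratio = if (any(ok)) mean(field$uz[sel][ok] / s[ok]) else NA_real_,
           n_voxels = sum(sel))
  })
  do.call(rbind, rows)
}
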