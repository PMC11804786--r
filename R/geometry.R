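#' Labelled voxel volume
#'
#' Container for a segmented 3-D voxel volume on a regular grid. Two label
#' schemes are accepted, mirroring the two conventions used at different
#' stages of micro-CT post-processing:
#' * canonical 3-label scheme: `0` = skeleton solid, `1` = inner pore,
#'   `2` = external pore;
#' * raw 2-label scheme: `1` = solid, `2` = pore (as produced by pixel
#'   classification of grayscale stacks).
#'
#' @param labels integer 3-D array of labels.
#' @param spacing voxel edge length in metres (scalar, > 0).
#' @param origin physical coordinates (m) of voxel `(0,0,0)`; length-3 numeric.
#' @param provenance free-text description of how the volume was produced.
#' @param openings optional list of declared skeleton openings, each a list
#'   with elements `center` (0-based voxel coordinates) and `radius` (voxels).
#'   Openings let [label_inner_pores()] treat pore space behind an open mouth
#'   as inner pore space (see its `cap_openings` argument).
#' @return An object of class `voxel_geometry`.
#' @seealso [generate_coral()], [label_inner_pores()], [porosity()]
#' @export
voxel_geometry <- function(labels, spacing, origin = c(0, 0, 0),
                           provenance = "unspecified", openings = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stopf("`labels` must be a 3-D array")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:2))
    stopf("labels must be drawn from {0, 1, 2}")
  if (!is_scalar_num(spacing) || spacing <= 0)
    stopf("`spacing` must be a positive scalar (metres)")
  structure(
    list(labels = labels, spacing = spacing, origin = as.numeric(origin),
         provenance = provenance, openings = openings),
    class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  d <- dim(x$labels)
  m <- label_masks(x)
  cat(sprintf("<voxel_geometry> %d x %d x %d voxels, spacing %.3g m\n",
              d[1], d[2], d[3], x$spacing))
  cat(sprintf("  solid: %d  inner pore: %d  external pore: %d\n",
              sum(m$solid), sum(m$inner), sum(m$pore) - sum(m$inner)))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.voxel_geometry <- function(x) dim(x$labels)

# solid / pore / inner masks under either label scheme
label_masks <- function(geometry) {
  lab <- geometry$labels
  if (any(lab == 0L)) {          # canonical scheme
    list(solid = lab == 0L, pore = lab != 0L, inner = lab == 1L,
         scheme = "canonical")
  } else {                       # raw 2-label scheme (solid 1, pore 2)
    list(solid = lab == 1L, pore = lab == 2L, inner = array(FALSE, dim(lab)),
         scheme = "two-label")
  }
}

#' Parameters for the synthetic coral-geometry generator
#'
#' Describes a coral-like porous cylinder with the structural features seen in
#' segmented micro-CT stacks of branching corals: a rough surface with bumps,
#' radial interconnected corallite cavities, a central axial channel with
#' bending points, an apical (tip) corallite, and an optional local defect.
#'
#' @param dims grid shape in voxels, length 3 (x, y, z; z is vertical).
#' @param radius,height branch cylinder radius and height in voxels.
#' @param channel_radius radius of the central axial channel (voxels).
#' @param channel_base height (voxels) at which the axial channel starts;
#'   below it the branch core is solid, emulating the densely calcified base.
#' @param n_bends number of bending (inflection) points along the axial
#'   channel.
#' @param bend_amplitude lateral amplitude of channel bends (voxels).
#' @param n_corallites number of annular corallite cavities (flat,
#'   washer-shaped rings encircling the channel, connected to it) stacked
#'   along the branch.
#' @param corallite_radius half-thickness of each annular cavity and radius
#'   of its radial mouths (voxels).
#' @param mouths_per_corallite number of radial mouths connecting each
#'   annular cavity to the surface.
#' @param bump_amplitude extra radius of the hemispherical surface bump
#'   co-located with each corallite mouth (voxels; 0 disables bumps).
#' @param apical_radius mouth radius of the apical corallite: the channel
#'   widens into a funnel over the top few voxel layers. Set equal to
#'   `channel_radius` for a plain (unflared) channel.
#' @param defect if `TRUE`, carve a through-wall defect (e.g. predator
#'   damage) of radius `defect_radius` at fractional height
#'   `defect_height_frac`.
#' @param defect_radius,defect_height_frac defect geometry, see `defect`.
#' @param seal_openings if `TRUE`, corallite cavities stop short of the
#'   surface and the channel is capped below the tip, producing strictly
#'   sealed inner pore space (useful for testing reachability labelling).
#' @param spacing voxel edge length in metres.
#' @param seed integer seed; the generated volume is a pure function of the
#'   parameter set including the seed.
#' @return An object of class `coral_params`.
#' @export
coral_params <- function(dims = c(64L, 64L, 128L), radius = 16, height = 96,
                         channel_radius = 4, channel_base = 6,
                         n_bends = 3, bend_amplitude = 2.5,
                         n_corallites = 8, corallite_radius = 2,
                         mouths_per_corallite = 3,
                         bump_amplitude = 2, apical_radius = 5,
                         defect = FALSE, defect_radius = 3,
                         defect_height_frac = 0.8,
                         seal_openings = FALSE,
                         spacing = 3.75e-4, seed = 1L) {
  p <- list(dims = as.integer(dims), radius = radius, height = height,
            channel_radius = channel_radius, channel_base = channel_base,
            n_bends = as.integer(n_bends), bend_amplitude = bend_amplitude,
            n_corallites = as.integer(n_corallites),
            corallite_radius = corallite_radius,
            mouths_per_corallite = as.integer(mouths_per_corallite),
            bump_amplitude = bump_amplitude, apical_radius = apical_radius,
            defect = isTRUE(defect), defect_radius = defect_radius,
            defect_height_frac = defect_height_frac,
            seal_openings = isTRUE(seal_openings),
            spacing = spacing, seed = as.integer(seed))
  validate_coral_params(p)
  structure(p, class = "coral_params")
}

validate_coral_params <- function(p) {
  if (length(p$dims) != 3L || any(p$dims < 8L))
    stopf("`dims` must be three voxel counts >= 8")
  if (p$channel_radius >= p$radius)
    stopf("channel radius (%g) must be smaller than cylinder radius (%g)",
          p$channel_radius, p$radius)
  if (p$apical_radius >= p$radius)
    stopf("apical corallite radius must be smaller than the cylinder radius")
  if (p$height > p$dims[3] - 2L)
    stopf("coral height %g does not fit the grid (nz = %d, 2 headroom voxels)",
          p$height, p$dims[3])
  reach <- p$radius + p$bump_amplitude + p$corallite_radius + 1
  half <- (min(p$dims[1:2]) - 1) / 2
  if (reach > half)
    stopf("radius + bump + corallite (%g voxels) exceeds the lateral half-width (%g)",
          reach, half)
  if (p$channel_base >= p$height / 2)
    stopf("channel base must lie in the lower half of the branch")
  invisible(p)
}

# voxel-coordinate arrays over an index box (0-based, inclusive)
box_coords <- function(xs, ys, zs) {
  nb <- c(length(xs), length(ys), length(zs))
  list(
    X = array(rep(xs, times = nb[2] * nb[3]), nb),
    Y = array(rep(rep(ys, each = nb[1]), times = nb[3]), nb),
    Z = array(rep(zs, each = nb[1] * nb[2]), nb))
}

clampi <- function(v, lo, hi) {
  v <- pmin(pmax(round(v), lo), hi)
  storage.mode(v) <- "integer"
  v
}

#' Generate a synthetic coral-like labelled voxel volume
#'
#' Rasterizes a vertical porous cylinder with a central (optionally bending)
#' axial channel, annular interconnected corallite cavities joined to the
#' channel and opening to the surface through radial mouths, hemispherical
#' surface bumps at the mouths, an apical corallite funnel at the tip, and an
#' optional through-wall defect. All
#' primitives are rasterized by centre-of-voxel inclusion so voxel counts are
#' exact integers. The result is a stand-in for a segmented micro-CT stack of
#' a branching-coral skeleton.
#'
#' The output uses the canonical 3-label scheme; inner pores are identified by
#' boundary flood fill with the generated openings capped (see
#' [label_inner_pores()]), so the channel and corallite system is labelled as
#' inner pore space even though its mouths are open.
#'
#' @param params a [coral_params()] object.
#' @return A [voxel_geometry()] with attributes recording the generating
#'   parameters and the channel axis path.
#' @examples
#' geom <- generate_coral(coral_params(dims = c(32, 32, 48), radius = 8,
#'                                     height = 36, channel_radius = 2,
#'                                     channel_base = 4, n_corallites = 4,
#'                                     corallite_radius = 1, bump_amplitude = 1,
#'                                     apical_radius = 3, seed = 7))
#' porosity(geom)
#' @export
generate_coral <- function(params) {
  if (!inherits(params, "coral_params")) params <- do.call(coral_params, params)
  p <- params
  nx <- p$dims[1]; ny <- p$dims[2]; nz <- p$dims[3]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  h <- round(p$height)

  with_seed(p$seed, {
    # bending axial channel: piecewise-linear lateral offsets at inflection knots
    zs <- 0:(h - 1)
    if (p$n_bends > 0) {
      zb <- p$channel_base +
        (1:p$n_bends) / (p$n_bends + 1) * (h - 1 - p$channel_base)
      ang <- stats::runif(p$n_bends, 0, 2 * pi)
      amp <- p$bend_amplitude * stats::runif(p$n_bends, 0.7, 1)
      kz <- c(0, zb, h - 1)
      kx <- c(0, amp * cos(ang), 0)
      ky <- c(0, amp * sin(ang), 0)
      axis_x <- cx + approx(kz, kx, xout = zs)$y
      axis_y <- cy + approx(kz, ky, xout = zs)$y
    } else {
      axis_x <- rep(cx, h); axis_y <- rep(cy, h)
    }

    labels <- array(2L, dim = c(nx, ny, nz))

    # (solid) branch cylinder
    r2 <- outer((0:(nx - 1) - cx)^2, (0:(ny - 1) - cy)^2, `+`)
    cyl <- r2 <= p$radius^2
    for (z in 0:(h - 1)) labels[, , z + 1][cyl] <- 0L

    # annular corallite cavities: heights and per-ring mouth azimuths
    # (golden-angle sequence with seeded jitter)
    openings <- list()
    cor_info <- NULL
    mouth_info <- NULL
    if (p$n_corallites > 0) {
      zj <- p$channel_base + 2 +
        (seq_len(p$n_corallites) - 0.5) / p$n_corallites *
          (h - p$channel_base - 14)
      zj <- round(zj)
      cor_info <- cbind(z = zj)
      ml <- list()
      for (j in seq_len(p$n_corallites)) {
        th <- 2 * pi * 0.381966 *
          (seq_len(p$mouths_per_corallite) + (j - 1) * p$mouths_per_corallite) +
          stats::runif(p$mouths_per_corallite, -0.25, 0.25)
        ml[[j]] <- cbind(z = rep(zj[j], p$mouths_per_corallite), theta = th)
      }
      mouth_info <- do.call(rbind, ml)
    }

    # surface bumps first (solid spheres at the cavity mouths), then carve
    carve_ball <- function(cen, r, value) {
      xs <- clampi(floor(cen[1] - r), 0L, nx - 1L):clampi(ceiling(cen[1] + r), 0L, nx - 1L)
      ys <- clampi(floor(cen[2] - r), 0L, ny - 1L):clampi(ceiling(cen[2] + r), 0L, ny - 1L)
      zsb <- clampi(floor(cen[3] - r), 0L, nz - 1L):clampi(ceiling(cen[3] + r), 0L, nz - 1L)
      g <- box_coords(xs, ys, zsb)
      m <- (g$X - cen[1])^2 + (g$Y - cen[2])^2 + (g$Z - cen[3])^2 <= r^2
      sub <- labels[xs + 1, ys + 1, zsb + 1, drop = FALSE]
      sub[m] <- value
      labels[xs + 1, ys + 1, zsb + 1] <<- sub
    }
    carve_radial_tube <- function(z0, theta, r_tube, L_out) {
      # tube around the horizontal segment from the channel axis outwards
      x0 <- axis_x[z0 + 1]; y0 <- axis_y[z0 + 1]
      dxy <- c(cos(theta), sin(theta))
      xe <- x0 + L_out * dxy[1]; ye <- y0 + L_out * dxy[2]
      xs <- clampi(floor(min(x0, xe) - r_tube), 0L, nx - 1L):
            clampi(ceiling(max(x0, xe) + r_tube), 0L, nx - 1L)
      ys <- clampi(floor(min(y0, ye) - r_tube), 0L, ny - 1L):
            clampi(ceiling(max(y0, ye) + r_tube), 0L, ny - 1L)
      zsb <- clampi(z0 - ceiling(r_tube), 0L, nz - 1L):
             clampi(z0 + ceiling(r_tube), 0L, nz - 1L)
      g <- box_coords(xs, ys, zsb)
      tpar <- pmin(pmax((g$X - x0) * dxy[1] + (g$Y - y0) * dxy[2], 0), L_out)
      d2 <- (g$X - x0 - tpar * dxy[1])^2 + (g$Y - y0 - tpar * dxy[2])^2 +
        (g$Z - z0)^2
      m <- d2 <= r_tube^2
      sub <- labels[xs + 1, ys + 1, zsb + 1, drop = FALSE]
      sub[m] <- 2L
      labels[xs + 1, ys + 1, zsb + 1] <<- sub
    }

    if (!is.null(mouth_info) && p$bump_amplitude > 0 && !p$seal_openings) {
      rb <- p$corallite_radius + p$bump_amplitude
      for (j in seq_len(nrow(mouth_info))) {
        z0 <- mouth_info[j, "z"]; th <- mouth_info[j, "theta"]
        cen <- c(axis_x[z0 + 1] + p$radius * cos(th),
                 axis_y[z0 + 1] + p$radius * sin(th), z0)
        carve_ball(cen, rb, 0L)
      }
    }

    # axial channel (with apical funnel) carved as pore
    funnel_len <- 6
    z_top <- if (p$seal_openings) h - 4 else h - 1
    for (z in p$channel_base:z_top) {
      rc <- p$channel_radius
      if (p$apical_radius > p$channel_radius && z >= h - 1 - funnel_len)
        rc <- p$channel_radius + (p$apical_radius - p$channel_radius) *
          (z - (h - 1 - funnel_len)) / funnel_len
      m <- outer((0:(nx - 1) - axis_x[z + 1])^2,
                 (0:(ny - 1) - axis_y[z + 1])^2, `+`) <= rc^2
      sl <- labels[, , z + 1]
      sl[m] <- 2L
      labels[, , z + 1] <- sl
    }
    if (!p$seal_openings) {
      top_cen <- c(axis_x[h], axis_y[h], h - 1)
      openings[[length(openings) + 1]] <-
        list(center = top_cen, radius = p$apical_radius + 2, depth = 4,
             kind = "apical")
    }

    # annular corallite cavities (washer-shaped, joined to the channel),
    # then their radial mouths through the outer wall
    if (!is.null(cor_info)) {
      r_in <- max(p$channel_radius - 1, 1)
      r_out <- p$radius - 2
      for (j in seq_len(nrow(cor_info))) {
        z0 <- cor_info[j, "z"]
        zlo <- max(z0 - ceiling(p$corallite_radius), 0)
        zhi <- min(z0 + ceiling(p$corallite_radius), h - 1)
        for (z in zlo:zhi) {
          # inner edge follows the bending axis, outer edge keeps a fixed
          # wall thickness to the (fixed-centre) cylinder surface
          rr_ax <- outer((0:(nx - 1) - axis_x[z + 1])^2,
                         (0:(ny - 1) - axis_y[z + 1])^2, `+`)
          rr_cy <- outer((0:(nx - 1) - cx)^2, (0:(ny - 1) - cy)^2, `+`)
          m <- rr_ax >= r_in^2 & rr_cy <= r_out^2
          sl <- labels[, , z + 1]
          sl[m] <- 2L
          labels[, , z + 1] <- sl
        }
      }
      if (!p$seal_openings) {
        L_open <- p$radius + p$bump_amplitude + p$corallite_radius + 1
        for (j in seq_len(nrow(mouth_info))) {
          z0 <- mouth_info[j, "z"]; th <- mouth_info[j, "theta"]
          carve_radial_tube(z0, th, p$corallite_radius, L_open)
          mouth <- c(axis_x[z0 + 1] + p$radius * cos(th),
                     axis_y[z0 + 1] + p$radius * sin(th), z0)
          openings[[length(openings) + 1]] <-
            list(center = mouth, radius = p$corallite_radius + 2.5,
                 kind = "corallite")
        }
      }
    }

    # local through-wall defect
    if (p$defect) {
      zd <- round(p$defect_height_frac * h)
      thd <- stats::runif(1, 0, 2 * pi)
      carve_radial_tube(zd, thd, p$defect_radius,
                        p$radius + p$bump_amplitude + p$defect_radius + 1)
      openings[[length(openings) + 1]] <-
        list(center = c(axis_x[zd + 1] + p$radius * cos(thd),
                        axis_y[zd + 1] + p$radius * sin(thd), zd),
             radius = p$defect_radius + 2.5, kind = "defect")
    }

    geom <- voxel_geometry(
      labels, spacing = p$spacing,
      provenance = sprintf("synthetic coral (seed %d)", p$seed),
      openings = if (length(openings)) openings else NULL)
    geom <- label_inner_pores(geom, cap_openings = length(openings) > 0)
    attr(geom, "params") <- p
    attr(geom, "axis") <- cbind(z = zs, x = axis_x, y = axis_y)
    attr(geom, "corallite_heights") <- if (is.null(cor_info)) integer(0)
                                       else as.integer(cor_info[, "z"])
    attr(geom, "mouths") <- mouth_info
    geom
  })
}

#' Classify pore voxels as inner or external
#'
#' Pore voxels reachable from any face of the bounding box through
#' face-connected (6-connectivity) pore paths are labelled external (2); the
#' remaining pore voxels are labelled inner (1); solid is relabelled 0. Input
#' may use either the raw 2-label scheme (solid 1 / pore 2) or the canonical
#' scheme; the operation is idempotent on canonical volumes.
#'
#' With `cap_openings = TRUE`, pore voxels inside the volume's declared
#' openings (see [voxel_geometry()]) are treated as sealed during the flood
#' fill, so pore space that communicates with the exterior only through a
#' declared skeleton mouth is classified as inner. Under strict reachability
#' (`cap_openings = FALSE`) such space is external.
#'
#' @param geometry a [voxel_geometry()].
#' @param cap_openings seal the declared openings during the reachability
#'   flood fill (default `FALSE`).
#' @param connectivity pore connectivity; only 6 (face adjacency) is
#'   supported.
#' @return A canonical-scheme [voxel_geometry()].
#' @export
label_inner_pores <- function(geometry, cap_openings = FALSE, connectivity = 6) {
  if (connectivity != 6) stopf("only 6-connectivity is supported")
  m <- label_masks(geometry)
  d <- dim(geometry$labels)
  if (!any(m$pore)) {
    warnf("volume contains no pore voxels; returning all-solid relabelled volume")
    out <- geometry
    out$labels <- array(0L, d)
    return(out)
  }
  open <- m$pore
  if (cap_openings && length(geometry$openings)) {
    for (op in geometry$openings) {
      cen <- op$center; r <- op$radius
      depth <- op$depth %||% NULL   # vertical plug (e.g. apical mouth)
      zlo <- if (is.null(depth)) cen[3] - r else cen[3] - depth
      zhi <- if (is.null(depth)) cen[3] + r else cen[3]
      xs <- clampi(floor(cen[1] - r), 0L, d[1] - 1L):clampi(ceiling(cen[1] + r), 0L, d[1] - 1L)
      ys <- clampi(floor(cen[2] - r), 0L, d[2] - 1L):clampi(ceiling(cen[2] + r), 0L, d[2] - 1L)
      zs <- clampi(floor(zlo), 0L, d[3] - 1L):clampi(ceiling(zhi), 0L, d[3] - 1L)
      g <- box_coords(xs, ys, zs)
      cap <- if (is.null(depth))
        (g$X - cen[1])^2 + (g$Y - cen[2])^2 + (g$Z - cen[3])^2 <= r^2
      else
        (g$X - cen[1])^2 + (g$Y - cen[2])^2 <= r^2
      sub <- open[xs + 1, ys + 1, zs + 1, drop = FALSE]
      sub[cap] <- FALSE
      open[xs + 1, ys + 1, zs + 1] <- sub
    }
  }
  ext <- array(flood_from_boundary_cpp(as.vector(open), d), d)
  lab <- array(0L, d)
  lab[m$pore] <- 1L
  lab[ext] <- 2L
  out <- geometry
  out$labels <- lab
  out
}

#' Voxel porosity of a labelled volume
#'
#' Two printed-count variants plus the conventional pore fraction:
#' * `"specific"`: pore count divided by solid count over the selected region,
#'   \eqn{n = S_{sr}(2) / S_{sr}(1)}. Note this is a pore/solid ratio and can
#'   exceed 1 when pores outnumber solid voxels.
#' * `"whole"`: inner-pore content of a sample against its pore-filled
#'   reference, \eqn{n = [S(2) - S_F(2)] / S(1)}, where the filled reference
#'   (see [fill_internal_pores()]) retains only the external pore space.
#' * `"fraction"`: conventional porosity pore/(pore + solid) over the region.
#'
#' All counts are exact integers before division.
#'
#' @param geometry a [voxel_geometry()].
#' @param variant `"specific"` (default), `"whole"`, or `"fraction"`.
#' @param region optional [region_box()] or logical mask restricting the
#'   counts (ignored for `"whole"`, which is defined on the full domain).
#' @param filled_reference the pore-filled reference volume (required for
#'   `"whole"`).
#' @return Porosity as a ratio (>= 0).
#' @export
porosity <- function(geometry, variant = c("specific", "whole", "fraction"),
                     region = NULL, filled_reference = NULL) {
  variant <- match.arg(variant)
  m <- label_masks(geometry)
  if (variant == "whole") {
    if (is.null(filled_reference))
      stopf("variant \"whole\" requires `filled_reference`")
    mf <- label_masks(filled_reference)
    solid <- sum(m$solid)
    if (solid == 0L) stopf("no solid voxels: porosity denominator is zero")
    return((sum(m$pore) - sum(mf$pore)) / solid)
  }
  keep <- region_mask(region, dim(geometry$labels))
  pore <- sum(m$pore & keep)
  solid <- sum(m$solid & keep)
  if (variant == "specific") {
    if (solid == 0L) stopf("no solid voxels in region: porosity denominator is zero")
    pore / solid
  } else {
    if (pore + solid == 0L) stopf("empty region")
    pore / (pore + solid)
  }
}

#' Fill the internal pore space of a volume
#'
#' All inner-pore voxels become solid; external pores are untouched. This
#' produces the pore-filled reference geometry used by the `"whole"` porosity
#' variant and by filled-skeleton flow comparisons (only the external surface
#' roughness is retained, so flow can only bypass the skeleton).
#'
#' @param geometry a canonical-scheme [voxel_geometry()] (2-label input is
#'   relabelled first via [label_inner_pores()]).
#' @return A [voxel_geometry()] with inner pores solidified.
#' @export
fill_internal_pores <- function(geometry) {
  m <- label_masks(geometry)
  if (m$scheme != "canonical") geometry <- label_inner_pores(geometry)
  out <- geometry
  out$labels[out$labels == 1L] <- 0L
  out$provenance <- paste(out$provenance, "+ internal pores filled")
  out
}

#' Rotate a volume half a turn about the vertical axis
#'
#' Rotates the label grid 180 degrees about the z axis (the sample's natural
#' vertical orientation), so ambient flow meets the structure from the
#' opposite side. Applying the rotation twice returns the original volume.
#'
#' @param geometry a [voxel_geometry()].
#' @return The rotated [voxel_geometry()].
#' @export
rotate_half_turn <- function(geometry) {
  d <- dim(geometry$labels)
  out <- geometry
  out$labels <- geometry$labels[d[1]:1, d[2]:1, , drop = FALSE]
  if (!is.null(out$openings))
    out$openings <- lapply(out$openings, function(op) {
      op$center[1:2] <- c(d[1] - 1 - op$center[1], d[2] - 1 - op$center[2])
      op
    })
  ax <- attr(geometry, "axis")
  if (!is.null(ax)) {
    ax[, "x"] <- d[1] - 1 - ax[, "x"]
    ax[, "y"] <- d[2] - 1 - ax[, "y"]
    attr(out, "axis") <- ax
  }
  out$provenance <- paste(geometry$provenance, "+ rotated 180 deg about z")
  out
}

#' Downsample a labelled volume by block majority vote
#'
#' Reduces each `factor^3` block of voxels to a single voxel carrying the
#' most frequent label in the block. Ties involving solid resolve to solid
#' (preserving thin walls); a tie between inner and external pore resolves to
#' inner. The grid is cropped to a multiple of `factor` if necessary.
#'
#' @param geometry a canonical-scheme [voxel_geometry()].
#' @param factor integer block edge (default 4).
#' @return The reduced [voxel_geometry()] with `spacing` scaled by `factor`.
#' @export
downsample_geometry <- function(geometry, factor = 4L) {
  f <- as.integer(factor)
  if (f < 2L) return(geometry)
  d <- dim(geometry$labels)
  dc <- (d %/% f) * f
  lab <- geometry$labels[seq_len(dc[1]), seq_len(dc[2]), seq_len(dc[3]), drop = FALSE]
  block_sum <- function(x) {
    a <- array(x, c(f, dc[1] %/% f, f, dc[2] %/% f, f, dc[3] %/% f))
    a <- aperm(a, c(1, 3, 5, 2, 4, 6))
    dim(a) <- c(f^3, prod(dc) %/% f^3)
    array(colSums(a), dc %/% f)
  }
  n0 <- block_sum(lab == 0L); n1 <- block_sum(lab == 1L); n2 <- block_sum(lab == 2L)
  out_lab <- array(2L, dc %/% f)
  out_lab[n1 >= n2] <- 1L
  out_lab[n0 >= pmax(n1, n2)] <- 0L
  voxel_geometry(out_lab, spacing = geometry$spacing * f,
                 origin = geometry$origin,
                 provenance = paste(geometry$provenance,
                                    sprintf("+ downsampled x%d (majority, solid-preferred)", f)))
}
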