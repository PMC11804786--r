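#' Axis-aligned region of a voxel grid
#'
#' Regions select sub-volumes for porosity, residence-time and asymmetry
#' statistics. Coordinates are 0-based voxel indices, inclusive at both ends.
#'
#' @param xlim,ylim,zlim length-2 integer ranges (0-based, inclusive).
#' @param name optional region name.
#' @return An object of class `region_box`.
#' @export
region_box <- function(xlim, ylim, zlim, name = NULL) {
  stopifnot(length(xlim) == 2L, length(ylim) == 2L, length(zlim) == 2L)
  structure(list(xlim = as.numeric(xlim), ylim = as.numeric(ylim),
                 zlim = as.numeric(zlim), name = name),
            class = "region_box")
}

#' @export
print.region_box <- function(x, ...) {
  cat(sprintf("<region_box%s> x [%g, %g]  y [%g, %g]  z [%g, %g]\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$xlim[1], x$xlim[2], x$ylim[1], x$ylim[2], x$zlim[1], x$zlim[2]))
  invisible(x)
}

# logical mask over a grid for a region (NULL region = whole grid)
region_mask <- function(region, dims) {
  if (is.null(region)) return(array(TRUE, dims))
  if (is.logical(region)) {
    if (!identical(dim(region), as.integer(dims)))
      stopf("region mask dimensions do not match the grid")
    return(region)
  }
  if (!inherits(region, "region_box")) stopf("region must be a region_box or mask")
  xi <- clampi(region$xlim[1], 0L, dims[1] - 1L):clampi(region$xlim[2], 0L, dims[1] - 1L)
  yi <- clampi(region$ylim[1], 0L, dims[2] - 1L):clampi(region$ylim[2], 0L, dims[2] - 1L)
  zi <- clampi(region$zlim[1], 0L, dims[3] - 1L):clampi(region$zlim[2], 0L, dims[3] - 1L)
  m <- array(FALSE, dims)
  m[xi + 1, yi + 1, zi + 1] <- TRUE
  m
}

# are continuous voxel-coordinate points inside the region (box or label mask)?
points_in_region <- function(region, pts) {
  if (is.logical(region)) {
    d <- dim(region)
    v <- clampi(pts, 0L, matrix(rep(d - 1L, each = nrow(pts)), ncol = 3))
    return(region[cbind(v[, 1] + 1L, v[, 2] + 1L, v[, 3] + 1L)])
  }
  pts[, 1] >= region$xlim[1] & pts[, 1] <= region$xlim[2] &
    pts[, 2] >= region$ylim[1] & pts[, 2] <= region$ylim[2] &
    pts[, 3] >= region$zlim[1] & pts[, 3] <= region$zlim[2]
}

#' Standard analysis regions for a synthetic coral geometry
#'
#' Builds the named sub-volumes used throughout the flow analysis from the
#' generator metadata attached by [generate_coral()]: the four
#' upstream/downstream x top/bottom sub-volumes, three paired
#' upstream/downstream slices (top, centre, bottom), and the four axial
#' channel sections (TipTop, Top, Center, Bottom). The ambient flow is
#' assumed to travel in +x.
#'
#' @param geometry a [generate_coral()] output.
#' @return A list with elements `subvolumes`, `slice_pairs`, `axial_sections`
#'   (each a named list of [region_box()]es) plus `channel_mask`, a logical
#'   array selecting pore voxels within the axial channel.
#' @export
coral_regions <- function(geometry) {
  p <- attr(geometry, "params")
  ax <- attr(geometry, "axis")
  if (is.null(p) || is.null(ax))
    stopf("geometry lacks generator metadata; pass a generate_coral() output")
  d <- dim(geometry$labels)
  h <- round(p$height); zb <- p$channel_base
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
  r <- p$radius
  zmid <- round(zb + 0.5 * (h - zb))

  sub <- list(
    top_upstream = region_box(c(cx - r, cx - 1), c(cy - r, cy + r), c(zmid, h - 1),
                              name = "Top-Upstream"),
    top_downstream = region_box(c(cx + 1, cx + r), c(cy - r, cy + r), c(zmid, h - 1),
                                name = "Top-Downstream"),
    bottom_upstream = region_box(c(cx - r, cx - 1), c(cy - r, cy + r), c(zb, zmid - 1),
                                 name = "Bottom-Upstream"),
    bottom_downstream = region_box(c(cx + 1, cx + r), c(cy - r, cy + r), c(zb, zmid - 1),
                                   name = "Bottom-Downstream"))

  # paired upstream/downstream slabs over the top, centre and bottom thirds
  # of the corallite span: each slab averages over the full annular
  # corallite system of its section, so the comparison is insensitive to
  # where individual mouths happen to sit
  span <- h - zb
  mk_pair <- function(f0, f1, nm) {
    zr <- c(round(zb + f0 * span), round(zb + f1 * span) - 1)
    list(name = nm,
         upstream = region_box(c(cx - r, cx - 2), c(cy - r, cy + r), zr),
         downstream = region_box(c(cx + 2, cx + r), c(cy - r, cy + r), zr))
  }
  pairs <- list(
    top = mk_pair(2 / 3, 1, "top"),
    center = mk_pair(1 / 3, 2 / 3, "center"),
    bottom = mk_pair(0, 1 / 3, "bottom"))

  span <- h - 1 - zb
  sect <- list(
    tiptop = region_box(c(0, d[1] - 1), c(0, d[2] - 1),
                        c(round(zb + 0.85 * span), h - 1), name = "TipTop"),
    top = region_box(c(0, d[1] - 1), c(0, d[2] - 1),
                     c(round(zb + 0.6 * span), round(zb + 0.85 * span) - 1),
                     name = "Top"),
    center = region_box(c(0, d[1] - 1), c(0, d[2] - 1),
                        c(round(zb + 0.3 * span), round(zb + 0.6 * span) - 1),
                        name = "Center"),
    bottom = region_box(c(0, d[1] - 1), c(0, d[2] - 1),
                        c(zb, round(zb + 0.3 * span) - 1), name = "Bottom"))

  # pore voxels within the (bending) axial channel
  chan <- array(FALSE, d)
  rc2 <- (p$channel_radius + 0.5)^2
  for (z in zb:(h - 1)) {
    m <- outer((0:(d[1] - 1) - ax[z + 1, "x"])^2,
               (0:(d[2] - 1) - ax[z + 1, "y"])^2, `+`) <= rc2
    chan[, , z + 1] <- m
  }
  chan <- chan & (geometry$labels != 0L)

  list(subvolumes = sub, slice_pairs = pairs, axial_sections = sect,
       channel_mask = chan)
}

#' Monitor points for interior/ambient speed comparison
#'
#' Picks a sheltered interior monitor point -- mid-annulus inside the
#' corallite cavity nearest a quarter of the branch height, at the azimuth
#' farthest from that cavity's mouths -- and a free-stream reference point
#' upstream of the branch at 5/8 height. Both are deterministic functions of
#' the geometry.
#'
#' @param geometry a [generate_coral()] output.
#' @return A list with integer voxel coordinates `interior` and `ambient`.
#' @export
coral_monitor_points <- function(geometry) {
  p <- attr(geometry, "params")
  ax <- attr(geometry, "axis")
  ch <- attr(geometry, "corallite_heights")
  if (is.null(p) || length(ch) == 0)
    stopf("geometry lacks corallite metadata; pass a generate_coral() output")
  h <- round(p$height)
  zc <- ch[which.min(abs(ch - 0.25 * h))]
  mouths <- attr(geometry, "mouths")
  th_m <- mouths[mouths[, "z"] == zc, "theta"] %% (2 * pi)
  cand <- seq(0, 2 * pi, length.out = 721)[-721]
  gap <- vapply(cand, function(th) {
    dd <- abs(th - th_m) %% (2 * pi)
    min(pmin(dd, 2 * pi - dd))
  }, numeric(1))
  th_best <- cand[which.max(gap)]
  rho <- (p$channel_radius + p$radius - 2) / 2
  interior <- c(round(ax[zc + 1, "x"] + rho * cos(th_best)),
                round(ax[zc + 1, "y"] + rho * sin(th_best)), zc)
  d <- dim(geometry$labels)
  ambient <- c(5L, round((d[2] - 1) / 2), round(0.625 * h))
  list(interior = as.integer(interior), ambient = as.integer(ambient))
}
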