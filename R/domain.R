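## Cell type codes shared with the C++ solver core.
CT_FLUID <- 0L
CT_IMPLANT <- 1L
CT_BONE <- 2L

## Zone codes (0 = solid / no zone).
ZN_INTERFACE <- 1L
ZN_THREAD <- 2L
ZN_OUTER <- 3L

## Vectorized even-odd point-in-polygon (ray casting along +x).
points_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## Vectorized min distance from points to a closed polyline.
points_polygon_distance <- function(px, py, xy) {
  e <- polygon_edges(xy)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(e))) {
    ax <- e[i, 1]; ay <- e[i, 2]; bx <- e[i, 3]; by <- e[i, 4]
    vx <- bx - ax; vy <- by - ay
    l2 <- vx * vx + vy * vy
    t <- if (l2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / l2))
         else 0
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

## Shoelace area of a closed polygon (mm^2).
polygon_area <- function(xy) {
  nxt <- c(seq_len(nrow(xy))[-1], 1L)
  abs(sum(xy[, 1] * xy[nxt, 2] - xy[nxt, 1] * xy[, 2])) / 2
}

#' Rasterize an implant profile into a structured flow domain
#'
#' Builds the uniform structured grid of the 2D half-domain: symmetry axis
#' on the left, implant solid in the interior, a bone wall of solid cells
#' on the right separated from the implant crest by `gap`, an apex inlet
#' along the bottom, a side-wall inlet through the bone, and the outlet at
#' the top.
#'
#' @param profile an [build_implant_profile()] object, or `NULL` for an
#'   all-fluid domain (then `domain_mm` must be given).
#' @param gap implant-bone gap, crest to bone wall (mm).
#' @param h grid spacing (um). Must resolve the gap with at least 8 cells.
#' @param apex_clearance fluid clearance below the implant apex (mm).
#' @param top_clearance fluid clearance above the implant top (mm).
#' @param bone_cells thickness of the bone wall in cells.
#' @param side_inlet_height height of the bone side-wall inlet segment (mm).
#' @param side_inlet_offset vertical offset of the side inlet above the
#'   implant apex level (mm).
#' @param domain_mm domain size `c(width, height)` in mm when
#'   `profile = NULL`.
#' @return An object of class `domain_geometry`: grid dimensions `nx`,
#'   `ny`, spacing `h_um`, cell-center coordinates `x`, `y` (mm), `type`
#'   matrix (0 fluid, 1 implant, 2 bone), inlet/outlet segment
#'   descriptions, and the implant-surface distance field.
#' @export
rasterize_domain <- function(profile, gap = 0.3, h = 25,
                             apex_clearance = 0.6, top_clearance = 0.6,
                             bone_cells = 2L, side_inlet_height = 0.6,
                             side_inlet_offset = 0, domain_mm = NULL) {
  h_mm <- h / 1000
  if (!is.null(profile)) {
    stopifnot(inherits(profile, "implant_profile"))
    if (h_mm > gap / 8)
      stop(sprintf(
        "rasterize_domain: h = %g um too coarse; the %g mm gap needs >= 8 cells",
        h, gap))
    w_fluid <- profile$crest_halfwidth + gap
    height <- apex_clearance + profile$length + top_clearance
  } else {
    if (is.null(domain_mm))
      stop("rasterize_domain: domain_mm required when profile is NULL")
    w_fluid <- domain_mm[1]
    height <- domain_mm[2]
    bone_cells <- 0L
  }
  nx_fluid <- as.integer(round(w_fluid / h_mm))
  nx <- nx_fluid + as.integer(bone_cells)
  ny <- as.integer(round(height / h_mm))
  x <- (seq_len(nx) - 0.5) * h_mm
  y <- (seq_len(ny) - 0.5) * h_mm
  type <- matrix(CT_FLUID, nx, ny)
  dist_implant <- matrix(Inf, nx, ny)
  if (bone_cells > 0L) type[(nx_fluid + 1L):nx, ] <- CT_BONE
  if (!is.null(profile)) {
    xy <- profile$xy
    xy[, 2] <- xy[, 2] + apex_clearance
    px <- rep(x, times = ny); py <- rep(y, each = nx)
    keep <- px <= profile$crest_halfwidth + 2 * h_mm  # only near the implant
    inside <- logical(length(px))
    inside[keep] <- points_in_polygon(px[keep], py[keep], xy)
    type[matrix(inside, nx, ny) & type == CT_FLUID] <- CT_IMPLANT
    near <- px <= w_fluid  # distances only needed in the fluid gap
    d <- rep(Inf, length(px))
    d[near] <- points_polygon_distance(px[near], py[near], xy)
    dist_implant <- matrix(d, nx, ny)
  }
  ## inlet / outlet segments
  apex_inlet_i <- which(type[, 1] == CT_FLUID)
  side_j <- integer(0)
  if (!is.null(profile) && side_inlet_height > 0 && bone_cells > 0L) {
    y0 <- apex_clearance + side_inlet_offset
    side_j <- which(y >= y0 & y <= y0 + side_inlet_height &
                      type[nx_fluid, ] == CT_FLUID)
  }
  outlet_i <- which(type[, ny] == CT_FLUID)
  geom <- structure(
    list(nx = nx, ny = ny, h_um = h, x = x, y = y, type = type,
         zone = matrix(0L, nx, ny), dist_implant = dist_implant,
         gap_mm = gap, nx_fluid = nx_fluid, profile = profile,
         apex_clearance = if (is.null(profile)) 0 else apex_clearance,
         inlet_apex_i = apex_inlet_i, inlet_side_j = side_j,
         outlet_i = outlet_i, interface_thickness_um = NA_real_),
    class = "domain_geometry"
  )
  geom
}

#' @export
print.domain_geometry <- function(x, ...) {
  cat(sprintf(
    "<domain_geometry> %d x %d cells at h = %g um (%d fluid, %d implant, %d bone)\n",
    x$nx, x$ny, x$h_um, sum(x$type == CT_FLUID), sum(x$type == CT_IMPLANT),
    sum(x$type == CT_BONE)))
  if (any(x$zone > 0))
    cat(sprintf("  zones: interface %d, thread %d, outer %d cells\n",
                sum(x$zone == ZN_INTERFACE), sum(x$zone == ZN_THREAD),
                sum(x$zone == ZN_OUTER)))
  invisible(x)
}

#' Assign the three peri-implant analysis zones
#'
#' Labels every fluid cell with exactly one zone: `interface` (fluid within
#' `interface_thickness` of the implant surface), `thread` (fluid inside
#' the thread envelope, between the crest line and the implant core, not
#' already interface), and `outer` (all remaining fluid).
#'
#' @param geom a [rasterize_domain()] result built from an implant profile.
#' @param interface_thickness thickness of the interface band (um).
#' @return `geom` with the `zone` matrix filled in.
#' @export
assign_zones <- function(geom, interface_thickness = 100) {
  stopifnot(inherits(geom, "domain_geometry"))
  if (!is.null(geom$profile) &&
      interface_thickness / 1000 >= geom$gap_mm)
    stop("assign_zones: interface_thickness must be smaller than the gap")
  t_mm <- interface_thickness / 1000
  fluid <- geom$type == CT_FLUID
  zone <- matrix(0L, geom$nx, geom$ny)
  zone[fluid] <- ZN_OUTER
  if (!is.null(geom$profile)) {
    p <- geom$profile
    iface <- fluid & geom$dist_implant <= t_mm
    zone[iface] <- ZN_INTERFACE
    if (!any(is.na(p$thread_envelope))) {
      env <- p$thread_envelope + geom$apex_clearance
      inx <- geom$x < p$crest_halfwidth
      iny <- geom$y >= env[1] & geom$y <= env[2]
      thr <- fluid & outer(inx, iny) & !iface
      zone[thr] <- ZN_THREAD
    }
  }
  geom$zone <- zone
  geom$interface_thickness_um <- interface_thickness
  geom
}

#' Count disjoint thread-zone pockets
#'
#' Connected components (4-neighbour) of the thread-labeled cells; for the
#' default screw profile this equals the number of implant threads.
#'
#' @param geom a zoned [domain_geometry][rasterize_domain()].
#' @return Integer number of disjoint thread pockets.
#' @export
thread_pocket_count <- function(geom) {
  lab <- geom$zone == ZN_THREAD
  if (!any(lab)) return(0L)
  nx <- geom$nx; ny <- geom$ny
  seen <- matrix(FALSE, nx, ny)
  comp <- 0L
  idx <- which(lab, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i0 <- idx[k, 1]; j0 <- idx[k, 2]
    if (seen[i0, j0]) next
    comp <- comp + 1L
    stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- cur[1]; j <- cur[2]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny &&
            lab[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  comp
}

#' Measured minimum implant-bone clearance
#'
#' Scans grid rows containing implant cells and returns the smallest fluid
#' span between implant and bone (mm); equals the designed gap to within
#' one cell.
#'
#' @param geom a [domain_geometry][rasterize_domain()].
#' @return Minimum clearance (mm).
#' @export
measure_min_clearance <- function(geom) {
  h_mm <- geom$h_um / 1000
  cl <- Inf
  for (j in seq_len(geom$ny)) {
    col <- geom$type[, j]
    imp <- which(col == CT_IMPLANT)
    if (!length(imp)) next
    nfluid <- sum(col[(max(imp) + 1):geom$nx] == CT_FLUID)
    cl <- min(cl, nfluid * h_mm)
  }
  cl
}
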