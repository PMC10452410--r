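#' Build a screw-shaped implant cross-section profile
#'
#' Constructs the closed boundary polyline of a 2D half-section through the
#' implant axis: a core rectangle with `thread_count` triangular thread
#' ridges on the lateral flank. Coordinates are in mm with `x = 0` on the
#' implant axis and `y = 0` at the implant apex (bottom).
#'
#' The thread ridges sit on the flank starting `thread_start` above the
#' apex; ridge `k` has its base on `[thread_start + (k-1) pitch,
#' thread_start + (k-1) pitch + base]` with `base = 0.6 * pitch`, and its
#' tip reaches the crest half-width `diameter / 2`. The thread envelope
#' (used for zone assignment) spans `thread_count * pitch` from
#' `thread_start`, which leaves exactly one open bay per thread.
#'
#' @param length implant length (mm).
#' @param diameter implant outer (crest) diameter (mm).
#' @param thread_count number of thread ridges.
#' @param thread_depth radial thread depth (mm); `0` gives a smooth
#'   rectangle profile with no ridges.
#' @param thread_pitch vertical distance between successive ridges (mm).
#' @param thread_start vertical offset of the first ridge base above the
#'   apex (mm).
#' @return An object of class `implant_profile` with the closed polyline
#'   `xy` (counterclockwise, mm), the nominal dimensions, and the thread
#'   envelope.
#' @export
build_implant_profile <- function(length = 11, diameter = 4,
                                  thread_count = 3, thread_depth = 0.35,
                                  thread_pitch = 1.2, thread_start = 0.5) {
  if (!(length > 0 && diameter > 0))
    stop("build_implant_profile: dimensions must be > 0")
  if (thread_depth < 0 || thread_pitch <= 0)
    stop("build_implant_profile: invalid thread geometry")
  if (thread_depth >= diameter / 2)
    stop("build_implant_profile: thread_depth must be < diameter/2")
  n <- as.integer(thread_count)
  if (n < 0) stop("build_implant_profile: thread_count must be >= 0")
  if (thread_depth > 0 && n > 0 &&
      thread_start + n * thread_pitch > length)
    stop("build_implant_profile: threads do not fit within implant length")
  r_crest <- diameter / 2
  r_core <- r_crest - thread_depth
  base <- 0.6 * thread_pitch
  pts <- list(c(0, 0), c(r_core, 0))
  ridges <- numeric(0)
  if (thread_depth > 0 && n > 0) {
    for (k in seq_len(n)) {
      yb <- thread_start + (k - 1) * thread_pitch
      pts <- c(pts, list(c(r_core, yb),
                         c(r_crest, yb + base / 2),
                         c(r_core, yb + base)))
      ridges <- c(ridges, yb + base / 2)
    }
  }
  pts <- c(pts, list(c(r_core, length), c(0, length)))
  xy <- do.call(rbind, pts)
  ## drop consecutive duplicate vertices (e.g. ridge base meeting flank end)
  keep <- c(TRUE, rowSums(abs(diff(xy))) > 1e-12)
  xy <- xy[keep, , drop = FALSE]
  ## envelope: first ridge tip to the end of the last bay, so each thread
  ## contributes exactly one pocket between consecutive crest lines
  envelope <- if (thread_depth > 0 && n > 0)
    c(thread_start + base / 2, thread_start + n * thread_pitch)
  else c(NA_real_, NA_real_)
  structure(
    list(xy = xy, length = length, diameter = diameter,
         thread_count = if (thread_depth > 0) n else 0L,
         thread_depth = thread_depth, thread_pitch = thread_pitch,
         thread_start = thread_start, ridge_tips = ridges,
         core_halfwidth = r_core, crest_halfwidth = r_crest,
         thread_envelope = envelope, texture = NULL),
    class = "implant_profile"
  )
}

#' @export
print.implant_profile <- function(x, ...) {
  cat(sprintf(
    "<implant_profile> %g mm x %g mm (half-width %g), %d thread ridge(s)%s\n",
    x$length, x$diameter, x$crest_halfwidth, x$thread_count,
    if (!is.null(x$texture)) paste0(", texture: ", x$texture$kind) else ""))
  invisible(x)
}

## Closed-polygon edges as (x1, y1, x2, y2) rows.
polygon_edges <- function(xy) {
  nxt <- c(seq_len(nrow(xy))[-1], 1L)
  cbind(xy, xy[nxt, , drop = FALSE])
}

#' Total arc length of a profile boundary polyline
#' @param profile an [build_implant_profile()] object.
#' @return Perimeter of the closed boundary (mm).
#' @export
profile_arc_length <- function(profile) {
  e <- polygon_edges(profile$xy)
  sum(sqrt((e[, 3] - e[, 1])^2 + (e[, 4] - e[, 2])^2))
}

## Proper-crossing test between all non-adjacent segment pairs of the
## closed polyline. O(n^2) sweep, vectorized over one index.
polygon_self_intersects <- function(xy, tol = 1e-12) {
  e <- polygon_edges(xy)
  n <- nrow(e)
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    ## skip the closing edge's adjacency with edge 1
    if (i == 1L) j <- j[j != n]
    p1x <- e[i, 1]; p1y <- e[i, 2]; p2x <- e[i, 3]; p2y <- e[i, 4]
    q1x <- e[j, 1]; q1y <- e[j, 2]; q2x <- e[j, 3]; q2y <- e[j, 4]
    d1 <- cross2(p2x - p1x, p2y - p1y, q1x - p1x, q1y - p1y)
    d2 <- cross2(p2x - p1x, p2y - p1y, q2x - p1x, q2y - p1y)
    d3 <- cross2(q2x - q1x, q2y - q1y, p1x - q1x, p1y - q1y)
    d4 <- cross2(q2x - q1x, q2y - q1y, p2x - q1x, p2y - q1y)
    hit <- (d1 * d2 < -tol) & (d3 * d4 < -tol)
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Apply surface texture to an implant profile
#'
#' Meso-scale spikes are appended as geometric serrations (a triangular
#' sawtooth of period `spike_width` and peak-to-valley `spike_height`)
#' along the implant-facing boundary; segments lying on the symmetry axis
#' are left untouched. The nano scale is never geometrically resolved at
#' profile scale: it is recorded as an annotation on the profile (the
#' `texture` field) and consumed by the flow solver through the effective
#' wetting / drag-layer models. An amorphous spec returns the profile
#' unchanged apart from the annotation.
#'
#' @param profile an [build_implant_profile()] object.
#' @param spec a [texture_spec()].
#' @param resolve_meso if `TRUE` (default) and the meso scale is active,
#'   serrate the boundary geometrically; if `FALSE`, only annotate.
#' @return The textured `implant_profile` (with `texture` set).
#' @export
apply_texture_to_profile <- function(profile, spec, resolve_meso = TRUE) {
  stopifnot(inherits(profile, "implant_profile"),
            inherits(spec, "texture_spec"))
  profile$texture <- spec
  if (!("meso" %in% active_scales(spec)) || !resolve_meso) return(profile)
  w <- spec$spike_width / 1000   # mm
  amp <- spec$spike_height / 1000
  xy <- profile$xy
  e <- polygon_edges(xy)
  out <- list()
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1:2]; q <- e[i, 3:4]
    seg <- q - p
    len <- sqrt(sum(seg^2))
    on_axis <- abs(p[1]) < 1e-12 && abs(q[1]) < 1e-12
    out[[length(out) + 1L]] <- p
    if (!on_axis && len > w) {
      nhalf <- floor(len / (w / 2))
      tvals <- seq_len(nhalf - 1L) * (w / 2) / len
      nrm <- c(seg[2], -seg[1]) / len   # outward normal (CCW polygon)
      sgn <- rep_len(c(1, -1), length(tvals)) * amp / 2
      mid <- cbind(p[1] + tvals * seg[1] + sgn * nrm[1],
                   p[2] + tvals * seg[2] + sgn * nrm[2])
      out[[length(out) + 1L]] <- mid
    }
  }
  xy2 <- do.call(rbind, out)
  if (polygon_self_intersects(xy2))
    stop("apply_texture_to_profile: serrated boundary self-intersects")
  profile$xy <- xy2
  profile
}
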