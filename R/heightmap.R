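#' Construct a surface height map
#'
#' A `heightmap` is a regular lateral grid of surface heights, the carrier of
#' texture and of the areal roughness metrics Sa / Sz / Sdr. Heights and
#' spacing are in micrometres. Sample `[i, j]` sits at lateral coordinates
#' `((i-1) * spacing, (j-1) * spacing)`.
#'
#' @param heights numeric matrix of surface heights (um).
#' @param spacing lateral sample spacing (um), `> 0`.
#' @return An object of class `heightmap` with fields `heights`, `spacing`
#'   and `extent` (lateral size in um, `dim(heights) * spacing`).
#' @export
heightmap <- function(heights, spacing) {
  heights <- as.matrix(heights)
  stopifnot(is.numeric(heights), is.numeric(spacing), length(spacing) == 1L)
  if (!(spacing > 0)) stop("heightmap: spacing must be > 0")
  if (!all(is.finite(heights))) stop("heightmap: all heights must be finite")
  structure(
    list(heights = heights, spacing = as.numeric(spacing),
         extent = dim(heights) * as.numeric(spacing)),
    class = "heightmap"
  )
}

#' @export
print.heightmap <- function(x, ...) {
  cat(sprintf("<heightmap> %d x %d samples, spacing %g um, extent %g x %g um\n",
              nrow(x$heights), ncol(x$heights), x$spacing,
              x$extent[1], x$extent[2]))
  invisible(x)
}

#' Describe a surface texture
#'
#' Parameterizes the three surface topographies compared in the model:
#' `"amorphous"` (no structure), `"nano"` (trabeculae-like nodular
#' protrusions), and `"hybrid"` (meso-scale spikes carved by crisscrossing
#' grooves, overlaid with the nano nodules). Meso dimensions are in um,
#' nano dimensions in nm.
#'
#' @param kind one of `"amorphous"`, `"nano"`, `"hybrid"`.
#' @param spike_height meso spike peak-to-valley height (um).
#' @param spike_width meso spike period / width (um).
#' @param nodule_height nano nodule height (nm).
#' @param nodule_width nano nodule width / period (nm).
#' @param nano_representation how the solver treats the nano scale:
#'   `"effective_wetting"` (Wenzel contact-angle correction, default),
#'   `"drag_layer"` (adds a thin porous drag layer), or `"resolved"`
#'   (geometric rendering; only sensible on tiny patch domains).
#' @param seed integer seed for stochastic nodule jitter.
#' @param jitter relative nodule amplitude jitter in `[0, 1)`; `0` (default)
#'   gives a perfectly periodic array.
#' @return An object of class `texture_spec`.
#' @export
texture_spec <- function(kind = c("amorphous", "nano", "hybrid"),
                         spike_height = 40, spike_width = 50,
                         nodule_height = 300, nodule_width = 300,
                         nano_representation = c("effective_wetting",
                                                 "drag_layer", "resolved"),
                         seed = 0L, jitter = 0) {
  kind <- match.arg(kind)
  nano_representation <- match.arg(nano_representation)
  if (kind != "amorphous") {
    if (!(nodule_height > 0 && nodule_width > 0))
      stop("texture_spec: nano scale active, nodule dimensions must be > 0")
  }
  if (kind == "hybrid") {
    if (!(spike_height > 0 && spike_width > 0))
      stop("texture_spec: meso scale active, spike dimensions must be > 0")
  }
  if (jitter < 0 || jitter >= 1) stop("texture_spec: jitter must be in [0, 1)")
  structure(
    list(kind = kind, spike_height = spike_height, spike_width = spike_width,
         nodule_height = nodule_height, nodule_width = nodule_width,
         nano_representation = nano_representation,
         seed = as.integer(seed), jitter = jitter),
    class = "texture_spec"
  )
}

#' Which texture scales are active for a texture kind
#' @param spec a [texture_spec()].
#' @return character vector, subset of `c("meso", "nano")`.
#' @export
active_scales <- function(spec) {
  switch(spec$kind,
         amorphous = character(0),
         nano = "nano",
         hybrid = c("meso", "nano"))
}

## Periodic "tent" profile: 1 at multiples of period, 0 at odd half-periods.
tent01 <- function(x, period) {
  u <- x / period
  1 - 2 * abs(u - round(u))
}

## Meso spike field (um): pyramidal spikes left by grooves carved in two
## perpendicular directions; groove floors are flat over a fraction
## `floor_frac` of the flank (carved grooves bottom out), so both extrema
## are attained exactly on sufficiently fine sample grids.
meso_height_field <- function(x, y, spike_height, spike_width,
                              floor_frac = 0.1) {
  tx <- tent01(x, spike_width)
  ty <- tent01(y, spike_width)
  t2 <- outer(tx, ty, pmin)
  spike_height * pmax(0, (t2 - floor_frac) / (1 - floor_frac))
}

## Nano nodule field (um): separable raised-cosine bumps, peak at lattice
## points spaced `nodule_width` apart, zero on the lattice mid-lines.
nano_height_field <- function(x, y, nodule_height_nm, nodule_width_nm,
                              seed = 0L, jitter = 0) {
  w <- nodule_width_nm / 1000
  hgt <- nodule_height_nm / 1000
  bx <- 0.5 * (1 + cospi(2 * x / w))
  by <- 0.5 * (1 + cospi(2 * y / w))
  h <- hgt * outer(bx, by)
  if (jitter > 0) {
    ## per-nodule amplitude jitter, seeded and reproducible
    ix <- 1L + as.integer(floor(x / w + 0.5))
    iy <- 1L + as.integer(floor(y / w + 0.5))
    set.seed(seed)
    amp <- matrix(1 + jitter * stats::runif(max(ix) * max(iy), -1, 1),
                  max(ix), max(iy))
    h <- h * amp[ix, iy, drop = FALSE]
  }
  h
}

#' Generate a texture height map
#'
#' Renders the requested texture scales of a [texture_spec()] onto a regular
#' lateral grid. Amorphous specs give an all-zero map; the meso scale gives a
#' periodic crisscross spike array with peak-to-valley `spike_height`; the
#' nano scale gives a nodular bump array with peak-to-valley
#' `nodule_height`; a hybrid renders the superposition of the rendered
#' scales.
#'
#' @param spec a [texture_spec()].
#' @param extent lateral extent (um), length-1 or length-2.
#' @param spacing lateral sample spacing (um).
#' @param scales which of the spec's active scales to render; defaults to
#'   all of them. Rendering a scale whose feature width is resolved by
#'   fewer than 4 samples is a resolution error.
#' @return A [heightmap()] in um.
#' @export
generate_texture_heightmap <- function(spec, extent, spacing,
                                       scales = active_scales(spec)) {
  stopifnot(inherits(spec, "texture_spec"))
  if (length(extent) == 1L) extent <- c(extent, extent)
  if (!(spacing > 0)) stop("generate_texture_heightmap: spacing must be > 0")
  scales <- intersect(scales, active_scales(spec))
  for (sc in scales) {
    w <- if (sc == "meso") spec$spike_width else spec$nodule_width / 1000
    if (spacing > w / 4)
      stop(sprintf(paste0("generate_texture_heightmap: spacing %g um too ",
                          "coarse to resolve %s features of width %g um ",
                          "(need >= 4 samples per feature)"),
                   spacing, sc, w))
  }
  nxy <- pmax(2L, as.integer(round(extent / spacing)))
  x <- (seq_len(nxy[1]) - 1) * spacing
  y <- (seq_len(nxy[2]) - 1) * spacing
  h <- matrix(0, nxy[1], nxy[2])
  if ("meso" %in% scales)
    h <- h + meso_height_field(x, y, spec$spike_height, spec$spike_width)
  if ("nano" %in% scales)
    h <- h + nano_height_field(x, y, spec$nodule_height, spec$nodule_width,
                               seed = spec$seed, jitter = spec$jitter)
  heightmap(h, spacing)
}

#' Areal surface roughness metrics
#'
#' Computes the three areal roughness parameters of a height map:
#' * `Sa` — arithmetical mean height: mean absolute deviation from the
#'   mean plane (um);
#' * `Sz` — maximum height: largest peak height plus largest pit depth
#'   relative to the mean plane, i.e. `max(h) - min(h)` (um);
#' * `Sdr` — developed interfacial area ratio: the extra surface area
#'   contributed by the texture relative to the planar definition area,
#'   as a dimensionless fraction (`Sdr_pct` gives the same as a
#'   percentage). The true area is computed by summing triangulated
#'   facets (two triangles per grid cell).
#'
#' @param map a [heightmap()].
#' @return A list of class `roughness_metrics` with `Sa`, `Sz`, `Sdr`,
#'   `Sdr_pct`.
#' @export
compute_roughness <- function(map) {
  stopifnot(inherits(map, "heightmap"))
  h <- map$heights
  if (nrow(h) < 2L || ncol(h) < 2L)
    stop("compute_roughness: need at least 2 x 2 samples")
  s <- map$spacing
  Sa <- mean(abs(h - mean(h)))
  Sz <- max(h) - min(h)
  n <- nrow(h); m <- ncol(h)
  z00 <- h[-n, -m]; z10 <- h[-1, -m]; z01 <- h[-n, -1]; z11 <- h[-1, -1]
  ## triangles (z00, z10, z11) and (z00, z11, z01) per cell; area from the
  ## cross product of the edge vectors
  ## triangle 1: p0=(0,0,z00), p1=(s,0,z10), p2=(s,s,z11)
  a1z <- z10 - z00
  b1z <- z11 - z00
  ## cross((a1x,0,a1z),(b1x,b1y,b1z)) = (-a1z*b1y, a1z*b1x - a1x*b1z, a1x*b1y)
  c1x <- -a1z * s; c1y <- a1z * s - s * b1z; c1z <- s * s
  A1 <- 0.5 * sqrt(c1x^2 + c1y^2 + c1z^2)
  ## triangle 2: p0=(0,0,z00), p1=(s,s,z11), p2=(0,s,z01)
  a2z <- z11 - z00
  b2z <- z01 - z00
  ## cross((s,s,a2z),(0,s,b2z)) = (s*b2z - a2z*s, -s*b2z, s*s)
  c2x <- s * b2z - a2z * s; c2y <- -s * b2z; c2z <- s * s
  A2 <- 0.5 * sqrt(c2x^2 + c2y^2 + c2z^2)
  true_area <- sum(A1) + sum(A2)
  planar <- (n - 1) * (m - 1) * s^2
  Sdr <- true_area / planar - 1
  structure(list(Sa = Sa, Sz = Sz, Sdr = Sdr, Sdr_pct = 100 * Sdr),
            class = "roughness_metrics")
}

#' @export
print.roughness_metrics <- function(x, ...) {
  cat(sprintf("Sa = %.4g um, Sz = %.4g um, Sdr = %.4g (%.3g%%)\n",
              x$Sa, x$Sz, x$Sdr, x$Sdr_pct))
  invisible(x)
}

#' Developed area ratio of a single unresolved texture scale
#'
#' Renders one period of the requested scale at fine sampling (64 samples
#' per feature width, deterministic, jitter off) and returns its Sdr. Used
#' to build the Wenzel roughness ratio for texture scales that are not
#' geometrically resolved on the flow grid.
#'
#' @param spec a [texture_spec()].
#' @param scale `"meso"` or `"nano"`.
#' @return Sdr of that scale as a dimensionless fraction (0 if the scale is
#'   not active for the spec's kind).
#' @export
texture_scale_sdr <- function(spec, scale = c("meso", "nano")) {
  scale <- match.arg(scale)
  if (!(scale %in% active_scales(spec))) return(0)
  w <- if (scale == "meso") spec$spike_width else spec$nodule_width / 1000
  spec0 <- spec
  spec0$jitter <- 0
  map <- generate_texture_heightmap(spec0, extent = c(2 * w, 2 * w),
                                    spacing = w / 64, scales = scale)
  compute_roughness(map)$Sdr
}

#' Write / read a height map as a CSV matrix
#'
#' The CSV carries the sample spacing in a `# spacing_um=` comment line so
#' that the round trip is lossless.
#'
#' @param map a [heightmap()].
#' @param path file path.
#' @return `write_heightmap_csv` returns `path` invisibly;
#'   `read_heightmap_csv` returns a [heightmap()].
#' @export
write_heightmap_csv <- function(map, path) {
  stopifnot(inherits(map, "heightmap"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spacing_um=%.17g", map$spacing), con)
  utils::write.table(map$heights, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_heightmap_csv
#' @export
read_heightmap_csv <- function(path) {
  if (!file.exists(path))
    stop("read_heightmap_csv: no such file: ", path)
  first <- readLines(path, n = 1L)
  if (!grepl("^# spacing_um=", first))
    stop("read_heightmap_csv: missing '# spacing_um=' header line")
  spacing <- as.numeric(sub("^# spacing_um=", "", first))
  h <- as.matrix(utils::read.table(path, sep = ",", skip = 1L,
                                   header = FALSE))
  dimnames(h) <- NULL
  heightmap(h, spacing)
}

#' Write / read a height map as a grayscale PNG
#'
#' Heights are linearly mapped to 8-bit gray levels; the physical scale
#' (spacing, min and max height) is stored in a sidecar JSON file
#' `<path>.scale.json` so the round trip recovers physical units.
#'
#' @param map a [heightmap()].
#' @param path PNG file path.
#' @return `write_heightmap_png` returns `path` invisibly;
#'   `read_heightmap_png` returns a [heightmap()] (quantized to 8 bits).
#' @export
write_heightmap_png <- function(map, path) {
  stopifnot(inherits(map, "heightmap"))
  h <- map$heights
  lo <- min(h); hi <- max(h)
  g <- if (hi > lo) (h - lo) / (hi - lo) else h * 0
  ## png images are row-major top-down; transpose so x runs along image rows
  png::writePNG(t(g)[seq(ncol(g), 1), , drop = FALSE], path)
  jsonlite::write_json(
    list(spacing_um = map$spacing, min_um = lo, max_um = hi),
    paste0(path, ".scale.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_heightmap_png
#' @export
read_heightmap_png <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".scale.json"))
  g <- png::readPNG(path)
  if (length(dim(g)) == 3L) g <- g[, , 1]
  g <- t(g[seq(nrow(g), 1), , drop = FALSE])
  heightmap(meta$min_um + g * (meta$max_um - meta$min_um), meta$spacing_um)
}
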