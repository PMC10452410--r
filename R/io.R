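#' Write a structured grid snapshot as legacy VTK
#'
#' Writes an ASCII legacy VTK `STRUCTURED_POINTS` dataset with the cell
#' data of a snapshot: liquid fraction `alpha`, pressure `p`, protein
#' concentration `c` (when present), cell `type`, `zone` labels, and the
#' cell-centred `velocity` vector field.
#'
#' @param path output file.
#' @param geom a [domain_geometry][rasterize_domain()].
#' @param state optional `flow_state` providing the fields; with
#'   `state = NULL` only `type` and `zone` are written.
#' @return `path`, invisibly.
#' @export
write_vtk_grid <- function(path, geom, state = NULL) {
  nx <- geom$nx; ny <- geom$ny
  h_m <- geom$h_um * 1e-6
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("periflow structured snapshot%s",
     if (!is.null(state)) sprintf(" t=%.9g", state$t) else "")
  wl("ASCII")
  wl("DATASET STRUCTURED_POINTS")
  wl("DIMENSIONS %d %d %d", nx + 1L, ny + 1L, 1L)
  wl("ORIGIN 0 0 0")
  wl("SPACING %.9g %.9g %.9g", h_m, h_m, h_m)
  wl("CELL_DATA %d", nx * ny)
  put_scalar <- function(name, m, fmt = "%.17g") {
    wl("SCALARS %s double 1", name)
    wl("LOOKUP_TABLE default")
    writeLines(sprintf(fmt, as.numeric(m)), con)
  }
  put_scalar("type", geom$type, "%d")
  put_scalar("zone", geom$zone, "%d")
  if (!is.null(state)) {
    put_scalar("alpha", state$alpha)
    put_scalar("p", state$p)
    if (!is.null(state$c)) put_scalar("c", state$c)
    uc <- 0.5 * (state$u[1:nx, , drop = FALSE] +
                   state$u[2:(nx + 1L), , drop = FALSE])
    vc <- 0.5 * (state$v[, 1:ny, drop = FALSE] +
                   state$v[, 2:(ny + 1L), drop = FALSE])
    wl("VECTORS velocity double")
    writeLines(sprintf("%.17g %.17g 0", as.numeric(uc), as.numeric(vc)), con)
  }
  invisible(path)
}

#' Read back a legacy VTK snapshot written by [write_vtk_grid()]
#'
#' A minimal reader for the subset of the legacy format this package
#' writes; returns the cell-data arrays as matrices.
#'
#' @param path VTK file path.
#' @return List with `nx`, `ny`, `spacing` (m) and one matrix per cell
#'   field (`velocity` as a list of `u`, `v`).
#' @export
read_vtk_grid <- function(path) {
  ln <- readLines(path)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "",
                                         grep("^DIMENSIONS", ln, value = TRUE))),
                              "\\s+")[[1]])
  nx <- dims[1] - 1L; ny <- dims[2] - 1L
  spacing <- as.numeric(strsplit(trimws(sub("SPACING", "",
                                            grep("^SPACING", ln, value = TRUE))),
                                 "\\s+")[[1]])[1]
  nc <- nx * ny
  out <- list(nx = nx, ny = ny, spacing = spacing)
  i <- 1L
  while (i <= length(ln)) {
    if (grepl("^SCALARS", ln[i])) {
      name <- strsplit(ln[i], "\\s+")[[1]][2]
      vals <- as.numeric(ln[(i + 2L):(i + 1L + nc)])
      out[[name]] <- matrix(vals, nx, ny)
      i <- i + 2L + nc
    } else if (grepl("^VECTORS", ln[i])) {
      name <- strsplit(ln[i], "\\s+")[[1]][2]
      rows <- do.call(rbind, lapply(strsplit(ln[(i + 1L):(i + nc)], "\\s+"),
                                    as.numeric))
      out[[name]] <- list(u = matrix(rows[, 1], nx, ny),
                          v = matrix(rows[, 2], nx, ny))
      i <- i + 1L + nc
    } else i <- i + 1L
  }
  out
}

#' Zone time series in the export schema
#'
#' Reshapes a run's zone series into the exported CSV schema: columns
#' `time`, `zone`, `topography`, `liquid_fraction`, `species_mass`,
#' `v_vertical`, `v_horizontal` (positive inbound, toward the implant) and
#' `speed` (magnitude of the zone-mean vector).
#'
#' @param run a `flow_run`, or its `series` data.frame.
#' @param topography label recorded in the `topography` column.
#' @return A data.frame.
#' @export
zone_series <- function(run, topography = NA_character_) {
  series <- if (inherits(run, "flow_run")) run$series else run
  data.frame(
    time = series$time, zone = series$zone,
    topography = rep_len(topography, length(series$time)),
    zone_volume = series$zone_volume,
    liquid_fraction = series$liquid_fraction,
    species_mass = series$species_mass,
    v_vertical = series$mean_v, v_horizontal = -series$mean_u,
    speed = sqrt(series$mean_u^2 + series$mean_v^2),
    mean_cell_speed = series$mean_cell_speed)
}

#' Write a zone time series as CSV
#'
#' RFC-4180 CSV, UTF-8, `.` decimal separator; an empty series yields a
#' header-only file.
#'
#' @param series a [zone_series()] data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_zone_series_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

## Simple blue-to-red color ramp for raster renderings.
ramp_colors <- function(m, lo = 0, hi = 1) {
  v <- pmin(1, pmax(0, (m - lo) / max(hi - lo, 1e-300)))
  r <- v
  g <- 1 - abs(2 * v - 1)
  b <- 1 - v
  array(c(r, g, b), dim = c(dim(m), 3))
}

## Orient a cell matrix (x across, y up) as a PNG raster (row 1 = top).
as_raster_rgb <- function(rgb_arr) {
  aperm(rgb_arr, c(2, 1, 3))[dim(rgb_arr)[2]:1, , , drop = FALSE]
}

#' Render the liquid fraction as a PNG color map
#'
#' Solid cells are drawn gray; the liquid fraction maps blue (void) to red
#' (liquid). Inspection output only; no numeric result is read from
#' images.
#'
#' @param state a `flow_state`.
#' @param geom a [domain_geometry][rasterize_domain()].
#' @param path output PNG.
#' @return `path`, invisibly.
#' @export
render_alpha_png <- function(state, geom, path) {
  rgb_arr <- ramp_colors(state$alpha)
  solid <- geom$type != CT_FLUID
  for (k in 1:3) {
    ch <- rgb_arr[, , k]
    ch[solid] <- 0.45
    rgb_arr[, , k] <- ch
  }
  png::writePNG(as_raster_rgb(rgb_arr), path)
  invisible(path)
}

#' Render the velocity field as a PNG map
#'
#' Speed magnitude as the color background with sparse arrows (drawn as
#' line rasters) showing direction, colored by magnitude.
#'
#' @param state a `flow_state`.
#' @param geom a [domain_geometry][rasterize_domain()].
#' @param path output PNG.
#' @param every arrow decimation (one arrow per `every` cells).
#' @return `path`, invisibly.
#' @export
render_vector_png <- function(state, geom, path, every = 6L) {
  nx <- geom$nx; ny <- geom$ny
  uc <- 0.5 * (state$u[1:nx, , drop = FALSE] +
                 state$u[2:(nx + 1L), , drop = FALSE])
  vc <- 0.5 * (state$v[, 1:ny, drop = FALSE] +
                 state$v[, 2:(ny + 1L), drop = FALSE])
  sp <- sqrt(uc^2 + vc^2)
  hi <- max(sp, 1e-12)
  rgb_arr <- ramp_colors(sp, 0, hi)
  solid <- geom$type != CT_FLUID
  for (k in 1:3) {
    ch <- rgb_arr[, , k]
    ch[solid] <- 0.45
    rgb_arr[, , k] <- ch
  }
  ## overlay arrows as white line segments along the local direction
  scale <- every * 0.8
  for (j in seq(1L, ny, by = every))
    for (i in seq(1L, nx, by = every)) {
      if (solid[i, j] || sp[i, j] < 1e-12) next
      dx <- uc[i, j] / hi * scale
      dy <- vc[i, j] / hi * scale
      nstep <- max(2L, ceiling(max(abs(dx), abs(dy))))
      tt <- seq(0, 1, length.out = nstep)
      xi <- pmin(nx, pmax(1L, as.integer(round(i + tt * dx))))
      yj <- pmin(ny, pmax(1L, as.integer(round(j + tt * dy))))
      for (k in 1:3) rgb_arr[cbind(xi, yj, k)] <- 1
    }
  png::writePNG(as_raster_rgb(rgb_arr), path)
  invisible(path)
}

#' Export the outputs of a completed run
#'
#' Writes VTK field checkpoints, the zone time-series CSV, a JSON run
#' summary (resolved configuration, solver diagnostics, recruitment
#' metrics and a configuration hash), and PNG renderings of the liquid
#' fraction and velocity field per checkpoint. Identical runs produce
#' byte-identical CSV/JSON outputs.
#'
#' @param run a `flow_run` (from [run_simulation()] or [execute_run()]).
#' @param out_dir output directory (created if needed).
#' @param topography label used in file names and the CSV.
#' @param formats subset of `c("vtk", "csv", "json", "png")`.
#' @return Character vector of the files written, invisibly.
#' @export
export_outputs <- function(run, out_dir, topography = NA_character_,
                           formats = c("vtk", "csv", "json", "png")) {
  stopifnot(inherits(run, "flow_run"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("export_outputs: cannot create output directory: ", out_dir)
  probe <- file.path(out_dir, ".write-test")
  ok <- tryCatch({ writeLines("", probe); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("export_outputs: output directory not writable: ", out_dir)
  unlink(probe)
  tag <- if (is.na(topography)) "run" else topography
  files <- character(0)
  if ("vtk" %in% formats) {
    for (ck in run$checkpoints) {
      f <- file.path(out_dir, sprintf("%s_t%04.0fms.vtk", tag, ck$t * 1000))
      write_vtk_grid(f, run$geom, ck)
      files <- c(files, f)
    }
  }
  if ("csv" %in% formats) {
    f <- file.path(out_dir, sprintf("%s_zones.csv", tag))
    write_zone_series_csv(zone_series(run, topography), f)
    files <- c(files, f)
  }
  if ("json" %in% formats) {
    cfg <- if (!is.null(run$run_config)) unclass(run$run_config) else NULL
    summ <- list(
      topography = topography,
      config = cfg,
      config_hash = if (!is.null(cfg))
        sum(utf8ToInt(paste(deparse(cfg), collapse = ""))) else NULL,
      theta_implant_deg = run$theta_implant,
      diagnostics = run$diag,
      recruitment_totals = as.list(recruitment_totals(run$series)),
      ## efficiency is undefined while the thread zone is still empty
      recruitment_efficiency_pct = tryCatch(
        as.list(recruitment_efficiency(run$series)),
        error = function(e) NULL))
    f <- file.path(out_dir, sprintf("%s_summary.json", tag))
    jsonlite::write_json(summ, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, f)
  }
  if ("png" %in% formats) {
    for (ck in run$checkpoints) {
      f1 <- file.path(out_dir, sprintf("%s_alpha_t%04.0fms.png", tag,
                                       ck$t * 1000))
      render_alpha_png(ck, run$geom, f1)
      f2 <- file.path(out_dir, sprintf("%s_vectors_t%04.0fms.png", tag,
                                       ck$t * 1000))
      render_vector_png(ck, run$geom, f2)
      files <- c(files, f1, f2)
    }
  }
  invisible(files)
}
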