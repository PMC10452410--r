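## Default run configuration tree. Every key that may appear in a config
## file is present here; unknown keys are rejected on load.
default_config_tree <- function() {
  list(
    geometry = list(
      length_mm = 11, diameter_mm = 4, gap_mm = 0.3,
      thread_count = 3L, thread_depth_mm = 0.35, thread_pitch_mm = 1.2,
      thread_start_mm = 0.5, h_um = 25,
      apex_clearance_mm = 0.6, top_clearance_mm = 0.6,
      side_inlet_height_mm = 0.6, side_inlet_offset_mm = 0,
      interface_thickness_um = 100),
    texture = list(
      kind = "amorphous", spike_height_um = 40, spike_width_um = 50,
      nodule_height_nm = 300, nodule_width_nm = 300,
      nano_representation = "effective_wetting", jitter = 0),
    fluids = list(
      rho_l = 1025, mu_l = 1.4e-3, rho_g = 1.2, mu_g = 1.8e-5,
      sigma = 0.058, contact_angle_deg = 70),
    solver = list(
      end_time_s = 3, cfl = 0.5, inlet_speed_m_s = 1e-3,
      checkpoint_times_s = c(1, 2, 3), output_interval_s = 0.05,
      gravity = c(0, 0), p_tol = 1e-8, p_maxit = 5000L, dt_max_s = 1e-3,
      calpha = 1, nsmooth = 2L),
    species = list(enabled = TRUE, diffusivity_m2_s = 2e-11,
                   inlet_concentration = 1),
    zones = list(weighting = "liquid"),
    output = list(dir = "periflow-out",
                  formats = c("vtk", "csv", "json", "png")),
    seed = 0L)
}

merge_config <- function(defaults, user, path = character(0)) {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults)) return(user)
  if (!is.list(user))
    stop("config: expected a block at '", paste(path, collapse = "."),
         "', got a scalar")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("config: unknown key(s): ",
         paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", "))
  for (nm in names(user))
    defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], c(path, nm))
  defaults
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  g <- cfg$geometry
  chk(g$length_mm > 0 && g$diameter_mm > 0 && g$gap_mm > 0,
      "geometry dimensions must be > 0")
  chk(g$h_um > 0, "geometry.h_um must be > 0")
  chk(g$interface_thickness_um / 1000 < g$gap_mm,
      "geometry.interface_thickness_um must be smaller than the gap")
  chk(cfg$texture$kind %in% c("amorphous", "nano", "hybrid"),
      "texture.kind must be amorphous, nano or hybrid")
  chk(cfg$texture$nano_representation %in%
        c("effective_wetting", "drag_layer", "resolved"),
      "texture.nano_representation invalid")
  f <- cfg$fluids
  chk(all(c(f$rho_l, f$rho_g, f$mu_l, f$mu_g) > 0),
      "fluid densities and viscosities must be > 0")
  chk(f$sigma >= 0, "fluids.sigma must be >= 0")
  chk(f$contact_angle_deg > 0 && f$contact_angle_deg < 180,
      "fluids.contact_angle_deg must be in (0, 180)")
  s <- cfg$solver
  chk(s$end_time_s >= 0, "solver.end_time_s must be >= 0")
  chk(s$cfl > 0 && s$cfl <= 1, "solver.cfl must be in (0, 1]")
  chk(all(s$checkpoint_times_s >= 0 & s$checkpoint_times_s <= s$end_time_s),
      "solver.checkpoint_times_s must lie in [0, end_time]")
  chk(cfg$species$diffusivity_m2_s >= 0,
      "species.diffusivity_m2_s must be >= 0")
  chk(cfg$zones$weighting %in% c("liquid", "unweighted"),
      "zones.weighting must be 'liquid' or 'unweighted'")
  invisible(cfg)
}

#' Build a run configuration
#'
#' A `run_config` bundles every input of a simulation run: geometry block
#' (implant dimensions, gap, threads, grid), texture block, fluids block,
#' solver block, species block, zones and output blocks, and the seed.
#' Arguments override the documented defaults; unknown keys are rejected.
#'
#' @param geometry,texture,fluids,solver,species,zones,output named lists
#'   of overrides for each block.
#' @param seed integer seed recorded in the run metadata and used for any
#'   stochastic texture jitter.
#' @return An object of class `run_config`.
#' @export
run_config <- function(geometry = list(), texture = list(),
                       fluids = list(), solver = list(), species = list(),
                       zones = list(), output = list(), seed = NULL) {
  user <- list(geometry = geometry, texture = texture, fluids = fluids,
               solver = solver, species = species, zones = zones,
               output = output)
  user <- Filter(function(x) length(x) > 0, user)
  if (!is.null(seed)) user$seed <- as.integer(seed)
  cfg <- merge_config(default_config_tree(), user)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Missing keys take their defaults; unknown keys, type mismatches and
#' physically invalid values are rejected with an error naming the
#' offending key. An empty file yields the all-defaults configuration
#' (11 mm x 4 mm implant, 0.3 mm gap, 3 threads).
#'
#' @param path path to a YAML (or JSON; YAML is a superset) file.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config_tree(), user)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param config a [run_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> %s texture, implant %g x %g mm, gap %g mm, h = %g um, t_end = %g s\n",
    x$texture$kind, x$geometry$length_mm, x$geometry$diameter_mm,
    x$geometry$gap_mm, x$geometry$h_um, x$solver$end_time_s))
  invisible(x)
}

## Build the geometry stack described by a run_config.
build_geometry_from_config <- function(cfg) {
  g <- cfg$geometry
  tx <- cfg$texture
  profile <- build_implant_profile(
    length = g$length_mm, diameter = g$diameter_mm,
    thread_count = g$thread_count, thread_depth = g$thread_depth_mm,
    thread_pitch = g$thread_pitch_mm, thread_start = g$thread_start_mm)
  spec <- texture_spec(kind = tx$kind, spike_height = tx$spike_height_um,
                       spike_width = tx$spike_width_um,
                       nodule_height = tx$nodule_height_nm,
                       nodule_width = tx$nodule_width_nm,
                       nano_representation = tx$nano_representation,
                       seed = cfg$seed, jitter = tx$jitter)
  resolve_meso <- "meso" %in% active_scales(spec) &&
    g$h_um <= tx$spike_width_um / 4
  profile <- apply_texture_to_profile(profile, spec,
                                      resolve_meso = resolve_meso)
  profile$meso_resolved <- resolve_meso
  if ("meso" %in% active_scales(spec) && !resolve_meso)
    message("meso spikes below grid resolution; folded into the ",
            "effective wetting / drag-layer model")
  geom <- rasterize_domain(profile, gap = g$gap_mm, h = g$h_um,
                           apex_clearance = g$apex_clearance_mm,
                           top_clearance = g$top_clearance_mm,
                           side_inlet_height = g$side_inlet_height_mm,
                           side_inlet_offset = g$side_inlet_offset_mm)
  assign_zones(geom, interface_thickness = g$interface_thickness_um)
}

props_from_config <- function(cfg) {
  f <- cfg$fluids
  fluid_properties(rho_l = f$rho_l, mu_l = f$mu_l, rho_g = f$rho_g,
                   mu_g = f$mu_g, sigma = f$sigma,
                   contact_angle = f$contact_angle_deg)
}

solver_from_config <- function(cfg) {
  s <- cfg$solver
  solver_config(end_time = s$end_time_s, cfl = s$cfl,
                inlet_speed = s$inlet_speed_m_s,
                checkpoint_times = s$checkpoint_times_s,
                output_interval = s$output_interval_s,
                gravity = as.numeric(s$gravity), p_tol = s$p_tol,
                p_maxit = s$p_maxit, dt_max = s$dt_max_s,
                calpha = s$calpha, nsmooth = s$nsmooth,
                species = isTRUE(cfg$species$enabled),
                diffusivity = cfg$species$diffusivity_m2_s,
                c_in = cfg$species$inlet_concentration)
}

#' Execute a configured run
#'
#' Builds the geometry, fluids and solver settings from a [run_config()]
#' and runs the transient filling simulation.
#'
#' @param config a [run_config()].
#' @return A `flow_run` (see [run_simulation()]), with the originating
#'   configuration attached as `$run_config`.
#' @export
execute_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  geom <- build_geometry_from_config(config)
  run <- run_simulation(geom, props_from_config(config),
                        solver_from_config(config))
  run$run_config <- config
  run
}
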