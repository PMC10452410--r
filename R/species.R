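#' Construct a species (fibrinogen) concentration field
#'
#' The model protein is carried as a passive scalar within the liquid
#' phase: concentration `c` is normalized to the inlet value (so all
#' reported quantities are relative), and is zero wherever there is no
#' liquid carrier.
#'
#' @param concentration matrix of concentration per cell (dimensionless,
#'   inlet-normalized, in `[0, 1]`).
#' @param diffusivity molecular diffusivity (m2/s).
#' @return An object of class `species_field`.
#' @export
species_field <- function(concentration, diffusivity = 2e-11) {
  concentration <- as.matrix(concentration)
  if (any(concentration < 0 | concentration > 1 + 1e-8))
    stop("species_field: concentration must lie in [0, 1]")
  structure(list(c = concentration, D = diffusivity),
            class = "species_field")
}

#' Advance the species field by one transport step
#'
#' Conservative advection of the species load `c * alpha` by the liquid
#' fluxes of the frozen flow state, plus diffusion within the liquid
#' (`div(D alpha grad c)`), with inlet concentration `c_in`, zero flux at
#' solids and advective outflow at the outlet. The scalar remains confined
#' to the liquid carrier.
#'
#' @param field a [species_field()].
#' @param state a `flow_state` providing the carrier `alpha` and the face
#'   velocities.
#' @param geom a [domain_geometry][rasterize_domain()].
#' @param props a [fluid_properties()].
#' @param config a [solver_config()].
#' @param dt time step (s); must satisfy the advective and diffusive
#'   stability bounds of [compute_dt()].
#' @param boundaries see [solver_geometry()].
#' @return The updated `species_field`.
#' @export
step_species <- function(field, state, geom, props = fluid_properties(),
                         config = solver_config(), dt, boundaries = NULL) {
  stopifnot(inherits(field, "species_field"), inherits(state, "flow_state"))
  dt_lim <- compute_dt(state, geom, props, config, boundaries)
  if (dt > dt_lim * (1 + 1e-9))
    stop(sprintf(
      "step_species: dt = %g exceeds the stability bound %g", dt, dt_lim))
  config$species <- TRUE
  config$diffusivity <- field$D
  st <- state
  st$m <- field$c * state$alpha
  sg <- solver_geometry(geom, props, config, boundaries)
  out <- cpp_step_species(sg, solver_params(props, config),
                          state_to_list(st), dt)
  species_field(matrix(out$c, geom$nx, geom$ny), field$D)
}

#' Species mass per zone
#'
#' Per-zone total species load `sum(c * alpha * cell volume)`; with the
#' inlet-normalized concentration this is a relative infiltrated protein
#' quantity (mm2 in the 2D model).
#'
#' @param field a [species_field()] (or a concentration matrix).
#' @param state a `flow_state` providing the carrier `alpha`.
#' @param geom a zoned [domain_geometry][rasterize_domain()].
#' @return Named numeric vector over zones `interface`, `thread`, `outer`.
#' @export
species_mass_in_zone <- function(field, state, geom) {
  conc <- if (inherits(field, "species_field")) field$c else as.matrix(field)
  if (!all(dim(conc) == dim(state$alpha)) ||
      !all(dim(conc) == dim(geom$zone)))
    stop("species_mass_in_zone: field, state and zones have mismatched grids")
  h2 <- (geom$h_um / 1000)^2
  load <- conc * state$alpha * h2
  vapply(c(interface = ZN_INTERFACE, thread = ZN_THREAD, outer = ZN_OUTER),
         function(z) sum(load[geom$zone == z]), numeric(1))
}
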