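## Face codes shared with the C++ core.
FC_INTERIOR <- 0L; FC_WALL <- 1L; FC_INLET <- 2L; FC_OUTLET <- 3L
FC_SYMM <- 4L

#' Fluid properties of the two-phase system
#'
#' Defaults are physiological plasma-like liquid against air: liquid
#' density 1025 kg/m3 and viscosity 1.4 mPa s, gas density 1.2 kg/m3 and
#' viscosity 1.8e-5 Pa s, surface tension 0.058 N/m, and an intrinsic
#' (smooth-surface) contact angle of 70 degrees.
#'
#' @param rho_l,rho_g liquid / gas density (kg/m3).
#' @param mu_l,mu_g liquid / gas dynamic viscosity (Pa s).
#' @param sigma surface tension (N/m).
#' @param contact_angle intrinsic contact angle on a smooth surface
#'   (degrees, in (0, 180)).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho_l = 1025, mu_l = 1.4e-3,
                             rho_g = 1.2, mu_g = 1.8e-5,
                             sigma = 0.058, contact_angle = 70) {
  if (any(c(rho_l, rho_g, mu_l, mu_g) <= 0))
    stop("fluid_properties: densities and viscosities must be > 0")
  if (sigma < 0) stop("fluid_properties: surface tension must be >= 0")
  if (!(contact_angle > 0 && contact_angle < 180))
    stop("fluid_properties: contact angle must be in (0, 180) degrees")
  structure(list(rho_l = rho_l, mu_l = mu_l, rho_g = rho_g, mu_g = mu_g,
                 sigma = sigma, contact_angle = contact_angle),
            class = "fluid_properties")
}

#' Solver configuration
#'
#' @param end_time simulation end time (s).
#' @param cfl advective CFL number in (0, 1].
#' @param inlet_speed prescribed inlet speed (m/s) at the implant-apex and
#'   bone side-wall inlets.
#' @param checkpoint_times times (s) at which full field snapshots are kept.
#' @param output_interval zone time-series sampling interval (s).
#' @param gravity gravity vector `c(gx, gy)` (m/s2); default off, the fill
#'   is capillary/inlet driven.
#' @param p_tol relative tolerance of the pressure (projection) solve.
#' @param p_maxit maximum pressure-solver iterations.
#' @param dt_max upper bound on the time step (s).
#' @param calpha interface compression coefficient of the VOF scheme
#'   (0 disables sharpening).
#' @param nsmooth smoothing passes applied to the liquid fraction before
#'   computing interface normals and curvature.
#' @param species logical, transport the protein scalar.
#' @param diffusivity protein diffusivity (m2/s); the default 2e-11 is the
#'   literature scale for a ~340 kDa plasma protein such as fibrinogen.
#' @param c_in inlet protein concentration (normalized, default 1).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(end_time = 3, cfl = 0.5, inlet_speed = 5e-3,
                          checkpoint_times = c(1, 2, 3),
                          output_interval = 0.05,
                          gravity = c(0, 0), p_tol = 1e-8, p_maxit = 5000L,
                          dt_max = 1e-3, calpha = 1, nsmooth = 2L,
                          species = TRUE, diffusivity = 2e-11, c_in = 1) {
  if (!(end_time >= 0)) stop("solver_config: end_time must be >= 0")
  if (!(cfl > 0 && cfl <= 1)) stop("solver_config: cfl must be in (0, 1]")
  if (any(checkpoint_times < 0 | checkpoint_times > end_time))
    stop("solver_config: checkpoint times must lie in [0, end_time]")
  structure(list(end_time = end_time, cfl = cfl, inlet_speed = inlet_speed,
                 checkpoint_times = checkpoint_times,
                 output_interval = output_interval, gravity = gravity,
                 p_tol = p_tol, p_maxit = as.integer(p_maxit),
                 dt_max = dt_max, calpha = calpha,
                 nsmooth = as.integer(nsmooth), species = species,
                 diffusivity = diffusivity, c_in = c_in),
            class = "solver_config")
}

#' Effective contact angle on an unresolved rough surface
#'
#' Wenzel-type correction for texture scales that are not geometrically
#' resolved on the flow grid: `cos(theta_eff) = r * cos(theta_base)`,
#' clamped to `[0, 180]` degrees, with roughness area ratio
#' `r = prod(1 + Sdr_scale)` over the unresolved scales (Wenzel ratios of
#' superposed textures multiply). An amorphous texture has `r = 1` and
#' returns the base angle unchanged.
#'
#' @param base_angle intrinsic contact angle (degrees, in (0, 180)).
#' @param texture a [texture_spec()], or a numeric roughness ratio `r`.
#' @param scales which texture scales are unresolved (default: all active).
#' @return Effective contact angle (degrees).
#' @export
effective_contact_angle <- function(base_angle, texture,
                                    scales = NULL) {
  if (!(base_angle > 0 && base_angle < 180))
    stop("effective_contact_angle: base angle must be in (0, 180)")
  if (is.numeric(texture)) {
    r <- texture
  } else {
    stopifnot(inherits(texture, "texture_spec"))
    if (is.null(scales)) scales <- active_scales(texture)
    scales <- intersect(scales, active_scales(texture))
    r <- 1
    for (sc in scales) r <- r * (1 + texture_scale_sdr(texture, sc))
  }
  if (r < 1) stop("effective_contact_angle: roughness ratio r must be >= 1")
  ce <- max(-1, min(1, r * cos(base_angle * pi / 180)))
  acos(ce) * 180 / pi
}

## ---- solver-level geometry marshalling -----------------------------------

## Kozeny-Carman permeability of the unresolved spike layer (grain size =
## spike width, porosity 0.5).
spike_layer_permeability <- function(width_um) {
  w <- width_um * 1e-6
  eps <- 0.5
  w^2 * eps^3 / (180 * (1 - eps)^2)
}

#' Low-level solver geometry
#'
#' Marshals a [domain_geometry][rasterize_domain()] into the flat arrays
#' consumed by the solver core: cell types and zones, per-cell drag sink of
#' the unresolved spike layer, per-solid-cell contact-angle cosines, and
#' face boundary codes (interior / wall / inlet / outlet / symmetry).
#'
#' Texture handling: the meso spike scale is resolved on the mesh only when
#' `h <= spike_width / 4` and the profile was geometrically serrated;
#' otherwise it is folded into the effective wetting model and (for
#' `kind = "hybrid"`) a porous drag layer one spike height thick along the
#' implant surface. The nano scale follows the spec's
#' `nano_representation`.
#'
#' @param geom a [domain_geometry][rasterize_domain()].
#' @param props a [fluid_properties()].
#' @param config a [solver_config()].
#' @param boundaries named list with entries `left`, `right`, `bottom`,
#'   `top`, each one of `"wall"`, `"symmetry"`, `"outlet"`, `"inlet"`.
#'   Defaults to the implant-domain layout (symmetry axis left, walls
#'   right/bottom, outlet top) plus the apex and side-wall inlet segments
#'   recorded in `geom`.
#' @return A list of flat arrays (internal format, passed to the compiled
#'   core).
#' @export
solver_geometry <- function(geom, props, config, boundaries = NULL) {
  stopifnot(inherits(geom, "domain_geometry"))
  nx <- geom$nx; ny <- geom$ny
  h_m <- geom$h_um * 1e-6
  type <- as.integer(geom$type)
  zone <- as.integer(geom$zone)
  if (is.null(boundaries))
    boundaries <- list(left = "symmetry", right = "wall",
                       bottom = "wall", top = "outlet")
  ## contact angles per solid cell
  theta_implant <- props$contact_angle
  drag <- numeric(nx * ny)
  kap_layer <- numeric(nx * ny)
  tex <- if (!is.null(geom$profile)) geom$profile$texture else NULL
  if (!is.null(tex)) {
    unresolved <- character(0)
    if ("meso" %in% active_scales(tex)) {
      meso_ok <- isTRUE(geom$profile$meso_resolved) &&
        geom$h_um <= tex$spike_width / 4
      if (!meso_ok) unresolved <- c(unresolved, "meso")
    }
    if ("nano" %in% active_scales(tex)) {
      nano_ok <- identical(tex$nano_representation, "resolved") &&
        geom$h_um <= tex$nodule_width / 1000 / 4
      if (!nano_ok) unresolved <- c(unresolved, "nano")
    }
    if (length(unresolved))
      theta_implant <- effective_contact_angle(props$contact_angle, tex,
                                               scales = unresolved)
    ## porous drag layer for unresolved meso texture along the implant
    ## surface: Darcy resistance plus imbibition (the wetting spike layer
    ## wicks liquid in with a capillary suction set by its pore radius,
    ## imposed as a prescribed interface curvature inside the layer)
    if ("meso" %in% unresolved) {
      K <- spike_layer_permeability(tex$spike_width)
      thick_mm <- tex$spike_height / 1000
      in_layer <- as.vector(geom$dist_implant <= thick_mm) & type == 0L
      drag[in_layer] <- drag[in_layer] + props$mu_l / K
      r_pore <- tex$spike_width / 4 * 1e-6   # groove half-width (m)
      kap_layer[in_layer] <- -2 * cos(theta_implant * pi / 180) / r_pore
    }
    if ("nano" %in% unresolved &&
        identical(tex$nano_representation, "drag_layer")) {
      K <- spike_layer_permeability(tex$nodule_width / 1000)
      thick_m <- tex$nodule_height * 1e-9
      frac <- min(1, thick_m / h_m)  # sub-cell layer: volume-fraction scaled
      wall_adj <- as.vector(geom$dist_implant <= geom$h_um / 1000) &
        type == 0L
      drag[wall_adj] <- drag[wall_adj] + frac * props$mu_l / K
    }
  }
  costh <- numeric(nx * ny)
  costh[type == 1L] <- cos(theta_implant * pi / 180)
  costh[type == 2L] <- cos(props$contact_angle * pi / 180)
  ## ---- face codes ----
  tm <- matrix(type, nx, ny)
  ucode <- matrix(FC_WALL, nx + 1L, ny)
  uvalm <- matrix(0, nx + 1L, ny)
  vcode <- matrix(FC_WALL, nx, ny + 1L)
  vvalm <- matrix(0, nx, ny + 1L)
  fl <- tm == 0L
  ## interior x-faces
  both <- fl[-nx, , drop = FALSE] & fl[-1, , drop = FALSE]
  ucode[2:nx, ][both] <- FC_INTERIOR
  ## interior y-faces
  bothv <- fl[, -ny, drop = FALSE] & fl[, -1, drop = FALSE]
  vcode[, 2:ny][bothv] <- FC_INTERIOR
  side_code <- function(kind) switch(kind, wall = FC_WALL,
                                     symmetry = FC_SYMM, outlet = FC_OUTLET,
                                     inlet = FC_INLET,
                                     stop("unknown boundary kind: ", kind))
  sp <- config$inlet_speed
  ## left edge (x = 0)
  k <- side_code(boundaries$left)
  ucode[1, fl[1, ]] <- k
  if (k == FC_INLET) uvalm[1, fl[1, ]] <- sp
  ## right edge
  k <- side_code(boundaries$right)
  ucode[nx + 1L, fl[nx, ]] <- k
  if (k == FC_INLET) uvalm[nx + 1L, fl[nx, ]] <- -sp
  ## bottom edge
  k <- side_code(boundaries$bottom)
  vcode[fl[, 1], 1] <- k
  if (k == FC_INLET) vvalm[fl[, 1], 1] <- sp
  ## top edge
  k <- side_code(boundaries$top)
  vcode[fl[, ny], ny + 1L] <- k
  if (k == FC_INLET) vvalm[fl[, ny], ny + 1L] <- -sp
  ## implant-domain inlet/outlet segments
  if (!is.null(geom$profile)) {
    if (length(geom$inlet_apex_i)) {
      vcode[geom$inlet_apex_i, 1] <- FC_INLET
      vvalm[geom$inlet_apex_i, 1] <- sp
    }
    if (length(geom$inlet_side_j)) {
      ucode[geom$nx_fluid + 1L, geom$inlet_side_j] <- FC_INLET
      uvalm[geom$nx_fluid + 1L, geom$inlet_side_j] <- -sp
    }
    if (length(geom$outlet_i)) {
      vcode[geom$outlet_i, ny + 1L] <- FC_OUTLET
      vvalm[geom$outlet_i, ny + 1L] <- 0
    }
  }
  ghost_sign <- function(kind) switch(kind, wall = -1, inlet = -1,
                                      symmetry = 1, outlet = 1)
  list(nx = nx, ny = ny, h = h_m, type = type, zone = zone,
       drag = drag, costh = costh, kap_layer = kap_layer,
       ucode = as.integer(ucode), uval = as.numeric(uvalm),
       vcode = as.integer(vcode), vval = as.numeric(vvalm),
       ghost_signs = c(ghost_sign(boundaries$left),
                       ghost_sign(boundaries$right),
                       ghost_sign(boundaries$bottom),
                       ghost_sign(boundaries$top)),
       theta_implant = theta_implant)
}

solver_params <- function(props, config) {
  list(rho_l = props$rho_l, rho_g = props$rho_g, mu_l = props$mu_l,
       mu_g = props$mu_g, sigma = props$sigma,
       D = config$diffusivity, gx = config$gravity[1],
       gy = config$gravity[2], cfl = config$cfl, dtmax = config$dt_max,
       calpha = config$calpha, ptol = config$p_tol,
       pmaxit = config$p_maxit, nsmooth = config$nsmooth,
       c_in = config$c_in, species_on = isTRUE(config$species))
}

state_to_list <- function(state) {
  list(t = state$t, u = as.numeric(state$u), v = as.numeric(state$v),
       p = as.numeric(state$p), alpha = as.numeric(state$alpha),
       m = as.numeric(state$m))
}

list_to_state <- function(lst, nx, ny) {
  structure(
    list(t = lst$t,
         u = matrix(lst$u, nx + 1L, ny), v = matrix(lst$v, nx, ny + 1L),
         p = matrix(lst$p, nx, ny), alpha = matrix(lst$alpha, nx, ny),
         m = matrix(lst$m, nx, ny),
         c = if (!is.null(lst$c)) matrix(lst$c, nx, ny) else NULL,
         diag = lst$diag),
    class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf(
    "<flow_state> t = %.4g s, mean alpha = %.4g, |u|max = %.4g m/s\n",
    x$t, mean(x$alpha), max(abs(range(x$u)), abs(range(x$v)))))
  invisible(x)
}

#' Initialize the flow state
#'
#' The fluid region starts as void (liquid fraction 0) with a one-cell
#' liquid seed at the inlet faces, zero velocity and zero pressure; the
#' interface and thread zones are therefore initially empty.
#'
#' @param geom a zoned [domain_geometry][rasterize_domain()].
#' @param props a [fluid_properties()] (unused by the initial condition but
#'   kept for interface symmetry).
#' @param config a [solver_config()]; seeds carry the inlet concentration
#'   when species transport is on.
#' @return A `flow_state`.
#' @export
initialize_state <- function(geom, props = fluid_properties(),
                             config = solver_config()) {
  nx <- geom$nx; ny <- geom$ny
  alpha <- matrix(0, nx, ny)
  ## seed: fluid cells adjacent to the inlet faces
  if (!is.null(geom$profile)) {
    if (length(geom$inlet_apex_i)) alpha[geom$inlet_apex_i, 1] <- 1
    if (length(geom$inlet_side_j))
      alpha[geom$nx_fluid, geom$inlet_side_j] <- 1
  }
  alpha[geom$type != CT_FLUID] <- 0
  m <- if (isTRUE(config$species)) alpha * config$c_in else alpha * 0
  structure(
    list(t = 0, u = matrix(0, nx + 1L, ny), v = matrix(0, nx, ny + 1L),
         p = matrix(0, nx, ny), alpha = alpha, m = m, c = m,
         diag = NULL),
    class = "flow_state")
}

#' Apply boundary conditions to a flow state
#'
#' Enforces prescribed inlet velocities, no-slip walls, the free-slip
#' symmetry axis, and zero-gradient outlet values on the face velocity
#' fields.
#'
#' @param state a `flow_state`.
#' @param geom a [domain_geometry][rasterize_domain()].
#' @param config a [solver_config()].
#' @param props a [fluid_properties()].
#' @param boundaries see [solver_geometry()].
#' @return The updated `flow_state`.
#' @export
apply_boundary_conditions <- function(state, geom, config,
                                      props = fluid_properties(),
                                      boundaries = NULL) {
  sg <- solver_geometry(geom, props, config, boundaries)
  list_to_state(cpp_apply_bcs(sg, solver_params(props, config),
                              state_to_list(state)), geom$nx, geom$ny)
}

#' Stable time step
#'
#' `dt = min(CFL h / |u|max, sqrt(rho_mean h^3 / (2 pi sigma)), dt_max)`,
#' further bounded by the explicit viscous and scalar-diffusion limits.
#'
#' @inheritParams apply_boundary_conditions
#' @return Time step (s), strictly positive.
#' @export
compute_dt <- function(state, geom, props, config, boundaries = NULL) {
  sg <- solver_geometry(geom, props, config, boundaries)
  cpp_compute_dt(sg, solver_params(props, config), state_to_list(state))
}

#' Advance the two-phase flow by one time step
#'
#' One step of: VOF advection of the liquid fraction (conservative,
#' bounded, with compressive interface sharpening and an FCT limiter),
#' species advection-diffusion, variable-density momentum update with
#' continuum-surface-force surface tension and the texture drag layer,
#' pressure projection to a discretely divergence-free field, and boundary
#' conditions.
#'
#' @inheritParams apply_boundary_conditions
#' @param dt time step (s), from [compute_dt()].
#' @return The updated `flow_state` (with solver diagnostics in `$diag`).
#' @export
step_flow <- function(state, geom, props, config, dt, boundaries = NULL) {
  sg <- solver_geometry(geom, props, config, boundaries)
  list_to_state(cpp_step(sg, solver_params(props, config),
                         state_to_list(state), dt), geom$nx, geom$ny)
}

#' Run a transient filling simulation
#'
#' Integrates the two-phase system from `t = 0` to `config$end_time`,
#' recording the per-zone time series every `config$output_interval` and
#' full field checkpoints at `config$checkpoint_times`. The run is
#' deterministic: identical inputs give bit-identical outputs.
#'
#' @param geom a zoned [domain_geometry][rasterize_domain()].
#' @param props a [fluid_properties()].
#' @param config a [solver_config()].
#' @param state optional initial `flow_state` (default [initialize_state()]).
#' @param boundaries see [solver_geometry()].
#' @return An object of class `flow_run`: `series` (zone time series
#'   data.frame), `globals` (domain totals and boundary fluxes over time),
#'   `checkpoints` (list of `flow_state`), `final_state`, `diag` (solver
#'   diagnostics), and the resolved inputs.
#' @export
run_simulation <- function(geom, props = fluid_properties(),
                           config = solver_config(), state = NULL,
                           boundaries = NULL) {
  stopifnot(inherits(geom, "domain_geometry"))
  if (is.null(state)) state <- initialize_state(geom, props, config)
  sg <- solver_geometry(geom, props, config, boundaries)
  out <- cpp_advance(sg, solver_params(props, config),
                     state_to_list(state), config$end_time,
                     config$checkpoint_times, config$output_interval)
  series <- as.data.frame(out$series)
  series$zone <- c("interface", "thread", "outer")[series$zone]
  ## areas/volumes to mm2 (2D volume-per-unit-depth)
  series$zone_volume <- series$zone_volume * 1e6
  series$species_mass <- series$species_mass * 1e6
  globals <- as.data.frame(out$globals)
  for (cl in c("liquid_total", "species_total", "liq_in", "liq_out",
               "sp_in", "sp_out"))
    globals[[cl]] <- globals[[cl]] * 1e6
  cks <- lapply(out$checkpoints, list_to_state, nx = geom$nx, ny = geom$ny)
  structure(
    list(series = series, globals = globals, checkpoints = cks,
         final_state = list_to_state(out$final_state, geom$nx, geom$ny),
         diag = out$diag, geom = geom, props = props, config = config,
         theta_implant = sg$theta_implant),
    class = "flow_run")
}

#' @export
print.flow_run <- function(x, ...) {
  d <- x$diag
  cat(sprintf("<flow_run> t_end = %g s, %d steps, %d checkpoints\n",
              max(x$globals$time), as.integer(d$nsteps),
              length(x$checkpoints)))
  cat(sprintf("  liquid: total %.4g, in %.4g, out %.4g (mm2-equivalent m2)\n",
              utils::tail(x$globals$liquid_total, 1), d$liq_in, d$liq_out))
  cat(sprintf("  alpha in [%.3g, %.3g], max divergence %.3g 1/s\n",
              d$alpha_min, d$alpha_max, d$max_div))
  invisible(x)
}
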