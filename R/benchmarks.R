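#' Benchmark case catalogue
#'
#' Synthetic validation cases with evaluable closed-form references, plus
#' the coarse `mini_implant` three-topography domain. Every case is
#' generated in code; no external data is involved.
#'
#' * `poiseuille` — body-force-driven single-phase channel flow; reference
#'   is the parabolic profile `u(x) = rho g x (W - x) / (2 mu)`.
#' * `static_droplet` — 2D liquid disc in gas; reference is the
#'   Young-Laplace pressure jump `sigma / R`.
#' * `gaussian_diffusion` — pure diffusion of a Gaussian release; reference
#'   is the radial second moment `M2(t) = M2(0) + 4 D t`.
#' * `capillary_channel` — liquid column in a vertical slot with wetting
#'   walls; reference is the meniscus pressure jump `2 sigma cos(theta)/W`.
#' * `mini_implant` — scaled screw-implant domain (3 threads, 0.3 mm gap,
#'   coarse grid) runnable in minutes; its error metric is the global
#'   liquid mass-balance defect.
#'
#' @param name case name.
#' @param topography texture kind for `mini_implant`.
#' @return An object of class `benchmark_case` with a `build(resolution)`
#'   closure, the default resolution, and the reference description.
#' @export
make_case <- function(name = c("poiseuille", "static_droplet",
                               "gaussian_diffusion", "capillary_channel",
                               "mini_implant"),
                      topography = "amorphous") {
  valid <- c("poiseuille", "static_droplet", "gaussian_diffusion",
             "capillary_channel", "mini_implant")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("make_case: unknown case '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "))
  case <- switch(
    name,
    poiseuille = list(
      default_resolution = 32L,
      reference = "parabolic channel profile u(x) = rho g x (W - x) / (2 mu)",
      build = function(n = 32L) poiseuille_case(n)),
    static_droplet = list(
      default_resolution = 64L,
      reference = "Young-Laplace 2D pressure jump sigma / R",
      build = function(n = 64L) droplet_case(n)),
    gaussian_diffusion = list(
      default_resolution = 64L,
      reference = "radial second moment M2(t) = M2(0) + 4 D t",
      build = function(n = 64L) gaussian_case(n)),
    capillary_channel = list(
      default_resolution = 24L,
      reference = "meniscus pressure jump 2 sigma cos(theta) / W",
      build = function(n = 24L) capillary_case(n)),
    mini_implant = list(
      default_resolution = 30,
      reference = "global liquid mass balance (no closed-form field)",
      build = function(n = 30) mini_implant_case(h_um = n,
                                                 topography = topography)))
  structure(c(list(name = name), case), class = "benchmark_case")
}

## ---- individual case builders -------------------------------------------

poiseuille_case <- function(n = 32L) {
  W <- 1e-3
  h_um <- W / n * 1e6
  geom <- rasterize_domain(NULL, h = h_um, domain_mm = c(1, 2))
  geom$zone[] <- ZN_OUTER
  geom$zone[geom$type != CT_FLUID] <- 0L
  props <- fluid_properties(rho_l = 1000, mu_l = 0.05, rho_g = 1.2,
                            mu_g = 1.8e-5, sigma = 0, contact_angle = 90)
  g <- 0.5
  config <- solver_config(end_time = 0.05, cfl = 0.5, inlet_speed = 0,
                          checkpoint_times = numeric(0),
                          output_interval = 0.05, gravity = c(0, g),
                          species = FALSE, calpha = 0)
  state <- initialize_state(geom, props, config)
  state$alpha[] <- 1
  state$alpha[geom$type != CT_FLUID] <- 0
  boundaries <- list(left = "wall", right = "wall",
                     bottom = "outlet", top = "outlet")
  evaluate <- function(run) {
    nx <- geom$nx; ny <- geom$ny
    st <- run$final_state
    vc <- 0.5 * (st$v[, 1:ny] + st$v[, 2:(ny + 1)])
    j <- as.integer(round(ny / 2))
    x <- (seq_len(nx) - 0.5) * (W / nx)
    uref <- props$rho_l * g * x * (W - x) / (2 * props$mu_l)
    err <- sqrt(sum((vc[, j] - uref)^2) / sum(uref^2))
    c(l2_rel = err)
  }
  list(geom = geom, props = props, config = config, state = state,
       boundaries = boundaries, evaluate = evaluate)
}

droplet_case <- function(n = 64L) {
  L <- 2e-3
  R_mm <- 0.5           # droplet radius (mm)
  h_um <- L / n * 1e6
  geom <- rasterize_domain(NULL, h = h_um, domain_mm = c(2, 2))
  geom$zone[] <- ZN_OUTER
  geom$zone[geom$type != CT_FLUID] <- 0L
  props <- fluid_properties()
  config <- solver_config(end_time = 0.002, cfl = 0.5, inlet_speed = 0,
                          checkpoint_times = numeric(0),
                          output_interval = 0.002, species = FALSE)
  state <- initialize_state(geom, props, config)
  xc <- outer(geom$x - 1, rep(1, geom$ny))        # mm, centred
  yc <- outer(rep(1, geom$nx), geom$y - 1)
  r <- sqrt(xc^2 + yc^2)
  h_mm <- geom$h_um / 1000
  state$alpha <- matrix(pmin(1, pmax(0, (R_mm - r) / h_mm + 0.5)),
                        geom$nx, geom$ny)
  boundaries <- list(left = "wall", right = "wall",
                     bottom = "wall", top = "outlet")
  evaluate <- function(run) {
    st <- run$final_state
    pin <- mean(st$p[st$alpha > 0.95 & r < 0.7 * R_mm])
    pout <- mean(st$p[st$alpha < 0.05 & r > 1.3 * R_mm])
    dp_ref <- props$sigma / (R_mm * 1e-3)
    c(dp = pin - pout, dp_ref = dp_ref,
      rel_err = abs((pin - pout) - dp_ref) / dp_ref)
  }
  list(geom = geom, props = props, config = config, state = state,
       boundaries = boundaries, evaluate = evaluate)
}

gaussian_case <- function(n = 64L) {
  L <- 1e-3
  D <- 1e-8
  h_um <- L / n * 1e6
  geom <- rasterize_domain(NULL, h = h_um, domain_mm = c(1, 1))
  geom$zone[] <- ZN_OUTER
  geom$zone[geom$type != CT_FLUID] <- 0L
  ## quiescent single-liquid box: both phases get the liquid properties so
  ## the (inactive) gas phase does not constrain the time step
  props <- fluid_properties(rho_l = 1000, mu_l = 1e-3, rho_g = 1000,
                            mu_g = 1e-3, sigma = 0)
  config <- solver_config(end_time = 0.5, cfl = 0.5, inlet_speed = 0,
                          checkpoint_times = numeric(0),
                          output_interval = 0.5,
                          species = TRUE, diffusivity = D, calpha = 0)
  state <- initialize_state(geom, props, config)
  state$alpha[] <- 1
  s0 <- 5e-5  # initial Gaussian std dev (m)
  xc <- outer(geom$x - 0.5, rep(1, geom$ny)) * 1e-3
  yc <- outer(rep(1, geom$nx), geom$y - 0.5) * 1e-3
  state$m <- 0.5 * exp(-(xc^2 + yc^2) / (2 * s0^2))
  boundaries <- list(left = "wall", right = "wall",
                     bottom = "wall", top = "outlet")
  m2_of <- function(m) {
    tot <- sum(m)
    mx <- sum(m * xc) / tot; my <- sum(m * yc) / tot
    sum(m * ((xc - mx)^2 + (yc - my)^2)) / tot
  }
  evaluate <- function(run) {
    m2_0 <- m2_of(state$m)
    m2_t <- m2_of(run$final_state$m)
    ref <- m2_0 + 4 * D * config$end_time
    c(m2 = m2_t, m2_ref = ref, rel_err = abs(m2_t - ref) / ref)
  }
  list(geom = geom, props = props, config = config, state = state,
       boundaries = boundaries, evaluate = evaluate)
}

capillary_case <- function(n = 24L) {
  W <- 0.3e-3
  h_um <- W / n * 1e6
  h_mm <- h_um / 1000
  nwall <- 2L  # wetting walls must be solid cells for the contact angle
  geom <- rasterize_domain(NULL, h = h_um,
                           domain_mm = c(0.3 + 2 * nwall * h_mm, 1.8))
  geom$type[c(seq_len(nwall), geom$nx - nwall + seq_len(nwall)), ] <- CT_BONE
  geom$zone[] <- ZN_OUTER
  geom$zone[geom$type != CT_FLUID] <- 0L
  props <- fluid_properties()
  config <- solver_config(end_time = 0.02, cfl = 0.5, inlet_speed = 0,
                          checkpoint_times = numeric(0),
                          output_interval = 0.02, species = FALSE)
  state <- initialize_state(geom, props, config)
  fill_mm <- 0.6
  state$alpha <- outer(rep(1, geom$nx), as.numeric(geom$y < fill_mm))
  state$alpha[geom$type != CT_FLUID] <- 0
  boundaries <- list(left = "wall", right = "wall",
                     bottom = "wall", top = "outlet")
  evaluate <- function(run) {
    st <- run$final_state
    yc <- outer(rep(1, geom$nx), geom$y)
    pliq <- mean(st$p[st$alpha > 0.99 & yc < 0.4])
    dp_ref <- 2 * props$sigma * cos(props$contact_angle * pi / 180) / W
    c(dp = -pliq, dp_ref = dp_ref, rel_err = abs(-pliq - dp_ref) / dp_ref)
  }
  list(geom = geom, props = props, config = config, state = state,
       boundaries = boundaries, evaluate = evaluate)
}

## Coarse scaled screw-implant domain: 3 threads, 0.3 mm gap, short thin
## shank so the three-topography experiment runs in minutes on one CPU.
mini_implant_case <- function(h_um = 30, topography = "amorphous",
                              end_time = 3) {
  profile <- build_implant_profile(length = 3.6, diameter = 2.4,
                                   thread_count = 3, thread_depth = 0.35,
                                   thread_pitch = 0.9, thread_start = 0.5)
  tex <- texture_spec(kind = topography)
  profile <- apply_texture_to_profile(profile, tex, resolve_meso = FALSE)
  geom <- rasterize_domain(profile, gap = 0.3, h = h_um,
                           apex_clearance = 0.45, top_clearance = 0.45,
                           side_inlet_height = 0.45)
  geom <- assign_zones(geom, interface_thickness = 100)
  ## scaled capillarity: the fill regime is governed by capillary dominance
  ## (capillary pressure >> viscous and dynamic pressures) and by the
  ## contact-angle contrast, not by the absolute surface tension; a reduced
  ## sigma keeps that regime while relaxing the capillary time-step bound.
  ## The gas viscosity is reduced in step (the vented gas is passive) so
  ## the gas-phase viscous bound does not undercut the capillary bound.
  props <- fluid_properties(sigma = 0.003, mu_g = 8e-6)
  config <- solver_config(end_time = end_time, cfl = 0.5,
                          inlet_speed = 3.5e-4, p_tol = 1e-5,
                          checkpoint_times = seq_len(floor(end_time)),
                          output_interval = 0.05, species = TRUE)
  evaluate <- function(run) {
    g <- run$globals
    net <- run$diag$liq_in - run$diag$liq_out
    liq0 <- g$liquid_total[1]
    liq1 <- utils::tail(g$liquid_total, 1)
    c(mass_balance_rel = abs((liq1 - liq0) * 1e-6 - net) /
        max(run$diag$liq_in, 1e-30))
  }
  list(geom = geom, props = props, config = config, state = NULL,
       boundaries = NULL, evaluate = evaluate)
}

#' Run a benchmark case
#'
#' Executes the case at one or more resolutions, reports its error norms,
#' and (for two or more resolutions) the observed convergence order from a
#' Richardson-style fit of the first error norm.
#'
#' @param case a [make_case()] result.
#' @param resolutions integer vector of resolutions (cells across the
#'   characteristic length; grid spacing in um for `mini_implant`).
#' @return A list with `errors` (data.frame of error norms per resolution)
#'   and `observed_order` (`NA` with a single resolution).
#' @export
run_benchmark <- function(case, resolutions = case$default_resolution) {
  stopifnot(inherits(case, "benchmark_case"))
  rows <- list()
  for (n in resolutions) {
    inst <- case$build(n)
    run <- tryCatch(
      run_simulation(inst$geom, inst$props, inst$config,
                     state = inst$state, boundaries = inst$boundaries),
      error = function(e) stop("benchmark '", case$name, "' at resolution ",
                               n, " failed: ", conditionMessage(e)))
    err <- inst$evaluate(run)
    rows[[as.character(n)]] <- c(resolution = n, err)
  }
  errors <- as.data.frame(do.call(rbind, rows))
  order_obs <- NA_real_
  if (nrow(errors) >= 2) {
    e <- errors[[ncol(errors)]]
    r <- errors$resolution
    fit <- stats::lm(log(e) ~ log(1 / r))
    order_obs <- unname(stats::coef(fit)[2])
  }
  list(case = case$name, errors = errors, observed_order = order_obs,
       reference = case$reference)
}

#' Default three-topography experiment configurations
#'
#' Three run configurations identical except for the surface texture:
#' amorphous, nano-trabecular (300 nm nodules), and hybrid (40 um / 50 um
#' meso spikes plus the nano nodules), on the printed implant geometry
#' (11 mm x 4 mm, 3 threads, 0.3 mm implant-bone gap) with a 3 s fill
#' transient and checkpoints at 1, 2 and 3 s.
#'
#' @param mini use the coarse scaled implant domain (5.4 mm shank, 30 um
#'   grid) instead of the full 11 mm geometry; this is the desk-scale
#'   variant used by the comparison experiment.
#' @return Named list of three [run_config()] objects.
#' @export
default_experiment <- function(mini = FALSE) {
  base <- if (mini) {
    run_config(geometry = list(length_mm = 3.6, diameter_mm = 2.4,
                               thread_pitch_mm = 0.9, h_um = 30,
                               apex_clearance_mm = 0.45,
                               top_clearance_mm = 0.45,
                               side_inlet_height_mm = 0.45),
               solver = list(inlet_speed_m_s = 3.5e-4, p_tol = 1e-5),
               fluids = list(sigma = 0.003, mu_g = 8e-6))
  } else {
    run_config(solver = list(inlet_speed_m_s = 1e-3))
  }
  out <- lapply(c(amorphous = "amorphous", nano = "nano", hybrid = "hybrid"),
                function(kind) {
                  cfg <- base
                  cfg$texture$kind <- kind
                  cfg
                })
  out
}

#' Execute a three-topography experiment
#'
#' @param configs named list of [run_config()] objects (e.g.
#'   [default_experiment()]).
#' @param verbose print progress.
#' @return Named list of `flow_run` results.
#' @export
run_topography_experiment <- function(configs, verbose = interactive()) {
  out <- list()
  for (nm in names(configs)) {
    if (verbose) message("running topography: ", nm)
    out[[nm]] <- execute_run(configs[[nm]])
  }
  out
}
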