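test_that("initial state is void except the inlet seed", {
  cs <- periflow:::mini_implant_case(30, "amorphous")
  st <- initialize_state(cs$geom, cs$props, cs$config)
  expect_true(all(is.finite(st$alpha)))
  expect_true(all(st$alpha >= 0 & st$alpha <= 1))
  ## seed volume bounded by one cell layer along the inlets
  n_inlet <- length(cs$geom$inlet_apex_i) + length(cs$geom$inlet_side_j)
  expect_lte(sum(st$alpha), n_inlet)
  ## interface and thread zones start empty
  zlf <- zone_liquid_fraction(st, cs$geom)
  expect_equal(unname(zlf[c("interface", "thread")]), c(0, 0))
})

test_that("boundary conditions impose inlet, wall and symmetry values", {
  cs <- periflow:::mini_implant_case(30, "amorphous")
  st <- initialize_state(cs$geom, cs$props, cs$config)
  st$u[] <- 0.1; st$v[] <- -0.2
  st2 <- apply_boundary_conditions(st, cs$geom, cs$config, cs$props)
  sp <- cs$config$inlet_speed
  expect_equal(unique(st2$v[cs$geom$inlet_apex_i, 1]), sp)
  expect_equal(unique(st2$u[cs$geom$nx_fluid + 1L, cs$geom$inlet_side_j]),
               -sp)
  expect_true(all(st2$u[1, ] == 0))  # symmetry axis
  ## zero inlet speed zeroes all boundary fluxes
  cs$config$inlet_speed <- 0
  st3 <- apply_boundary_conditions(st, cs$geom, cs$config, cs$props)
  expect_true(all(st3$v[, 1] == 0))
  expect_true(all(st3$u[cs$geom$nx + 1L, ] == 0))
})

test_that("effective contact angle follows the Wenzel correction", {
  expect_equal(effective_contact_angle(70, texture_spec("amorphous")), 70)
  expect_equal(effective_contact_angle(90, 1.7), 90) # cos = 0 fixed point
  expect_equal(effective_contact_angle(70, 1.5),
               acos(1.5 * cos(70 * pi / 180)) * 180 / pi)
  ## clamped to complete wetting for strong roughness
  expect_equal(effective_contact_angle(70, 4), 0)
  expect_error(effective_contact_angle(70, 0.8), ">= 1")
  expect_error(effective_contact_angle(200, 1.5), "0, 180")
})

test_that("time step honors the advective and capillary bounds", {
  g <- rasterize_domain(NULL, h = 50, domain_mm = c(1, 1))
  g$zone[] <- periflow:::ZN_OUTER
  props <- fluid_properties(mu_l = 1e-5, mu_g = 1e-6, rho_g = 500,
                            sigma = 0.05)
  config <- solver_config(inlet_speed = 0, species = FALSE, dt_max = 1e-2)
  st <- state_with(g, alpha = 1)
  ## zero velocity: the capillary limit binds
  h <- 50e-6
  cap <- sqrt(0.5 * (props$rho_l + props$rho_g) * h^3 /
                (2 * pi * props$sigma))
  expect_equal(compute_dt(st, g, props, config), cap, tolerance = 1e-12)
  ## hand-set velocity: advective bound matches a brute-force face scan
  set.seed(1)
  st$u[] <- runif(length(st$u), -1, 1)
  st$v[] <- runif(length(st$v), -1, 1)
  st2 <- apply_boundary_conditions(st, g, config, props)
  umax <- max(abs(st2$u), abs(st2$v))
  expect_equal(compute_dt(st, g, props, config),
               min(cap, config$cfl * h / umax), tolerance = 1e-12)
  ## halving h at fixed velocity halves the advective bound (surface
  ## tension off so only the advective limit is active)
  props0 <- fluid_properties(mu_l = 1e-5, mu_g = 1e-6, rho_g = 500,
                             sigma = 0)
  g2 <- rasterize_domain(NULL, h = 25, domain_mm = c(1, 1))
  g2$zone[] <- periflow:::ZN_OUTER
  st3 <- state_with(g2, alpha = 1, u = 1)
  st4 <- state_with(g, alpha = 1, u = 1)
  expect_equal(compute_dt(st3, g2, props0, config) /
                 compute_dt(st4, g, props0, config), 0.5, tolerance = 1e-9)
})

test_that("a quiescent full-liquid state is a fixed point of the step", {
  g <- rasterize_domain(NULL, h = 50, domain_mm = c(1, 1))
  g$zone[] <- periflow:::ZN_OUTER
  props <- fluid_properties()
  config <- solver_config(inlet_speed = 0, species = FALSE)
  st <- state_with(g, alpha = 1)
  bnd <- list(left = "wall", right = "wall", bottom = "wall", top = "outlet")
  st2 <- step_flow(st, g, props, config, dt = 1e-5, boundaries = bnd)
  expect_lt(max(abs(st2$u)), 1e-10)
  expect_lt(max(abs(st2$alpha - st$alpha)), 1e-10)
})

test_that("projection balances inflow and outflow in single-phase flow", {
  g <- rasterize_domain(NULL, h = 50, domain_mm = c(0.8, 1.6))
  g$zone[] <- periflow:::ZN_OUTER
  props <- fluid_properties(sigma = 0)
  config <- solver_config(inlet_speed = 2e-3, species = FALSE, calpha = 0)
  st <- state_with(g, alpha = 1)
  bnd <- list(left = "wall", right = "wall", bottom = "inlet", top = "outlet")
  for (k in 1:5) {
    dt <- compute_dt(st, g, props, config, boundaries = bnd)
    st <- step_flow(st, g, props, config, dt, boundaries = bnd)
  }
  h_m <- 50e-6
  inflow <- sum(st$v[, 1]) * h_m
  outflow <- sum(st$v[, g$ny + 1L]) * h_m
  expect_equal(outflow, inflow, tolerance = 1e-8)
  expect_gt(inflow, 0)
})

test_that("identical configurations give bit-identical runs", {
  cs <- periflow:::mini_implant_case(30, "nano", end_time = 0.02)
  r1 <- run_simulation(cs$geom, cs$props, cs$config,
                       boundaries = cs$boundaries)
  r2 <- run_simulation(cs$geom, cs$props, cs$config,
                       boundaries = cs$boundaries)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$final_state$alpha, r2$final_state$alpha)
  expect_identical(r1$final_state$u, r2$final_state$u)
})

test_that("a zero-length run returns only the initial state", {
  cs <- periflow:::mini_implant_case(30, "amorphous", end_time = 0)
  cs$config$checkpoint_times <- numeric(0)
  run <- run_simulation(cs$geom, cs$props, cs$config,
                        boundaries = cs$boundaries)
  expect_equal(run$diag$nsteps, 0)
  expect_equal(nrow(run$globals), 1L)
  expect_equal(run$final_state$t, 0)
})
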