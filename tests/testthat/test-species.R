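test_that("uniform concentration in a quiescent liquid is unchanged", {
  g <- rasterize_domain(NULL, h = 50, domain_mm = c(1, 1))
  g$zone[] <- periflow:::ZN_OUTER
  st <- state_with(g, alpha = 1, c = 1)
  f <- species_field(st$c / pmax(st$alpha, 1e-12), diffusivity = 1e-9)
  f$c[] <- 1
  bnd <- list(left = "wall", right = "wall", bottom = "wall", top = "wall")
  slack <- fluid_properties(rho_l = 1000, mu_l = 1e-4, rho_g = 1000,
                            mu_g = 1e-4, sigma = 0)
  f2 <- step_species(f, st, g, slack,
                     solver_config(inlet_speed = 0), dt = 1e-4,
                     boundaries = bnd)
  expect_lt(max(abs(f2$c - 1)), 1e-10)
})

test_that("pure advection displaces the centre of mass by u t", {
  g <- rasterize_domain(NULL, h = 25, domain_mm = c(0.5, 2))
  g$zone[] <- periflow:::ZN_OUTER
  U <- 0.02
  st <- state_with(g, alpha = 1, v = U)
  ## concentrated release in the lower part of the channel
  conc <- matrix(0, g$nx, g$ny)
  conc[, 12:16] <- 1
  f <- species_field(conc, diffusivity = 0)
  props <- fluid_properties(rho_l = 1000, mu_l = 1e-4, rho_g = 1000,
                            mu_g = 1e-4, sigma = 0)
  config <- solver_config(inlet_speed = U, species = TRUE, calpha = 0)
  bnd <- list(left = "symmetry", right = "symmetry",
              bottom = "inlet", top = "outlet")
  com0 <- sum(f$c * outer(rep(1, g$nx), g$y)) / sum(f$c)
  nsteps <- 40
  dt <- 2e-4
  for (k in seq_len(nsteps)) {
    ## inlet carries concentration 1, so track only the interior blob
    f <- step_species(f, st, g, props, config, dt, boundaries = bnd)
  }
  ## mask out inlet-fed contamination near the bottom
  cc <- f$c
  cc[, 1:8] <- 0
  com1 <- sum(cc * outer(rep(1, g$nx), g$y)) / sum(cc)
  expect_equal(com1 - com0, U * nsteps * dt * 1000,
               tolerance = 25 / 1000 / (U * nsteps * dt * 1000))
})

test_that("diffusion grows the radial second moment at 4 D t", {
  g <- rasterize_domain(NULL, h = 1000 / 48, domain_mm = c(1, 1))
  g$zone[] <- periflow:::ZN_OUTER
  st <- state_with(g, alpha = 1)
  D <- 1e-8
  xc <- outer(g$x - 0.5, rep(1, g$ny)) * 1e-3
  yc <- outer(rep(1, g$nx), g$y - 0.5) * 1e-3
  s0 <- 6e-5
  conc <- 0.5 * exp(-(xc^2 + yc^2) / (2 * s0^2))
  f <- species_field(conc, diffusivity = D)
  m2 <- function(m) sum(m * (xc^2 + yc^2)) / sum(m)
  m2_0 <- m2(f$c)
  props <- fluid_properties(rho_l = 1000, mu_l = 1e-5, rho_g = 1000,
                            mu_g = 1e-5, sigma = 0)
  config <- solver_config(inlet_speed = 0, species = TRUE, diffusivity = D,
                          dt_max = 0.05)
  bnd <- list(left = "wall", right = "wall", bottom = "wall", top = "wall")
  dt <- 0.2 * (1000 / 48 * 1e-6)^2 / D
  nsteps <- 25
  for (k in seq_len(nsteps)) f <- step_species(f, st, g, props, config, dt,
                                               boundaries = bnd)
  expect_equal(m2(f$c), m2_0 + 4 * D * nsteps * dt, tolerance = 0.02)
})

test_that("dt above the stability bound is rejected with a diagnostic", {
  g <- rasterize_domain(NULL, h = 50, domain_mm = c(1, 1))
  g$zone[] <- periflow:::ZN_OUTER
  st <- state_with(g, alpha = 1)
  f <- species_field(matrix(0, g$nx, g$ny), diffusivity = 1e-7)
  expect_error(step_species(f, st, g, fluid_properties(sigma = 0),
                            solver_config(inlet_speed = 0), dt = 1),
               "stability")
})

test_that("protein arrival never precedes its liquid carrier", {
  ## protein mass in a zone is bounded by the liquid volume there, at every
  ## recorded time of the filling run (concentration is inlet-normalized)
  runs <- mini_runs()
  for (run in runs) {
    s <- run$series
    expect_true(all(s$species_mass <=
                      s$liquid_fraction * s$zone_volume + 1e-9))
    ## discrete maximum principle: c never exceeds the inlet value
    expect_lte(max(run$final_state$c), 1 + 1e-8)
  }
})

test_that("zone species mass equals the direct per-cell sum", {
  cs <- periflow:::mini_implant_case(30, "amorphous")
  g <- cs$geom
  set.seed(5)
  st <- initialize_state(g, cs$props, cs$config)
  st$alpha <- matrix(runif(g$nx * g$ny), g$nx, g$ny)
  st$alpha[g$type != 0L] <- 0
  conc <- matrix(runif(g$nx * g$ny), g$nx, g$ny)
  f <- species_field(conc)
  got <- species_mass_in_zone(f, st, g)
  h2 <- (g$h_um / 1000)^2
  for (z in 1:3) {
    ref <- 0
    for (i in seq_len(g$nx))
      for (j in seq_len(g$ny))
        if (g$zone[i, j] == z) ref <- ref + conc[i, j] * st$alpha[i, j] * h2
    expect_equal(unname(got[z]), ref, tolerance = 1e-12)
  }
  ## degenerate cases
  expect_equal(unname(species_mass_in_zone(species_field(conc * 0), st, g)),
               c(0, 0, 0))
  stf <- st; stf$alpha[] <- 1; stf$alpha[g$type != 0L] <- 0
  full <- species_mass_in_zone(species_field(conc * 0 + 1), stf, g)
  zone_vol <- sapply(1:3, function(z) sum(g$zone == z) * h2)
  expect_equal(unname(full), zone_vol, tolerance = 1e-12)
})
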