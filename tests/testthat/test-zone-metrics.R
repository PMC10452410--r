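test_that("zone liquid fractions reduce correctly", {
  g <- tiny_zoned_domain()
  st <- state_with(g, alpha = 1)
  expect_equal(unname(zone_liquid_fraction(st, g)), c(1, 1, 1))
  st$alpha[] <- 0
  expect_equal(unname(zone_liquid_fraction(st, g)), c(0, 0, 0))
  ## checkerboard against a hand-computed mean
  st$alpha <- outer(1:g$nx, 1:g$ny, function(i, j) (i + j) %% 2)
  got <- zone_liquid_fraction(st, g)
  for (z in 1:3) {
    sel <- g$zone == z
    expect_equal(unname(got[z]), sum(st$alpha[sel]) / sum(sel),
                 tolerance = 1e-12)
  }
})

test_that("zone mean vectors follow the sign conventions", {
  g <- tiny_zoned_domain()
  U <- 0.3
  st <- state_with(g, alpha = 1, v = U)       # uniform upward flow
  mv <- zone_mean_vectors(st, g)
  expect_equal(mv$vertical, rep(U, 3), tolerance = 1e-12)
  expect_equal(mv$horizontal, rep(0, 3), tolerance = 1e-12)
  expect_equal(mv$speed, rep(U, 3), tolerance = 1e-12)
  ## flow from the bone toward the implant axis: -x, inbound positive
  V <- 0.1
  st2 <- state_with(g, alpha = 1, u = -V)
  mv2 <- zone_mean_vectors(st2, g)
  expect_equal(mv2$horizontal, rep(V, 3), tolerance = 1e-12)
  expect_equal(mv2$vertical, rep(0, 3), tolerance = 1e-12)
  expect_equal(mv2$speed, rep(V, 3), tolerance = 1e-12)
})

test_that("zone mean vectors match a brute-force weighted average", {
  g <- tiny_zoned_domain(n = 6)
  set.seed(9)
  st <- state_with(g)
  st$alpha <- matrix(runif(g$nx * g$ny), g$nx, g$ny)
  st$u <- matrix(rnorm((g$nx + 1) * g$ny), g$nx + 1, g$ny)
  st$v <- matrix(rnorm(g$nx * (g$ny + 1)), g$nx, g$ny + 1)
  mv <- zone_mean_vectors(st, g)
  for (z in 1:3) {
    su <- sv <- sw <- 0
    for (i in seq_len(g$nx))
      for (j in seq_len(g$ny)) {
        if (g$zone[i, j] != z) next
        uc <- 0.5 * (st$u[i, j] + st$u[i + 1, j])
        vc <- 0.5 * (st$v[i, j] + st$v[i, j + 1])
        su <- su + st$alpha[i, j] * uc
        sv <- sv + st$alpha[i, j] * vc
        sw <- sw + st$alpha[i, j]
      }
    expect_equal(mv$vertical[z], sv / sw, tolerance = 1e-12)
    expect_equal(mv$horizontal[z], -su / sw, tolerance = 1e-12)
    expect_equal(mv$speed[z], sqrt((su / sw)^2 + (sv / sw)^2),
                 tolerance = 1e-12)
  }
  ## zone with zero liquid is flagged undefined, not zero
  st$alpha[g$zone == 2L] <- 0
  mv0 <- zone_mean_vectors(st, g)
  expect_true(is.na(mv0$speed[2]))
})

make_series <- function(iface_lf, thread_lf, iface_m = 0, thread_m = 0,
                        vol = 1, outer_lf = 0.5) {
  data.frame(
    time = rep(c(0, 3), each = 3),
    zone = rep(c("interface", "thread", "outer"), 2),
    zone_volume = vol,
    liquid_fraction = c(0, 0, 0, iface_lf, thread_lf, outer_lf),
    species_mass = c(0, 0, 0, iface_m, thread_m, 0.1),
    mean_u = 0, mean_v = 0, mean_cell_speed = 0)
}

test_that("recruitment totals and efficiency follow their definitions", {
  s <- make_series(0.3, 0.5, iface_m = 0.02, thread_m = 0.08)
  tot <- recruitment_totals(s)
  expect_equal(unname(tot["blood"]), 0.3 * 1 + 0.5 * 1)
  expect_equal(unname(tot["species"]), 0.1)
  eff <- recruitment_efficiency(s)
  expect_equal(unname(eff["blood"]), 100 * 0.3 / 0.5)
  expect_equal(unname(eff["species"]), 25)
  ## totals ignore the outer zone entirely
  s2 <- make_series(0.3, 0.5, 0.02, 0.08, outer_lf = 0.9)
  expect_equal(recruitment_totals(s2), tot)
  ## zero-quantity cases
  expect_equal(unname(recruitment_totals(make_series(0, 0))), c(0, 0))
  expect_equal(unname(recruitment_efficiency(make_series(0, 0.5))["blood"]),
               0)
  expect_error(recruitment_efficiency(make_series(0.2, 0)), "zero")
})

test_that("identical topographies compare to unit ratios and +/- labels", {
  s <- make_series(0.4, 0.6, 0.1, 0.2)
  s$mean_v <- 0.01
  s$mean_u <- -0.005
  cmp <- compare_topographies(list(amorphous = s, nano = s, hybrid = s))
  expect_true(all(abs(cmp$zones$density_fold - 1) < 1e-12))
  expect_true(all(abs(cmp$zones$speed_fold - 1) < 1e-12))
  expect_true(all(cmp$zones$density_label == "+/-"))
  expect_true(all(cmp$zones$speed_label == "+/-"))
  expect_true(all(cmp$zones$vector == "Up and In"))
})

test_that("fold ratios and qualitative labels respect the thresholds", {
  base <- make_series(0.4, 0.6, 0.1, 0.2)
  base$mean_v <- 0.02
  slow <- base
  slow$mean_v <- ifelse(slow$zone == "interface", 0.005, 0.02)
  cmp <- compare_topographies(list(amorphous = base, hybrid = slow))
  zi <- cmp$zones[cmp$zones$topography == "hybrid" &
                    cmp$zones$zone == "interface", ]
  expect_equal(zi$speed_fold, 0.25, tolerance = 1e-12)
  expect_equal(zi$speed_label, "Very slow")
  ## enumerate the label table across each threshold boundary
  lab <- function(r) periflow:::ratio_label(r, hi = 1.5, lo = 1.15)
  expect_equal(sapply(c(1.6, 1.5, 1.3, 1.15, 1.0, 0.87, 0.85, 0.7), lab),
               c("++", "++", "+", "+", "+/-", "+/-", "-", "-"))
  slab <- function(r) periflow:::speed_label(r, hi = 1.5, lo = 1.15)
  expect_equal(sapply(c(0.5, 2/3, 0.8, 0.86, 1, 1.2), slab),
               c("Very slow", "Very slow", "Slow", "Slow", "+/-", "Fast"))
  ## missing baseline rejected
  expect_error(compare_topographies(list(nano = base)), "amorphous")
})
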