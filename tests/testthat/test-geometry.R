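test_that("default profile honors the printed implant dimensions", {
  p <- build_implant_profile(length = 11, diameter = 4, thread_count = 3)
  expect_equal(diff(range(p$xy[, 2])), 11)
  expect_equal(max(p$xy[, 1]), 2)
  expect_equal(p$thread_count, 3L)
  expect_length(p$ridge_tips, 3L)
  expect_false(brute_force_self_intersects(p$xy))
})

test_that("zero thread depth degenerates to a smooth rectangle profile", {
  p <- build_implant_profile(thread_depth = 0)
  expect_equal(p$thread_count, 0L)
  expect_equal(nrow(p$xy), 4L)
  expect_equal(max(p$xy[, 1]), 2)
})

test_that("thread geometry that does not fit is rejected", {
  expect_error(build_implant_profile(length = 3, thread_pitch = 1.2,
                                     thread_count = 3),
               "fit")
})

test_that("randomized profiles never self-intersect", {
  set.seed(11)
  for (k in 1:8) {
    p <- build_implant_profile(length = runif(1, 6, 14),
                               diameter = runif(1, 3, 5),
                               thread_count = sample(0:3, 1),
                               thread_depth = runif(1, 0.1, 0.5),
                               thread_pitch = runif(1, 0.8, 1.4))
    expect_false(brute_force_self_intersects(p$xy))
  }
})

test_that("meso texturing serrates the boundary and adds arc length", {
  p <- build_implant_profile()
  hyb <- texture_spec("hybrid")
  pt <- apply_texture_to_profile(p, hyb)
  expect_gt(profile_arc_length(pt), profile_arc_length(p))
  expect_false(brute_force_self_intersects(pt$xy))
  ## serration peak-to-valley across the flank equals the spike height
  flank <- pt$xy[abs(pt$xy[, 2] - 8) < 1 & pt$xy[, 1] > 1, ]
  expect_equal(max(flank[, 1]) - min(flank[, 1]), hyb$spike_height / 1000,
               tolerance = 1e-9)
  ## amorphous leaves the polyline untouched
  pa <- apply_texture_to_profile(p, texture_spec("amorphous"))
  expect_identical(pa$xy, p$xy)
})

test_that("rasterization reproduces the designed implant-bone gap", {
  p <- build_implant_profile()
  g <- rasterize_domain(p, gap = 0.3, h = 25)
  expect_equal(measure_min_clearance(g), 0.3, tolerance = 25 / 1000)
})

test_that("solid mask area matches the shoelace polygon area", {
  p <- build_implant_profile()
  ## wide gap so coarse grids satisfy the gap-resolution precondition
  for (h in c(50, 25)) {
    g <- rasterize_domain(p, gap = 0.8, h = h)
    mask_area <- sum(g$type == 1L) * (h / 1000)^2
    poly_area <- periflow:::polygon_area(p$xy)
    perim <- profile_arc_length(p)
    expect_lt(abs(mask_area - poly_area), perim * (h / 1000))
  }
  ## rasterization error shrinks under refinement (observed order >= 1)
  err <- sapply(c(100, 50, 25), function(h) {
    g <- rasterize_domain(p, gap = 0.8, h = h)
    abs(sum(g$type == 1L) * (h / 1000)^2 - periflow:::polygon_area(p$xy))
  })
  expect_lt(err[3], err[1])
  expect_gt(log2(err[1] / err[3]) / 2, 0.9)
})

test_that("absent profile rasterizes to an all-fluid domain", {
  g <- rasterize_domain(NULL, h = 50, domain_mm = c(1, 2))
  expect_true(all(g$type == 0L))
  expect_equal(dim(g$type), c(20L, 40L))
})

test_that("too-coarse grids are rejected", {
  expect_error(rasterize_domain(build_implant_profile(), gap = 0.3, h = 60),
               "8 cells")
})

test_that("zone labels partition the fluid exactly", {
  g <- assign_zones(rasterize_domain(build_implant_profile(), gap = 0.3,
                                     h = 25), 100)
  fluid <- g$type == 0L
  expect_true(all(g$zone[fluid] %in% 1:3))
  expect_true(all(g$zone[!fluid] == 0L))
  expect_equal(sum(g$zone == 1L) + sum(g$zone == 2L) + sum(g$zone == 3L),
               sum(fluid))
})

test_that("the default implant yields one thread pocket per thread", {
  g <- assign_zones(rasterize_domain(build_implant_profile(), gap = 0.3,
                                     h = 25), 100)
  expect_equal(thread_pocket_count(g), 3L)
})

test_that("interface band area matches the analytic band around a smooth implant", {
  p <- build_implant_profile(thread_depth = 0)
  t_um <- 100
  g <- assign_zones(rasterize_domain(p, gap = 0.3, h = 25), t_um)
  band_area <- sum(g$zone == 1L) * (25 / 1000)^2
  ## exposed perimeter: flank + apex + top faces of the rectangle profile
  perim <- p$length + 2 * p$crest_halfwidth
  expect_lt(abs(band_area - perim * t_um / 1000),
            2 * (25 / 1000) * perim)
})

test_that("interface thickness at least as wide as the gap is rejected", {
  g <- rasterize_domain(build_implant_profile(), gap = 0.3, h = 25)
  expect_error(assign_zones(g, 300), "smaller than the gap")
})
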