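test_that("flat surfaces have zero roughness at any offset", {
  for (offset in c(0, -3.2, 17.5)) {
    m <- heightmap(matrix(offset, 16, 16), spacing = 1)
    r <- compute_roughness(m)
    expect_equal(r$Sa, 0)
    expect_equal(r$Sz, 0)
    expect_equal(r$Sdr, 0)
  }
  amorph <- generate_texture_heightmap(texture_spec("amorphous"), 100, 2)
  r <- compute_roughness(amorph)
  expect_true(r$Sa == 0 && r$Sz == 0 && r$Sdr == 0)
})

test_that("symmetric triangular wave gives Sa = H/4 and Sz = H", {
  H <- 12
  P <- 40
  x <- seq(0, 400 - 0.5, by = 0.5)
  tent <- 1 - 2 * abs(x / P - round(x / P))
  hm <- heightmap(matrix(rep(H * tent, 8), nrow = length(x)), spacing = 0.5)
  r <- compute_roughness(hm)
  ## oracle: closed-form integral of |h - mean| over one period is H/4
  expect_equal(r$Sa, H / 4, tolerance = 1e-3)
  expect_equal(r$Sz, H)
})

test_that("tilted plane has the analytic developed area ratio", {
  for (s in c(0.25, 1, 2.5)) {
    x <- (0:40)
    hm <- heightmap(outer(s * x, rep(1, 21)), spacing = 1)
    r <- compute_roughness(hm)
    expect_equal(r$Sdr, sqrt(1 + s^2) - 1, tolerance = 1e-12)
  }
})

test_that("roughness matches a direct per-sample oracle", {
  set.seed(42)
  h <- matrix(rnorm(37 * 23), 37, 23)
  m <- heightmap(h, spacing = 0.7)
  r <- compute_roughness(m)
  ## brute-force oracle: explicit sums
  expect_equal(r$Sa, sum(abs(h - sum(h) / length(h))) / length(h),
               tolerance = 1e-12)
  expect_equal(r$Sz, max(h) - min(h), tolerance = 1e-12)
  ## facet-sum oracle with explicit loops
  s <- 0.7
  area <- 0
  for (i in 1:(nrow(h) - 1)) {
    for (j in 1:(ncol(h) - 1)) {
      p00 <- c(0, 0, h[i, j]); p10 <- c(s, 0, h[i + 1, j])
      p01 <- c(0, s, h[i, j + 1]); p11 <- c(s, s, h[i + 1, j + 1])
      cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
      area <- area +
        0.5 * sqrt(sum(cr(p10 - p00, p11 - p00)^2)) +
        0.5 * sqrt(sum(cr(p11 - p00, p01 - p00)^2))
    }
  }
  planar <- (nrow(h) - 1) * (ncol(h) - 1) * s^2
  expect_equal(r$Sdr, area / planar - 1, tolerance = 1e-12)
})

test_that("Sdr is offset-invariant and Sa, Sz are sign-flip invariant", {
  set.seed(7)
  h <- matrix(rnorm(20 * 20), 20, 20)
  r0 <- compute_roughness(heightmap(h, 1))
  r_off <- compute_roughness(heightmap(h + 11.3, 1))
  r_neg <- compute_roughness(heightmap(-h, 1))
  expect_equal(r_off$Sdr, r0$Sdr, tolerance = 1e-12)
  expect_equal(r_neg$Sa, r0$Sa, tolerance = 1e-12)
  expect_equal(r_neg$Sz, r0$Sz, tolerance = 1e-12)
})

test_that("texture generator renders the printed feature heights exactly", {
  hyb <- texture_spec("hybrid")
  meso <- generate_texture_heightmap(hyb, extent = 500, spacing = 2,
                                     scales = "meso")
  expect_equal(compute_roughness(meso)$Sz, 40)
  nano <- generate_texture_heightmap(texture_spec("nano"),
                                     extent = 10, spacing = 0.03)
  expect_equal(compute_roughness(nano)$Sz, 0.3)
  ## hybrid = superposition of the rendered scales
  both <- generate_texture_heightmap(hyb, extent = 20, spacing = 0.03)
  m <- generate_texture_heightmap(hyb, extent = 20, spacing = 0.03,
                                  scales = "meso")
  n <- generate_texture_heightmap(hyb, extent = 20, spacing = 0.03,
                                  scales = "nano")
  expect_equal(both$heights, m$heights + n$heights, tolerance = 1e-12)
})

test_that("too-coarse sampling of an active scale is rejected", {
  expect_error(generate_texture_heightmap(texture_spec("nano"),
                                          extent = 10, spacing = 0.2),
               "too coarse")
  expect_error(compute_roughness(heightmap(matrix(1, 1, 5), 1)),
               "2 x 2")
})

test_that("nodule jitter is seeded and reproducible", {
  sp1 <- texture_spec("nano", seed = 3, jitter = 0.2)
  sp2 <- texture_spec("nano", seed = 3, jitter = 0.2)
  sp3 <- texture_spec("nano", seed = 4, jitter = 0.2)
  a <- generate_texture_heightmap(sp1, 5, 0.05)
  b <- generate_texture_heightmap(sp2, 5, 0.05)
  d <- generate_texture_heightmap(sp3, 5, 0.05)
  expect_identical(a$heights, b$heights)
  expect_false(identical(a$heights, d$heights))
})

test_that("height maps round-trip through CSV and PNG", {
  m <- generate_texture_heightmap(texture_spec("nano"), 3, 0.05)
  csv <- tempfile(fileext = ".csv")
  write_heightmap_csv(m, csv)
  m2 <- read_heightmap_csv(csv)
  expect_equal(m2$heights, m$heights, tolerance = 1e-12)
  expect_equal(m2$spacing, m$spacing)
  png_f <- tempfile(fileext = ".png")
  write_heightmap_png(m, png_f)
  m3 <- read_heightmap_png(png_f)
  ## gray PNG quantizes to 8 bits of the height range
  expect_lt(max(abs(m3$heights - m$heights)),
            (max(m$heights) - min(m$heights)) / 255)
  expect_equal(m3$spacing, m$spacing)
})
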