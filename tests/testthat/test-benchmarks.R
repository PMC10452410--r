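test_that("unknown benchmark names are rejected with the valid list", {
  expect_error(make_case("foo"), "poiseuille")
  expect_error(make_case("foo"), "mini_implant")
})

test_that("channel flow converges to the parabolic profile", {
  rep_ <- run_benchmark(make_case("poiseuille"), c(8, 16))
  expect_lt(rep_$errors$l2_rel[2], 0.02)
  ## halving h cuts the error consistently with order >= 1
  expect_gt(rep_$observed_order, 1)
})

test_that("benchmark case definitions carry evaluable references", {
  for (nm in c("poiseuille", "static_droplet", "gaussian_diffusion",
               "capillary_channel", "mini_implant")) {
    case <- make_case(nm)
    expect_s3_class(case, "benchmark_case")
    inst <- case$build(case$default_resolution)
    expect_s3_class(inst$geom, "domain_geometry")
    expect_true(is.function(inst$evaluate))
  }
})

test_that("capillary channel reproduces the slot meniscus pressure", {
  rep_ <- run_benchmark(make_case("capillary_channel"), 16)
  expect_lt(rep_$errors$rel_err, 0.2)
})
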