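test_that("phantom generation is a pure function of its spec", {
  spec <- phantom_spec(shape = c(32L, 32L, 32L), seed = 99, texture_knot = 8L)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$data, b$labels$data)
  c <- make_phantom(phantom_spec(shape = c(32L, 32L, 32L), seed = 100,
                                 texture_knot = 8L))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("the default pancreas is small, elongated and inside bounds", {
  ph <- fixture_phantom()
  n <- sum(ph$labels$data == 11)
  expect_gte(n, 300); expect_lte(n, 3000)
  idx <- which(ph$labels$data == 11, arr.ind = TRUE)
  ext <- apply(idx, 2, function(x) diff(range(x)))
  expect_gt(max(ext) / min(ext), 2)  # elongated
})

test_that("phantom generation leaves the global RNG state untouched", {
  set.seed(77)
  before <- .Random.seed
  invisible(make_phantom(phantom_spec(shape = c(16L, 16L, 16L))))
  expect_identical(.Random.seed, before)
})

test_that("organs outside the body are rejected", {
  spec <- phantom_spec(shape = c(32L, 32L, 32L),
                       organs = list(list(label = 6L, hu = 90,
                                          parts = list(list(center = c(2, 2, 2),
                                                            radii = c(4, 4, 4))))))
  expect_error(make_phantom(spec), "outside the body")
})

test_that("smooth warps honor the amplitude contract and stay fold-free", {
  w <- make_smooth_warp(c(48, 48, 48), max_disp = 8, knot_spacing = 24,
                        seed = 15)
  mag <- sqrt(w$displacements[, , , 1]^2 + w$displacements[, , , 2]^2 +
                w$displacements[, , , 3]^2)
  expect_equal(max(mag), 8, tolerance = 1e-6)
  expect_gt(pancatlas:::.min_jacobian(w), 0)
  expect_equal(make_smooth_warp(c(16, 16, 16), max_disp = 0)$displacements,
               zero_field(c(16, 16, 16))$displacements)
  # same seed, same field
  w2 <- make_smooth_warp(c(48, 48, 48), max_disp = 8, knot_spacing = 24,
                         seed = 15)
  expect_identical(w$displacements, w2$displacements)
})

test_that("generated warps invert below half a voxel residual", {
  for (seed in 16:18) {
    w <- make_smooth_warp(c(32, 32, 32), max_disp = 6, knot_spacing = 16,
                          seed = seed)
    expect_lt(attr(invert_field(w), "residual"), 0.5)
  }
})

test_that("cohorts are deterministic and reduce to the template at zero warp", {
  spec <- phantom_spec(shape = c(32L, 32L, 32L), texture_knot = 8L)
  co <- make_cohort(2, spec, warp = list(max_disp = 4, knot_spacing = 12),
                    seed = 3)
  co2 <- make_cohort(2, spec, warp = list(max_disp = 4, knot_spacing = 12),
                     seed = 3)
  expect_identical(co$subjects[[1]]$volume$data, co2$subjects[[1]]$volume$data)
  # zero warp, zero noise: subject equals template exactly
  co0 <- make_cohort(1, spec, warp = list(max_disp = 0, knot_spacing = 12),
                     noise_sd = 0, seed = 3)
  expect_equal(co0$subjects[[1]]$volume$data, co0$template$volume$data,
               tolerance = 1e-9)
  # with noise the difference is pure noise of the configured scale
  con <- make_cohort(1, spec, warp = list(max_disp = 0, knot_spacing = 12),
                     noise_sd = 5, seed = 3)
  resid <- con$subjects[[1]]$volume$data - con$template$volume$data
  expect_lt(abs(sd(as.vector(resid)) - 5), 0.5)
})

test_that("phase offsets shift organ intensities only", {
  spec <- phantom_spec(shape = c(32L, 32L, 32L), texture_knot = 8L)
  co <- make_cohort(2, spec, warp = list(max_disp = 0, knot_spacing = 12),
                    phase_offsets = c(arterial = 40, delayed = 0),
                    noise_sd = 0, seed = 4)
  expect_identical(co$subjects[[1]]$phase, "arterial")
  s <- co$subjects[[1]]
  organ <- s$labels$data > 0
  expect_equal(s$volume$data[organ] - co$template$volume$data[organ],
               rep(40, sum(organ)), tolerance = 1e-9)
  expect_equal(s$volume$data[!organ], co$template$volume$data[!organ],
               tolerance = 1e-9)
})

test_that("score profiles are monotone with exact anchors and endpoints", {
  s <- make_score_profile(96, 10, 88)
  expect_identical(s$n_slices, 96L)
  expect_true(all(diff(s$scores) >= 0))
  expect_equal(s$scores[1], -12)
  expect_equal(s$scores[96], 12)
  expect_identical(s$scores[10], -6)
  expect_identical(s$scores[88], 5)
  expect_error(make_score_profile(96, 50, 50), "z_of_minus6")
})

test_that("cropping a generated profile retains exactly the anchored slices", {
  v <- new_volume(array(rnorm(4 * 4 * 120), c(4, 4, 120)))
  s <- make_score_profile(120, 17, 103)
  cr <- crop_by_scores(v, s)
  expect_identical(attr(cr, "kept_slices"), c(17L, 103L))
})

test_that("mask_body removes exactly the bed voxels of a bedded phantom", {
  ph <- make_phantom(phantom_spec(bed = TRUE))
  nobed <- make_phantom(phantom_spec(bed = FALSE))
  m <- mask_body(ph$volume)
  cleaned <- ph$volume
  cleaned$data[m$data == 0] <- -1000
  # anywhere the bedded and clean phantoms differ (the bed) is now -1000
  bed_voxels <- ph$volume$data != nobed$volume$data
  expect_true(all(cleaned$data[bed_voxels] == -1000))
})
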