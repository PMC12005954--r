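test_that("patch weights follow the reciprocal-deviation law", {
  p <- array(5, c(4, 4, 4))
  expect_equal(patch_weight(p, p, epsilon = 0.55), 1 / 0.55)
  # deviations in ratio 2:1 give weights in ratio 1:2 (epsilon negligible)
  t0 <- array(0, c(4, 4, 4))
  w1 <- patch_weight(t0 + 4, t0, epsilon = 1e-9)
  w2 <- patch_weight(t0 + 2, t0, epsilon = 1e-9)
  expect_equal(w2 / w1, 2, tolerance = 1e-6)
  # constant offset c gives 1 / (|c| + eps)
  expect_equal(patch_weight(t0 + 3, t0, epsilon = 0.55), 1 / 3.55)
})

test_that("averaging identical volumes reproduces the volume bit-near-exactly", {
  ph <- fixture_small_phantom()
  vols <- list(ph$windowed, ph$windowed, ph$windowed)
  res <- weighted_sliding_average(vols, patch_size = 32, overlap = 0.75)
  expect_lt(max(abs(res$average$data - ph$windowed$data)), 1e-8)
  expect_true(all(res$weight_sum > 0))
})

test_that("two constant volumes average to their midpoint by symmetry", {
  a <- small_volume(c(8, 8, 8), 10)
  b <- small_volume(c(8, 8, 8), 20)
  res <- weighted_sliding_average(list(a, b), patch_size = 8, n_iter = 1)
  expect_equal(res$average$data, array(15, c(8, 8, 8)), tolerance = 1e-10)
})

test_that("an outlier volume is down-weighted below the arithmetic mean", {
  eps <- 0.55
  vols <- list(small_volume(c(6, 6, 6), 0), small_volume(c(6, 6, 6), 0),
               small_volume(c(6, 6, 6), 9))
  res <- weighted_sliding_average(vols, patch_size = 6, n_iter = 1,
                                  epsilon = eps)
  # closed form: mu0 = 3; w = 1/(|x - 3| + eps); mu1 = 9*w9 / (2*w0 + w9)
  w0 <- 1 / (3 + eps); w9 <- 1 / (6 + eps)
  mu1 <- 9 * w9 / (2 * w0 + w9)
  expect_equal(res$average$data[1], mu1, tolerance = 1e-12)
  expect_lt(mu1, 3)
})

test_that("uniform weights reduce the sliding average to the voxelwise mean", {
  set.seed(41)
  vols <- lapply(1:4, function(i)
    new_volume(array(rnorm(12^3), c(12, 12, 12))))
  res <- weighted_sliding_average(vols, patch_size = 6, overlap = 0.5,
                                  uniform_weights = TRUE)
  mean_vol <- Reduce(`+`, lapply(vols, `[[`, "data")) / 4
  expect_lt(max(abs(res$average$data - mean_vol)), 1e-10)
})

test_that("sequential sweep reproduces identical inputs and orders matter otherwise", {
  ph <- fixture_small_phantom()
  vols <- list(ph$windowed, ph$windowed)
  res <- weighted_sliding_average(vols, patch_size = 32, sweep = "sequential")
  expect_lt(max(abs(res$average$data - ph$windowed$data)), 1e-8)
  a <- small_volume(c(6, 6, 6), 0); b <- small_volume(c(6, 6, 6), 9)
  seq_ab <- weighted_sliding_average(list(a, b), patch_size = 6, n_iter = 1,
                                     sweep = "sequential")
  agg <- weighted_sliding_average(list(a, b), patch_size = 6, n_iter = 1)
  # the running template visits a first, pulling the result toward it
  expect_false(isTRUE(all.equal(seq_ab$average$data, agg$average$data)))
})

test_that("variance map: zeros for identical inputs, closed form, body zeroing", {
  ph <- fixture_small_phantom()
  vols <- list(ph$windowed, ph$windowed)
  vm <- variance_map(vols, ph$windowed)
  expect_true(all(vm$data == 0))
  a <- small_volume(c(6, 6, 6), 0); b <- small_volume(c(6, 6, 6), 2)
  avg <- small_volume(c(6, 6, 6), 1)
  body <- new_labelmap(array(0L, c(6, 6, 6)), label_names = c(`1` = "body"))
  body$data[2:5, 2:5, 2:5] <- 1L
  vm2 <- variance_map(list(a, b), avg, body)
  expect_equal(vm2$data[3, 3, 3], 1)
  expect_equal(vm2$data[1, 1, 1], 0)
  expect_error(variance_map(list(), avg), "at least one")
})

test_that("variance of seeded unit-variance noise is 1 within Monte-Carlo tol", {
  set.seed(42)
  N <- 20; dims <- c(24, 24, 24)
  vols <- lapply(seq_len(N), function(i)
    new_volume(array(rnorm(prod(dims)), dims)))
  truth <- small_volume(dims, 0)  # population mean, so E[map] = 1 exactly
  vm <- variance_map(vols, truth)
  # mean(vm) = chi^2_{NV} / (NV): sd = sqrt(2/(NV)); allow 3.3 sigma
  expect_lt(abs(mean(vm$data) - 1), 3.3 * sqrt(2 / (N * prod(dims))))
})

test_that("majority vote follows the printed tie-break rules", {
  mk <- function(val) new_labelmap(array(as.integer(val), c(1, 1, 1)))
  expect_identical(majority_vote(list(mk(11), mk(11), mk(0)))$data[1], 11L)
  expect_identical(majority_vote(list(mk(0), mk(11)))$data[1], 0L)
  expect_identical(majority_vote(list(mk(2), mk(3), mk(3)))$data[1], 3L)
  expect_identical(majority_vote(list(mk(2), mk(3)))$data[1], 2L)  # low id wins
  expect_error(majority_vote(list()), "at least one")
})

test_that("fused label set is a subset of the union of input label sets", {
  set.seed(43)
  labs <- lapply(1:5, function(i)
    new_labelmap(array(sample(c(0L, 1L, 6L, 11L), 6^3, TRUE), c(6, 6, 6))))
  fused <- majority_vote(labs)
  expect_true(all(unique(as.vector(fused$data)) %in% c(0L, 1L, 6L, 11L)))
})

test_that("single-subject atlas bundle reproduces that subject", {
  ph <- fixture_small_phantom()
  bundle <- build_phase_atlas(list(list(volume = ph$windowed,
                                        labels = ph$labels)),
                              phase = "arterial",
                              cfg = atlas_config(patch_size = 32))
  expect_equal(bundle$average$data, ph$windowed$data, tolerance = 1e-8)
  expect_identical(bundle$fused_label$data, ph$labels$data)
  expect_lt(max(bundle$variance$data), 1e-20)
  expect_identical(bundle$n_subjects, 1L)
  expect_identical(bundle$phase, "arterial")
  expect_error(build_phase_atlas(list()), "empty")
})

test_that("atlas bundles write three volumes and a JSON sidecar", {
  ph <- fixture_small_phantom()
  bundle <- build_phase_atlas(list(list(volume = ph$windowed,
                                        labels = ph$labels)),
                              cfg = atlas_config(patch_size = 32))
  dir <- tempfile("bundle")
  write_atlas_bundle(bundle, dir)
  expect_true(all(file.exists(file.path(dir,
    c("average.nii.gz", "variance.nii.gz", "fused_label.nii.gz",
      "atlas.json")))))
  meta <- jsonlite::read_json(file.path(dir, "atlas.json"))
  expect_identical(meta$n_subjects, 1L)
  expect_identical(meta$patch_size, 32L)
})
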