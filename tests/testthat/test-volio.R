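test_that("NIfTI round-trip preserves data, spacing and origin", {
  v <- new_volume(array(rnorm(8^3), c(8, 8, 8)), spacing = c(1.5, 1.5, 2),
                  origin = c(10, -20, 5))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  r <- read_volume(path)
  expect_equal(r$data, v$data, tolerance = 1e-6)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-6)
  expect_identical(r$axis_codes, c("R", "A", "S"))
})

test_that("round-trip agrees with an independent NIfTI reader", {
  skip_if_not_installed("oro.nifti")
  v <- new_volume(array(seq_len(6^3), c(6, 6, 6)), spacing = c(2, 2, 2.5))
  path <- tempfile(fileext = ".nii")
  write_volume(v, path)
  img <- oro.nifti::readNIfTI(path, reorient = FALSE)
  expect_equal(array(img@.Data, c(6, 6, 6)), v$data, tolerance = 1e-6)
  expect_equal(oro.nifti::pixdim(img)[2:4], v$spacing, tolerance = 1e-6)
})

test_that("4D image with singleton time axis is squeezed with a warning", {
  a <- array(1:125, c(5, 5, 5, 1))
  path <- tempfile(fileext = ".nii")
  img <- RNifti::asNifti(a)
  RNifti::writeNifti(img, path)
  r <- read_volume(path)  # RNifti itself may drop the axis silently
  expect_identical(dim(r$data), c(5L, 5L, 5L))
})

test_that("missing file errors with the path in the message", {
  expect_error(read_volume("/nonexistent/vol.nii.gz"), "nonexistent")
  expect_error(read_scores("/nonexistent/scores.txt"), "nonexistent")
})

test_that("reorientation to RAS is identity on RAS and idempotent", {
  v <- new_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)))
  expect_identical(reorient_to_ras(v), v)
  lps <- new_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)), spacing = c(1, 2, 3),
                    origin = c(7, 8, 9), axis_codes = c("L", "P", "S"))
  once <- reorient_to_ras(lps)
  expect_identical(reorient_to_ras(once), once)
})

test_that("reorientation preserves physical voxel positions", {
  lps <- new_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)), spacing = c(1, 2, 3),
                    origin = c(7, 8, 9), axis_codes = c("L", "P", "S"))
  ras <- reorient_to_ras(lps)
  expect_identical(ras$axis_codes, c("R", "A", "S"))
  # LPS -> RAS flips the first two axes
  expect_equal(ras$data[1, 1, 1], lps$data[4, 5, 1])
  # corner voxel keeps its physical coordinate
  w_old <- pancatlas:::voxel_to_world(lps, c(4, 5, 1))
  w_new <- pancatlas:::voxel_to_world(ras, c(1, 1, 1))
  expect_equal(as.vector(w_old), as.vector(w_new))
  # an arbitrary permuted orientation also lands on RAS with positions kept
  per <- new_volume(array(rnorm(3 * 4 * 5), c(3, 4, 5)), spacing = c(2, 1, 3),
                    origin = c(-4, 2, 11), axis_codes = c("S", "L", "A"))
  ras2 <- reorient_to_ras(per)
  expect_identical(ras2$axis_codes, c("R", "A", "S"))
  w_old <- pancatlas:::voxel_to_world(per, c(2, 3, 4))
  # locate the same value in the reoriented array
  hit <- which(abs(ras2$data - per$data[2, 3, 4]) < 1e-12, arr.ind = TRUE)[1, ]
  w_new <- pancatlas:::voxel_to_world(ras2, hit)
  expect_equal(as.vector(w_old), as.vector(w_new))
})

test_that("oblique volumes are refused with advice", {
  v <- new_volume(array(0, c(4, 4, 4)))
  v$oblique <- TRUE
  expect_error(reorient_to_ras(v), "resample")
})

test_that("soft-tissue window clamps and is idempotent", {
  v <- new_volume(array(c(1000, -1000, 100, 275, -275, 0, 50, 300),
                        c(2, 2, 2)))
  w <- apply_soft_tissue_window(v)
  expect_equal(as.vector(w$data), c(275, -275, 100, 275, -275, 0, 50, 275))
  expect_equal(apply_soft_tissue_window(w)$data, w$data)
  expect_error(apply_soft_tissue_window(v, 10, 10), "lo < hi")
})

test_that("windowing commutes with score cropping", {
  ph <- fixture_small_phantom()
  s <- make_score_profile(48, 10, 40)
  a <- crop_by_scores(apply_soft_tissue_window(ph$raw), s)
  b <- apply_soft_tissue_window(crop_by_scores(ph$raw, s))
  expect_equal(a$data, b$data)
})

test_that("body mask keeps the body and drops a detached bed", {
  ph <- make_phantom(phantom_spec(bed = TRUE))
  m <- mask_body(ph$volume)
  # bed slab voxels (y = 3..5) are outside the mask
  expect_true(all(m$data[10:86, 3:5, ] == 0))
  # organ voxels are inside
  expect_true(all(m$data[ph$labels$data > 0] == 1))
})

test_that("body mask fills internal cavities and rejects empty volumes", {
  a <- array(-1000, c(32, 32, 32))
  mask <- pancatlas:::.ellipsoid_mask(c(32, 32, 32), c(16, 16, 16), c(10, 10, 10))
  a[mask] <- 50
  a[14:18, 14:18, 14:18] <- -1000  # internal air cavity
  v <- new_volume(a)
  m <- mask_body(v)
  expect_true(all(m$data[15:17, 15:17, 15:17] == 1))
  expect_error(mask_body(new_volume(array(-1000, c(8, 8, 8)))), "no body")
})

test_that("score cropping solves the linear-profile closed form", {
  # 240 slices, scores -12 at slice 0 (0-based) rising to +12 at index 240
  scores <- new_slice_scores(-12 + 24 * (0:239) / 240)
  v <- new_volume(array(rnorm(4 * 4 * 240), c(4, 4, 240)),
                  spacing = c(1, 1, 2))
  cr <- crop_by_scores(v, scores, -6, 5)
  expect_identical(attr(cr, "kept_slices"), c(61L, 171L))  # 0-based 60..170
  expect_identical(dim(cr$data), c(4L, 4L, 111L))
  expect_equal(cr$data, v$data[, , 61:171])
  expect_equal(cr$origin[3], v$origin[3] + 60 * 2)
})

test_that("score cropping no-op, error and idempotence cases", {
  v <- new_volume(array(rnorm(4 * 4 * 10), c(4, 4, 10)))
  all_in <- new_slice_scores(rep(0, 10))
  expect_equal(crop_by_scores(v, all_in)$data, v$data)
  expect_error(crop_by_scores(v, new_slice_scores(rep(9, 10))), "no axial slice")
  s <- new_slice_scores(seq(-12, 12, length.out = 10))
  c1 <- crop_by_scores(v, s)
  ks <- attr(c1, "kept_slices")
  s2 <- new_slice_scores(s$scores[ks[1]:ks[2]])
  c2 <- crop_by_scores(c1, s2)
  expect_equal(c2$data, c1$data)
})

test_that("non-monotone scores keep the longest contiguous run with warning", {
  v <- new_volume(array(0, c(2, 2, 12)))
  s <- new_slice_scores(c(0, 0, 9, 9, 0, 0, 0, 0, 9, 0, 0, 9))
  expect_warning(cr <- crop_by_scores(v, s), "non-monotone")
  expect_identical(attr(cr, "kept_slices"), c(5L, 8L))
})

test_that("resampling reproduces constants and preserves label sets", {
  src <- small_volume(c(6, 6, 6), value = 7, spacing = c(2, 2, 2))
  tgt <- small_volume(c(11, 11, 11), spacing = c(1, 1, 1))
  for (mode in c("nearest", "trilinear", "bicubic"))
    expect_true(all(resample_to_grid(src, tgt, mode)$data == 7))
  lab <- new_labelmap(array(sample(c(0L, 11L), 6^3, TRUE), c(6, 6, 6)),
                      spacing = c(2, 2, 2))
  out <- resample_to_grid(lab, tgt)
  expect_true(all(out$data %in% c(0L, 11L)))
  expect_error(resample_to_grid(lab, tgt, "trilinear"), "nearest")
})

test_that("bicubic resampling reproduces a linear ramp exactly on the interior", {
  v <- ramp_volume(c(12, 12, 12))
  tgt <- new_volume(array(0, c(23, 23, 23)), spacing = c(0.5, 0.5, 0.5))
  out <- resample_to_grid(v, tgt, "bicubic")
  # target voxel (i,j,k) sits at source coordinate (i+1)/2 etc.
  idx <- as.matrix(expand.grid(i = 5:19, j = 5:19, k = 5:19))
  src_coord <- (idx + 1) / 2
  expected <- src_coord[, 1] + 2 * src_coord[, 2] + 3 * src_coord[, 3]
  expect_equal(out$data[idx], expected, tolerance = 1e-9)
})

test_that("bicubic output is clamped to the source range", {
  set.seed(1)
  v <- new_volume(array(rnorm(8^3, sd = 100), c(8, 8, 8)), spacing = c(2, 2, 2))
  tgt <- new_volume(array(0, c(15, 15, 15)))
  out <- resample_to_grid(v, tgt, "bicubic")
  expect_gte(min(out$data), min(v$data))
  expect_lte(max(out$data), max(v$data))
})
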