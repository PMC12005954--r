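test_that("block matching reports zero displacement for identical fields", {
  ph <- fixture_small_phantom()
  s <- compute_ssc(ph$windowed)
  bm <- suppressWarnings(block_match(s, s, n_blocks = 32, search_radius = 2))
  expect_true(all(bm$disp == 0L))
  expect_true(all(bm$score == 0))
})

test_that("block matching recovers an integer translation on interior blocks", {
  ph <- fixture_small_phantom()
  v <- ph$windowed
  mv <- v
  mv$data <- array(min(v$data), dim(v$data))
  mv$data[1:(48 - 3), , ] <- v$data[4:48, , ]  # moving = fixed shifted by (3,0,0)
  fs <- compute_ssc(v)
  ms <- compute_ssc(mv)
  bm <- suppressWarnings(block_match(fs, ms, n_blocks = 27, search_radius = 4))
  interior <- bm$centers[, 1] > 8 & bm$centers[, 1] < 40 &
    bm$centers[, 2] > 8 & bm$centers[, 2] < 40 &
    bm$centers[, 3] > 8 & bm$centers[, 3] < 40
  expect_true(any(interior))
  expect_true(all(bm$disp[interior, 1] == -3L))
  expect_true(all(bm$disp[interior, 2:3] == 0L))
})

test_that("featureless volumes tie-break to zero displacement", {
  v <- small_volume(c(16, 16, 16), value = 1)
  s <- compute_ssc(v)
  bm <- suppressWarnings(block_match(s, s, n_blocks = 8, search_radius = 3))
  expect_true(all(bm$disp == 0L))
})

test_that("trimmed least squares recovers an exact affine to 1e-6", {
  set.seed(11)
  A <- random_affine()
  C <- cbind(runif(60, 5, 40), runif(60, 5, 40), runif(60, 5, 40))
  D <- pancatlas:::affine_apply(A, C) - C
  fit <- fit_affine_trimmed(list(centers = C, disp = D))
  expect_equal(fit$matrix, A$matrix, tolerance = 1e-6)
  expect_equal(fit$translation, A$translation, tolerance = 1e-6)
  # identity matches give the identity transform
  fit0 <- fit_affine_trimmed(list(centers = C, disp = 0 * D))
  expect_equal(fit0$matrix, diag(3), tolerance = 1e-12)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("trimming rejects 40% gross outliers", {
  set.seed(12)
  A <- random_affine()
  C <- cbind(runif(100, 5, 40), runif(100, 5, 40), runif(100, 5, 40))
  D <- pancatlas:::affine_apply(A, C) - C
  bad <- sample(100, 40)
  D[bad, ] <- D[bad, ] + matrix(runif(120, 10, 30) * sample(c(-1, 1), 120, TRUE),
                                ncol = 3)
  fit <- fit_affine_trimmed(list(centers = C, disp = D), keep_fraction = 0.5)
  expect_equal(fit$matrix, A$matrix, tolerance = 1e-3)
  expect_equal(fit$translation, A$translation, tolerance = 1e-3)
})

test_that("keep_fraction 1 equals ordinary least squares (normal equations)", {
  set.seed(13)
  C <- cbind(runif(40, 1, 30), runif(40, 1, 30), runif(40, 1, 30))
  D <- matrix(rnorm(120), ncol = 3)
  fit <- fit_affine_trimmed(list(centers = C, disp = D), keep_fraction = 1)
  X <- cbind(C, 1)
  beta <- solve(t(X) %*% X, t(X) %*% (C + D))  # closed-form normal equations
  expect_equal(fit$matrix, t(beta[1:3, ]), tolerance = 1e-8)
  expect_equal(fit$translation, as.vector(beta[4, ]), tolerance = 1e-8)
})

test_that("degenerate coplanar support is refused", {
  C <- cbind(runif(20, 1, 30), runif(20, 1, 30), 7)
  expect_error(fit_affine_trimmed(list(centers = C, disp = 0 * C)),
               "coplanar|singular")
})

test_that("affine serialization round-trips through text", {
  set.seed(14)
  a <- random_affine()
  path <- tempfile(fileext = ".txt")
  write_affine(a, path)
  b <- read_affine(path)
  expect_equal(b$matrix, a$matrix, tolerance = 1e-12)
  expect_equal(b$translation, a$translation, tolerance = 1e-12)
})

test_that("self-registration yields the identity within half a voxel", {
  ph <- fixture_small_phantom()
  cfg <- affine_config(factors = c(2L, 1L), search_radii = c(4L, 2L),
                       n_blocks = 64L)
  a <- suppressWarnings(register_affine(ph$windowed, ph$windowed, cfg))
  corners <- as.matrix(expand.grid(c(1, 48), c(1, 48), c(1, 48)))
  disp <- pancatlas:::affine_apply(a, corners) - corners
  expect_lt(max(sqrt(rowSums(disp^2))), 0.5)
})

test_that("a known similarity transform is recovered within tolerance", {
  spec <- fixture_small_phantom()$spec
  v <- fixture_small_phantom()$windowed
  th <- 5 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  A <- affine_transform(1.1 * Rz, c(2, -3, 1))
  mov <- apply_soft_tissue_window(make_phantom(spec, affine = invert_affine(A))$volume)
  cfg <- affine_config(factors = c(2L, 1L), search_radii = c(5L, 2L),
                       n_blocks = 64L)
  rec <- suppressWarnings(register_affine(v, mov, cfg))
  expect_lt(max(abs(rec$matrix - A$matrix)), 0.02)
  expect_lt(max(abs(rec$translation - A$translation)), 0.5)
})

test_that("registration is equivariant under a small extra translation", {
  spec <- fixture_small_phantom()$spec
  v <- fixture_small_phantom()$windowed
  T0 <- affine_transform(diag(3), c(2, 0, -1))
  mov0 <- make_phantom(spec, affine = T0)$volume      # mov0 = phantom o T0
  cfg <- affine_config(factors = c(2L, 1L), search_radii = c(4L, 2L),
                       n_blocks = 64L)
  a0 <- suppressWarnings(register_affine(v, apply_soft_tissue_window(mov0), cfg))
  # registering against (phantom o (T0 o T1)) must compose the extra T1
  T1 <- affine_transform(diag(3), c(0, 3, 0))
  mov1 <- make_phantom(spec, affine = pancatlas:::affine_compose(T0, T1))$volume
  a1 <- suppressWarnings(register_affine(v, apply_soft_tissue_window(mov1), cfg))
  # a1 approx inv(T0 o T1) = inv(T1) o a0 ; compare translations
  pred <- pancatlas:::affine_compose(invert_affine(T1), a0)
  expect_lt(max(abs(a1$translation - pred$translation)), 0.5)
  expect_lt(max(abs(a1$matrix - pred$matrix)), 0.02)
})
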