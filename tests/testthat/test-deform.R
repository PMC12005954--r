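test_that("candidate sets enumerate the quantized displacement cube", {
  c1 <- candidate_set(1, 1)
  expect_identical(nrow(c1), 27L)
  expect_true(any(rowSums(abs(c1)) == 0))
  c2 <- candidate_set(6, 5)
  expect_identical(nrow(c2), 2197L)
  expect_equal(max(abs(c2)), 30)
  c3 <- candidate_set(2, 2)
  expect_identical(nrow(c3), 125L)
  expect_true(all(c3 %% 2 == 0))
})

test_that("data costs point at the identity for identical inputs", {
  ph <- fixture_small_phantom()
  s <- compute_ssc(ph$windowed)
  cps <- as.matrix(expand.grid(c(12, 24, 36), c(12, 24, 36), c(12, 24, 36)))
  cands <- candidate_set(2, 1)
  costs <- data_costs(s, s, cps, cands, patch = 6)
  zero <- which(rowSums(abs(cands)) == 0)
  expect_true(all(apply(costs, 1, which.min) == zero))
  expect_true(all(costs[, zero] == 0))
})

test_that("data costs locate a pure axial shift at interior control points", {
  ph <- fixture_small_phantom()
  v <- ph$windowed
  mv <- v
  mv$data <- array(min(v$data), dim(v$data))
  mv$data[, , 1:(48 - 4)] <- v$data[, , 5:48]  # moving shifted by (0,0,4)
  fs <- compute_ssc(v)
  ms <- compute_ssc(mv)
  cps <- as.matrix(expand.grid(c(20, 28), c(20, 28), c(20, 28)))
  cands <- candidate_set(4, 1)
  costs <- data_costs(fs, ms, cps, cands, patch = 6)
  best <- cands[apply(costs, 1, which.min), , drop = FALSE]
  expect_true(all(best[, 1] == 0))
  expect_true(all(best[, 2] == 0))
  expect_true(all(best[, 3] == -4))
})

test_that("constant volumes give all-zero costs and zero-displacement argmin", {
  v <- small_volume(c(24, 24, 24), value = 3)
  s <- compute_ssc(v)
  cps <- as.matrix(expand.grid(c(8, 16), c(8, 16), c(8, 16)))
  cands <- candidate_set(2, 1)
  costs <- data_costs(s, s, cps, cands, patch = 4)
  expect_true(all(costs == 0))
  sol <- mst_optimize(costs, cps, cands, alpha = 0.4)
  expect_true(all(sol$disp == 0))
})

test_that("alpha = 0 reduces the optimizer to per-point argmin", {
  set.seed(21)
  cands <- candidate_set(1, 1)
  cps <- as.matrix(expand.grid(c(4, 8), c(4, 8), c(4, 8)))
  costs <- matrix(runif(8 * 27), 8, 27)
  sol <- mst_optimize(costs, cps, cands, alpha = 0)
  expect_identical(sol$selected, as.integer(apply(costs, 1, which.min)))
})

test_that("huge alpha forces one shared displacement minimizing summed cost", {
  set.seed(22)
  cands <- candidate_set(1, 1)
  cps <- as.matrix(expand.grid(c(4, 8, 12), c(4, 8), 4))
  costs <- matrix(runif(6 * 27), 6, 27)
  sol <- mst_optimize(costs, cps, cands, alpha = 1e6)
  expect_identical(length(unique(sol$selected)), 1L)
  expect_identical(sol$selected[1], as.integer(which.min(colSums(costs))))
})

test_that("tree optimization equals exhaustive enumeration on a 2x1x1 lattice", {
  cands <- matrix(c(0, 0, 0, 2, 0, 0, 0, -1, 0), ncol = 3, byrow = TRUE)
  costs <- matrix(c(0.3, 0.1, 0.5,
                    0.2, 0.6, 0.05), nrow = 2, byrow = TRUE)
  cps <- matrix(c(4, 4, 4, 8, 4, 4), ncol = 3, byrow = TRUE)
  alpha <- 0.3; quant <- 1
  sol <- mst_optimize(costs, cps, cands, alpha, quant)
  oracle <- brute_tree_argmin(costs, cands, alpha, quant)
  expect_identical(sol$selected, as.integer(oracle$lab))
  expect_equal(sol$objective, oracle$objective, tolerance = 1e-12)
})

test_that("optimizer matches the brute-force oracle on random small instances", {
  set.seed(23)
  for (trial in 1:50) {
    n <- sample(1:3, 1)
    m <- sample(2:5, 1)
    cands <- matrix(sample(-3:3, 3 * m, TRUE), ncol = 3)
    cands <- cands[!duplicated(cands), , drop = FALSE]
    m <- nrow(cands)
    if (m < 2) next
    costs <- matrix(runif(n * m), n, m)
    cps <- cbind(seq_len(n) * 5, 4, 4)  # path lattice along x
    alpha <- runif(1, 0, 2)
    quant <- sample(1:3, 1)
    sol <- mst_optimize(costs, cps, cands, alpha, quant)
    oracle <- brute_tree_argmin(costs, cands, alpha, quant)
    expect_equal(sol$objective, oracle$objective, tolerance = 1e-10)
    expect_identical(sol$selected, as.integer(oracle$lab))
  }
})

test_that("deformable self-registration returns a (near) zero field", {
  ph <- fixture_small_phantom()
  sched <- level_schedule(n_levels = 3, grid_spacing = c(8L, 6L, 4L),
                          search_radius = c(4L, 3L, 2L),
                          quantization = c(3L, 2L, 1L), dense_refine = 5L)
  f <- register_deformable(ph$windowed, ph$windowed, sched)
  expect_lt(max(abs(f$displacements)), 0.5)
})

test_that("deformable registration recovers a known smooth warp at desk scale", {
  ph <- fixture_small_phantom()
  v <- ph$windowed
  w <- make_smooth_warp(c(48, 48, 48), max_disp = 4, knot_spacing = 16,
                        seed = 5)
  mov <- apply_transform(v, f = w, mode = "trilinear")
  lab_mov <- apply_transform(ph$labels, f = w)
  sched <- level_schedule(n_levels = 3, grid_spacing = c(8L, 6L, 4L),
                          search_radius = c(4L, 3L, 2L),
                          quantization = c(3L, 2L, 1L))
  f <- register_deformable(v, mov, sched)
  winv <- invert_field(w)
  err <- sqrt(rowSums(matrix(f$displacements - winv$displacements, ncol = 3)^2))
  body <- as.vector(v$data > -270)
  expect_lt(mean(err[body]), 1.5)
  recovered <- apply_transform(lab_mov, f = f)
  expect_gt(dice(recovered, ph$labels, 11), 0.9)
  expect_gt(dice(recovered, ph$labels, 6), 0.9)
})

test_that("per-level data cost of the selection never exceeds the zero cost", {
  ph <- fixture_small_phantom()
  v <- ph$windowed
  w <- make_smooth_warp(c(48, 48, 48), max_disp = 4, knot_spacing = 16,
                        seed = 6)
  mov <- apply_transform(v, f = w, mode = "trilinear")
  sched <- level_schedule(n_levels = 3, grid_spacing = c(8L, 6L, 4L),
                          search_radius = c(4L, 3L, 2L),
                          quantization = c(3L, 2L, 1L), dense_refine = 0L)
  f <- register_deformable(v, mov, sched)
  for (lev in attr(f, "diagnostics")$levels)
    expect_lte(lev$mean_cost, lev$mean_cost0 + 1e-12)
})

test_that("deformation fields serialize to 4D NIfTI and back", {
  w <- make_smooth_warp(c(12, 12, 12), max_disp = 2, knot_spacing = 6, seed = 7)
  path <- tempfile(fileext = ".nii.gz")
  write_field(w, path)
  r <- read_field(path)
  expect_equal(r$displacements, w$displacements, tolerance = 1e-6)
})
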