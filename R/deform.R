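#' Dense deformation field on the fixed grid
#'
#' Displacements are voxel-unit 3-vectors in the pull-back convention: a
#' warped image samples the moving image at `x + f(x)`.
#'
#' @param displacements 4D array `c(dims, 3)` of per-voxel displacements.
#' @param control Optional control-point form: list with `spacing` (lattice
#'   step, voxels), `start` (1-based coordinate of the first control point)
#'   and `disp` (4D lattice array of displacements).
#' @return An object of class `deformation_field`.
#' @export
new_deformation_field <- function(displacements, control = NULL) {
  d <- dim(displacements)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacements must be a 4D array with last dimension 3")
  if (any(!is.finite(displacements))) stop("displacements must be finite")
  structure(list(displacements = displacements, dims = d[1:3],
                 control = control),
            class = "deformation_field")
}

#' All-zero deformation field
#' @param dims Fixed-grid dimensions.
#' @return A [new_deformation_field()] of zeros.
#' @export
zero_field <- function(dims) {
  new_deformation_field(array(0, c(dims, 3)))
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$displacements[, , , 1]^2 + x$displacements[, , , 2]^2 +
                x$displacements[, , , 3]^2)
  cat(sprintf("<deformation_field> %s voxels, |d| max %.3f mean %.3f\n",
              paste(x$dims, collapse = "x"), max(mag), mean(mag)))
  invisible(x)
}

# per-voxel displacement magnitude
field_magnitude <- function(f) {
  sqrt(f$displacements[, , , 1]^2 + f$displacements[, , , 2]^2 +
         f$displacements[, , , 3]^2)
}

#' Write a deformation field as 4D NIfTI
#'
#' The three displacement components are stacked on the fourth axis, in voxel
#' units of the fixed grid.
#'
#' @param f A [new_deformation_field()].
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param spacing Voxel spacing recorded in the header.
#' @return `path`, invisibly.
#' @export
write_field <- function(f, path, spacing = c(1, 1, 1)) {
  stopifnot(inherits(f, "deformation_field"))
  img <- RNifti::asNifti(f$displacements)
  xf <- rbind(cbind(diag(spacing), c(0, 0, 0)), c(0, 0, 0, 1))
  RNifti::`sform<-`(img, structure(xf, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a deformation field written by [write_field()]
#' @param path Path to the 4D NIfTI file.
#' @return A [new_deformation_field()].
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4D displacement NIfTI with 3 components, got ",
         paste(d, collapse = "x"))
  new_deformation_field(array(as.numeric(img), d))
}

#' Level schedule for dense-displacement-sampling registration
#'
#' Defaults follow the five-level coarse-to-fine parameterization used for
#' abdominal CT: control-grid spacings 8..4 voxels, search radii 6..2 steps,
#' step quantization 5..1 voxels, regularization weight 0.4.
#'
#' @param n_levels Number of levels.
#' @param grid_spacing Control-point spacing (voxels) per level.
#' @param search_radius Displacement search radius (steps) per level.
#' @param quantization Voxels per step per level.
#' @param alpha Regularization weight coupling neighboring control points.
#' @param dense_refine Iterations of the final dense diffusion-regularized
#'   intensity refinement that lifts the quantized discrete solution to
#'   sub-voxel accuracy (0 disables).
#' @param refine_sigma Gaussian smoothing (voxels) of each dense refinement
#'   update (the diffusion regularizer).
#' @return A list of class `level_schedule`.
#' @export
level_schedule <- function(n_levels = 5L, grid_spacing = c(8L, 7L, 6L, 5L, 4L),
                           search_radius = c(6L, 5L, 4L, 3L, 2L),
                           quantization = c(5L, 4L, 3L, 2L, 1L),
                           alpha = 0.4, dense_refine = 10L,
                           refine_sigma = 1.5) {
  n_levels <- as.integer(n_levels)
  if (length(grid_spacing) != n_levels || length(search_radius) != n_levels ||
      length(quantization) != n_levels)
    stop("per-level lists must all have length n_levels")
  if (any(grid_spacing < 1L) || any(search_radius < 1L) || any(quantization < 1L))
    stop("spacings, radii and quantization must be strictly positive")
  structure(list(n_levels = n_levels,
                 grid_spacing = as.integer(grid_spacing),
                 search_radius = as.integer(search_radius),
                 quantization = as.integer(quantization),
                 alpha = alpha, dense_refine = as.integer(dense_refine),
                 refine_sigma = refine_sigma), class = "level_schedule")
}

#' Displacement candidate set for one level
#'
#' The cube of integer displacements `{-radius*quant .. +radius*quant}` in
#' steps of `quant` voxels, each axis independently: `(2*radius+1)^3`
#' candidates.
#'
#' @param radius Search radius in steps.
#' @param quant Voxels per step.
#' @return Numeric matrix `m x 3`; attributes `gdim` (per-axis grid size) and
#'   `gidx` (0-based grid index of each candidate) describe the cube layout.
#' @export
candidate_set <- function(radius, quant) {
  if (radius < 1L || quant < 1L) stop("radius and quant must be >= 1")
  ax <- seq(-radius * quant, radius * quant, by = quant)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  dimnames(g) <- NULL
  attr(g, "gdim") <- rep(2L * radius + 1L, 3)
  attr(g, "gidx") <- as.matrix(expand.grid(0:(2 * radius), 0:(2 * radius),
                                           0:(2 * radius)))
  attr(g, "step") <- quant
  g
}

#' Data costs for the discrete deformable stage
#'
#' For each control point and candidate displacement, the mean normalized
#' Hamming distance between the fixed descriptors over the patch around the
#' control point and the moving descriptors displaced by the candidate.
#'
#' @param fixed_ssc,moving_ssc [compute_ssc()] fields on the fixed grid.
#' @param cps Control points, `n x 3` 1-based voxel coordinates.
#' @param candidates Displacement candidates, `m x 3` (integer voxels).
#' @param patch Patch edge length in voxels (the control-grid spacing).
#' @return `n x m` cost matrix with values in \[0, 1\].
#' @export
data_costs <- function(fixed_ssc, moving_ssc, cps, candidates, patch) {
  stopifnot(inherits(fixed_ssc, "ssc_field"), inherits(moving_ssc, "ssc_field"))
  if (!identical(fixed_ssc$dims, moving_ssc$dims))
    stop("descriptor fields must share the fixed grid")
  phalf <- max(0L, as.integer(patch) %/% 2L)
  cpp_data_costs(as.vector(fixed_ssc$packed), as.vector(moving_ssc$packed),
                 fixed_ssc$dims, base::matrix(as.integer(cps), ncol = 3) - 1L,
                 base::matrix(as.integer(round(candidates)), ncol = 3),
                 phalf, fixed_ssc$total_bits)
}

# detect whether candidates form a full uniform cube grid (enables the
# separable lower-envelope message passing)
.cand_grid <- function(candidates) {
  ax <- lapply(1:3, function(k) sort(unique(candidates[, k])))
  sizes <- lengths(ax)
  if (prod(sizes) != nrow(candidates)) return(NULL)
  steps <- vapply(ax, function(u) if (length(u) > 1) diff(u)[1] else 1,
                  numeric(1))
  for (k in 1:3) {
    u <- ax[[k]]
    if (length(u) > 1 && max(abs(diff(u) - steps[k])) > 1e-9) return(NULL)
  }
  if (length(unique(steps[sizes > 1])) > 1) return(NULL)
  step <- if (any(sizes > 1)) steps[sizes > 1][1] else 1
  gidx <- vapply(1:3, function(k) match(candidates[, k], ax[[k]]) - 1L,
                 integer(nrow(candidates)))
  list(gdim = as.integer(sizes), gidx = base::matrix(gidx, ncol = 3),
       step = step)
}

#' Exact discrete optimization over a control-point lattice
#'
#' Minimizes the sum of per-control-point data costs and a quadratic diffusion
#' regularizer `alpha * ||d_c - d_parent||^2 / quant^2` over a minimum
#' spanning tree of the 6-connected lattice (edge weights: squared difference
#' of local intensity means). Dynamic programming over the tree is exact; ties
#' break toward the smallest displacement norm, then lexicographically.
#'
#' @param costs `n x m` cost table from [data_costs()].
#' @param cps Control points (`n x 3`, 1-based), forming a regular lattice in
#'   column-major order.
#' @param candidates `m x 3` displacement candidates.
#' @param alpha Regularization weight.
#' @param quant Voxels per displacement step (scales the regularizer).
#' @param node_means Per-control-point local intensity means used for the MST
#'   edge weights; defaults to zeros (all edges tied, spanning tree fixed by
#'   construction order).
#' @return List with `disp` (`n x 3` selected displacements), `selected`
#'   (candidate index per control point) and `objective`.
#' @export
mst_optimize <- function(costs, cps, candidates, alpha, quant = 1,
                         node_means = NULL) {
  costs <- as.matrix(costs)
  cps <- base::matrix(as.numeric(cps), ncol = 3)
  candidates <- base::matrix(as.numeric(candidates), ncol = 3)
  n <- nrow(costs)
  if (nrow(cps) != n) stop("cps must match cost rows")
  ldim <- vapply(1:3, function(k) length(unique(cps[, k])), integer(1))
  if (prod(ldim) != n)
    stop("control points must form a regular lattice")
  if (is.null(node_means)) node_means <- numeric(n)
  grid <- .cand_grid(candidates)
  if (is.null(grid)) {
    res <- cpp_mst_optimize(costs, ldim, candidates, alpha, quant, node_means,
                            FALSE, integer(3), base::matrix(0L, 1, 3), 0)
  } else {
    dtw <- alpha * (grid$step / quant)^2
    res <- cpp_mst_optimize(costs, ldim, candidates, alpha, quant, node_means,
                            TRUE, grid$gdim, grid$gidx, dtw)
  }
  list(disp = res$disp, selected = as.integer(res$selected),
       objective = res$objective)
}

# trilinear upsampling of a control-lattice displacement increment to the
# dense fixed grid (flat extension beyond the boundary control points)
.upsample_lattice <- function(lat_disp, ldim, starts, spacing, dims) {
  dense <- array(0, c(dims, 3))
  A <- cbind(diag(1 / spacing, 3), -(starts - 1) / spacing)
  for (c in 1:3) {
    comp <- array(lat_disp[, c], ldim)
    dense[, , , c] <- array(cpp_warp(as.vector(comp), ldim, dims, A, NULL,
                                     1L, 0, TRUE, FALSE), dims)
  }
  dense
}

#' Second-stage deformable registration by dense displacement sampling
#'
#' Coarse-to-fine discrete registration on a control-point lattice: at each
#' level the moving volume is warped by the running field, self-similarity
#' descriptors are recomputed on the warped image, per-control-point data
#' costs over the quantized displacement cube are minimized exactly together
#' with the diffusion regularizer over a spanning tree, and the incremental
#' field is trilinearly densified and composed into the running field. A final
#' dense diffusion-regularized intensity refinement (a few local-force
#' iterations with Gaussian-smoothed updates) removes the residual sub-voxel
#' quantization error of the discrete stage.
#'
#' @param fixed Template `ct_volume` (preprocessed).
#' @param moving Moving `ct_volume`, already affine-aligned on the fixed grid
#'   (pass `init` to have the alignment applied here).
#' @param schedule A [level_schedule()].
#' @param init Optional [affine_transform()] applied to `moving` first.
#' @param ssc_cfg An [ssc_config()].
#' @return A [new_deformation_field()]; element `levels` of its `diagnostics`
#'   attribute records per-level mean data costs.
#' @export
register_deformable <- function(fixed, moving, schedule = level_schedule(),
                                init = NULL, ssc_cfg = ssc_config()) {
  stopifnot(inherits(fixed, "ct_volume"), inherits(moving, "ct_volume"))
  if (!identical(dim(fixed$data), dim(moving$data)))
    stop("fixed and moving volumes must share the fixed grid")
  dims <- dim(fixed$data)
  bg <- min(moving$data)
  mov <- moving$data
  if (!is.null(init)) mov <- .warp_array(mov, init, NULL, 1L, bg)
  fssc <- compute_ssc(fixed, ssc_cfg)
  u <- array(0, c(dims, 3))
  diag_levels <- vector("list", schedule$n_levels)
  for (lev in seq_len(schedule$n_levels)) {
    g <- schedule$grid_spacing[lev]
    r <- schedule$search_radius[lev]
    q <- schedule$quantization[lev]
    warped <- .warp_array(mov, NULL, u, 1L, bg)
    mssc <- compute_ssc(new_volume(warped), ssc_cfg)
    starts <- pmin(ceiling(g / 2), dims)
    axes <- lapply(1:3, function(k) seq(starts[k], dims[k], by = g))
    ldim <- lengths(axes)
    cps <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
    cands <- candidate_set(r, q)
    costs <- data_costs(fssc, mssc, cps, cands, patch = g)
    feats <- cpp_patch_means(as.vector(fixed$data), dims, cps - 1L, g %/% 2L)
    sol <- mst_optimize(costs, cps, cands, schedule$alpha, quant = q,
                        node_means = feats)
    inc <- .upsample_lattice(sol$disp, ldim,
                             vapply(axes, `[`, numeric(1), 1),
                             rep(g, 3), dims)
    # compose: u_new(x) = inc(x) + u(x + inc(x))
    u_at <- array(0, c(dims, 3))
    for (c in 1:3)
      u_at[, , , c] <- .warp_array(u[, , , c], NULL, inc, 1L, 0, edge_clamp = TRUE)
    u <- inc + u_at
    diag_levels[[lev]] <- list(grid_spacing = g, radius = r, quant = q,
                               n_cps = nrow(cps),
                               mean_cost0 = mean(costs[, which(rowSums(abs(cands)) == 0)[1]]),
                               mean_cost = mean(costs[cbind(seq_len(nrow(cps)),
                                                            sol$selected)]),
                               objective = sol$objective)
  }
  if (schedule$dense_refine > 0L)
    u <- .dense_refine(fixed$data, mov, u, bg,
                       n_iter = schedule$dense_refine,
                       sigma = schedule$refine_sigma)
  out <- new_deformation_field(u)
  attr(out, "diagnostics") <- list(levels = diag_levels)
  out
}

# dense intensity refinement: normalized local-force updates (force saturates
# at ~1.5 voxels where the residual dominates the gradient), each update
# Gaussian-smoothed (diffusion regularization), added to the running field.
# The images themselves are band-limited (sigma 1) first: crisp body/air
# edges otherwise drive persistently large one-sided forces that steepen the
# field until it is no longer cleanly invertible.
.dense_refine <- function(fixed, moving, u, background, n_iter = 10L,
                          sigma = 1.5, image_sigma = 0) {
  dims <- dim(fixed)
  sm <- function(x) array(cpp_gauss3(as.vector(x), dims, sigma), dims)
  if (image_sigma > 0) {
    fixed <- array(cpp_gauss3(as.vector(fixed), dims, image_sigma), dims)
    moving <- array(cpp_gauss3(as.vector(moving), dims, image_sigma), dims)
    background <- min(moving)
  }
  for (it in seq_len(n_iter)) {
    w <- .warp_array(moving, NULL, u, 1L, background)
    g1 <- array(0, dims); g2 <- array(0, dims); g3 <- array(0, dims)
    g1[2:(dims[1] - 1), , ] <- (w[3:dims[1], , ] - w[1:(dims[1] - 2), , ]) / 2
    g2[, 2:(dims[2] - 1), ] <- (w[, 3:dims[2], ] - w[, 1:(dims[2] - 2), ]) / 2
    g3[, , 2:(dims[3] - 1)] <- (w[, , 3:dims[3]] - w[, , 1:(dims[3] - 2)]) / 2
    r <- fixed - w
    den <- g1^2 + g2^2 + g3^2 + r^2 / 9
    den[den < 1e-6] <- 1e-6
    s <- r / den
    u[, , , 1] <- u[, , , 1] + sm(s * g1)
    u[, , , 2] <- u[, , , 2] + sm(s * g2)
    u[, , , 3] <- u[, , , 3] + sm(s * g3)
  }
  u
}
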