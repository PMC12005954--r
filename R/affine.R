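#' 12-degree-of-freedom affine transform
#'
#' Pull-back convention: the transform maps 1-based voxel coordinates of the
#' fixed grid to 1-based voxel coordinates of the moving grid, so warping is a
#' single gather operation.
#'
#' @param matrix 3x3 linear part (rotation/scale/shear), `|det| > 1e-8`.
#' @param translation Length-3 translation in voxels of the fixed grid.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L) stop("translation must have length 3")
  if (abs(det(matrix)) <= 1e-8) stop("affine matrix is singular")
  structure(list(matrix = matrix, translation = translation),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> fixed -> moving (voxels)\n")
  m <- cbind(x$matrix, x$translation)
  dimnames(m) <- list(NULL, c("", "", "", "t"))
  print(round(m, 5))
  invisible(x)
}

# apply to 1-based coordinates (n x 3)
affine_apply <- function(a, pts) {
  pts <- base::matrix(pts, ncol = 3)
  t(a$matrix %*% t(pts) + a$translation)
}

# a(b(x)): composition, both in the 1-based voxel convention
affine_compose <- function(a, b) {
  affine_transform(a$matrix %*% b$matrix,
                   as.vector(a$matrix %*% b$translation) + a$translation)
}

# 3x4 matrix usable by cpp_warp (0-based voxel coordinates)
affine_as_cpp <- function(a) {
  cbind(a$matrix, as.vector(a$matrix %*% c(1, 1, 1)) + a$translation - 1)
}

#' Write an affine transform as a plain-text homogeneous matrix
#'
#' Serialized as a 4x4 row-major homogeneous matrix, one row per line, acting
#' on 1-based voxel coordinates of the fixed grid.
#'
#' @param a An [affine_transform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_affine <- function(a, path) {
  m <- rbind(cbind(a$matrix, a$translation), c(0, 0, 0, 1))
  writeLines(apply(m, 1, function(r) paste(format(r, digits = 17), collapse = " ")),
             path)
  invisible(path)
}

#' Read an affine transform written by [write_affine()]
#' @param path Path to the 4x4 text file.
#' @return An [affine_transform()].
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (!all(dim(m) == c(4, 4))) stop("expected a 4x4 matrix in ", path)
  affine_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Block matching between two descriptor fields
#'
#' Selects the `n_blocks` non-overlapping blocks of highest intensity variance
#' on the fixed image, and for each scores every integer displacement in the
#' cube of radius `search_radius` by the mean normalized Hamming distance of
#' the quantized descriptors over the block. Ties break toward the smallest
#' displacement norm, then lexicographically, so featureless blocks report
#' zero displacement.
#'
#' @param fixed_ssc,moving_ssc [compute_ssc()] fields on equal-size grids.
#' @param n_blocks Number of blocks to match (reduced with a warning if fewer
#'   are available).
#' @param search_radius Exhaustive search radius in voxels.
#' @param block_size Odd block edge length in voxels.
#' @param refine Additionally return separable parabolic sub-voxel refinement
#'   of each argmin.
#' @return List with `centers` (n x 3, 1-based), `disp` (integer n x 3),
#'   `refined` (numeric n x 3) and `score` (best mean Hamming cost).
#' @export
block_match <- function(fixed_ssc, moving_ssc, n_blocks = 256L,
                        search_radius = 6L, block_size = 7L, refine = FALSE) {
  stopifnot(inherits(fixed_ssc, "ssc_field"), inherits(moving_ssc, "ssc_field"))
  if (!identical(fixed_ssc$dims, moving_ssc$dims))
    stop("descriptor fields must share a common grid size")
  if (block_size %% 2L != 1L) stop("block_size must be odd")
  dims <- fixed_ssc$dims
  bs <- block_size
  starts <- lapply(dims, function(d) seq(1L, max(d - bs + 1L, 1L), by = bs))
  tiles <- as.matrix(expand.grid(starts[[1]], starts[[2]], starts[[3]]))
  if (nrow(tiles) < n_blocks) {
    warning("only ", nrow(tiles), " non-overlapping blocks available; ",
            "reducing n_blocks")
    n_blocks <- nrow(tiles)
  }
  src <- fixed_ssc$source
  vars <- apply(tiles, 1, function(s) {
    stats::var(as.vector(src[s[1]:min(s[1] + bs - 1L, dims[1]),
                             s[2]:min(s[2] + bs - 1L, dims[2]),
                             s[3]:min(s[3] + bs - 1L, dims[3])]))
  })
  sel <- order(vars, decreasing = TRUE)[seq_len(n_blocks)]
  centers <- tiles[sel, , drop = FALSE] + (bs - 1L) %/% 2L
  res <- cpp_block_match(as.vector(fixed_ssc$packed),
                         as.vector(moving_ssc$packed), dims,
                         centers - 1L, (bs - 1L) %/% 2L,
                         as.integer(search_radius), fixed_ssc$total_bits,
                         refine)
  list(centers = centers, disp = res$disp, refined = res$refined,
       score = as.numeric(res$score))
}

#' Trimmed least-squares fit of an affine transform to block matches
#'
#' Alternates a least-squares fit of the 12 affine parameters to the
#' (center -> center + displacement) pairs with discarding of the worst-residual
#' matches, keeping the best `keep_fraction` each iteration. With
#' `keep_fraction = 1` this is ordinary least squares.
#'
#' @param matches A [block_match()] result (or any list with `centers` and
#'   `disp`/`refined` matrices).
#' @param keep_fraction Fraction of matches kept after each trim.
#' @param n_iter Number of fit/trim alternations.
#' @param use_refined Fit to the sub-voxel refined displacements if present.
#' @return An [affine_transform()].
#' @export
fit_affine_trimmed <- function(matches, keep_fraction = 0.5, n_iter = 5L,
                               use_refined = TRUE) {
  C <- base::matrix(as.numeric(matches$centers), ncol = 3)
  D <- matches$refined
  if (is.null(D) || !use_refined) D <- matches$disp
  D <- base::matrix(as.numeric(D), ncol = 3)
  n <- nrow(C)
  if (n < 4L) stop("need at least 4 matches to fit an affine transform")
  X <- cbind(C, 1)
  Y <- C + D
  fit <- function(idx) {
    if (qr(X[idx, , drop = FALSE])$rank < 4L)
      stop("degenerate (coplanar) support after trimming; use more blocks")
    qr.solve(X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
  }
  kept <- seq_len(n)
  beta <- fit(kept)
  # keep at least 8 matches so the trimmed support stays well-conditioned
  # when few blocks are available (coarse pyramid levels on small grids)
  keep_n <- min(n, max(8L, ceiling(keep_fraction * n)))
  for (it in seq_len(n_iter)) {
    res <- sqrt(rowSums((X %*% beta - Y)^2))
    kept <- order(res)[seq_len(keep_n)]
    beta <- fit(kept)
  }
  affine_transform(t(beta[1:3, ]), beta[4, ])
}

#' Affine registration configuration
#'
#' @param factors Integer downsampling factor per level, coarse to fine.
#' @param search_radii Block-match search radius (level voxels) per level.
#' @param block_size Odd block edge length in voxels.
#' @param n_blocks Blocks matched per level.
#' @param keep_fraction,n_iter Trimmed least-squares settings.
#' @param ssc An [ssc_config()].
#' @param refine Use sub-voxel parabolic refinement of block displacements.
#' @param polish_iter Gauss-Newton intensity-based polish iterations applied
#'   after the block-matching levels (0 disables).
#' @return A list of class `affine_config`.
#' @export
affine_config <- function(factors = c(4L, 2L, 1L), search_radii = c(6L, 4L, 2L),
                          block_size = 7L, n_blocks = 256L,
                          keep_fraction = 0.5, n_iter = 5L,
                          ssc = ssc_config(), refine = TRUE,
                          polish_iter = 10L) {
  stopifnot(length(factors) == length(search_radii))
  structure(list(factors = as.integer(factors),
                 search_radii = as.integer(search_radii),
                 block_size = as.integer(block_size),
                 n_blocks = as.integer(n_blocks),
                 keep_fraction = keep_fraction, n_iter = as.integer(n_iter),
                 ssc = ssc, refine = refine,
                 polish_iter = as.integer(polish_iter)),
          class = "affine_config")
}

# Multi-resolution Gauss-Newton intensity polish of the 12 affine parameters
# (sub-voxel accuracy beyond the integer/parabolic block-matching estimate).
# Coarse levels extend the capture range; the finest level sets the accuracy.
# The final pass runs on a Gaussian-smoothed image pair: resampling crisp
# content beyond the grid Nyquist rate aliases and biases the plain SSD
# optimum, and symmetric band-limiting removes most of that bias.
.polish_affine <- function(fixed, moving, a, n_iter = 5L, background = NULL,
                           factors = c(4L, 2L, 1L), final_sigma = 1.5) {
  if (is.null(background)) background <- min(moving)
  dims <- dim(fixed)
  for (f in factors) {
    if (f > 1L) {
      fx <- cpp_downsample(as.vector(fixed), dims, f)
      ldims <- attr(fx, "odim")
      fx <- array(fx, ldims)
      mv <- array(cpp_downsample(as.vector(moving), dims, f), ldims)
    } else {
      fx <- fixed; mv <- moving
    }
    # level coords: x = f * x_l + (1 - f) / 2  (1-based, box-average centers)
    cc <- (1 - f) / 2
    al <- affine_transform(a$matrix,
                           (as.vector(a$matrix %*% rep(cc, 3)) +
                              a$translation - cc) / f)
    al <- .polish_affine_level(fx, mv, al, n_iter, background)
    a <- affine_transform(al$matrix,
                          f * al$translation -
                            as.vector(al$matrix %*% rep(cc, 3)) + cc)
  }
  if (final_sigma > 0) {
    fx <- array(cpp_gauss3(as.vector(fixed), dims, final_sigma), dims)
    mv <- array(cpp_gauss3(as.vector(moving), dims, final_sigma), dims)
    # smoothing blends out-of-view fill values inward, so guard the pass with
    # an FOV coverage map dilated by the same kernel
    ones <- array(1, dims)
    cover <- .warp_array(ones, a, NULL, 1L, 0)
    cover <- array(cpp_gauss3(as.vector(cover), dims, final_sigma), dims)
    a <- .polish_affine_level(fx, mv, a, n_iter, min(mv),
                              mask = cover > 0.999)
  }
  a
}

.polish_affine_level <- function(fixed, moving, a, n_iter = 5L,
                                 background = NULL, mask = NULL) {
  dims <- dim(fixed)
  if (is.null(background)) background <- min(moving)
  crd <- lapply(1:3, function(k) seq_len(dims[k]))
  for (it in seq_len(n_iter)) {
    w <- .warp_array(moving, a, NULL, 1L, background)
    g <- list(array(0, dims), array(0, dims), array(0, dims))
    g[[1]][2:(dims[1] - 1), , ] <- (w[3:dims[1], , ] - w[1:(dims[1] - 2), , ]) / 2
    g[[2]][, 2:(dims[2] - 1), ] <- (w[, 3:dims[2], ] - w[, 1:(dims[2] - 2), ]) / 2
    g[[3]][, , 2:(dims[3] - 1)] <- (w[, , 3:dims[3]] - w[, , 1:(dims[3] - 2)]) / 2
    r <- fixed - w
    # samples that fell outside the moving field of view carry no information
    out_fov <- w == background
    if (!is.null(mask)) out_fov <- out_fov | !mask
    if (any(out_fov)) {
      r[out_fov] <- 0
      for (k in 1:3) g[[k]][out_fov] <- 0
    }
    X <- list(array(rep(crd[[1]], times = dims[2] * dims[3]), dims),
              array(rep(rep(crd[[2]], each = dims[1]), times = dims[3]), dims),
              array(rep(crd[[3]], each = dims[1] * dims[2]), dims))
    # J columns: dA[i,j] (row-major over i then j), then dt[i]
    J <- vector("list", 12L)
    for (i in 1:3) for (j in 1:3) J[[(i - 1) * 3 + j]] <- g[[i]] * X[[j]]
    for (i in 1:3) J[[9 + i]] <- g[[i]]
    JtJ <- matrix(0, 12, 12)
    Jtr <- numeric(12)
    for (p in 1:12) {
      Jtr[p] <- sum(J[[p]] * r)
      for (q in p:12) JtJ[p, q] <- JtJ[q, p] <- sum(J[[p]] * J[[q]])
    }
    delta <- tryCatch(solve(JtJ + diag(1e-8 * max(diag(JtJ)), 12), Jtr),
                      error = function(e) rep(0, 12))
    if (!all(is.finite(delta))) break
    dM <- matrix(delta[1:9], 3, 3, byrow = TRUE)
    a <- affine_transform(a$matrix + dM, a$translation + delta[10:12])
    if (max(abs(delta)) < 1e-6) break
  }
  a
}

#' First-stage affine registration by block matching
#'
#' Runs a coarse-to-fine schedule: at each level the moving volume is warped
#' by the current transform, both volumes are block-averaged down by the level
#' factor, self-similarity descriptors are computed, blocks are matched
#' exhaustively, and a trimmed least-squares increment is composed into the
#' running transform. The result maps fixed-grid voxel coordinates to
#' moving-grid coordinates (12 degrees of freedom).
#'
#' @param fixed,moving Preprocessed `ct_volume`s on a common grid.
#' @param cfg An [affine_config()].
#' @return An [affine_transform()].
#' @export
register_affine <- function(fixed, moving, cfg = affine_config()) {
  stopifnot(inherits(fixed, "ct_volume"), inherits(moving, "ct_volume"))
  if (!identical(dim(fixed$data), dim(moving$data)))
    stop("fixed and moving volumes must share the template grid")
  dims <- dim(fixed$data)
  bg <- min(moving$data)
  a <- affine_transform()
  for (lev in seq_along(cfg$factors)) {
    f <- cfg$factors[lev]
    warped <- .warp_array(moving$data, a, NULL, mode = 1L, background = bg)
    if (f > 1L) {
      fx <- cpp_downsample(as.vector(fixed$data), dims, f)
      ldims <- attr(fx, "odim")
      fx <- array(fx, ldims)
      mv <- array(cpp_downsample(as.vector(warped), dims, f), ldims)
    } else {
      fx <- fixed$data; mv <- warped; ldims <- dims
    }
    fssc <- compute_ssc(new_volume(fx), cfg$ssc)
    mssc <- compute_ssc(new_volume(mv), cfg$ssc)
    bm <- block_match(fssc, mssc, n_blocks = cfg$n_blocks,
                      search_radius = cfg$search_radii[lev],
                      block_size = cfg$block_size, refine = cfg$refine)
    centers_full <- (bm$centers - 1) * f + (f + 1) / 2
    disp_full <- (if (cfg$refine) bm$refined else bm$disp) * f
    inc <- fit_affine_trimmed(list(centers = centers_full, disp = disp_full),
                              keep_fraction = cfg$keep_fraction,
                              n_iter = cfg$n_iter)
    a <- affine_compose(a, inc)
  }
  if (cfg$polish_iter > 0L)
    a <- .polish_affine(fixed$data, moving$data, a, cfg$polish_iter, bg)
  a
}

# low-level warp of a bare array by affine a (may be NULL) and/or dense field
.warp_array <- function(data, a = NULL, field = NULL, mode = 1L,
                        background = 0, edge_clamp = FALSE) {
  dims <- dim(data)
  odims <- if (!is.null(field)) dim(field)[1:3] else dims
  A <- if (is.null(a)) cbind(diag(3), c(0, 0, 0)) else affine_as_cpp(a)
  fv <- if (is.null(field)) NULL else as.vector(field)
  array(cpp_warp(as.vector(data), dims, odims, A, fv, mode, background,
                 edge_clamp, TRUE), odims)
}
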