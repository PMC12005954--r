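#' Apply affine and/or deformable transforms to a volume or label map
#'
#' Pull-back warping on the fixed grid: the output at voxel `x` samples the
#' input at `a(x) + f(x)`. Samples falling outside the input take the
#' background value (-1000 HU before windowing, the lower window bound after
#' windowing, 0 for labels). Label maps must use nearest-neighbor
#' interpolation, which never introduces labels absent from the input.
#'
#' @param v A `ct_volume` or `ct_labelmap` (the moving image).
#' @param a An [affine_transform()], or `NULL` for identity.
#' @param f A [new_deformation_field()], or `NULL` for the zero field.
#' @param mode `"trilinear"`, `"bicubic"` or `"nearest"`.
#' @param background Fill value for out-of-volume samples (default by type as
#'   above).
#' @return The warped object, on the grid of `f` if given, else that of `v`.
#' @export
apply_transform <- function(v, a = NULL, f = NULL,
                            mode = if (inherits(v, "ct_labelmap")) "nearest" else "trilinear",
                            background = NULL) {
  stopifnot(inherits(v, "ct_volume"))
  if (inherits(v, "ct_labelmap") && mode != "nearest")
    stop("label maps must be warped with mode = \"nearest\"")
  if (!is.null(a) && !inherits(a, "affine_transform"))
    stop("a must be an affine_transform or NULL")
  if (!is.null(f) && !inherits(f, "deformation_field"))
    stop("f must be a deformation_field or NULL")
  if (is.null(background)) {
    background <- if (inherits(v, "ct_labelmap")) 0
      else if (!is.null(v$window)) v$window[1] else -1000
  }
  field <- if (is.null(f)) NULL else f$displacements
  out <- v
  out$data <- .warp_array(v$data, a, field, .mode_code(mode), background)
  if (inherits(v, "ct_labelmap"))
    out$data <- array(as.integer(round(out$data)), dim(out$data))
  out
}

#' Invert an affine transform
#'
#' @param a An [affine_transform()] with a well-conditioned matrix.
#' @return The inverse transform: `a` composed with it is the identity.
#' @export
invert_affine <- function(a) {
  stopifnot(inherits(a, "affine_transform"))
  if (abs(det(a$matrix)) < 1e-8 || kappa(a$matrix) > 1e10)
    stop("affine matrix is singular or near-singular")
  minv <- solve(a$matrix)
  affine_transform(minv, -as.vector(minv %*% a$translation))
}

# sample every component of a dense field at x + g(x) (edge-clamped trilinear)
.sample_field <- function(f_disp, g_disp) {
  dims <- dim(f_disp)[1:3]
  out <- array(0, dim(f_disp))
  for (c in 1:3)
    out[, , , c] <- .warp_array(f_disp[, , , c], NULL, g_disp, 1L, 0,
                                edge_clamp = TRUE)
  out
}

#' Invert a deformation field by fixed-point iteration
#'
#' Solves `g(x) = -f(x + g(x))` starting from `g = -f`, so that warping with
#' `f` then with `g` is the identity up to the reported residual. Requires a
#' smooth, non-folding field.
#'
#' @param f A [new_deformation_field()].
#' @param n_iter Maximum fixed-point iterations.
#' @param tol Stop when the maximum update falls below this (voxels).
#' @return The inverse field; attribute `residual` gives
#'   `max |f(x + g(x)) + g(x)|` in voxels. Non-convergence warns but still
#'   returns the result.
#' @export
invert_field <- function(f, n_iter = 20L, tol = 0.05) {
  stopifnot(inherits(f, "deformation_field"))
  g <- -f$displacements
  delta <- Inf
  for (it in seq_len(n_iter)) {
    f_at <- .sample_field(f$displacements, g)
    gnew <- -f_at
    delta <- max(abs(gnew - g))
    g <- gnew
    if (delta < tol) break
  }
  f_at <- .sample_field(f$displacements, g)
  residual <- max(abs(f_at + g))
  if (delta >= tol)
    warning(sprintf("field inversion did not converge (residual %.3f voxels)",
                    residual))
  out <- new_deformation_field(g)
  attr(out, "residual") <- residual
  out
}

#' Fold an affine and a deformation field into one dense field
#'
#' With `order = "affine_last"` returns `u(x) = a(x + f(x)) - x`: one warp by
#' `u` equals warping by `f` and then resampling through `a`. With
#' `order = "affine_first"` returns `u(x) = a(x) + f(a(x)) - x`: resampling
#' through `a`, then warping by `f` (the shape of an inverse two-stage
#' transform). Folding the stages into one gather halves the interpolation
#' (or, for labels, rounding) losses of sequential application.
#'
#' @param a An [affine_transform()], or `NULL` for identity.
#' @param f A [new_deformation_field()], or `NULL` for the zero field (then
#'   `dims` must be given).
#' @param order Which stage acts first (see above).
#' @param dims Fixed-grid dimensions when `f` is `NULL`.
#' @return A [new_deformation_field()].
#' @export
compose_affine_field <- function(a = NULL, f = NULL,
                                 order = c("affine_last", "affine_first"),
                                 dims = NULL) {
  order <- match.arg(order)
  if (is.null(f) && is.null(dims)) stop("need f or dims")
  if (is.null(dims)) dims <- f$dims
  if (is.null(a)) a <- affine_transform()
  X <- .grid_coords(dims)
  u <- array(0, c(dims, 3))
  M <- a$matrix; t <- a$translation
  if (order == "affine_last") {
    fx <- if (is.null(f)) list(0, 0, 0)
      else list(f$displacements[, , , 1], f$displacements[, , , 2],
                f$displacements[, , , 3])
    for (k in 1:3)
      u[, , , k] <- M[k, 1] * (X[[1]] + fx[[1]]) +
        M[k, 2] * (X[[2]] + fx[[2]]) +
        M[k, 3] * (X[[3]] + fx[[3]]) + t[k] - X[[k]]
  } else {
    # f sampled at a(x), edge-clamped trilinear
    for (k in 1:3) {
      ax <- M[k, 1] * X[[1]] + M[k, 2] * X[[2]] + M[k, 3] * X[[3]] + t[k]
      f_at <- if (is.null(f)) 0
        else .warp_array(f$displacements[, , , k], a, NULL, 1L, 0,
                         edge_clamp = TRUE)
      u[, , , k] <- ax + f_at - X[[k]]
    }
  }
  new_deformation_field(u)
}

#' Compose two deformation fields
#'
#' `(outer o inner)(x) = inner(x) + outer(x + inner(x))`: warping with the
#' composed field equals warping with `inner` then with `outer`.
#'
#' @param outer,inner [new_deformation_field()]s on a shared fixed grid.
#' @return The composed field.
#' @export
compose_fields <- function(outer, inner) {
  stopifnot(inherits(outer, "deformation_field"),
            inherits(inner, "deformation_field"))
  if (!identical(outer$dims, inner$dims))
    stop("fields must share the fixed grid")
  new_deformation_field(inner$displacements +
                          .sample_field(outer$displacements,
                                        inner$displacements))
}
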