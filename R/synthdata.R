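# Deterministic synthetic abdominal phantoms: a superellipsoid soft-tissue
# body on a -1000 HU background, ellipsoidal organs at distinct HU, a small
# elongated two-part pancreas (label 11), optional detached "bed" slab, smooth
# seeded texture. All generators are pure functions of their seed.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

.default_organs <- function(shape) {
  s <- shape / 96  # organ geometry scales with the grid
  el <- function(center, radii) list(center = center * s, radii = radii * s)
  list(
    list(label = 6L, hu = 90, parts = list(el(c(34, 42, 58), c(13, 11, 12)))),
    list(label = 1L, hu = 100, parts = list(el(c(66, 44, 60), c(7, 6, 8)))),
    list(label = 2L, hu = 120, parts = list(el(c(34, 56, 40), c(6, 6, 8)))),
    list(label = 3L, hu = 120, parts = list(el(c(62, 56, 40), c(6, 6, 8)))),
    list(label = 7L, hu = 20, parts = list(el(c(55, 36, 55), c(8, 7, 7)))),
    list(label = 8L, hu = 80, parts = list(el(c(48, 54, 48), c(4, 4, 18)))),
    # pancreas: bulkier head + thin elongated tail (head/tail asymmetry)
    list(label = 11L, hu = 70, parts = list(el(c(58, 46, 48), c(5, 4, 4)),
                                            el(c(46, 44, 50), c(11, 3, 3))))
  )
}

#' Specification of a synthetic abdominal phantom
#'
#' @param shape Grid dimensions (voxels).
#' @param seed Integer seed; the phantom is a pure function of the spec.
#' @param organs List of organs, each `list(label =, hu =, parts = list(
#'   list(center =, radii =), ...))` (ellipsoid parts, voxel units). Defaults
#'   to a seven-organ abdomen with a small elongated pancreas (label 11).
#' @param body Superellipsoid body envelope: `list(center =, radii =,
#'   exponent =, hu =)` (`center = NULL` centers it in the grid).
#' @param bed Add a detached CT-bed slab at 0 HU.
#' @param texture_amplitude Amplitude (HU) of the smooth seeded texture.
#' @param texture_knot Knot spacing (voxels) of the texture lattice.
#' @param smooth_sigma Partial-volume blur of the final volume (voxels);
#'   emulates the CT point-spread function and softens organ boundaries.
#' @param spacing Voxel spacing in mm.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L), seed = 1L, organs = NULL,
                         body = list(center = NULL, radii = NULL,
                                     exponent = 2.5, hu = 40),
                         bed = FALSE, texture_amplitude = 15,
                         texture_knot = 12L, smooth_sigma = 0.8,
                         spacing = c(2, 2, 2)) {
  shape <- as.integer(shape)
  if (is.null(organs)) organs <- .default_organs(shape)
  if (is.null(body$center)) body$center <- (shape + 1) / 2
  if (is.null(body$radii)) body$radii <- shape * c(34, 27, 36) / 96
  structure(list(shape = shape, seed = as.integer(seed), organs = organs,
                 body = body, bed = bed,
                 texture_amplitude = texture_amplitude,
                 texture_knot = as.integer(texture_knot),
                 smooth_sigma = smooth_sigma,
                 spacing = spacing),
            class = "phantom_spec")
}

# superellipsoid/ellipsoid mask; separable outer sums on the identity grid,
# or evaluated at analytically transformed coordinates (coords = list of three
# arrays) for interpolation-free warped phantoms
.ellipsoid_mask <- function(shape, center, radii, exponent = 2, coords = NULL) {
  if (is.null(coords)) {
    ax <- lapply(1:3, function(k)
      (abs(seq_len(shape[k]) - center[k]) / radii[k])^exponent)
    return(outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`) <= 1)
  }
  (abs(coords[[1]] - center[1]) / radii[1])^exponent +
    (abs(coords[[2]] - center[2]) / radii[2])^exponent +
    (abs(coords[[3]] - center[3]) / radii[3])^exponent <= 1
}

# 1-based voxel coordinate arrays of the grid, optionally mapped through a
# pull-back affine
.grid_coords <- function(shape, affine = NULL) {
  X <- list(array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), shape),
            array(rep(rep(seq_len(shape[2]), each = shape[1]),
                      times = shape[3]), shape),
            array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape))
  if (is.null(affine)) return(X)
  M <- affine$matrix; t <- affine$translation
  lapply(1:3, function(k)
    M[k, 1] * X[[1]] + M[k, 2] * X[[2]] + M[k, 3] * X[[3]] + t[k])
}

# smooth random texture: seeded normal knots on a coarse lattice, trilinearly
# upsampled to the full grid (optionally evaluated at affinely transformed
# coordinates, consuming the same random knots)
.smooth_noise <- function(shape, knot, amplitude, affine = NULL) {
  # the lattice extends `margin` voxels beyond the grid so that affinely
  # transformed coordinates still see texture, not a clamped plateau
  margin <- 2L * knot
  kd <- pmax(2L, as.integer(ceiling((shape - 1 + 2 * margin) / knot)) + 1L)
  knots <- array(stats::rnorm(prod(kd)), kd)
  if (is.null(affine)) {
    A <- cbind(diag(1 / knot, 3), rep(margin / knot, 3))
  } else {
    # knot-lattice coords of a(x): ((M (x0+1) + t) - 1 + margin) / knot
    M <- affine$matrix; t <- affine$translation
    A <- cbind(M / knot,
               (as.vector(M %*% c(1, 1, 1)) + t - 1 + margin) / knot)
  }
  amplitude * array(cpp_warp(as.vector(knots), kd, shape, A, NULL, 1L, 0,
                             TRUE, FALSE), shape)
}

#' Generate a synthetic abdominal phantom
#'
#' With `affine`, the phantom is evaluated analytically at the transformed
#' coordinates `a(x)` (pull-back convention): the result is an exact,
#' interpolation-free affinely warped phantom, suitable as ground truth for
#' parameter-recovery experiments.
#'
#' @param spec A [phantom_spec()].
#' @param affine Optional [affine_transform()] under which to evaluate the
#'   phantom.
#' @return List with `volume` (a `ct_volume`, HU) and `labels` (the exact
#'   `ct_labelmap`). Same spec (including seed) gives bit-identical output.
#' @export
make_phantom <- function(spec = phantom_spec(), affine = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  coords <- if (is.null(affine)) NULL else .grid_coords(shape, affine)
  body <- .ellipsoid_mask(shape, spec$body$center, spec$body$radii,
                          spec$body$exponent, coords)
  vol <- array(-1000, shape)
  tex <- .with_seed(spec$seed,
                    .smooth_noise(shape, spec$texture_knot,
                                  spec$texture_amplitude, affine))
  vol[body] <- spec$body$hu + tex[body]
  lab <- array(0L, shape)
  for (organ in spec$organs) {
    m <- Reduce(`|`, lapply(organ$parts, function(p)
      .ellipsoid_mask(shape, p$center, p$radii, 2, coords)))
    if (is.null(affine) && any(m & !body))
      stop("organ with label ", organ$label, " extends outside the body")
    vol[m] <- organ$hu + tex[m]
    lab[m] <- organ$label
  }
  if (!is.null(spec$smooth_sigma) && spec$smooth_sigma > 0)
    vol <- array(cpp_gauss3(as.vector(vol), shape, spec$smooth_sigma), shape)
  if (isTRUE(spec$bed)) {
    ymax <- min(5L, shape[2])
    vol[10:max(10L, shape[1] - 10L), 3:ymax, ] <- 0
  }
  list(volume = new_volume(vol, spacing = spec$spacing),
       labels = new_labelmap(lab, spacing = spec$spacing))
}

#' Generate a smooth, invertible random deformation field
#'
#' Seeded normal displacements on a coarse knot lattice are trilinearly
#' upsampled and rescaled so the maximum displacement magnitude equals
#' `max_disp`. With `max_disp < knot_spacing / 2` the field is free of folding
#' (positive Jacobian); if folding is detected anyway the amplitude is damped
#' by 0.8 and the check repeated.
#'
#' @param shape Fixed-grid dimensions.
#' @param max_disp Maximum displacement magnitude in voxels.
#' @param knot_spacing Knot lattice spacing in voxels.
#' @param seed Integer seed.
#' @return A [new_deformation_field()].
#' @export
make_smooth_warp <- function(shape, max_disp = 8, knot_spacing = 24L,
                             seed = 1L) {
  shape <- as.integer(shape)
  if (max_disp == 0) return(zero_field(shape))
  disp <- .with_seed(seed, {
    d <- array(0, c(shape, 3))
    for (c in 1:3)
      d[, , , c] <- .smooth_noise(shape, knot_spacing, 1)
    d
  })
  mag <- sqrt(disp[, , , 1]^2 + disp[, , , 2]^2 + disp[, , , 3]^2)
  scale <- max_disp / max(mag)
  for (damp in 0:8) {
    f <- new_deformation_field(disp * scale)
    if (.min_jacobian(f) > 0) {
      if (damp > 0)
        message("smooth warp damped by 0.8^", damp, " to remove folding")
      return(f)
    }
    scale <- scale * 0.8
  }
  stop("could not generate a fold-free field")
}

# minimum finite-difference Jacobian determinant of x + f(x) over the grid
.min_jacobian <- function(f) {
  d <- f$displacements
  dims <- dim(d)[1:3]
  if (any(dims < 3L)) return(1)
  J <- array(0, c(dims - 2L, 3, 3))
  core <- function(a, k) {
    # central difference of component a along axis k, interior voxels
    idx1 <- switch(k, list(3:dims[1], 2:(dims[2] - 1), 2:(dims[3] - 1)),
                   list(2:(dims[1] - 1), 3:dims[2], 2:(dims[3] - 1)),
                   list(2:(dims[1] - 1), 2:(dims[2] - 1), 3:dims[3]))
    idx0 <- switch(k, list(1:(dims[1] - 2), 2:(dims[2] - 1), 2:(dims[3] - 1)),
                   list(2:(dims[1] - 1), 1:(dims[2] - 2), 2:(dims[3] - 1)),
                   list(2:(dims[1] - 1), 2:(dims[2] - 1), 1:(dims[3] - 2)))
    (d[idx1[[1]], idx1[[2]], idx1[[3]], a] -
        d[idx0[[1]], idx0[[2]], idx0[[3]], a]) / 2
  }
  for (a in 1:3) for (k in 1:3)
    J[, , , a, k] <- core(a, k) + (a == k)
  det3 <- J[, , , 1, 1] * (J[, , , 2, 2] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 2]) -
    J[, , , 1, 2] * (J[, , , 2, 1] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 1]) +
    J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] - J[, , , 2, 2] * J[, , , 3, 1])
  min(det3)
}

#' Generate a synthetic multi-subject cohort from a template phantom
#'
#' Each subject is the template phantom warped by an independent seeded smooth
#' deformation, with a phase-dependent HU offset added to organ voxels and
#' seeded voxel noise. Ground-truth fields are returned for recovery
#' evaluation.
#'
#' @param n Number of subjects.
#' @param template_spec A [phantom_spec()] for the template.
#' @param warp List with `max_disp` and `knot_spacing` for
#'   [make_smooth_warp()].
#' @param phase_offsets Named numeric vector of per-phase organ HU shifts;
#'   subjects cycle through the phases.
#' @param noise_sd Voxel noise standard deviation (HU).
#' @param seed Integer master seed (subject seeds are derived from it).
#' @return List with `template` (the [make_phantom()] output) and `subjects`,
#'   each `list(id =, volume =, labels =, gt_field =, phase =)`.
#' @export
make_cohort <- function(n, template_spec = phantom_spec(),
                        warp = list(max_disp = 8, knot_spacing = 24L),
                        phase_offsets = c(`portal venous` = 0),
                        noise_sd = 5, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  template <- make_phantom(template_spec)
  shape <- template_spec$shape
  phases <- rep(names(phase_offsets), length.out = n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    si <- (as.integer(seed) * 131L + i * 7919L) %% .Machine$integer.max
    w <- make_smooth_warp(shape, warp$max_disp, warp$knot_spacing, seed = si)
    vol <- apply_transform(template$volume, f = w, mode = "trilinear",
                           background = -1000)
    lab <- apply_transform(template$labels, f = w)
    off <- phase_offsets[[phases[i]]]
    if (off != 0) vol$data[lab$data > 0] <- vol$data[lab$data > 0] + off
    if (noise_sd > 0)
      vol$data <- vol$data +
        .with_seed(si + 1L, array(stats::rnorm(prod(shape), sd = noise_sd), shape))
    subjects[[i]] <- list(id = sprintf("S%02d", i), volume = vol, labels = lab,
                          gt_field = w, phase = phases[i])
  }
  list(template = template, subjects = subjects)
}

#' Generate a monotone piecewise-linear body-part score profile
#'
#' Passes through -12 at the first slice, -6 at `z_of_minus6`, +5 at
#' `z_of_plus5`, and +12 at the last slice, so that [crop_by_scores()] with
#' the default window retains exactly `z_of_minus6..z_of_plus5`.
#'
#' @param n_slices Number of axial slices.
#' @param z_of_minus6,z_of_plus5 1-based slice indices of the -6 and +5
#'   anchors, `1 <= z_of_minus6 < z_of_plus5 <= n_slices`.
#' @return A [new_slice_scores()] profile.
#' @export
make_score_profile <- function(n_slices, z_of_minus6, z_of_plus5) {
  n <- as.integer(n_slices)
  a <- as.integer(z_of_minus6); b <- as.integer(z_of_plus5)
  if (!(1L <= a && a < b && b <= n))
    stop("need 1 <= z_of_minus6 < z_of_plus5 <= n_slices")
  kx <- c(1L, a, b, n)
  ky <- c(-12, -6, 5, 12)
  # when an anchor sits on a volume end the anchor wins over the +/-12 endpoint
  keep <- rep(TRUE, 4L)
  if (a == 1L) keep[1L] <- FALSE
  if (b == n) keep[4L] <- FALSE
  s <- stats::approx(kx[keep], ky[keep], xout = seq_len(n), rule = 2)$y
  s[a] <- -6; s[b] <- 5  # anchors exact despite floating-point interpolation
  new_slice_scores(s)
}
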