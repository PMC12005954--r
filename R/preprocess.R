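#' Reorient a volume to the canonical RAS frame
#'
#' Permutes and flips the array axes so that the first axis increases to the
#' subject's Right, the second Anterior and the third Superior. The physical
#' position of every voxel is preserved (spacing, origin and orientation codes
#' are updated together). Idempotent on already-RAS volumes.
#'
#' @param v A `ct_volume` (or `ct_labelmap`).
#' @return The same type of object, in RAS orientation.
#' @export
reorient_to_ras <- function(v) {
  stopifnot(inherits(v, "ct_volume"))
  if (isTRUE(v$oblique))
    stop("volume has an oblique orientation; resample it to an axis-aligned ",
         "grid before reorienting")
  codes <- v$axis_codes
  perm <- order(.axis_of(codes))
  data <- if (all(perm == 1:3)) v$data else aperm(v$data, perm)
  spacing <- v$spacing[perm]
  codes <- codes[perm]
  origin <- v$origin
  dirs <- .axis_dirs(codes)
  for (k in 1:3) {
    if (codes[k] %in% c("L", "P", "I")) {
      n <- dim(data)[k]
      idx <- switch(k,
                    list(n:1, TRUE, TRUE),
                    list(TRUE, n:1, TRUE),
                    list(TRUE, TRUE, n:1))
      data <- do.call(`[`, c(list(data), idx, list(drop = FALSE)))
      origin <- origin + dirs[, k] * spacing[k] * (n - 1)
      codes[k] <- c(L = "R", P = "A", I = "S")[codes[k]]
    }
  }
  out <- v
  out$data <- data
  out$spacing <- spacing
  out$origin <- origin
  out$axis_codes <- codes
  out
}

#' Clamp intensities to a soft-tissue window
#'
#' Every voxel is clipped to `[lo, hi]` HU; the default window (-275 to
#' 275 HU) emphasizes abdominal soft-tissue contrast.
#'
#' @param v A `ct_volume`.
#' @param lo,hi Window bounds in HU, `lo < hi`.
#' @return The windowed volume; it remembers its window in `$window`.
#' @export
apply_soft_tissue_window <- function(v, lo = -275, hi = 275) {
  stopifnot(inherits(v, "ct_volume"))
  if (!(lo < hi)) stop("window requires lo < hi")
  out <- v
  out$data <- pmin(pmax(v$data, lo), hi)
  out$window <- c(lo, hi)
  out
}

.ball_offsets <- function(r) {
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= r^2, ]
  as.matrix(g)
}

.dilate <- function(mask, dims, offsets) {
  array(cpp_dilate(as.vector(mask), dims, offsets), dims)
}

.fill_holes <- function(mask, dims) {
  bg <- !mask
  lab <- array(cpp_components(as.vector(bg), dims), dims)
  border <- unique(c(lab[1, , ], lab[dim(lab)[1], , ],
                     lab[, 1, ], lab[, dim(lab)[2], ],
                     lab[, , 1], lab[, , dim(lab)[3]]))
  border <- setdiff(border, 0L)
  mask | (bg & !(lab %in% border))
}

#' Segment the body from a CT volume
#'
#' Produces a binary body mask: voxels above `threshold` HU are closed with a
#' ball structuring element, internal cavities are filled, and the largest
#' 6-connected 3D component is kept. Detached structures such as the CT bed
#' fall outside the mask; callers typically set voxels outside the mask to
#' -1000 HU and zero variance maps there.
#'
#' @param v A `ct_volume` in HU (before windowing).
#' @param threshold Body threshold in HU.
#' @param close_radius Radius (voxels) of the ball used for morphological
#'   closing.
#' @return A binary `ct_labelmap` (1 = body).
#' @export
mask_body <- function(v, threshold = -500, close_radius = 3) {
  stopifnot(inherits(v, "ct_volume"))
  dims <- dim(v$data)
  m <- v$data > threshold
  if (!any(m)) stop("no body found: no voxel above ", threshold, " HU")
  off <- .ball_offsets(close_radius)
  m <- !.dilate(!.dilate(m, dims, off), dims, off)   # closing
  m <- .fill_holes(m, dims)
  lab <- array(cpp_components(as.vector(m), dims), dims)
  sizes <- tabulate(lab)
  if (!length(sizes)) stop("no body found: mask empty after morphology")
  keep <- which.max(sizes)
  new_labelmap(array(as.integer(lab == keep), dims),
               spacing = v$spacing, origin = v$origin,
               axis_codes = v$axis_codes, label_names = c(`1` = "body"))
}

#' Crop axial slices by body-part score range
#'
#' Keeps the contiguous axial slices (third array axis, RAS) whose score lies
#' in `[lo, hi]`; the default window -6..+5 isolates the abdomen from a whole
#' torso scan. The origin is shifted so retained voxels keep their physical
#' coordinates. If the in-range slices are not contiguous (non-monotone score
#' profile), the longest contiguous run wins, with a warning.
#'
#' @param v A `ct_volume` or `ct_labelmap`.
#' @param s A [new_slice_scores()] profile matching `v`'s axial extent.
#' @param lo,hi Score window, `lo < hi`.
#' @return The cropped object; attribute `kept_slices` holds the retained
#'   1-based slice range for score/sidecar bookkeeping.
#' @export
crop_by_scores <- function(v, s, lo = -6, hi = 5) {
  stopifnot(inherits(v, "ct_volume"), inherits(s, "slice_scores"))
  if (!(lo < hi)) stop("score window requires lo < hi")
  nz <- dim(v$data)[3]
  if (s$n_slices != nz)
    stop("score profile has ", s$n_slices, " entries but volume has ", nz,
         " axial slices")
  inr <- s$scores >= lo & s$scores <= hi
  if (!any(inr)) stop("no axial slice has a score within [", lo, ", ", hi, "]")
  runs <- rle(inr)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hits <- which(runs$values)
  if (length(hits) > 1L) {
    warning("score profile is non-monotone; keeping the longest contiguous ",
            "in-range run")
    hits <- hits[which.max(runs$lengths[hits])]
  }
  i0 <- starts[hits]; i1 <- ends[hits]
  out <- v
  out$data <- v$data[, , i0:i1, drop = FALSE]
  dirs <- .axis_dirs(v$axis_codes)
  out$origin <- v$origin + dirs[, 3] * v$spacing[3] * (i0 - 1)
  attr(out, "kept_slices") <- c(i0, i1)
  out
}

.mode_code <- function(mode) {
  switch(mode, nearest = 0L, trilinear = 1L, bicubic = 2L,
         stop("unknown interpolation mode: ", mode))
}

#' Resample a volume onto the grid of another volume
#'
#' The output takes the target's shape, spacing and origin; values are pulled
#' from the source through world coordinates. Bicubic output is clamped to the
#' source range to suppress interpolation overshoot; nearest-neighbor output
#' never contains a value absent from the source, and is mandatory for label
#' maps.
#'
#' @param v Source `ct_volume` or `ct_labelmap`.
#' @param target A `ct_volume` defining the output grid.
#' @param mode One of `"bicubic"`, `"trilinear"`, `"nearest"`.
#' @param background Fill value for output voxels sampling outside the source;
#'   defaults to 0 for label maps and the source minimum otherwise.
#' @return The resampled object on the target grid.
#' @export
resample_to_grid <- function(v, target,
                             mode = if (inherits(v, "ct_labelmap")) "nearest" else "bicubic",
                             background = NULL) {
  stopifnot(inherits(v, "ct_volume"), inherits(target, "ct_volume"))
  if (inherits(v, "ct_labelmap") && mode != "nearest")
    stop("label maps must be resampled with mode = \"nearest\"")
  if (any(dim(target$data) < 1L)) stop("degenerate target grid")
  if (is.null(background))
    background <- if (inherits(v, "ct_labelmap")) 0 else min(v$data)
  Ds <- .axis_dirs(v$axis_codes); Dt <- .axis_dirs(target$axis_codes)
  A3 <- diag(1 / v$spacing) %*% t(Ds) %*% Dt %*% diag(target$spacing)
  t3 <- diag(1 / v$spacing) %*% t(Ds) %*% (target$origin - v$origin)
  A <- cbind(A3, t3)
  res <- cpp_warp(as.vector(v$data), dim(v$data), dim(target$data), A,
                  NULL, .mode_code(mode), background,
                  FALSE, TRUE)
  out <- v
  out$data <- array(res, dim(target$data))
  out$spacing <- target$spacing
  out$origin <- target$origin
  out$axis_codes <- target$axis_codes
  if (inherits(v, "ct_labelmap")) out$data <- array(as.integer(round(out$data)),
                                                    dim(target$data))
  out
}
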