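#' Construct a 3D CT volume
#'
#' A volume couples a 3D scalar grid (Hounsfield units, or unitless after
#' windowing) with its voxel spacing, the physical position of voxel
#' `(1,1,1)`, and an orientation triplet. The orientation codes give, for each
#' array axis, the anatomical direction along which the index increases
#' (`"R"`/`"L"`, `"A"`/`"P"`, `"S"`/`"I"`); the package's canonical frame is
#' RAS (right-anterior-superior).
#'
#' @param data 3D numeric array.
#' @param spacing Per-axis voxel size in mm (all > 0).
#' @param origin Physical coordinate (mm, RAS world frame) of voxel `(1,1,1)`.
#' @param axis_codes Character triplet, a signed permutation of the anatomical
#'   axes, e.g. `c("R","A","S")` or `c("L","P","S")`.
#' @return An object of class `ct_volume`.
#' @export
new_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       axis_codes = c("R", "A", "S")) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (any(dim(data) < 1L)) stop("every volume dimension must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values")
  .check_axis_codes(axis_codes)
  structure(list(data = data, spacing = spacing, origin = origin,
                 axis_codes = toupper(axis_codes)),
            class = "ct_volume")
}

.axis_of <- function(code) {
  match(code, c("R", "A", "S")) -> fwd
  match(code, c("L", "P", "I")) -> rev
  ifelse(is.na(fwd), rev, fwd)
}

.check_axis_codes <- function(codes) {
  codes <- toupper(codes)
  if (length(codes) != 3L || !all(codes %in% c("R", "L", "A", "P", "S", "I")))
    stop("axis_codes must be three of R/L, A/P, S/I")
  if (anyDuplicated(.axis_of(codes)))
    stop("axis_codes must cover the three anatomical axes exactly once")
  invisible(codes)
}

#' Construct an integer organ label map
#'
#' A label map shares the geometry contract of [new_volume()] but stores
#' non-negative integer organ ids (0 = background). The default naming follows
#' the 13-organ abdominal scheme in which the pancreas is label 11.
#'
#' @param data 3D array of non-negative integers.
#' @param label_names Named character vector mapping id (as name) to organ.
#' @inheritParams new_volume
#' @return An object of class `ct_labelmap` (also a `ct_volume`).
#' @export
new_labelmap <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         axis_codes = c("R", "A", "S"),
                         label_names = organ_labels()) {
  v <- new_volume(data, spacing, origin, axis_codes)
  ids <- unique(as.vector(data))
  if (any(ids < 0) || any(ids != round(ids)))
    stop("label data must be non-negative integers")
  unknown <- setdiff(ids, c(0, as.integer(names(label_names))))
  if (length(unknown))
    stop("label ids not in label_names: ", paste(unknown, collapse = ", "))
  v$label_names <- label_names
  class(v) <- c("ct_labelmap", "ct_volume")
  v
}

#' The 13-organ abdominal labeling scheme
#'
#' Ids follow the standard multi-atlas abdominal labeling convention
#' (spleen 1 ... left adrenal gland 13); the pancreas is label 11.
#'
#' @return Named character vector (names are the integer ids).
#' @export
organ_labels <- function() {
  c(`1` = "spleen", `2` = "right kidney", `3` = "left kidney",
    `4` = "gall bladder", `5` = "esophagus", `6` = "liver",
    `7` = "stomach", `8` = "aorta", `9` = "inferior vena cava",
    `10` = "portal splenic vein", `11` = "pancreas",
    `12` = "right adrenal gland", `13` = "left adrenal gland")
}

#' Id of the pancreas in the 13-organ scheme
#' @return Integer scalar, 11.
#' @export
pancreas_label <- function() 11L

#' Per-slice body-part score profile
#'
#' One dimensionless anatomical-height score per axial slice, in the
#' conventional range \[-12, +12\] (-12 upper chest, +12 pelvis), as produced
#' by body part regression models. Axial slices are the third array axis of a
#' RAS-oriented volume.
#'
#' @param scores Numeric vector, one finite score per axial slice.
#' @return An object of class `slice_scores`.
#' @export
new_slice_scores <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) < 1L || any(!is.finite(scores)))
    stop("scores must be a non-empty vector of finite values")
  structure(list(scores = scores, n_slices = length(scores)),
            class = "slice_scores")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, %s, range [%.1f, %.1f]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              paste(x$axis_codes, collapse = ""),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.ct_labelmap <- function(x, ...) {
  ids <- setdiff(sort(unique(as.vector(x$data))), 0)
  cat(sprintf("<ct_labelmap> %s voxels, labels: %s\n",
              paste(dim(x$data), collapse = "x"),
              if (length(ids)) paste(ids, collapse = ", ") else "(background only)"))
  invisible(x)
}

#' @export
print.slice_scores <- function(x, ...) {
  cat(sprintf("<slice_scores> %d slices, range [%.2f, %.2f]\n",
              x$n_slices, min(x$scores), max(x$scores)))
  invisible(x)
}

# shared geometry check used across modules
.same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol
}

# physical (world RAS) coordinate of 1-based voxel indices (n x 3 matrix)
voxel_to_world <- function(v, idx) {
  idx <- matrix(idx, ncol = 3)
  dirs <- .axis_dirs(v$axis_codes)
  t(apply(idx, 1, function(i) v$origin + dirs %*% ((i - 1) * v$spacing)))
}

# 3x3 signed permutation matrix: column k = world direction of array axis k
.axis_dirs <- function(codes) {
  m <- matrix(0, 3, 3)
  for (k in 1:3) {
    ax <- .axis_of(codes[k])
    m[ax, k] <- if (codes[k] %in% c("R", "A", "S")) 1 else -1
  }
  m
}
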