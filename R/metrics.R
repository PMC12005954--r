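#' Dice overlap between two label maps for one organ
#'
#' `2 |P n G| / (|P| + |G|)` over voxels equal to `label`. Defined as 1 when
#' both masks are empty and 0 when exactly one is.
#'
#' @param P,G `ct_labelmap`s on a common grid (prediction, ground truth).
#' @param label Organ id (default: pancreas).
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(P, G, label = pancreas_label()) {
  stopifnot(inherits(P, "ct_labelmap"), inherits(G, "ct_labelmap"))
  if (!identical(dim(P$data), dim(G$data))) stop("label maps on different grids")
  p <- P$data == label
  g <- G$data == label
  np <- sum(p); ng <- sum(g)
  if (np == 0 && ng == 0) return(1)
  if (np == 0 || ng == 0) return(0)
  2 * sum(p & g) / (np + ng)
}

#' Extract the boundary surface of a labeled organ as points
#'
#' Surface voxels are mask voxels with at least one six-connected background
#' neighbor (the volume border counts as background); their 1-based voxel
#' indices are scaled to mm by the spacing.
#'
#' @param mask A `ct_labelmap`.
#' @param label Organ id.
#' @return An object of class `surface_points` with `points` (`n x 3` mm
#'   coordinates) and `source_label`.
#' @export
extract_surface <- function(mask, label = pancreas_label()) {
  stopifnot(inherits(mask, "ct_labelmap"))
  m <- mask$data == label
  if (!any(m)) stop("mask is empty for label ", label)
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  interior <-
    pad[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    pad[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]] &
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
  bnd <- m & !interior
  idx <- which(bnd, arr.ind = TRUE)
  pts <- sweep(idx, 2, mask$spacing, `*`)
  dimnames(pts) <- NULL
  structure(list(points = pts, source_label = label), class = "surface_points")
}

#' @export
print.surface_points <- function(x, ...) {
  cat(sprintf("<surface_points> %d points (label %d)\n",
              nrow(x$points), x$source_label))
  invisible(x)
}

#' Hausdorff distance between two surface point sets
#'
#' Directed form: `max over vp of min distance to vg` (Euclidean, mm).
#' The symmetric variant takes the max of the two directed values.
#'
#' @param vp,vg `surface_points` (or bare `n x 3` matrices), both non-empty.
#' @param symmetric Return the symmetric Hausdorff distance.
#' @return Distance in mm.
#' @export
hausdorff <- function(vp, vg, symmetric = FALSE) {
  P <- if (inherits(vp, "surface_points")) vp$points else base::matrix(vp, ncol = 3)
  G <- if (inherits(vg, "surface_points")) vg$points else base::matrix(vg, ncol = 3)
  if (!nrow(P) || !nrow(G)) stop("empty surface point set")
  h <- cpp_directed_hausdorff(P, G)
  if (symmetric) h <- max(h, cpp_directed_hausdorff(G, P))
  h
}

#' Cohort quality gate on inverse-transferred pancreas labels
#'
#' Computes the pancreas Dice between each subject's inverse-transferred atlas
#' label and the subject's own label; subjects below the threshold are
#' excluded from atlas construction.
#'
#' @param cohort List of `list(id =, transferred =, reference =)` entries
#'   (inverse-transferred label map and subject label map).
#' @param threshold Minimum Dice to keep a subject.
#' @param label Organ id gated on (default: pancreas).
#' @return List with `kept` and `excluded` (ids, input order preserved) and
#'   `dice` (named per-subject scores).
#' @export
quality_gate <- function(cohort, threshold = 0.1, label = pancreas_label()) {
  ids <- vapply(cohort, function(s) as.character(s$id), character(1))
  scores <- vapply(cohort, function(s) dice(s$transferred, s$reference, label),
                   numeric(1))
  names(scores) <- ids
  list(kept = ids[scores >= threshold],
       excluded = ids[scores < threshold],
       dice = scores)
}
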