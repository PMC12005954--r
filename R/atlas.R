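#' Deviation-reciprocal patch weight
#'
#' Weight of a candidate patch against the current template patch:
#' `1 / (rms(patch - template_patch) + epsilon)`. Patches agreeing with the
#' template dominate the average, which counteracts the blurring of a plain
#' arithmetic mean.
#'
#' @param patch,template_patch Equal-shape numeric arrays.
#' @param epsilon Small positive guard against the singularity at exact
#'   equality (HU).
#' @return Strictly positive finite scalar.
#' @export
patch_weight <- function(patch, template_patch, epsilon = 0.55) {
  if (!identical(dim(patch), dim(template_patch)) &&
      length(patch) != length(template_patch))
    stop("patch shapes differ")
  1 / (sqrt(mean((patch - template_patch)^2)) + epsilon)
}

.patch_starts <- function(d, ps, stride) {
  unique(c(seq(1L, max(d - ps + 1L, 1L), by = stride), max(d - ps + 1L, 1L)))
}

#' Weighted sliding-window average of registered volumes
#'
#' Iteratively refines the template: starting from the voxelwise arithmetic
#' mean, each pass accumulates every sliding patch of every volume into the
#' template with weight [patch_weight()] against the current template, then
#' renormalizes by the accumulated weights. Boundary patches are clamped to
#' lie fully inside the grid, so every voxel is covered.
#'
#' @param volumes Non-empty list of `ct_volume`s on a common grid.
#' @param patch_size Patch edge length in voxels (clamped to the grid).
#' @param overlap Fractional per-axis patch overlap in \[0, 1); the stride is
#'   `patch_size * (1 - overlap)`.
#' @param n_iter Number of reweighting passes.
#' @param epsilon Weight guard in HU (see [patch_weight()]).
#' @param uniform_weights Force all patch weights to 1, reducing the result to
#'   the voxelwise arithmetic mean (used for validation).
#' @param sweep `"aggregate"` (default) accumulates every volume against the
#'   same template within a pass, so the result is independent of subject
#'   order; `"sequential"` renormalizes the template after each volume
#'   (a running template).
#' @return List with `average` (a `ct_volume`) and `weight_sum` (array of
#'   accumulated weights from the final pass).
#' @export
weighted_sliding_average <- function(volumes, patch_size = 96L, overlap = 0.75,
                                     n_iter = 2L, epsilon = 0.55,
                                     uniform_weights = FALSE,
                                     sweep = c("aggregate", "sequential")) {
  sweep <- match.arg(sweep)
  if (!length(volumes)) stop("need at least one volume")
  stopifnot(all(vapply(volumes, inherits, logical(1), "ct_volume")))
  dims <- dim(volumes[[1]]$data)
  if (!all(vapply(volumes, function(v) identical(dim(v$data), dims), logical(1))))
    stop("all volumes must share the fixed atlas grid")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  ps <- pmin(as.integer(patch_size), dims)
  stride <- pmax(1L, as.integer(round(ps * (1 - overlap))))
  starts <- lapply(1:3, function(k) .patch_starts(dims[k], ps[k], stride[k]))
  arrs <- lapply(volumes, function(v) v$data)
  mu <- Reduce(`+`, arrs) / length(arrs)
  wsum <- NULL
  for (it in seq_len(n_iter)) {
    acc <- array(0, dims)
    wacc <- array(0, dims)
    for (x in arrs) {
      for (s3 in starts[[3]]) for (s2 in starts[[2]]) for (s1 in starts[[1]]) {
        r1 <- s1:(s1 + ps[1] - 1L)
        r2 <- s2:(s2 + ps[2] - 1L)
        r3 <- s3:(s3 + ps[3] - 1L)
        xp <- x[r1, r2, r3]
        w <- if (uniform_weights) 1 else patch_weight(xp, mu[r1, r2, r3], epsilon)
        acc[r1, r2, r3] <- acc[r1, r2, r3] + w * xp
        wacc[r1, r2, r3] <- wacc[r1, r2, r3] + w
      }
      if (sweep == "sequential") mu <- acc / pmax(wacc, .Machine$double.eps)
    }
    mu <- acc / wacc
    wsum <- wacc
  }
  out <- volumes[[1]]
  out$data <- mu
  list(average = out, weight_sum = wsum)
}

#' Per-voxel variance between registered subjects and the average template
#'
#' Mean squared deviation from the average (denominator `N`), set to zero
#' outside the body mask.
#'
#' @param volumes Non-empty list of `ct_volume`s on the template grid.
#' @param average The average template `ct_volume`.
#' @param body Optional binary body `ct_labelmap`; voxels outside it are
#'   zeroed.
#' @return A `ct_volume` of variances (intensity squared).
#' @export
variance_map <- function(volumes, average, body = NULL) {
  if (!length(volumes)) stop("need at least one volume")
  dims <- dim(average$data)
  if (!all(vapply(volumes, function(v) identical(dim(v$data), dims), logical(1))))
    stop("volumes and average must share a common grid")
  v <- Reduce(`+`, lapply(volumes, function(x) (x$data - average$data)^2)) /
    length(volumes)
  if (!is.null(body)) {
    if (!identical(dim(body$data), dims)) stop("body mask grid mismatch")
    v[body$data == 0] <- 0
  }
  out <- average
  out$data <- v
  out
}

#' Majority-vote fusion of registered label maps
#'
#' Per voxel, the most frequent label wins; ties break toward background (0),
#' then toward the lowest label id.
#'
#' @param labels Non-empty list of `ct_labelmap`s on a common grid with a
#'   shared labeling scheme.
#' @return The fused `ct_labelmap`.
#' @export
majority_vote <- function(labels) {
  if (!length(labels)) stop("need at least one label map")
  stopifnot(all(vapply(labels, inherits, logical(1), "ct_labelmap")))
  dims <- dim(labels[[1]]$data)
  if (!all(vapply(labels, function(v) identical(dim(v$data), dims), logical(1))))
    stop("all label maps must share a common grid")
  ids <- sort(unique(unlist(lapply(labels, function(l) unique(as.vector(l$data))))))
  ids <- c(0L, setdiff(ids, 0L))  # background first for the tie-break
  best_count <- Reduce(`+`, lapply(labels, function(l) l$data == ids[1]))
  fused <- array(ids[1], dims)
  for (id in ids[-1]) {
    cnt <- Reduce(`+`, lapply(labels, function(l) l$data == id))
    take <- cnt > best_count
    fused[take] <- id
    best_count[take] <- cnt[take]
  }
  out <- labels[[1]]
  out$data <- array(as.integer(fused), dims)
  out
}

#' Atlas construction configuration
#'
#' @param patch_size Sliding-window patch edge length (voxels).
#' @param overlap Fractional per-axis patch overlap.
#' @param n_iter Reweighting passes of [weighted_sliding_average()].
#' @param epsilon Patch-weight guard (HU).
#' @return A list of class `atlas_config`.
#' @export
atlas_config <- function(patch_size = 96L, overlap = 0.75, n_iter = 2L,
                         epsilon = 0.55) {
  structure(list(patch_size = as.integer(patch_size), overlap = overlap,
                 n_iter = as.integer(n_iter), epsilon = epsilon),
            class = "atlas_config")
}

#' Build a single-phase atlas bundle
#'
#' Runs the weighted sliding-window average, the variance map and
#' majority-vote label fusion over a registered, quality-gated cohort.
#'
#' @param registered Non-empty list of `list(volume =, labels =)` pairs on the
#'   template grid.
#' @param phase Contrast-phase tag (`"non-contrast"`, `"arterial"`,
#'   `"portal venous"`, `"delayed"`, or any label).
#' @param cfg An [atlas_config()].
#' @param body Optional binary body mask for variance zeroing.
#' @return An object of class `atlas_bundle` with elements `average`,
#'   `variance`, `fused_label`, `weight_sum`, `n_subjects`, `phase`.
#' @export
build_phase_atlas <- function(registered, phase = "portal venous",
                              cfg = atlas_config(), body = NULL) {
  if (!length(registered)) stop("empty cohort")
  vols <- lapply(registered, `[[`, "volume")
  labs <- lapply(registered, `[[`, "labels")
  if (any(vapply(vols, is.null, logical(1))) ||
      any(vapply(labs, is.null, logical(1))))
    stop("each registered subject needs a volume and a labels entry")
  avg <- weighted_sliding_average(vols, cfg$patch_size, cfg$overlap,
                                  cfg$n_iter, cfg$epsilon)
  varm <- variance_map(vols, avg$average, body)
  fused <- majority_vote(labs)
  structure(list(average = avg$average, variance = varm, fused_label = fused,
                 weight_sum = avg$weight_sum, n_subjects = length(registered),
                 phase = phase, config = cfg),
            class = "atlas_bundle")
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf("<atlas_bundle> phase \"%s\", %d subject(s), %s voxels\n",
              x$phase, x$n_subjects, paste(dim(x$average$data), collapse = "x")))
  invisible(x)
}

#' Write an atlas bundle to a directory
#'
#' Emits `average.nii.gz`, `variance.nii.gz`, `fused_label.nii.gz` and a JSON
#' sidecar with the phase, subject count and patch configuration.
#'
#' @param bundle An `atlas_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_atlas_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(bundle$average, file.path(dir, "average.nii.gz"))
  write_volume(bundle$variance, file.path(dir, "variance.nii.gz"))
  write_volume(bundle$fused_label, file.path(dir, "fused_label.nii.gz"))
  meta <- list(phase = bundle$phase, n_subjects = bundle$n_subjects,
               patch_size = bundle$config$patch_size,
               overlap = bundle$config$overlap,
               n_iter = bundle$config$n_iter,
               epsilon = bundle$config$epsilon)
  jsonlite::write_json(meta, file.path(dir, "atlas.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
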