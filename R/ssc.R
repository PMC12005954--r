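#' Self-similarity context descriptor configuration
#'
#' The descriptor compares patches in a voxel's neighborhood with each other
#' rather than across images, which makes it robust to noise and artifacts.
#' The default neighborhood is the six face neighbors at center distance
#' `2 * patch_radius + 1`, and the twelve descriptor entries are the patch
#' distances between every non-opposite (orthogonal) pair of neighbors.
#'
#' @param patch_radius Cubic patch radius in voxels (1 gives 3^3 patches).
#' @param bits Quantization depth per descriptor entry for Hamming comparison.
#' @param offsets 6 x 3 integer matrix of neighborhood offsets (one per row),
#'   symmetric about the origin.
#' @param pairs 12 x 2 integer matrix indexing rows of `offsets`.
#' @return An object of class `ssc_config`.
#' @export
ssc_config <- function(patch_radius = 1L, bits = 4L,
                       offsets = NULL, pairs = NULL) {
  d <- 2L * patch_radius + 1L
  if (is.null(offsets))
    offsets <- rbind(c(d, 0, 0), c(-d, 0, 0), c(0, d, 0),
                     c(0, -d, 0), c(0, 0, d), c(0, 0, -d))
  offsets <- matrix(as.integer(offsets), ncol = 3)
  if (nrow(offsets) != 6L) stop("exactly six neighborhood offsets are required")
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  if (!setequal(key(offsets), key(-offsets)))
    stop("offsets must be symmetric about the origin")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(6L, 2L))
    opposite <- apply(pairs, 1, function(p)
      all(offsets[p[1], ] == -offsets[p[2], ]))
    pairs <- pairs[!opposite, , drop = FALSE]
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) != 12L) stop("exactly twelve offset pairs are required")
  structure(list(patch_radius = as.integer(patch_radius),
                 bits = as.integer(bits), offsets = offsets, pairs = pairs),
            class = "ssc_config")
}

#' Sum of squared differences between two image patches
#'
#' Distance between the cubic patches of radius `r` centred at the 1-based
#' voxel coordinates `px` and `py` (replicate-padded at the volume edge).
#' Symmetric in its two arguments.
#'
#' @param v A `ct_volume`.
#' @param px,py 1-based voxel coordinates (length-3 integer vectors).
#' @param r Patch radius in voxels.
#' @return Non-negative scalar SSD.
#' @export
patch_ssd <- function(v, px, py, r = 1L) {
  stopifnot(inherits(v, "ct_volume"))
  cpp_patch_ssd(as.vector(v$data), dim(v$data),
                as.integer(px) - 1L, as.integer(py) - 1L, as.integer(r))
}

#' Compute self-similarity context descriptors
#'
#' For every voxel, the twelve neighborhood patch distances `S` are converted
#' to similarities `exp(-S / q^2)` in (0, 1], where `q^2` — the local noise
#' estimate — is the mean of the six face-neighbor patch SSDs at that voxel,
#' floored at `1e-6` of the global intensity variance. Entries are quantized
#' to `2^bits` uniform bins of (0, 1] and packed into one code per voxel for
#' fast Hamming comparison.
#'
#' @param v A preprocessed (windowed) `ct_volume`.
#' @param cfg An [ssc_config()].
#' @param return_cont Also return the continuous 12-entry descriptors
#'   (memory-heavy; mainly for inspection and testing).
#' @return An object of class `ssc_field` with elements `packed` (3D array of
#'   packed codes), `noise_scale` (3D array of `q^2`), `dims`, `total_bits`,
#'   `source` (the intensity array), and optionally `values` (12 x nvox).
#' @export
compute_ssc <- function(v, cfg = ssc_config(), return_cont = FALSE) {
  stopifnot(inherits(v, "ct_volume"), inherits(cfg, "ssc_config"))
  dims <- dim(v$data)
  gvar <- stats::var(as.vector(v$data))
  qfloor <- max(1e-6 * gvar, 1e-12)
  res <- cpp_compute_ssc(as.vector(v$data), dims, cfg$offsets, cfg$pairs,
                         cfg$patch_radius, cfg$bits, qfloor, return_cont)
  out <- list(packed = array(res$packed, dims),
              noise_scale = array(res$qsq, dims),
              dims = dims,
              total_bits = cfg$bits * nrow(cfg$pairs),
              config = cfg,
              source = v$data)
  if (return_cont) out$values <- res$cont
  structure(out, class = "ssc_field")
}

#' @export
print.ssc_field <- function(x, ...) {
  cat(sprintf("<ssc_field> %s voxels, %d-bit packed codes\n",
              paste(x$dims, collapse = "x"), x$total_bits))
  invisible(x)
}

#' Normalized Hamming distance between two descriptor fields
#'
#' Compares the quantized descriptor of `a` at voxel `at` with that of `b` at
#' `at + displacement` (replicate-clamped at the edge), normalized to
#' \[0, 1\] by the code length.
#'
#' @param a,b `ssc_field` objects on grids of equal size.
#' @param at 1-based voxel coordinate in `a`.
#' @param displacement Integer 3-vector added to `at` to index `b`.
#' @return Scalar in \[0, 1\].
#' @export
hamming_distance <- function(a, b, at, displacement = c(0L, 0L, 0L)) {
  stopifnot(inherits(a, "ssc_field"), inherits(b, "ssc_field"))
  if (!identical(a$dims, b$dims)) stop("descriptor fields have different shapes")
  if (a$total_bits != b$total_bits) stop("descriptor fields have different bit depth")
  cpp_hamming_at(as.vector(a$packed), as.vector(b$packed), a$dims,
                 as.integer(at) - 1L, as.integer(displacement), a$total_bits)
}
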