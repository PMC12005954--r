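#' Read a 3D volume from a NIfTI-1 file
#'
#' Decodes spacing, origin and orientation codes from the stronger of the
#' sform/qform transforms. A 4D image whose trailing axes all have length 1 is
#' squeezed to 3D with a warning; any other non-3D shape is an error. Intensity
#' values are passed through unmodified.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [new_volume()] object. If the stored transform is oblique (not
#'   aligned with the anatomical axes) the returned volume carries
#'   `oblique = TRUE` and cannot be reoriented without prior resampling.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) {
    if (all(d[-(1:3)] == 1L)) {
      warning("squeezing ", length(d), "D image with singleton trailing axes to 3D")
      d <- d[1:3]
    } else {
      stop("expected a 3D image, got dimensions ", paste(d, collapse = "x"))
    }
  }
  if (length(d) != 3L)
    stop("expected a 3D image, got dimensions ", paste(d, collapse = "x"))
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop("invalid voxel spacing in NIfTI header of ", path)
  dirs <- sweep(rot, 2, spacing, "/")
  oblique <- any(apply(abs(dirs), 2, function(col) sum(col > 1e-3)) > 1L)
  codes <- strsplit(RNifti::orientation(img), "")[[1]]
  v <- new_volume(array(as.numeric(img), dim = d), spacing = spacing,
                  origin = xf[1:3, 4], axis_codes = codes)
  v$oblique <- oblique
  v
}

#' Read an integer label map from a NIfTI-1 file
#'
#' @inheritParams read_volume
#' @param label_names Named character vector mapping ids to organ names.
#' @return A [new_labelmap()] object.
#' @export
read_labelmap <- function(path, label_names = organ_labels()) {
  v <- read_volume(path)
  new_labelmap(round(v$data), spacing = v$spacing, origin = v$origin,
               axis_codes = v$axis_codes, label_names = label_names)
}

#' Write a volume or label map to a NIfTI-1 file
#'
#' @param v A `ct_volume` or `ct_labelmap`.
#' @param path Output path; `.nii.gz` compresses.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "ct_volume"))
  img <- RNifti::asNifti(v$data)
  RNifti::`pixdim<-`(img, v$spacing) -> img
  xf <- rbind(cbind(.axis_dirs(v$axis_codes) %*% diag(v$spacing), v$origin),
              c(0, 0, 0, 1))
  RNifti::`sform<-`(img, structure(xf, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(xf, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a per-slice score file
#'
#' Plain text, one score per line, first axial slice first.
#'
#' @param path Path to the score file.
#' @return A [new_slice_scores()] object.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("cannot read score file: ", path)
  new_slice_scores(scan(path, what = numeric(), quiet = TRUE))
}

#' Write a per-slice score file
#' @param s A `slice_scores` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(s, path) {
  stopifnot(inherits(s, "slice_scores"))
  writeLines(format(s$scores, digits = 10, trim = TRUE), path)
  invisible(path)
}
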