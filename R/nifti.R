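#' Read and write NIfTI volumes
#'
#' Thin wrappers around RNifti that carry the package's
#' [image_volume()] / [time_series_image()] types across NIfTI-1 files.
#' The voxel-to-world affine is stored in the sform (code 2); for 4-D
#' series the repetition time is stored in, and recovered from, the
#' time-axis spacing field (`pixdim[4]` in NIfTI terms).
#'
#' @param volume an [image_volume()] or [time_series_image()].
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_volume()` returns an [image_volume()] or, when the file
#'   holds a 4-D series, a [time_series_image()]; `write_volume()` returns
#'   `path` invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$data)
  is4d <- inherits(volume, "time_series_image")
  sp <- voxel_spacing(volume$affine)
  nd <- length(d)
  dimfield <- c(nd, d, rep(1L, 7L - nd))
  pixfield <- c(1, sp, if (is4d) volume$tr else 1, rep(1, 3))[1:8]
  hdr <- RNifti::niftiHeader(list(
    dim = dimfield, pixdim = pixfield,
    srow_x = volume$affine[1, ], srow_y = volume$affine[2, ],
    srow_z = volume$affine[3, ],
    sform_code = 2L, qform_code = 0L,
    xyzt_units = 10L))  # mm + seconds
  img <- RNifti::asNifti(volume$data, reference = hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param space frame label to attach to the returned volume.
#' @export
read_volume <- function(path, space = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           path, " (", conditionMessage(e), ")",
                                           call. = FALSE))
  arr <- as.array(img)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = dim(affine))
  nd <- length(dim(arr))
  if (nd == 3L) {
    image_volume(arr, affine, space)
  } else if (nd == 4L) {
    tr <- RNifti::niftiHeader(img)$pixdim[5]
    if (!is.finite(tr) || tr <= 0)
      stop("4-D NIfTI without a positive time-axis spacing: ", path)
    time_series_image(arr, affine, tr = tr, space = space)
  } else {
    stop("unsupported NIfTI dimensionality (", nd, "-D): ", path)
  }
}
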