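#' Read a NIfTI volume
#'
#' Only axis-aligned images (diagonal affine with positive spacings, within
#' a 1e-3 tolerance) are supported; oblique or axis-permuted orientations
#' raise an explicit error rather than being silently reinterpreted.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return an [ImageVolume-class].
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  rot <- aff[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-3) || any(diag(rot) <= 0))
    stop("unsupported orientation: only axis-aligned NIfTI volumes with ",
         "positive diagonal affine are supported")
  arr <- as.array(img)
  attributes(arr) <- list(dim = unname(dim(arr)))    # plain base array
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(arr)), " dims")
  storage.mode(arr) <- "double"
  imageVolume(arr, gridDescriptor(dim(arr), diag(rot), aff[1:3, 4]))
}

#' Write a volume as NIfTI (float64, axis-aligned affine)
#'
#' @param vol an [ImageVolume-class] (or a logical mask array plus `grid`).
#' @param path destination `.nii` or `.nii.gz` path.
#' @param grid used when `vol` is a raw array.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path, grid = NULL) {
  if (!is(vol, "ImageVolume")) vol <- imageVolume(vol + 0, grid)
  img <- RNifti::asNifti(vol@voxels)
  RNifti::pixdim(img) <- vol@grid@spacing
  aff <- diag(c(vol@grid@spacing, 1))
  aff[1:3, 4] <- vol@grid@origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a displacement field stored as 4D NIfTI (3 components, mm)
#' @param path a NIfTI file with a trailing component dimension of 3.
#' @return a [DisplacementField-class].
#' @export
readField <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = unname(dim(arr)))
  d <- dim(arr)
  if (length(d) == 5L) arr <- array(arr, c(d[1:3], d[5]))  # NIfTI vector conv
  d <- dim(arr)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4D displacement field with 3 components")
  aff <- unclass(RNifti::xform(img))
  grid <- gridDescriptor(d[1:3], diag(aff[1:3, 1:3]), aff[1:3, 4])
  displacementField(arr, grid)
}

#' Write a displacement field as 4D NIfTI
#' @param field a [DisplacementField-class].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeField <- function(field, path) {
  img <- RNifti::asNifti(field@vectors)
  RNifti::pixdim(img) <- c(field@grid@spacing, 1)
  aff <- diag(c(field@grid@spacing, 1))
  aff[1:3, 4] <- field@grid@origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
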