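# Warping daily-frame data back onto the planning grid through a
# displacement field in the pull-back convention: the warped value at
# planning voxel p is the daily value at world point p + u(p).

# Continuous voxel coordinates (in the daily grid) of every planning voxel
# mapped through the field.
#' @noRd
mappedVoxelCoords <- function(field, dailyGrid) {
  g <- field@grid
  ax <- latticeAxes(g)
  v <- field@vectors
  wx <- ax$x * g@spacing[1] + g@origin[1] + as.vector(v[, , , 1])
  wy <- ax$y * g@spacing[2] + g@origin[2] + as.vector(v[, , , 2])
  wz <- ax$z * g@spacing[3] + g@origin[3] + as.vector(v[, , , 3])
  list(
    cx = (wx - dailyGrid@origin[1]) / dailyGrid@spacing[1],
    cy = (wy - dailyGrid@origin[2]) / dailyGrid@spacing[2],
    cz = (wz - dailyGrid@origin[3]) / dailyGrid@spacing[3]
  )
}

#' Warp a daily image onto the planning grid
#'
#' Trilinear interpolation of the daily image at the field-mapped planning
#' voxel centers.
#'
#' @param field a [DisplacementField-class] on the planning grid.
#' @param image an [ImageVolume-class] on the daily grid.
#' @return an [ImageVolume-class] on the planning grid.
#' @export
warpImage <- function(field, image) {
  cc <- mappedVoxelCoords(field, image@grid)
  vals <- cpp_sample_trilinear(image@voxels, image@grid@shape,
                               cc$cx, cc$cy, cc$cz, 0)
  imageVolume(array(vals, field@grid@shape), field@grid)
}

#' Warp a daily binary mask onto the planning grid
#'
#' The mask is interpolated linearly as a 0/1 field and thresholded at 0.5,
#' so pure integer-voxel translations are reproduced exactly.
#'
#' @param field a [DisplacementField-class] on the planning grid.
#' @param mask logical 3D array on the daily grid, or an [ImageVolume-class].
#' @param dailyGrid the daily [GridDescriptor-class]; defaults to the field
#'   grid (shared-lattice phantoms) or the mask's own grid.
#' @return logical 3D array on the planning grid.
#' @export
warpMask <- function(field, mask, dailyGrid = NULL) {
  if (is(mask, "ImageVolume")) {
    if (is.null(dailyGrid)) dailyGrid <- mask@grid
    mask <- mask@voxels
  }
  if (is.null(dailyGrid)) dailyGrid <- field@grid
  cc <- mappedVoxelCoords(field, dailyGrid)
  vals <- cpp_sample_trilinear(mask + 0, dailyGrid@shape,
                               cc$cx, cc$cy, cc$cz, 0)
  array(vals >= 0.5, field@grid@shape)
}

#' Warp a whole structure set onto the planning grid
#'
#' @param field a [DisplacementField-class].
#' @param structures a [StructureSet-class] on the daily grid.
#' @return a [StructureSet-class] on the planning grid.
#' @export
warpStructureSet <- function(field, structures) {
  masks <- lapply(structures@masks, function(m)
    warpMask(field, m, dailyGrid = structures@grid))
  structureSet(masks, field@grid)
}
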