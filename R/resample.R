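# Sampling and resampling. All interpolation funnels through the trilinear /
# nearest kernels in src/; out-of-support points take the fill value (0).

#' Sample a volume at world points
#'
#' @param vol an [ImageVolume-class].
#' @param world n x 3 matrix of world coordinates (mm).
#' @param mode `"linear"` (trilinear) or `"nearest"`.
#' @param fill value for points outside the volume support.
#' @return numeric vector of sampled values.
#' @export
sampleVolume <- function(vol, world, mode = c("linear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  vc <- voxelCoords(vol@grid, world)
  samp <- if (mode == "linear") cpp_sample_trilinear else cpp_sample_nearest
  samp(vol@voxels, vol@grid@shape, vc[, 1], vc[, 2], vc[, 3], fill)
}

#' Resample a volume onto another grid
#'
#' Values are interpolated at the target voxel centers; target voxels
#' outside the source support are set to 0.
#'
#' @param vol an [ImageVolume-class].
#' @param grid target [GridDescriptor-class].
#' @param mode `"linear"` or `"nearest"`.
#' @return an [ImageVolume-class] on `grid`.
#' @export
resampleToGrid <- function(vol, grid, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  ax <- latticeAxes(grid)
  sg <- vol@grid
  cx <- (ax$x * grid@spacing[1] + grid@origin[1] - sg@origin[1]) / sg@spacing[1]
  cy <- (ax$y * grid@spacing[2] + grid@origin[2] - sg@origin[2]) / sg@spacing[2]
  cz <- (ax$z * grid@spacing[3] + grid@origin[3] - sg@origin[3]) / sg@spacing[3]
  samp <- if (mode == "linear") cpp_sample_trilinear else cpp_sample_nearest
  vals <- samp(vol@voxels, sg@shape, cx, cy, cz, 0)
  imageVolume(array(vals, grid@shape), grid)
}

# Sample a raw array (on `grid`) at mapped world coordinates given per-axis
# continuous voxel coordinate vectors; shared by the warp operations.
#' @noRd
sampleArrayAt <- function(arr, grid, cx, cy, cz, mode = "linear", fill = 0) {
  samp <- if (mode == "linear") cpp_sample_trilinear else cpp_sample_nearest
  samp(arr, grid@shape, cx, cy, cz, fill)
}
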