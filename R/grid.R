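#' Construct a grid descriptor
#'
#' @param shape integer(3): voxels per axis (x = RL, y = AP, z = SI).
#' @param spacing numeric(3) or scalar: voxel size in mm.
#' @param origin numeric(3): world coordinate (mm) of the center of voxel
#'   (0, 0, 0). Default places the grid symmetrically about the world origin.
#' @return a [GridDescriptor-class].
#' @examples
#' g <- gridDescriptor(c(64, 64, 64), 1.5)
#' worldCoords(g, cbind(1, 1, 1))
#' @export
gridDescriptor <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(origin)) origin <- -(shape - 1L) * spacing / 2
  new("GridDescriptor", shape = shape, spacing = spacing,
      origin = as.numeric(origin))
}

#' Construct an image volume
#'
#' @param voxels a 3D numeric array.
#' @param grid a [GridDescriptor-class]; alternatively supply `spacing` and
#'   `origin`.
#' @param spacing,origin used when `grid` is missing.
#' @return an [ImageVolume-class].
#' @export
imageVolume <- function(voxels, grid = NULL, spacing = NULL, origin = NULL) {
  if (is.null(grid)) grid <- gridDescriptor(dim(voxels), spacing, origin)
  storage.mode(voxels) <- "double"
  new("ImageVolume", voxels = voxels, grid = grid)
}

#' Construct a structure set
#'
#' @param masks named list of logical 3D arrays.
#' @param grid shared [GridDescriptor-class].
#' @return a [StructureSet-class].
#' @export
structureSet <- function(masks, grid) {
  masks <- lapply(masks, function(m) { storage.mode(m) <- "logical"; m })
  new("StructureSet", masks = masks, grid = grid)
}

#' Construct a displacement field
#'
#' @param vectors 4D array `[nx, ny, nz, 3]` of displacements in mm
#'   (planning point p maps to daily point p + u(p)).
#' @param grid planning [GridDescriptor-class].
#' @return a [DisplacementField-class].
#' @export
displacementField <- function(vectors, grid) {
  storage.mode(vectors) <- "double"
  new("DisplacementField", vectors = vectors, grid = grid)
}

#' An all-zero (identity) displacement field on a grid
#' @param grid a [GridDescriptor-class].
#' @return a [DisplacementField-class] of zero vectors.
#' @export
identityField <- function(grid) {
  displacementField(array(0, c(grid@shape, 3L)), grid)
}

#' World coordinates of voxel indices
#'
#' @param grid a [GridDescriptor-class].
#' @param index numeric matrix (n x 3) of 0-based voxel indices (may be
#'   fractional).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
worldCoords <- function(grid, index) {
  index <- rbind(index)
  sweep(sweep(index, 2, grid@spacing, `*`), 2, grid@origin, `+`)
}

#' Continuous 0-based voxel indices of world coordinates
#'
#' @param grid a [GridDescriptor-class].
#' @param world numeric matrix (n x 3) of world coordinates in mm.
#' @return n x 3 matrix of fractional voxel indices.
#' @export
voxelCoords <- function(grid, world) {
  world <- rbind(world)
  sweep(sweep(world, 2, grid@origin, `-`), 2, grid@spacing, `/`)
}

#' Voxel volume of a grid in cc
#' @param grid a [GridDescriptor-class] (or object with a grid).
#' @return scalar, cm^3 per voxel.
#' @export
voxelVolumeCc <- function(grid) {
  if (is(grid, "ImageVolume") || is(grid, "StructureSet")) grid <- grid@grid
  prod(grid@spacing) / 1000
}

#' @noRd
sameGrid <- function(a, b, tol = 1e-6) {
  identical(a@shape, b@shape) &&
    all(abs(a@spacing - b@spacing) < tol) &&
    all(abs(a@origin - b@origin) < tol)
}

# Expanded 0-based index triples for all voxels of a grid (n x 3 matrix).
#' @noRd
allVoxelIndices <- function(grid) {
  s <- grid@shape
  cbind(
    rep.int(seq_len(s[1]) - 1L, times = s[2] * s[3]),
    rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), times = s[3]),
    rep(seq_len(s[3]) - 1L, each = s[1] * s[2])
  )
}

# Per-axis 0-based index vectors recycled to the full column-major lattice,
# returned lazily as three vectors to avoid one big cbind when possible.
#' @noRd
latticeAxes <- function(grid) {
  s <- grid@shape
  list(
    x = rep.int(seq_len(s[1]) - 1, times = s[2] * s[3]),
    y = rep.int(rep(seq_len(s[2]) - 1, each = s[1]), times = s[3]),
    z = rep(seq_len(s[3]) - 1, each = s[1] * s[2])
  )
}
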