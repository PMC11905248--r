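# Rigid stage: alignment restricted to the PTV-focused box, maximizing
# normalized cross-correlation via a deterministic multi-start search
# (coarse translation grid, then simplex refinement of all 6 parameters).

#' Build the PTV-focused registration box
#'
#' Bounding box of the target mask expanded by the focus margins — 30 mm in
#' the right-left and anterior-posterior directions and 20 mm
#' superior-inferior — and clipped to the image extent.
#'
#' @param ptvMask logical 3D array (PTV_eval), nonempty.
#' @param grid the [GridDescriptor-class] the mask lives on.
#' @param marginsMm numeric(3): RL/AP/SI margins in mm (defaults 30/30/20).
#' @return a [FocusBox-class].
#' @export
makeFocusBox <- function(ptvMask, grid, marginsMm = c(30, 30, 20)) {
  if (is(ptvMask, "ImageVolume")) ptvMask <- ptvMask@voxels >= 0.5
  if (!any(ptvMask)) stop("cannot build a focus box from an empty mask")
  idx <- which(ptvMask, arr.ind = TRUE) - 1L
  lo_w <- grid@origin + apply(idx, 2, min) * grid@spacing - marginsMm
  hi_w <- grid@origin + apply(idx, 2, max) * grid@spacing + marginsMm
  glo <- grid@origin
  ghi <- grid@origin + (grid@shape - 1L) * grid@spacing
  new("FocusBox", lower = as.numeric(pmax(lo_w, glo)),
      upper = as.numeric(pmin(hi_w, ghi)))
}

#' Construct a rigid transform
#' @param angles Euler angles (radians), rotation Rz(a3) Ry(a2) Rx(a1).
#' @param translation translation in mm.
#' @param center rotation center in mm.
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  new("RigidTransform", angles = as.numeric(angles),
      translation = as.numeric(translation), center = as.numeric(center))
}

#' @noRd
.rotationMatrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

#' Apply a rigid transform to points
#' @param transform a [RigidTransform-class].
#' @param pts n x 3 matrix of world points (mm).
#' @return n x 3 matrix of mapped points.
#' @export
transformPoints <- function(transform, pts) {
  R <- .rotationMatrix(transform@angles)
  ctr <- transform@center
  sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr + transform@translation, `+`)
}

#' Invert a rigid transform
#' @param transform a [RigidTransform-class].
#' @return the inverse mapping as a new [RigidTransform-class]-like closure
#'   result: an object such that composing point mappings yields identity.
#' @export
invertRigid <- function(transform) {
  R <- .rotationMatrix(transform@angles)
  # y = R (x - c) + c + t  =>  x = R' (y - c - t) + c
  # expressed in the same (center, translation) parameterization:
  # x = R' (y - c) + c + [R'(-t)] with angles of R'
  a <- transform@angles
  # ZYX inverse of Rz Ry Rx is Rx(-a1) Ry(-a2) Rz(-a3): recover Euler angles
  Ri <- t(R)
  ang <- c(atan2(Ri[3, 2], Ri[3, 3]), -asin(Ri[3, 1]), atan2(Ri[2, 1], Ri[1, 1]))
  new("RigidTransform", angles = ang,
      translation = as.numeric(-Ri %*% transform@translation),
      center = transform@center)
}

# Fixed-image sample positions inside the box (stride-subsampled world
# coordinates + values), shared by the metric evaluations.
#' @noRd
.boxSamples <- function(vol, box, stride = 1L) {
  g <- vol@grid
  rng <- lapply(1:3, function(ax) {
    lo <- max(0L, ceiling((box@lower[ax] - g@origin[ax]) / g@spacing[ax]))
    hi <- min(g@shape[ax] - 1L, floor((box@upper[ax] - g@origin[ax]) /
                                        g@spacing[ax]))
    if (hi < lo) stop("focus box does not intersect the image grid")
    seq.int(lo, hi, by = stride)
  })
  idx <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  world <- worldCoords(g, idx)
  vals <- vol@voxels[idx + 1L]
  list(world = world, values = vals)
}

#' Rigid registration inside the focus box
#'
#' Finds the rigid transform mapping fixed-frame (planning) points into the
#' moving (daily) frame that maximizes the normalized cross-correlation of
#' the moving image, sampled at the transformed points, with the fixed
#' image inside the box. Deterministic multi-start: a coarse translation
#' grid search followed by Nelder-Mead refinement of all six parameters
#' around the best start.
#'
#' @param fixed,moving [ImageVolume-class] images.
#' @param box a [FocusBox-class] (from [makeFocusBox()]).
#' @param maxIterations simplex iteration budget.
#' @param strideVox fixed-image subsampling stride inside the box.
#' @param startRangeMm coarse translation-search half-range (mm).
#' @param startStepMm coarse translation-search step (mm).
#' @return a [RigidTransform-class] with attribute `metric` (final NCC).
#' @export
registerRigid <- function(fixed, moving, box, maxIterations = 400L,
                          strideVox = 2L, startRangeMm = 8,
                          startStepMm = 4) {
  fs <- .boxSamples(fixed, box, stride = strideVox)
  if (stats::sd(fs$values) == 0)
    stop("degenerate fixed image inside the focus box (constant intensity)")
  ctr <- colMeans(fs$world)
  mg <- moving@grid

  ncc <- function(par) {
    tr <- new("RigidTransform", angles = par[1:3], translation = par[4:6],
              center = ctr)
    pts <- transformPoints(tr, fs$world)
    vc <- voxelCoords(mg, pts)
    mv <- cpp_sample_trilinear(moving@voxels, mg@shape,
                               vc[, 1], vc[, 2], vc[, 3], NA_real_)
    ok <- !is.na(mv)
    if (sum(ok) < 10 || stats::sd(mv[ok]) == 0) return(NA_real_)
    stats::cor(fs$values[ok], mv[ok])
  }

  steps <- seq(-startRangeMm, startRangeMm, by = startStepMm)
  starts <- as.matrix(expand.grid(tx = steps, ty = steps, tz = steps))
  metrics <- apply(starts, 1, function(t) ncc(c(0, 0, 0, t)))
  if (all(is.na(metrics)))
    stop("registration metric is non-finite: no overlap inside the box")
  best <- starts[which.max(metrics), ]

  obj <- function(par) {
    v <- ncc(par)
    if (is.na(v)) 2 else -v
  }
  fit <- stats::optim(c(0, 0, 0, best), obj, method = "Nelder-Mead",
                      control = list(maxit = maxIterations, reltol = 1e-10,
                                     parscale = c(rep(0.02, 3), rep(2, 3))))
  # keep whichever of {identity, best coarse start, refined} scores highest,
  # so exact self-alignment is returned exactly
  cand <- list(rep(0, 6), c(0, 0, 0, best), fit$par)
  scores <- vapply(cand, function(p) {
    v <- ncc(p)
    if (is.na(v)) -2 else v
  }, numeric(1))
  pick <- cand[[which.max(scores)]]
  out <- new("RigidTransform", angles = pick[1:3],
             translation = pick[4:6], center = ctr)
  attr(out, "metric") <- max(scores)
  out
}
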