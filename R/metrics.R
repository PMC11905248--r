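# Validation metrics: volume-overlap and surface-distance indices between
# contour masks, 3D global gamma analysis between dose distributions, and
# the two-sample t-test used to compare accumulation workflows.

# Face-connected boundary voxels of a mask (voxels with at least one of the
# 6 neighbours outside the mask; the region beyond the grid counts as
# outside).
#' @noRd
.surfaceVoxels <- function(mask) {
  d <- dim(mask)
  inner <- array(TRUE, d)
  shift_ok <- function(axis, by) {
    out <- array(FALSE, d)
    n <- d[axis]
    src <- seq_len(n) - by
    ok <- src >= 1 & src <= n
    idx_to <- switch(axis, list(which(ok), TRUE, TRUE),
                     list(TRUE, which(ok), TRUE), list(TRUE, TRUE, which(ok)))
    idx_from <- switch(axis, list(src[ok], TRUE, TRUE),
                       list(TRUE, src[ok], TRUE), list(TRUE, TRUE, src[ok]))
    out_sub <- do.call(`[`, c(list(mask), idx_from, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), idx_to, list(out_sub)))
    out
  }
  for (axis in 1:3) for (by in c(-1L, 1L))
    inner <- inner & shift_ok(axis, by)
  mask & !inner
}

#' Geometric agreement indices between two binary masks
#'
#' Computes the Dice and Jaccard overlap coefficients and Hausdorff surface
#' distances. Surfaces are the face-connected boundary voxels; distances
#' are voxel-center Euclidean distances in mm via a distance transform.
#' `hdMaxMm` is the classical (maximum) Hausdorff distance, the larger of
#' the two directed maximum nearest-surface distances; `hdMeanMm` is the
#' mean symmetric surface distance.
#'
#' @param a,b logical 3D arrays on the same grid, both nonempty.
#' @param spacing voxel spacing in mm (numeric(3) or scalar), or a
#'   [GridDescriptor-class].
#' @return a [GeometricIndices-class].
#' @export
geometricIndices <- function(a, b, spacing = c(1, 1, 1)) {
  if (is(spacing, "GridDescriptor")) spacing <- spacing@spacing
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  na <- sum(a); nb <- sum(b)
  if (na == 0 || nb == 0) stop("geometric indices need two nonempty masks")
  inter <- sum(a & b)
  dice <- 2 * inter / (na + nb)
  jaccard <- inter / (na + nb - inter)

  sa <- .surfaceVoxels(a); sb <- .surfaceVoxels(b)
  d <- dim(a)
  dist_to_b <- sqrt(cpp_edt_sq(as.vector(sb), as.integer(d), spacing))
  dist_to_a <- sqrt(cpp_edt_sq(as.vector(sa), as.integer(d), spacing))
  dab <- dist_to_b[sa]             # distances from surface A to surface B
  dba <- dist_to_a[sb]
  new("GeometricIndices", dice = dice, jaccard = jaccard,
      hdMaxMm = max(max(dab), max(dba)),
      hdMeanMm = (sum(dab) + sum(dba)) / (length(dab) + length(dba)))
}

#' 3D global gamma analysis
#'
#' Pointwise dose-comparison index combining a dose-difference criterion
#' (percent of the global normalization dose) and a distance-to-agreement
#' criterion (mm). The minimization searches a sphere of radius
#' `searchFactor x dtaMm` on a sub-voxel lattice (offsets ordered by
#' distance with early termination). Voxels whose reference dose falls
#' below the low-dose threshold are excluded from the pass rate.
#'
#' @param refDose,evalDose [ImageVolume-class] doses on a common grid (Gy).
#' @param dosePct dose-difference criterion, % of normalization (default 3).
#' @param dtaMm distance-to-agreement criterion in mm (default 3).
#' @param thresholdPct low-dose threshold, % of normalization (default 10).
#' @param normalizationGy global normalization dose; defaults to the
#'   reference maximum (use the prescription for clinical semantics).
#' @param searchFactor search-sphere radius as a multiple of `dtaMm`.
#' @param stepMm sub-voxel search step; default half the smallest spacing.
#' @return a [GammaResult-class].
#' @export
gammaAnalysis <- function(refDose, evalDose, dosePct = 3, dtaMm = 3,
                          thresholdPct = 10, normalizationGy = NULL,
                          searchFactor = 3, stepMm = NULL) {
  if (!sameGrid(refDose@grid, evalDose@grid))
    stop("gamma analysis requires doses resampled to a common grid")
  if (is.null(normalizationGy)) normalizationGy <- max(refDose@voxels)
  if (normalizationGy <= 0)
    stop("zero normalization dose: gamma criteria are undefined")
  g <- refDose@grid
  if (is.null(stepMm)) stepMm <- min(g@spacing) / 2
  gam <- cpp_gamma(refDose@voxels, evalDose@voxels, g@shape, g@spacing,
                   dosePct / 100 * normalizationGy, dtaMm,
                   searchFactor * dtaMm, stepMm)
  gam <- array(gam, g@shape)
  evaluated <- refDose@voxels >= thresholdPct / 100 * normalizationGy
  pass <- if (any(evaluated)) {
    100 * mean(gam[evaluated] <= 1 + 1e-12)
  } else 100
  new("GammaResult", map = gam, evaluated = evaluated, passRatePct = pass,
      criteria = list(dosePct = dosePct, dtaMm = dtaMm,
                      thresholdPct = thresholdPct,
                      normalizationGy = normalizationGy))
}

#' Two-sample t-test
#'
#' Welch's unequal-variance variant by default, with a pooled-variance
#' option. Degenerate samples (zero variance in both groups) return p = 1
#' for equal means and p = 0 otherwise rather than erroring.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @param variant `"welch"` or `"pooled"`.
#' @return list with `statistic`, `df`, `pValue`, `variant`.
#' @export
twoSampleTTest <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2)
    stop("both samples need at least two observations")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (equal) 0 else Inf,
                df = length(x) + length(y) - 2,
                pValue = if (equal) 1 else 0, variant = variant))
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       pValue = ht$p.value, variant = variant)
}
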