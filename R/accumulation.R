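# Progressive dose accumulation on the planning grid: each warped daily
# fraction dose replaces one planned fraction, so after k of N fractions
# the composite is sum(delivered_1..k) + (N - k)/N * planned_total.

#' Scale a total dose to one fraction
#'
#' @param totalDose an [ImageVolume-class] in Gy.
#' @param nFractions number of fractions (>= 1).
#' @return an [ImageVolume-class]: `totalDose / nFractions` voxelwise.
#' @examples
#' # 36.25 Gy in 5 fractions is 7.25 Gy per fraction
#' @export
scaleToOneFraction <- function(totalDose, nFractions) {
  nFractions <- as.integer(nFractions)
  if (is.na(nFractions) || nFractions < 1L)
    stop("nFractions must be an integer >= 1")
  imageVolume(totalDose@voxels / nFractions, totalDose@grid)
}

#' Warp a daily dose onto the planning grid
#'
#' Trilinear interpolation of the daily dose at the field-mapped planning
#' voxel centers (pull-back). This is pure dose mapping: no Jacobian
#' energy/mass correction is applied, matching common commercial DIR-based
#' accumulation; voxels mapped outside the daily dose support receive 0 and
#' the covered fraction is reported as an attribute.
#'
#' @param dailyDose an [ImageVolume-class] on the daily grid (Gy).
#' @param field a [DisplacementField-class] on the planning grid.
#' @param planningGrid optional target [GridDescriptor-class]; must equal
#'   the field grid (checked) — present for interface symmetry.
#' @return an [ImageVolume-class] on the planning grid, with attribute
#'   `coverage` (fraction of planning voxels mapped inside the daily
#'   support).
#' @export
warpDose <- function(dailyDose, field, planningGrid = NULL) {
  if (!is.null(planningGrid) && !sameGrid(planningGrid, field@grid))
    stop("the displacement field must live on the planning grid")
  cc <- mappedVoxelCoords(field, dailyDose@grid)
  g <- dailyDose@grid
  inside <- cc$cx >= 0 & cc$cy >= 0 & cc$cz >= 0 &
    cc$cx <= g@shape[1] - 1 & cc$cy <= g@shape[2] - 1 &
    cc$cz <= g@shape[3] - 1
  vals <- cpp_sample_trilinear(dailyDose@voxels, g@shape,
                               cc$cx, cc$cy, cc$cz, 0)
  out <- imageVolume(array(vals, field@grid@shape), field@grid)
  attr(out@voxels, "coverage") <- mean(inside)
  out
}

#' Construct a fraction record
#'
#' @param fractionIndex integer fraction number (1..N).
#' @param deliveredDoseDaily one-fraction delivered dose on the daily grid.
#' @param field [DisplacementField-class] mapping planning points into the
#'   daily frame; defaults to the identity on the dose grid.
#' @return a [FractionRecord-class] with the dose warped onto the planning
#'   grid.
#' @export
fractionRecord <- function(fractionIndex, deliveredDoseDaily, field = NULL) {
  if (is.null(field)) field <- identityField(deliveredDoseDaily@grid)
  planned <- warpDose(deliveredDoseDaily, field)
  new("FractionRecord", fractionIndex = as.integer(fractionIndex),
      deliveredDoseDaily = deliveredDoseDaily, field = field,
      deliveredDosePlanning = planned)
}

#' Initialize the progressive composite
#'
#' With no fractions delivered the composite equals the planned total.
#'
#' @param plannedTotal planned total dose on the planning grid (Gy).
#' @param nFractions number of fractions N.
#' @return a [CompositeState-class] at k = 0.
#' @export
compositeState <- function(plannedTotal, nFractions) {
  new("CompositeState", plannedTotal = plannedTotal,
      nFractions = as.integer(nFractions), delivered = list(),
      composite = plannedTotal)
}

#' Add one delivered fraction to the progressive composite
#'
#' The warped delivered fraction dose replaces one planned fraction:
#' composite(k) = sum of the k delivered doses (planning frame) +
#' (N - k)/N x planned total. At k = N the composite is the fully
#' accumulated delivered dose.
#'
#' @param state a [CompositeState-class].
#' @param record a [FractionRecord-class]; its index must not already be
#'   present.
#' @return the updated [CompositeState-class].
#' @export
progressiveComposite <- function(state, record) {
  idx <- vapply(state@delivered, function(r) r@fractionIndex, integer(1))
  if (record@fractionIndex %in% idx)
    stop("fraction ", record@fractionIndex, " has already been accumulated")
  if (length(state@delivered) >= state@nFractions)
    stop("all ", state@nFractions, " fractions already accumulated")
  vox <- state@composite@voxels +
    record@deliveredDosePlanning@voxels -
    state@plannedTotal@voxels / state@nFractions
  attr(vox, "coverage") <- NULL
  new("CompositeState", plannedTotal = state@plannedTotal,
      nFractions = state@nFractions,
      delivered = c(state@delivered, list(record)),
      composite = imageVolume(vox, state@composite@grid))
}
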