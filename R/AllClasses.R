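# Central S4 containers. All voxel lattices use 0-based voxel indices with a
# voxel-center world mapping: world_mm = origin_mm + index * spacing_mm.
# Axis convention throughout: x = right-left (RL), y = anterior-posterior
# (AP), z = superior-inferior (SI), all in millimetres.

#' GridDescriptor: geometry of an axis-aligned voxel lattice
#'
#' Describes the sampling geometry shared by images, masks, dose grids and
#' displacement fields: voxels per axis, per-axis spacing (mm) and the world
#' position (mm) of the center of voxel (0, 0, 0).
#'
#' @slot shape integer(3), voxels per axis.
#' @slot spacing numeric(3), voxel size in mm (all > 0).
#' @slot origin numeric(3), world coordinate (mm) of the first voxel center.
#' @exportClass GridDescriptor
setClass("GridDescriptor",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(object@shape) != 3L || any(object@shape < 1L))
      return("shape must be three positive integers")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be three positive finite values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("origin must be three finite values (mm)")
    TRUE
  })

#' ImageVolume: a 3D scalar field on an axis-aligned grid
#'
#' Container for MR intensities, dose grids (Gy) and rasterized masks.
#'
#' @slot voxels 3D numeric array (column-major, dims = grid shape).
#' @slot grid a [GridDescriptor-class].
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(voxels = "array", grid = "GridDescriptor"),
  validity = function(object) {
    d <- dim(object@voxels)
    if (length(d) != 3L) return("voxels must be a 3D array")
    if (!identical(as.integer(d), object@grid@shape))
      return("voxel array dimensions disagree with the grid shape")
    TRUE
  })

#' StructureSet: named binary masks on a shared grid
#'
#' @slot masks named list of logical 3D arrays, all on `grid`.
#' @slot grid a [GridDescriptor-class].
#' @exportClass StructureSet
setClass("StructureSet",
  representation(masks = "list", grid = "GridDescriptor"),
  validity = function(object) {
    if (length(object@masks) &&
        (is.null(names(object@masks)) || any(!nzchar(names(object@masks)))))
      return("all masks must be named")
    for (nm in names(object@masks)) {
      m <- object@masks[[nm]]
      if (!is.logical(m) || !identical(as.integer(dim(m)), object@grid@shape))
        return(sprintf("mask '%s' is not a logical array on the shared grid", nm))
    }
    TRUE
  })

#' DisplacementField: per-voxel 3-vectors (mm) on the planning grid
#'
#' Pull-back convention: a planning-frame point p maps to the daily-frame
#' point p + u(p); daily data are resampled onto the planning grid by
#' evaluating them at the mapped points.
#'
#' @slot vectors 4D numeric array `[nx, ny, nz, 3]`, displacements in mm.
#' @slot grid planning-frame [GridDescriptor-class].
#' @exportClass DisplacementField
setClass("DisplacementField",
  representation(vectors = "array", grid = "GridDescriptor"),
  validity = function(object) {
    d <- dim(object@vectors)
    if (length(d) != 4L || d[4] != 3L)
      return("vectors must be a 4D array with 3 components in the last dim")
    if (!identical(as.integer(d[1:3]), object@grid@shape))
      return("vector array dimensions disagree with the grid shape")
    if (any(!is.finite(object@vectors)))
      return("displacement vectors must be finite")
    TRUE
  })

#' RigidTransform: rotation + translation about a fixed center
#'
#' Maps a planning-frame point x (mm) to R (x - center) + center +
#' translation in the daily frame, with R built from extrinsic XYZ Euler
#' angles.
#'
#' @slot angles numeric(3) Euler angles (radians).
#' @slot translation numeric(3) in mm.
#' @slot center numeric(3) rotation center in mm (focus-box centroid).
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(angles = "numeric", translation = "numeric",
                 center = "numeric"),
  validity = function(object) {
    if (length(object@angles) != 3L || length(object@translation) != 3L ||
        length(object@center) != 3L)
      return("angles, translation and center must have length 3")
    if (any(!is.finite(c(object@angles, object@translation, object@center))))
      return("rigid parameters must be finite")
    TRUE
  })

#' FocusBox: axis-aligned registration support region (mm)
#'
#' The target-focused region inside which registration costs are evaluated:
#' the PTV_eval bounding box expanded by 30 mm right-left and
#' anterior-posterior and 20 mm superior-inferior, clipped to the image.
#'
#' @slot lower,upper numeric(3) world corners in mm (lower <= upper).
#' @exportClass FocusBox
setClass("FocusBox",
  representation(lower = "numeric", upper = "numeric"),
  validity = function(object) {
    if (length(object@lower) != 3L || length(object@upper) != 3L)
      return("corners must have length 3")
    if (any(object@upper < object@lower))
      return("upper corner must dominate lower corner")
    TRUE
  })

#' DVHCurve: cumulative dose-volume histogram
#'
#' @slot doseGy dose thresholds (uniform bins, Gy).
#' @slot volumeCc,volumePct volume receiving at least each threshold dose.
#' @slot totalVolumeCc structure volume in cc.
#' @slot structure structure name.
#' @slot binGy bin width in Gy.
#' @exportClass DVHCurve
setClass("DVHCurve",
  representation(doseGy = "numeric", volumeCc = "numeric",
                 volumePct = "numeric", totalVolumeCc = "numeric",
                 structure = "character", binGy = "numeric"),
  validity = function(object) {
    if (length(object@doseGy) != length(object@volumeCc) ||
        length(object@doseGy) != length(object@volumePct))
      return("curve vectors must have equal length")
    if (any(diff(object@volumeCc) > 1e-9))
      return("cumulative volume must be non-increasing in dose")
    TRUE
  })

#' FractionRecord: one delivered fraction and its mapping to the planning frame
#'
#' @slot fractionIndex integer in 1..N.
#' @slot deliveredDoseDaily one-fraction delivered dose (Gy) on the daily grid.
#' @slot field [DisplacementField-class] mapping planning points into the
#'   daily frame.
#' @slot deliveredDosePlanning the same dose warped onto the planning grid.
#' @exportClass FractionRecord
setClass("FractionRecord",
  representation(fractionIndex = "integer",
                 deliveredDoseDaily = "ImageVolume",
                 field = "DisplacementField",
                 deliveredDosePlanning = "ImageVolume"))

#' CompositeState: progressive composite dose bookkeeping
#'
#' After k delivered fractions of N, the composite equals the sum of the k
#' warped delivered fraction doses plus (N - k)/N of the planned total, so
#' the delivered dose gradually replaces the planned dose fraction by
#' fraction.
#'
#' @slot plannedTotal planned total dose (Gy) on the planning grid.
#' @slot nFractions integer N.
#' @slot delivered list of [FractionRecord-class] (k entries).
#' @slot composite current composite dose (Gy).
#' @exportClass CompositeState
setClass("CompositeState",
  representation(plannedTotal = "ImageVolume", nFractions = "integer",
                 delivered = "list", composite = "ImageVolume"),
  validity = function(object) {
    if (object@nFractions < 1L) return("nFractions must be >= 1")
    k <- length(object@delivered)
    if (k > object@nFractions) return("more delivered fractions than N")
    idx <- vapply(object@delivered, function(r) r@fractionIndex, integer(1))
    if (anyDuplicated(idx)) return("duplicate fraction indices")
    TRUE
  })

#' GammaResult: 3D gamma analysis of two dose distributions
#'
#' @slot map per-voxel gamma values (unitless).
#' @slot evaluated logical array: voxels above the low-dose threshold.
#' @slot passRatePct percentage of evaluated voxels with gamma <= 1.
#' @slot criteria list(dosePct, dtaMm, thresholdPct, normalizationGy).
#' @exportClass GammaResult
setClass("GammaResult",
  representation(map = "array", evaluated = "array", passRatePct = "numeric",
                 criteria = "list"),
  validity = function(object) {
    if (object@passRatePct < 0 || object@passRatePct > 100)
      return("pass rate must lie in [0, 100]")
    TRUE
  })

#' GeometricIndices: volume-overlap and surface-distance agreement metrics
#'
#' @slot dice,jaccard overlap coefficients in `[0, 1]`.
#' @slot hdMaxMm maximum Hausdorff distance (mm).
#' @slot hdMeanMm mean symmetric surface distance (mm).
#' @exportClass GeometricIndices
setClass("GeometricIndices",
  representation(dice = "numeric", jaccard = "numeric", hdMaxMm = "numeric",
                 hdMeanMm = "numeric"),
  validity = function(object) {
    if (object@dice < 0 || object@dice > 1) return("dice out of [0,1]")
    if (object@jaccard < 0 || object@jaccard > 1) return("jaccard out of [0,1]")
    if (object@hdMeanMm > object@hdMaxMm + 1e-9)
      return("mean surface distance cannot exceed the maximum")
    TRUE
  })

#' PhantomSpec: parameters of the synthetic pelvis planning case
#'
#' The defaults emulate the study conditions of a 0.35T MR-linac prostate
#' SBRT protocol: 1.5 mm isotropic voxels (grid cropped to desk scale), a
#' prostate/PTV ellipsoid whose PTV_eval volume falls in the reported
#' clinical range, rectum, bladder, urethra + PRV, femoral heads and penile
#' bulb, piecewise-constant MR-like intensities with additive Gaussian
#' noise.
#'
#' @slot gridShape integer(3) voxels per axis.
#' @slot spacingMm numeric(3) voxel size, mm.
#' @slot organParams named list of organ geometry (centers/radii in mm,
#'   world coordinates relative to the grid center).
#' @slot intensities named numeric organ intensity levels (arbitrary units).
#' @slot noiseSd additive intensity noise standard deviation.
#' @slot seed integer RNG seed (propagated to named substreams).
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(gridShape = "integer", spacingMm = "numeric",
                 organParams = "list", intensities = "numeric",
                 noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (any(object@spacingMm <= 0)) return("spacingMm must be positive")
    if (object@noiseSd < 0) return("noiseSd must be non-negative")
    TRUE
  })

#' DeformationSpec: parameters of a synthetic inter-fraction deformation
#'
#' A ground-truth displacement field built from three smooth components:
#' radial bladder filling, a Gaussian rectal bump, and a smooth random field
#' with a given correlation length. The invertibility margin (peak random
#' displacement at most 0.45 x correlation length) keeps the Jacobian
#' determinant positive everywhere, which is also checked numerically.
#'
#' @slot bladderFillScale radial scale factor (1 = no change).
#' @slot rectalBumpMm peak displacement (mm) of the anterior rectal bump.
#' @slot randomFieldAmpMm peak magnitude (mm) of the random component.
#' @slot randomFieldCorrMm Gaussian correlation length (mm).
#' @slot seed integer RNG seed.
#' @exportClass DeformationSpec
setClass("DeformationSpec",
  representation(bladderFillScale = "numeric", rectalBumpMm = "numeric",
                 randomFieldAmpMm = "numeric", randomFieldCorrMm = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@randomFieldCorrMm <= 0)
      return("randomFieldCorrMm must be positive")
    if (object@randomFieldAmpMm < 0 || object@rectalBumpMm < 0)
      return("amplitudes must be non-negative")
    if (object@randomFieldAmpMm > 0.45 * object@randomFieldCorrMm)
      return(paste0("randomFieldAmpMm exceeds the invertibility margin ",
                    "(0.45 x randomFieldCorrMm)"))
    TRUE
  })

#' CaseBundle: a planning case (image, structures, plan dose)
#'
#' @slot image MR-like planning image.
#' @slot structures [StructureSet-class] with PTV_eval and OARs.
#' @slot planDose planned total dose (Gy), normalized so PTV_eval D95%
#'   equals the prescription.
#' @slot nFractions integer number of fractions (default 5).
#' @slot prescriptionGy total prescription in Gy (default 36.25).
#' @exportClass CaseBundle
setClass("CaseBundle",
  representation(image = "ImageVolume", structures = "StructureSet",
                 planDose = "ImageVolume", nFractions = "integer",
                 prescriptionGy = "numeric"),
  validity = function(object) {
    if (object@nFractions < 1L) return("nFractions must be >= 1")
    if (min(object@planDose@voxels) < 0) return("plan dose must be >= 0")
    TRUE
  })

#' DailyCase: one synthetic treatment fraction
#'
#' @slot image daily MR-like image (planning anatomy pushed through the
#'   ground-truth deformation).
#' @slot structures daily contours (truth-warped planning contours).
#' @slot deliveredFractionDose one-fraction delivered dose on the daily
#'   anatomy (Gy).
#' @slot truthField ground-truth [DisplacementField-class] (planning ->
#'   daily, pull-back convention).
#' @slot fractionIndex integer.
#' @exportClass DailyCase
setClass("DailyCase",
  representation(image = "ImageVolume", structures = "StructureSet",
                 deliveredFractionDose = "ImageVolume",
                 truthField = "DisplacementField",
                 fractionIndex = "integer"))
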