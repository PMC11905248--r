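#' @name accessors
#' @title Accessors for doseAccum containers
#' @description Slot accessors for the S4 containers; user code should use
#'   these rather than reaching into slots.
#' @param x an object.
#' @param name a structure name.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("imageGrid", function(x) standardGeneric("imageGrid"))

#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))

#' @rdname accessors
#' @export
setGeneric("getMask", function(x, name) standardGeneric("getMask"))

#' @rdname accessors
#' @export
setGeneric("fieldVectors", function(x) standardGeneric("fieldVectors"))

#' @rdname accessors
#' @export
setGeneric("maxDisplacement", function(x) standardGeneric("maxDisplacement"))

#' @rdname accessors
#' @export
setGeneric("compositeDose", function(x) standardGeneric("compositeDose"))

#' @rdname accessors
#' @export
setGeneric("deliveredCount", function(x) standardGeneric("deliveredCount"))

setMethod("voxels", "ImageVolume", function(x) x@voxels)
setMethod("imageGrid", "ImageVolume", function(x) x@grid)
setMethod("imageGrid", "StructureSet", function(x) x@grid)
setMethod("imageGrid", "DisplacementField", function(x) x@grid)
setMethod("gridShape", "GridDescriptor", function(x) x@shape)
setMethod("gridSpacing", "GridDescriptor", function(x) x@spacing)
setMethod("gridOrigin", "GridDescriptor", function(x) x@origin)
setMethod("gridShape", "ImageVolume", function(x) x@grid@shape)
setMethod("gridSpacing", "ImageVolume", function(x) x@grid@spacing)
setMethod("gridOrigin", "ImageVolume", function(x) x@grid@origin)
setMethod("structureNames", "StructureSet", function(x) names(x@masks))
setMethod("getMask", "StructureSet", function(x, name) {
  if (!name %in% names(x@masks))
    stop("structure '", name, "' not present in the set")
  x@masks[[name]]
})
setMethod("fieldVectors", "DisplacementField", function(x) x@vectors)
setMethod("maxDisplacement", "DisplacementField", function(x) {
  v <- x@vectors
  sqrt(max(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2))
})
setMethod("compositeDose", "CompositeState", function(x) x@composite)
setMethod("deliveredCount", "CompositeState", function(x) length(x@delivered))

setMethod("dim", "ImageVolume", function(x) dim(x@voxels))

setMethod("show", "GridDescriptor", function(object) {
  cat(sprintf("GridDescriptor: %s voxels, spacing %s mm, origin %s mm\n",
              paste(object@shape, collapse = "x"),
              paste(format(object@spacing), collapse = "/"),
              paste(format(object@origin), collapse = "/")))
})
setMethod("show", "ImageVolume", function(object) {
  v <- object@voxels
  cat(sprintf("ImageVolume: %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(v), collapse = "x"),
              paste(format(object@grid@spacing), collapse = "/"),
              min(v), max(v)))
})
setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet with %d structures on a %s grid\n",
              length(object@masks), paste(object@grid@shape, collapse = "x")))
  for (nm in names(object@masks)) {
    vol <- sum(object@masks[[nm]]) * prod(object@grid@spacing) / 1000
    cat(sprintf("  %-12s %8.2f cc\n", nm, vol))
  }
})
setMethod("show", "DisplacementField", function(object) {
  cat(sprintf("DisplacementField on a %s grid, max |u| = %.3f mm\n",
              paste(object@grid@shape, collapse = "x"),
              maxDisplacement(object)))
})
setMethod("show", "RigidTransform", function(object) {
  cat(sprintf(
    "RigidTransform: angles (%.4f, %.4f, %.4f) rad, t = (%.2f, %.2f, %.2f) mm\n",
    object@angles[1], object@angles[2], object@angles[3],
    object@translation[1], object@translation[2], object@translation[3]))
})
setMethod("show", "FocusBox", function(object) {
  cat(sprintf("FocusBox: [%s] to [%s] mm\n",
              paste(format(object@lower), collapse = ", "),
              paste(format(object@upper), collapse = ", ")))
})
setMethod("show", "DVHCurve", function(object) {
  cat(sprintf("DVHCurve for '%s': %.2f cc, %d bins of %.3g Gy\n",
              object@structure, object@totalVolumeCc,
              length(object@doseGy), object@binGy))
})
setMethod("show", "CompositeState", function(object) {
  cat(sprintf("CompositeState: %d of %d fractions delivered\n",
              length(object@delivered), object@nFractions))
})
setMethod("show", "GammaResult", function(object) {
  cr <- object@criteria
  cat(sprintf("GammaResult %.3g%%/%.3g mm (threshold %.3g%%): pass rate %.2f%%\n",
              cr$dosePct, cr$dtaMm, cr$thresholdPct, object@passRatePct))
})
setMethod("show", "GeometricIndices", function(object) {
  cat(sprintf(
    "GeometricIndices: DICE %.4f, Jaccard %.4f, HD max %.3f mm, HD mean %.3f mm\n",
    object@dice, object@jaccard, object@hdMaxMm, object@hdMeanMm))
})
setMethod("show", "CaseBundle", function(object) {
  cat(sprintf(
    "CaseBundle: %s grid, %d structures, %d fractions, prescription %.2f Gy\n",
    paste(object@image@grid@shape, collapse = "x"),
    length(object@structures@masks), object@nFractions, object@prescriptionGy))
})
setMethod("show", "DailyCase", function(object) {
  cat(sprintf("DailyCase (fraction %d), truth field max |u| = %.2f mm\n",
              object@fractionIndex, maxDisplacement(object@truthField)))
})
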