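# Cumulative dose-volume histograms and DVH metrics. Binned engine
# (default 0.01 Gy bins) with linear interpolation between bins for Dx
# metrics; masks are binary (no partial-volume weighting).

#' Compute a cumulative DVH
#'
#' @param dose an [ImageVolume-class] in Gy.
#' @param mask logical 3D array on the same grid (binary structure mask).
#' @param binGy bin width in Gy (default 0.01).
#' @param structure structure name carried into the curve (for messages).
#' @return a [DVHCurve-class]: volume (cc and %) receiving at least each
#'   threshold dose.
#' @export
computeDVH <- function(dose, mask, binGy = 0.01, structure = "structure") {
  if (is(mask, "ImageVolume")) mask <- mask@voxels >= 0.5
  if (!identical(dim(mask), dim(dose@voxels)))
    stop("dose and mask must share a grid (resample first)")
  n <- sum(mask)
  if (n == 0) stop("empty mask for structure '", structure, "'")
  vals <- dose@voxels[mask]
  vv <- voxelVolumeCc(dose@grid)
  nb <- floor(max(vals) / binGy + 1e-9) + 2L
  # voxel with dose d counts toward every threshold j*binGy <= d
  bin <- pmin(floor(vals / binGy + 1e-9), nb - 1L) + 1L
  counts <- tabulate(bin, nbins = nb)
  cum <- rev(cumsum(rev(counts)))
  new("DVHCurve", doseGy = (seq_len(nb) - 1L) * binGy,
      volumeCc = cum * vv, volumePct = 100 * cum / n,
      totalVolumeCc = n * vv, structure = structure, binGy = binGy)
}

#' Evaluate a DVH metric on a curve
#'
#' Supported metrics, given as strings in the clinical notation:
#' * `"D95%"`: minimum dose to the hottest 95% of the volume (Gy);
#' * `"D0.03cc"`: minimum dose to the hottest 0.03 cc (Gy);
#' * `"V36.25Gy"`: volume receiving at least 36.25 Gy, in `%` or `cc`.
#'
#' Dx metrics are interpolated linearly between bins: the largest dose d
#' with cumulative volume(d) >= x.
#'
#' @param curve a [DVHCurve-class].
#' @param metric metric string.
#' @param unit for V-metrics, `"pct"` or `"cc"`.
#' @return the metric value.
#' @export
dvhMetric <- function(curve, metric, unit = c("pct", "cc")) {
  unit <- match.arg(unit)
  t <- curve@doseGy
  if (grepl("^D[0-9.]+%$", metric)) {
    x <- as.numeric(sub("^D([0-9.]+)%$", "\\1", metric))
    return(.dvh_dx(t, curve@volumePct, x, curve@binGy))
  }
  if (grepl("^D[0-9.]+cc$", metric)) {
    x <- as.numeric(sub("^D([0-9.]+)cc$", "\\1", metric))
    if (x > curve@totalVolumeCc)
      stop("D", x, "cc exceeds the structure volume (",
           format(curve@totalVolumeCc), " cc)")
    return(.dvh_dx(t, curve@volumeCc, x, curve@binGy))
  }
  if (grepl("^V[0-9.]+Gy$", metric)) {
    x <- as.numeric(sub("^V([0-9.]+)Gy$", "\\1", metric))
    cum <- if (unit == "pct") curve@volumePct else curve@volumeCc
    return(.dvh_vx(t, cum, x, curve@binGy))
  }
  stop("unrecognized DVH metric: '", metric, "'")
}

# Dx: largest dose with cumulative volume >= x, linear between bins.
#' @noRd
.dvh_dx <- function(t, cum, x, bin) {
  if (x > cum[1] + 1e-12)
    stop("requested volume ", x, " exceeds the structure volume")
  j <- max(which(cum >= x))
  if (j == length(cum)) return(t[j])
  t[j] + bin * (cum[j] - x) / (cum[j] - cum[j + 1L])
}

# Vx: cumulative volume at dose x, linear between bins; 0 beyond the curve.
#' @noRd
.dvh_vx <- function(t, cum, x, bin) {
  if (x <= 0) return(cum[1])
  if (x >= t[length(t)]) return(0)
  j <- floor(x / bin + 1e-9) + 1L
  if (j >= length(cum)) return(cum[length(cum)])
  f <- (x - t[j]) / bin
  cum[j] * (1 - f) + cum[j + 1L] * f
}

#' Percent volume discrepancy between accumulated and planned values
#'
#' `(vAccum - vPlanned) * 100 / vPlanned`: the signed percent difference of
#' an accumulated dose-volume value relative to its planned value.
#'
#' @param vAccum,vPlanned the two values (same units); `vPlanned` must be
#'   positive.
#' @return signed percent discrepancy.
#' @examples
#' percentVolumeDiscrepancy(98.2, 100)  # -1.8
#' @export
percentVolumeDiscrepancy <- function(vAccum, vPlanned) {
  if (any(vPlanned <= 0))
    stop("undefined result: the planned value must be positive")
  (vAccum - vPlanned) * 100 / vPlanned
}
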