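# Hybrid contour + intensity deformable registration: multiresolution cubic
# B-spline free-form deformation minimizing
#   C = w_I * SSD(intensity) + w_C * sum_s SSD(signed distance map of s)
#       + lambda * bending energy,
# evaluated inside the PTV-focused box ("ring" support region). The data
# terms are normalized to unit initial magnitude so the default weights are
# scale-free. Optimized per pyramid level by spectral (Barzilai-Borwein)
# projected gradient descent with Armijo backtracking, which is
# deterministic and yields a monotone non-increasing cost trace.

#' Deformable registration configuration
#'
#' @param intensityWeight w_I >= 0, weight of the intensity SSD term.
#' @param contourWeight w_C >= 0, weight of the contour
#'   (signed-distance-map) SSD term.
#' @param regularizationWeight lambda >= 0, bending-energy weight (applied
#'   to the normalized cost).
#' @param pyramidLevels number of image-pyramid levels (level l is
#'   downsampled by 2^(l-1)).
#' @param controlPointSpacingMm B-spline knot spacing in mm.
#' @param maxIterations iteration cap per level (recycled over levels,
#'   coarsest first).
#' @param convergenceTol relative cost-change stopping tolerance.
#' @param ringOnly evaluate the cost only inside the focus box (default);
#'   otherwise over the whole grid.
#' @param structures structure names for the contour term; default: all
#'   names shared by the two structure sets.
#' @param sdmTruncationMm truncation of the signed distance maps (mm).
#' @param maxDisplacementMm cap on the reported field magnitude; larger
#'   vectors are clamped with a warning.
#' @return a named list of settings.
#' @export
registrationConfig <- function(intensityWeight = 1, contourWeight = 1,
                               regularizationWeight = 0.05,
                               pyramidLevels = 2L,
                               controlPointSpacingMm = 20,
                               maxIterations = c(40L, 20L),
                               convergenceTol = 1e-4, ringOnly = TRUE,
                               structures = NULL, sdmTruncationMm = 20,
                               maxDisplacementMm = 30) {
  if (intensityWeight < 0 || contourWeight < 0 || regularizationWeight < 0)
    stop("weights must be non-negative")
  if (intensityWeight + contourWeight <= 0)
    stop("at least one of the intensity and contour weights must be positive")
  if (pyramidLevels < 1) stop("pyramidLevels must be >= 1")
  list(intensityWeight = intensityWeight, contourWeight = contourWeight,
       regularizationWeight = regularizationWeight,
       pyramidLevels = as.integer(pyramidLevels),
       controlPointSpacingMm = controlPointSpacingMm,
       maxIterations = as.integer(maxIterations),
       convergenceTol = convergenceTol, ringOnly = ringOnly,
       structures = structures, sdmTruncationMm = sdmTruncationMm,
       maxDisplacementMm = maxDisplacementMm)
}

#' Truncated signed Euclidean distance map of a mask (mm)
#'
#' Negative inside the mask, positive outside, clipped to +/- `truncMm`.
#'
#' @param mask logical 3D array.
#' @param grid its [GridDescriptor-class].
#' @param truncMm truncation distance (mm).
#' @return 3D numeric array.
#' @export
signedDistanceMap <- function(mask, grid, truncMm = 20) {
  d_out <- sqrt(cpp_edt_sq(as.vector(mask), grid@shape, grid@spacing))
  d_in <- sqrt(cpp_edt_sq(as.vector(!mask), grid@shape, grid@spacing))
  sdm <- ifelse(as.vector(mask), -d_in, d_out)
  array(pmin(pmax(sdm, -truncMm), truncMm), grid@shape)
}

# Monotone spectral gradient descent with Armijo backtracking.
#' @noRd
.bbOptim <- function(par, fngr, maxit, tol) {
  ev <- fngr(par)
  f <- ev$cost; g <- ev$grad
  trace <- f
  gmax <- max(abs(g))
  if (!is.finite(f)) stop("non-finite registration cost at initialization")
  if (gmax < 1e-14) return(list(par = par, value = f, trace = trace))
  step <- 0.5 / gmax                      # first move of at most 0.5 mm
  for (it in seq_len(maxit)) {
    gnorm2 <- sum(g^2)
    s <- step
    accepted <- FALSE
    for (ls in 1:25) {
      cand <- par - s * g
      evc <- fngr(cand)
      if (is.finite(evc$cost) && evc$cost <= f - 1e-4 * s * gnorm2) {
        accepted <- TRUE
        break
      }
      s <- s / 2
    }
    if (!accepted) break
    sk <- cand - par
    yk <- evc$grad - g
    sy <- sum(sk * yk)
    step <- if (sy > 1e-300) sum(sk * sk) / sy else s * 2
    rel <- (f - evc$cost) / max(abs(f), 1e-300)
    par <- cand; f <- evc$cost; g <- evc$grad
    trace <- c(trace, f)
    if (rel < tol) break
  }
  list(par = par, value = f, trace = trace)
}

#' @noRd
.downsampleVol <- function(vol, factor) {
  if (factor == 1) return(vol)
  g <- vol@grid
  shape <- pmax(2L, as.integer(ceiling(g@shape / factor)))
  resampleToGrid(vol, gridDescriptor(shape, g@spacing * factor, g@origin))
}

#' Hybrid contour + intensity deformable registration
#'
#' Estimates the displacement field mapping planning-frame points into the
#' daily frame (pull-back convention) as a cubic B-spline free-form
#' deformation composed with the rigid initialization. The cost combines
#' intensity SSD and SSD between truncated signed distance maps of
#' corresponding structures, plus a bending-energy penalty, evaluated
#' inside the focus box.
#'
#' @param fixed planning [ImageVolume-class].
#' @param moving daily [ImageVolume-class].
#' @param fixedStructures,movingStructures [StructureSet-class] contours in
#'   the two frames; structures missing from either set are skipped with a
#'   warning.
#' @param init [RigidTransform-class] initialization (or `NULL`).
#' @param cfg a [registrationConfig()].
#' @param box optional [FocusBox-class]; default built from the fixed
#'   `PTV_eval`.
#' @return a [DisplacementField-class] on the fixed grid, with attributes
#'   `costTrace` (list of per-level accepted-cost traces) and `diagnostics`.
#' @export
registerHybridDeformable <- function(fixed, moving, fixedStructures,
                                     movingStructures, init = NULL,
                                     cfg = registrationConfig(),
                                     box = NULL) {
  g <- fixed@grid
  if (is.null(init)) init <- rigidTransform()
  if (is.null(box)) {
    box <- if (cfg$ringOnly) {
      makeFocusBox(getMask(fixedStructures, "PTV_eval"), g)
    } else {
      new("FocusBox", lower = g@origin,
          upper = g@origin + (g@shape - 1L) * g@spacing)
    }
  }

  # structures driving the contour term
  wanted <- cfg$structures %||% structureNames(fixedStructures)
  shared <- intersect(wanted, structureNames(movingStructures))
  shared <- intersect(shared, structureNames(fixedStructures))
  missing <- setdiff(wanted, shared)
  if (length(missing))
    warning("structures skipped (absent from one side): ",
            paste(missing, collapse = ", "))
  if (cfg$contourWeight > 0 && length(shared) == 0 && cfg$intensityWeight <= 0)
    stop("no shared structures and no intensity term: empty cost")

  # resample moving data through the rigid initialization once
  ax <- latticeAxes(g)
  w0 <- cbind(ax$x * g@spacing[1] + g@origin[1],
              ax$y * g@spacing[2] + g@origin[2],
              ax$z * g@spacing[3] + g@origin[3])
  wr <- transformPoints(init, w0)
  vc <- voxelCoords(moving@grid, wr)
  mov0 <- imageVolume(array(
    cpp_sample_trilinear(moving@voxels, moving@grid@shape,
                         vc[, 1], vc[, 2], vc[, 3], 0), g@shape), g)
  movMasks <- lapply(shared, function(nm) {
    m <- getMask(movingStructures, nm)
    mg <- movingStructures@grid
    vcm <- voxelCoords(mg, wr)
    array(cpp_sample_trilinear(m + 0, mg@shape, vcm[, 1], vcm[, 2],
                               vcm[, 3], 0) >= 0.5, g@shape)
  })
  names(movMasks) <- shared

  # control lattice (mm, fixed across pyramid levels)
  cps <- cfg$controlPointSpacingMm
  nc <- as.integer(ceiling((box@upper - box@lower) / cps)) + 5L
  ctrl_origin_mm <- box@lower - 2 * cps

  nlev <- cfg$pyramidLevels
  maxit <- rep_len(cfg$maxIterations, nlev)
  coef <- numeric(3 * prod(nc))
  traces <- vector("list", nlev)
  level_info <- list()

  for (lev in seq.int(nlev, 1L)) {
    factor <- 2^(lev - 1L)
    fL <- .downsampleVol(fixed, factor)
    mL <- .downsampleVol(mov0, factor)
    gL <- fL@grid
    fixMasksL <- lapply(shared, function(nm)
      .downsampleVol(imageVolume(getMask(fixedStructures, nm) + 0, g),
                     factor)@voxels >= 0.5)
    movMasksL <- lapply(shared, function(nm)
      .downsampleVol(imageVolume(movMasks[[nm]] + 0, g), factor)@voxels >= 0.5)
    names(fixMasksL) <- names(movMasksL) <- shared

    # ROI voxels inside the focus box at this level
    rng <- lapply(1:3, function(a2) {
      lo <- max(0L, ceiling((box@lower[a2] - gL@origin[a2]) / gL@spacing[a2]))
      hi <- min(gL@shape[a2] - 1L,
                floor((box@upper[a2] - gL@origin[a2]) / gL@spacing[a2]))
      seq.int(lo, hi)
    })
    roi <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))

    fixCh <- list(); movCh <- list(); wch <- numeric(0)
    roi_lin <- roi[, 1] + gL@shape[1] * (roi[, 2] + gL@shape[2] * roi[, 3]) + 1
    if (cfg$intensityWeight > 0) {
      fixCh[[length(fixCh) + 1L]] <- fL@voxels[roi_lin]
      movCh[[length(movCh) + 1L]] <- mL@voxels
      wch <- c(wch, NA)                       # normalized below
    }
    nInt <- length(wch)
    if (cfg$contourWeight > 0) {
      for (nm in shared) {
        fixCh[[length(fixCh) + 1L]] <- signedDistanceMap(
          fixMasksL[[nm]], gL, cfg$sdmTruncationMm)[roi_lin]
        movCh[[length(movCh) + 1L]] <- signedDistanceMap(
          movMasksL[[nm]], gL, cfg$sdmTruncationMm)
        wch <- c(wch, NA)
      }
    }
    fixChM <- do.call(cbind, fixCh)

    # per-term normalization to unit initial magnitude (identity field)
    ssd0 <- vapply(seq_along(movCh), function(c2)
      mean((movCh[[c2]][roi_lin] - fixChM[, c2])^2), numeric(1))
    ssd_int <- if (nInt > 0) ssd0[1] else 0
    ssd_con <- if (length(ssd0) > nInt) sum(ssd0[(nInt + 1):length(ssd0)]) else 0
    w_int <- if (nInt > 0) cfg$intensityWeight / max(ssd_int, 1e-9) else numeric(0)
    w_con <- if (length(ssd0) > nInt)
      rep(cfg$contourWeight / max(ssd_con, 1e-9),
          length(ssd0) - nInt) else numeric(0)
    weights <- c(w_int, w_con)

    ctrl_origin_vox <- (ctrl_origin_mm - gL@origin) / gL@spacing
    ctrl_spacing_vox <- cps / gL@spacing
    fngr <- function(par) {
      cpp_ffd_cost_grad(par, nc, ctrl_origin_vox, ctrl_spacing_vox,
                        as.integer(roi[, 1]), as.integer(roi[, 2]),
                        as.integer(roi[, 3]), fixChM, movCh, weights,
                        gL@shape, gL@spacing, cfg$regularizationWeight)
    }
    res <- .bbOptim(coef, fngr, maxit[lev], cfg$convergenceTol)
    if (any(diff(res$trace) > 1e-12))
      stop("divergent registration cost at pyramid level ", lev,
           " (trace: ", paste(format(res$trace), collapse = ", "), ")")
    coef <- res$par
    traces[[nlev - lev + 1L]] <- res$trace
    level_info[[nlev - lev + 1L]] <- list(level = lev,
                                          grid = gL@shape,
                                          roiVoxels = nrow(roi),
                                          finalCost = res$value)
  }

  # dense B-spline field on the full fixed grid, composed with the rigid
  # initialization: planning point x maps to T_rigid(x + u_B(x))
  ctrl_origin_vox <- (ctrl_origin_mm - g@origin) / g@spacing
  ctrl_spacing_vox <- cps / g@spacing
  uB <- cpp_ffd_eval(coef, nc, ctrl_origin_vox, ctrl_spacing_vox,
                     ax$x, ax$y, ax$z)
  xb <- w0 + uB
  ytot <- transformPoints(init, xb)
  u <- ytot - w0
  mag <- sqrt(rowSums(u^2))
  if (max(mag) > cfg$maxDisplacementMm) {
    warning("displacement magnitudes clamped to the configured cap (",
            cfg$maxDisplacementMm, " mm)")
    sc <- pmin(1, cfg$maxDisplacementMm / pmax(mag, 1e-12))
    u <- u * sc
  }
  field <- displacementField(array(u, c(g@shape, 3L)), g)
  attr(field, "costTrace") <- traces
  attr(field, "diagnostics") <- level_info
  field
}
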