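# Synthetic pelvis phantom: planning cases and deformed daily cases with
# known ground-truth displacement fields, emulating a five-fraction 36.25 Gy
# prostate SBRT protocol on a 0.35T MR-linac (1.5 mm isotropic voxels,
# T2/T1-like piecewise-constant contrast).

#' Default organ geometry of the pelvis phantom (mm, world coordinates)
#'
#' Centers are relative to the grid center; sizes are chosen so the PTV_eval
#' volume lands inside the clinically reported range (tens of cc) and every
#' organ fits a 96^3 x 1.5 mm grid or larger.
#'
#' @return named list of organ parameter lists.
#' @export
defaultOrganParams <- function() {
  list(
    prostate    = list(center = c(0, 0, 0),     radii = c(25, 22, 24)),
    urethra     = list(center = c(0, 0, 0),     radius = 3, halfLength = 24,
                       prvExpandMm = 2),
    rectum      = list(center = c(0, 35, 0),    radius = 14, halfLength = 50),
    bladder     = list(center = c(0, -38, 28),  radii = c(28, 24, 24)),
    femur_r     = list(center = c(-48, 0, 0),   radius = 18),
    femur_l     = list(center = c(48, 0, 0),    radius = 18),
    penile_bulb = list(center = c(0, 12, -42),  radii = c(12, 10, 10))
  )
}

#' Default organ intensity levels (arbitrary MR-like units)
#' @return named numeric vector (plus a `background` level).
#' @export
defaultIntensities <- function() {
  c(background = 100, prostate = 160, urethra = 170, rectum = 60,
    bladder = 210, femur_r = 140, femur_l = 140, penile_bulb = 150)
}

#' Construct a phantom specification
#'
#' @param gridShape integer(3), default 128^3.
#' @param spacingMm voxel size in mm (default 1.5 mm isotropic).
#' @param organParams organ geometry, see [defaultOrganParams()].
#' @param intensities organ intensity levels, see [defaultIntensities()].
#' @param noiseSd additive Gaussian intensity noise SD (default 5).
#' @param seed integer RNG seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape = c(128L, 128L, 128L), spacingMm = 1.5,
                        organParams = defaultOrganParams(),
                        intensities = defaultIntensities(),
                        noiseSd = 5, seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacingMm = rep_len(as.numeric(spacingMm), 3L),
      organParams = organParams, intensities = intensities,
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Construct a deformation specification
#'
#' @param bladderFillScale radial bladder scale factor (1 = unchanged).
#' @param rectalBumpMm peak anterior displacement (mm) of a Gaussian bump
#'   centred at the rectum.
#' @param randomFieldAmpMm peak magnitude (mm) of the smooth random
#'   component; must not exceed 0.45 x `randomFieldCorrMm` (invertibility
#'   margin).
#' @param randomFieldCorrMm Gaussian correlation length (mm) of the random
#'   component.
#' @param seed integer RNG seed.
#' @return a [DeformationSpec-class].
#' @export
deformationSpec <- function(bladderFillScale = 1.05, rectalBumpMm = 4,
                            randomFieldAmpMm = 3, randomFieldCorrMm = 40,
                            seed = 1L) {
  new("DeformationSpec", bladderFillScale = as.numeric(bladderFillScale),
      rectalBumpMm = as.numeric(rectalBumpMm),
      randomFieldAmpMm = as.numeric(randomFieldAmpMm),
      randomFieldCorrMm = as.numeric(randomFieldCorrMm),
      seed = as.integer(seed))
}

# Deterministic named RNG substreams derived from one master seed, so the
# geometry, noise and field draws are individually reproducible.
#' @noRd
.substreamSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2654435761) %% 1e9
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483629)
}

#' @noRd
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' @noRd
.organExtent <- function(p) {
  if (!is.null(p$radii)) {
    rbind(p$center - p$radii, p$center + p$radii)
  } else if (!is.null(p$halfLength)) {
    r <- p$radius + (p$prvExpandMm %||% 0)
    h <- p$halfLength + (p$prvExpandMm %||% 0)
    rbind(p$center - c(r, r, h), p$center + c(r, r, h))
  } else {
    rbind(p$center - p$radius, p$center + p$radius)
  }
}

# Rasterize one organ as a logical mask over precomputed world-coordinate
# axis vectors.
#' @noRd
.organMask <- function(p, w, shape, expand = 0) {
  if (!is.null(p$radii)) {                         # ellipsoid
    r <- p$radii + expand
    m <- ((w$x - p$center[1]) / r[1])^2 + ((w$y - p$center[2]) / r[2])^2 +
      ((w$z - p$center[3]) / r[3])^2 <= 1
  } else if (!is.null(p$halfLength)) {             # z-aligned cylinder
    r <- p$radius + expand
    m <- (w$x - p$center[1])^2 + (w$y - p$center[2])^2 <= r^2 &
      abs(w$z - p$center[3]) <= p$halfLength + expand
  } else {                                         # sphere
    m <- (w$x - p$center[1])^2 + (w$y - p$center[2])^2 +
      (w$z - p$center[3])^2 <= (p$radius + expand)^2
  }
  array(m, shape)
}

#' Generate a synthetic planning case
#'
#' Builds the structure set (PTV_eval defined as the prostate PTV minus any
#' OAR overlap), a piecewise-constant MR-like intensity image with additive
#' Gaussian noise, and an analytic plan dose normalized so that PTV_eval
#' D95% equals the prescription.
#'
#' @param spec a [PhantomSpec-class].
#' @param prescriptionGy total prescription dose (default 36.25 Gy).
#' @param nFractions number of fractions (default 5).
#' @param penumbraMm Gaussian dose falloff scale outside the target
#'   (default 5 mm).
#' @return a [CaseBundle-class].
#' @export
generatePlanningCase <- function(spec, prescriptionGy = 36.25,
                                 nFractions = 5L, penumbraMm = 5) {
  grid <- gridDescriptor(spec@gridShape, spec@spacingMm)
  lo <- grid@origin
  hi <- grid@origin + (grid@shape - 1L) * grid@spacing
  for (nm in names(spec@organParams)) {
    ext <- .organExtent(spec@organParams[[nm]])
    if (any(ext[1, ] < lo - 1e-9) || any(ext[2, ] > hi + 1e-9))
      stop("phantom geometry error: organ '", nm,
           "' does not fit inside the grid")
  }

  ax <- latticeAxes(grid)
  w <- list(x = ax$x * grid@spacing[1] + grid@origin[1],
            y = ax$y * grid@spacing[2] + grid@origin[2],
            z = ax$z * grid@spacing[3] + grid@origin[3])

  op <- spec@organParams
  ptv <- .organMask(op$prostate, w, grid@shape)
  urethra <- .organMask(op$urethra, w, grid@shape)
  urethra_prv <- .organMask(op$urethra, w, grid@shape,
                            expand = op$urethra$prvExpandMm %||% 2)
  oars <- list(
    rectum = .organMask(op$rectum, w, grid@shape),
    bladder = .organMask(op$bladder, w, grid@shape),
    urethra_prv = urethra_prv,
    femur_r = .organMask(op$femur_r, w, grid@shape),
    femur_l = .organMask(op$femur_l, w, grid@shape),
    penile_bulb = .organMask(op$penile_bulb, w, grid@shape)
  )
  ptv_eval <- ptv
  for (m in oars) ptv_eval <- ptv_eval & !m
  masks <- c(list(PTV_eval = ptv_eval), oars)
  structures <- structureSet(masks, grid)

  # piecewise-constant intensities; later organs overwrite earlier ones
  img <- array(spec@intensities[["background"]], grid@shape)
  paint <- list(femur_r = oars$femur_r, femur_l = oars$femur_l,
                penile_bulb = oars$penile_bulb, rectum = oars$rectum,
                bladder = oars$bladder, prostate = ptv, urethra = urethra)
  for (nm in names(paint)) img[paint[[nm]]] <- spec@intensities[[nm]]
  if (spec@noiseSd > 0)
    img <- img + .withSeed(.substreamSeed(spec@seed, "noise"),
                           array(rnorm(length(img), sd = spec@noiseSd),
                                 dim(img)))
  dose <- makePlanDose(structures, prescriptionGy = prescriptionGy,
                       penumbraMm = penumbraMm)
  new("CaseBundle", image = imageVolume(img, grid), structures = structures,
      planDose = dose, nFractions = as.integer(nFractions),
      prescriptionGy = prescriptionGy)
}

#' Analytic plan dose: near-uniform in the target, Gaussian falloff outside
#'
#' Inside PTV_eval the dose is the prescription with a small center-peaked
#' heterogeneity (up to `heterogeneity`, emulating a realistic SBRT hot
#' spot); outside it falls off as `exp(-d^2 / (2 penumbraMm^2))` with the
#' Euclidean distance d to the target. The whole distribution is then
#' rescaled globally (iteratively, since the DVH is binned) so that
#' PTV_eval D95% equals the prescription to within half a DVH bin.
#'
#' @param structures a [StructureSet-class] containing `PTV_eval`.
#' @param prescriptionGy total prescription (Gy).
#' @param penumbraMm Gaussian falloff scale (mm).
#' @param binGy DVH bin width used for the D95% normalization.
#' @param heterogeneity fractional intra-target dose peak (default 0.04).
#' @return an [ImageVolume-class] in Gy.
#' @export
makePlanDose <- function(structures, prescriptionGy = 36.25, penumbraMm = 5,
                         binGy = 0.01, heterogeneity = 0.04) {
  grid <- structures@grid
  ptv <- getMask(structures, "PTV_eval")
  if (!any(ptv)) stop("PTV_eval is empty: cannot build a plan dose")
  d_out <- sqrt(cpp_edt_sq(as.vector(ptv), grid@shape, grid@spacing))
  dose <- prescriptionGy * exp(-d_out^2 / (2 * penumbraMm^2))
  if (heterogeneity > 0) {
    d_in <- sqrt(cpp_edt_sq(as.vector(!ptv), grid@shape, grid@spacing))
    ref <- max(d_in)
    if (ref > 0)
      dose <- dose * (1 + heterogeneity * pmin(d_in / ref, 1))
  }
  dose <- array(dose, grid@shape)
  # the binned DVH makes D95 a piecewise quantity: a couple of fixed-point
  # rescales land it within half a bin of the prescription (the target is
  # biased a quarter bin high so target coverage V_Rx stays >= 95%)
  target <- prescriptionGy + binGy / 4
  for (it in 1:4) {
    d95 <- dvhMetric(computeDVH(imageVolume(dose, grid), ptv, binGy = binGy),
                     "D95%")
    if (abs(d95 - prescriptionGy) <= binGy / 2 && d95 >= prescriptionGy) break
    dose <- dose * (target / d95)
  }
  imageVolume(dose, grid)
}

# Smooth random vector field: white noise on a coarse lattice (spacing =
# correlation length / 2), Gaussian-smoothed, trilinearly upsampled, then
# normalized to the requested peak magnitude.
#' @noRd
.smoothRandomField <- function(grid, ampMm, corrMm, seed) {
  if (ampMm <= 0) return(array(0, c(grid@shape, 3L)))
  extent <- (grid@shape - 1L) * grid@spacing
  cs <- corrMm / 2
  nshape <- pmax(4L, as.integer(ceiling(extent / cs)) + 3L)
  coarse <- gridDescriptor(nshape, cs,
                           origin = grid@origin - cs)
  comps <- .withSeed(seed, lapply(1:3, function(i)
    array(rnorm(prod(nshape)), nshape)))
  g <- dnorm(-2:2); g <- g / sum(g)                 # sigma = 1 coarse voxel
  smooth1 <- function(a, dim) {
    out <- array(0, dim(a))
    n <- dim(a)[dim]
    for (t in seq_along(g)) {
      off <- t - 3L
      src <- pmin(pmax(seq_len(n) + off, 1L), n)
      idx <- switch(dim, list(src, TRUE, TRUE), list(TRUE, src, TRUE),
                    list(TRUE, TRUE, src))
      out <- out + g[t] * do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    }
    out
  }
  comps <- lapply(comps, function(a) smooth1(smooth1(smooth1(a, 1L), 2L), 3L))
  up <- lapply(comps, function(a)
    resampleToGrid(imageVolume(a, coarse), grid)@voxels)
  mag <- sqrt(up[[1]]^2 + up[[2]]^2 + up[[3]]^2)
  scale <- ampMm / max(mag)
  field <- array(0, c(grid@shape, 3L))
  for (i in 1:3) field[, , , i] <- up[[i]] * scale
  field
}

#' Synthesize a ground-truth displacement field
#'
#' Sum of three smooth components on the planning grid (pull-back
#' convention): radial bladder filling, an anterior Gaussian rectal bump,
#' and a smooth random field. The Jacobian determinant of the resulting map
#' is checked numerically and must be positive everywhere.
#'
#' @param spec a [DeformationSpec-class].
#' @param grid planning [GridDescriptor-class].
#' @param organParams organ geometry (bladder/rectum centers); defaults to
#'   [defaultOrganParams()].
#' @param rectalBumpSigmaMm width (mm) of the Gaussian rectal bump.
#' @return a [DisplacementField-class].
#' @export
synthDisplacementField <- function(spec, grid,
                                   organParams = defaultOrganParams(),
                                   rectalBumpSigmaMm = 15) {
  validObject(spec)
  ax <- latticeAxes(grid)
  wx <- ax$x * grid@spacing[1] + grid@origin[1]
  wy <- ax$y * grid@spacing[2] + grid@origin[2]
  wz <- ax$z * grid@spacing[3] + grid@origin[3]
  field <- .smoothRandomField(grid, spec@randomFieldAmpMm,
                              spec@randomFieldCorrMm,
                              .substreamSeed(spec@seed, "field"))

  if (spec@bladderFillScale != 1) {
    c_b <- organParams$bladder$center
    sigma <- mean(organParams$bladder$radii)
    dx <- wx - c_b[1]; dy <- wy - c_b[2]; dz <- wz - c_b[3]
    env <- (spec@bladderFillScale - 1) * exp(-(dx^2 + dy^2 + dz^2) /
                                               (2 * sigma^2))
    field[, , , 1] <- field[, , , 1] + env * dx
    field[, , , 2] <- field[, , , 2] + env * dy
    field[, , , 3] <- field[, , , 3] + env * dz
  }
  if (spec@rectalBumpMm > 0) {
    c_r <- organParams$rectum$center
    r2 <- (wx - c_r[1])^2 + (wy - c_r[2])^2 + (wz - c_r[3])^2
    # anterior push (toward -y)
    field[, , , 2] <- field[, , , 2] -
      spec@rectalBumpMm * exp(-r2 / (2 * rectalBumpSigmaMm^2))
  }
  out <- displacementField(field, grid)
  if (spec@rectalBumpMm > 0 || spec@randomFieldAmpMm > 0 ||
      spec@bladderFillScale != 1) {
    jmin <- min(jacobianDeterminant(out))
    if (jmin <= 0)
      stop("deformation parameter error: the displacement field folds ",
           "(min Jacobian determinant = ", format(jmin), ")")
  }
  out
}

#' Jacobian determinant of the mapping x + u(x), by central differences
#'
#' @param field a [DisplacementField-class].
#' @return 3D array of determinant values (1 for the identity field).
#' @export
jacobianDeterminant <- function(field) {
  v <- field@vectors
  sp <- field@grid@spacing
  d <- function(comp, axis) {
    a <- v[, , , comp]
    n <- dim(a)[axis]
    hi <- pmin(seq_len(n) + 1L, n)
    lo <- pmax(seq_len(n) - 1L, 1L)
    den <- (hi - lo) * sp[axis]
    pick <- function(src) switch(axis,
      a[src, , , drop = FALSE], a[, src, , drop = FALSE],
      a[, , src, drop = FALSE])
    diff <- pick(hi) - pick(lo)
    sweep(diff, axis, den, `/`)
  }
  j11 <- 1 + d(1, 1); j12 <- d(1, 2); j13 <- d(1, 3)
  j21 <- d(2, 1); j22 <- 1 + d(2, 2); j23 <- d(2, 3)
  j31 <- d(3, 1); j32 <- d(3, 2); j33 <- 1 + d(3, 3)
  det <- j11 * (j22 * j33 - j23 * j32) - j12 * (j21 * j33 - j23 * j31) +
    j13 * (j21 * j32 - j22 * j31)
  array(det, dim(v)[1:3])
}

# Numerically invert a pull-back field u (planning -> daily) to the forward
# resampling field v on the daily grid with v(q) = -u(q + v(q)).
#' @noRd
.invertField <- function(field, iters = 15L) {
  g <- field@grid
  ax <- latticeAxes(g)
  wx <- ax$x * g@spacing[1] + g@origin[1]
  wy <- ax$y * g@spacing[2] + g@origin[2]
  wz <- ax$z * g@spacing[3] + g@origin[3]
  ux <- field@vectors[, , , 1]; uy <- field@vectors[, , , 2]
  uz <- field@vectors[, , , 3]
  vx <- vy <- vz <- numeric(length(wx))
  for (it in seq_len(iters)) {
    cx <- (wx + vx - g@origin[1]) / g@spacing[1]
    cy <- (wy + vy - g@origin[2]) / g@spacing[2]
    cz <- (wz + vz - g@origin[3]) / g@spacing[3]
    vx <- -cpp_sample_trilinear(ux, g@shape, cx, cy, cz, 0)
    vy <- -cpp_sample_trilinear(uy, g@shape, cx, cy, cz, 0)
    vz <- -cpp_sample_trilinear(uz, g@shape, cx, cy, cz, 0)
  }
  out <- array(0, c(g@shape, 3L))
  out[, , , 1] <- vx; out[, , , 2] <- vy; out[, , , 3] <- vz
  displacementField(out, g)
}

#' Generate a deformed daily case from a planning case
#'
#' The daily image and contours are the planning ones pushed through the
#' ground-truth deformation (the pull-back truth field is inverted
#' numerically to resample in the forward direction). The delivered
#' fraction dose is a per-fraction re-plan on the daily anatomy: the
#' analytic plan dose recomputed on the warped structures and scaled to one
#' fraction.
#'
#' @param planning a [CaseBundle-class].
#' @param deform a [DeformationSpec-class].
#' @param fractionIndex integer in 1..nFractions.
#' @param organParams organ geometry used for the deformation components.
#' @param deliveryPerturbGy optional uniform dose perturbation (Gy, one
#'   fraction) emulating delivery deviation; default 0.
#' @param penumbraMm falloff scale for the daily re-plan dose.
#' @return a [DailyCase-class].
#' @export
generateDailyCase <- function(planning, deform, fractionIndex,
                              organParams = defaultOrganParams(),
                              deliveryPerturbGy = 0, penumbraMm = 5) {
  fractionIndex <- as.integer(fractionIndex)
  if (fractionIndex < 1L || fractionIndex > planning@nFractions)
    stop("fractionIndex must lie in 1..", planning@nFractions)
  grid <- planning@image@grid
  truth <- synthDisplacementField(deform, grid, organParams = organParams)

  if (maxDisplacement(truth) == 0) {
    image <- planning@image
    structures <- planning@structures
  } else {
    fwd <- .invertField(truth)
    image <- warpImage(fwd, planning@image)
    structures <- warpStructureSet(fwd, planning@structures)
  }
  daily_total <- makePlanDose(structures,
                              prescriptionGy = planning@prescriptionGy,
                              penumbraMm = penumbraMm)
  # identity deformation must reproduce the planning dose exactly
  if (maxDisplacement(truth) == 0) daily_total <- planning@planDose
  delivered <- scaleToOneFraction(daily_total, planning@nFractions)
  if (deliveryPerturbGy != 0)
    delivered <- imageVolume(pmax(delivered@voxels + deliveryPerturbGy, 0),
                             grid)
  new("DailyCase", image = image, structures = structures,
      deliveredFractionDose = delivered, truthField = truth,
      fractionIndex = fractionIndex)
}
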