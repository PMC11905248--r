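# Synthetic phantom: determinism, geometry oracles, ground-truth
# deformation fields and daily-case construction.

test_that("same seed gives a bit-identical phantom", {
  s <- phantomSpec(gridShape = c(48, 48, 48), spacingMm = 3, seed = 42L)
  a <- generatePlanningCase(s)
  b <- generatePlanningCase(s)
  expect_identical(voxels(a@image), voxels(b@image))
  expect_identical(voxels(a@planDose), voxels(b@planDose))
  expect_identical(a@structures@masks, b@structures@masks)
})

test_that("default-geometry PTV_eval volume lies in the clinical range", {
  case <- planning_case_96()
  vol <- sum(getMask(case@structures, "PTV_eval")) *
    voxelVolumeCc(imageGrid(case@image))
  expect_gt(vol, 30)
  expect_lt(vol, 110)
})

test_that("an isolated PTV matches the analytic ellipsoid volume", {
  # organs far apart so no OAR carves voxels out of the PTV
  op <- defaultOrganParams()
  op$rectum$center <- c(0, 55, 0); op$rectum$halfLength <- 10
  op$bladder$center <- c(0, -50, 40); op$bladder$radii <- c(10, 10, 10)
  op$urethra$radius <- 0.1; op$urethra$halfLength <- 0.1
  op$penile_bulb$center <- c(0, 12, -55)
  spec <- phantomSpec(gridShape = c(96, 96, 96), organParams = op,
                      noiseSd = 0, seed = 2L)
  case <- generatePlanningCase(spec)
  vol <- sum(getMask(case@structures, "PTV_eval")) *
    voxelVolumeCc(imageGrid(case@image))
  r <- op$prostate$radii
  analytic <- 4 / 3 * pi * prod(r) / 1000
  expect_lt(abs(vol - analytic) / analytic, 0.05)
})

test_that("PTV_eval excludes every OAR voxel by construction", {
  case <- planning_case_96()
  ptv <- getMask(case@structures, "PTV_eval")
  for (nm in setdiff(structureNames(case@structures), "PTV_eval"))
    expect_equal(sum(ptv & getMask(case@structures, nm)), 0,
                 info = nm)
})

test_that("organs that do not fit the grid raise a geometry error", {
  op <- defaultOrganParams()
  op$femur_l$center <- c(200, 0, 0)
  expect_error(
    generatePlanningCase(phantomSpec(gridShape = c(96, 96, 96),
                                     organParams = op)),
    "femur_l")
})

test_that("plan dose: D95 normalization, penumbra tail and ceiling", {
  case <- planning_case_96()
  g <- imageGrid(case@image)
  ptv <- getMask(case@structures, "PTV_eval")
  curve <- computeDVH(case@planDose, ptv)
  expect_lt(abs(dvhMetric(curve, "D95%") - 36.25), 0.005 + 1e-9)
  # Gaussian tail: < 1% of prescription at >= 5 penumbra widths
  d <- sqrt(array(doseAccum:::cpp_edt_sq(as.vector(ptv), g@shape,
                                         g@spacing), g@shape))
  far <- d >= 25
  expect_lt(max(voxels(case@planDose)[far]), 0.01 * 36.25)
  # institutional ceiling (hottest 0.03 cc below 43.50 Gy)
  expect_lt(dvhMetric(curve, "D0.03cc"), 43.50)
  expect_error(makePlanDose(structureSet(
    list(PTV_eval = array(FALSE, c(4, 4, 4))),
    gridDescriptor(c(4, 4, 4), 1))), "empty")
})

test_that("zero-amplitude deformation is the identity field", {
  g <- gridDescriptor(c(32, 32, 32), 3)
  fld <- synthDisplacementField(identity_deform_spec(), g)
  expect_true(all(fieldVectors(fld) == 0))
})

test_that("rectal bump peak displacement is attained on the lattice", {
  case <- planning_case_96()
  fld <- synthDisplacementField(
    deformationSpec(bladderFillScale = 1, rectalBumpMm = 8,
                    randomFieldAmpMm = 0, seed = 1L),
    imageGrid(case@image))
  expect_gte(maxDisplacement(fld), 7.2)
  expect_lte(maxDisplacement(fld), 8.0)
})

test_that("synthetic fields keep a positive Jacobian determinant", {
  g <- gridDescriptor(c(64, 64, 64), 2.25)
  fld <- synthDisplacementField(
    deformationSpec(bladderFillScale = 1.06, rectalBumpMm = 6,
                    randomFieldAmpMm = 5, randomFieldCorrMm = 40,
                    seed = 7L), g)
  expect_gt(min(jacobianDeterminant(fld)), 0)
  expect_lte(maxDisplacement(fld), 5 + 6 + 0.06 * mean(c(28, 24, 24)))
})

test_that("the invertibility margin is enforced as a parameter error", {
  expect_error(deformationSpec(randomFieldAmpMm = 20, randomFieldCorrMm = 40),
               "margin")
})

test_that("identity deformation reproduces the planning case bit-exactly", {
  case <- planning_case_96()
  daily <- generateDailyCase(case, identity_deform_spec(), 1L)
  expect_identical(voxels(daily@image), voxels(case@image))
  expect_identical(daily@structures@masks, case@structures@masks)
  expect_equal(voxels(daily@deliveredFractionDose),
               voxels(case@planDose) / 5, tolerance = 1e-12)
})

test_that("fraction index outside 1..N is rejected", {
  case <- planning_case_96()
  expect_error(generateDailyCase(case, identity_deform_spec(), 6L), "1..5")
})

test_that("warped daily rectum volume stays near the planning volume", {
  case <- planning_case_96()
  daily <- deformed_daily_96()
  v0 <- sum(getMask(case@structures, "rectum"))
  v1 <- sum(getMask(daily@structures, "rectum"))
  expect_lt(abs(v1 - v0) / v0, 0.15)
})

test_that("truth fields are numerically invertible on the intensity image", {
  # noise-free phantom so the round trip error is purely geometric
  spec <- phantomSpec(gridShape = c(96, 96, 96), noiseSd = 0, seed = 1L)
  case <- generatePlanningCase(spec)
  daily <- generateDailyCase(case, truth_deform_spec(), 1L)
  back <- warpImage(daily@truthField, daily@image)
  rng <- diff(range(voxels(case@image)))
  err <- abs(voxels(back) - voxels(case@image)) / rng
  # away from boundaries: exclude the grid margin and organ interfaces
  g <- imageGrid(case@image)
  interface <- array(FALSE, g@shape)
  for (nm in structureNames(case@structures)) {
    sdm <- signedDistanceMap(getMask(case@structures, nm), g, truncMm = 20)
    interface <- interface | abs(sdm) < 9   # clear of displaced interfaces
  }
  margin <- array(TRUE, g@shape)
  margin[7:90, 7:90, 7:90] <- FALSE
  keep <- !interface & !margin
  expect_gt(sum(keep), 1e5)
  expect_lt(max(err[keep]), 0.02)
})
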