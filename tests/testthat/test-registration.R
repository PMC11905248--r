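# Focus box construction, rigid alignment, warping operators and hybrid
# deformable recovery of known ground-truth transforms.

test_that("focus box applies the 30/30/20 mm margins and clips to the grid", {
  g <- gridDescriptor(c(96, 96, 96), 1.5)
  m <- array(FALSE, g@shape)
  m[41:56, 45:52, 44:53] <- TRUE                 # bbox widths 22.5/10.5/13.5
  box <- makeFocusBox(m, g)
  expect_equal(box@upper[1] - box@lower[1], 22.5 + 60)   # RL: +30 per side
  expect_equal(box@upper[2] - box@lower[2], 10.5 + 60)   # AP: +30 per side
  expect_equal(box@upper[3] - box@lower[3], 13.5 + 40)   # SI: +20 per side

  zero <- makeFocusBox(m, g, marginsMm = c(0, 0, 0))
  idx <- which(m, arr.ind = TRUE) - 1L
  expect_equal(zero@lower, as.numeric(gridOrigin(g) +
                                        apply(idx, 2, min) * 1.5))
  expect_equal(zero@upper, as.numeric(gridOrigin(g) +
                                        apply(idx, 2, max) * 1.5))

  edge <- array(FALSE, g@shape); edge[1:10, 1:10, 1:10] <- TRUE
  boxe <- makeFocusBox(edge, g)
  expect_equal(boxe@lower, as.numeric(gridOrigin(g)))
  expect_error(makeFocusBox(array(FALSE, g@shape), g), "empty")
})

test_that("rigid transforms compose with their inverse to identity", {
  tr <- rigidTransform(angles = c(0.1, -0.05, 0.2),
                       translation = c(4, -3, 2), center = c(10, 0, -5))
  inv <- invertRigid(tr)
  pts <- matrix(rnorm(30, sd = 50), ncol = 3)
  back <- transformPoints(inv, transformPoints(tr, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("self rigid registration returns the identity", {
  case <- planning_case_96()
  box <- makeFocusBox(getMask(case@structures, "PTV_eval"),
                      imageGrid(case@image))
  tr <- registerRigid(case@image, case@image, box)
  expect_lt(max(abs(tr@translation)), 0.1)
  expect_lt(max(abs(tr@angles)), 1e-3)
  expect_gt(attr(tr, "metric"), 0.999)
})

test_that("known translations and rotations are recovered in the box", {
  case <- planning_case_96()
  g <- imageGrid(case@image)
  box <- makeFocusBox(getMask(case@structures, "PTV_eval"), g)
  # content shifted by +t: moving(q) = fixed(q - t)
  t_true <- c(4, -3, 2)
  mg <- gridDescriptor(g@shape, g@spacing, gridOrigin(g) + t_true)
  mov <- resampleToGrid(imageVolume(voxels(case@image), mg), g)
  tr <- registerRigid(case@image, mov, box)
  expect_lt(max(abs(tr@translation - t_true)), 0.5 * 1.5)  # 0.5 voxel
  expect_lt(max(abs(tr@angles)), 0.5 * pi / 180)

  # 3 degrees about SI through the box center
  th <- 3 * pi / 180
  ctr <- (box@lower + box@upper) / 2
  rot <- rigidTransform(angles = c(0, 0, th), center = ctr)
  ax <- expand.grid(x = 0:(g@shape[1] - 1), y = 0:(g@shape[2] - 1),
                    z = 0:(g@shape[3] - 1))
  w <- worldCoords(g, as.matrix(ax))
  src <- transformPoints(invertRigid(rot), w)
  movr <- imageVolume(array(sampleVolume(case@image, src), g@shape), g)
  tr2 <- registerRigid(case@image, movr, box)
  expect_lt(abs(tr2@angles[3] - th), 0.5 * pi / 180)
  expect_lt(max(abs(tr2@angles[1:2])), 0.5 * pi / 180)
})

test_that("warp operators: identity and exact integer shifts", {
  g <- gridDescriptor(c(24, 24, 24), 1, origin = c(0, 0, 0))
  m <- array(FALSE, g@shape); m[8:15, 9:14, 10:13] <- TRUE
  img <- array(rnorm(prod(g@shape)), g@shape)
  id <- identityField(g)
  expect_identical(warpMask(id, m), m)
  expect_identical(voxels(warpImage(id, imageVolume(img, g))), img)

  shift <- displacementField(array(rep(c(3, 0, 0),
                                       each = prod(g@shape)),
                                   c(g@shape, 3)), g)
  wm <- warpMask(shift, m)
  expect_identical(wm[5:12, 9:14, 10:13], m[8:15, 9:14, 10:13])
  expect_equal(sum(wm), sum(m))
  wi <- voxels(warpImage(shift, imageVolume(img, g)))
  expect_identical(wi[1:21, , ], img[4:24, , ])
})

test_that("truth-field warping brings daily masks back onto planning ones", {
  case <- planning_case_96()
  daily <- deformed_daily_96()
  wb <- warpMask(daily@truthField, getMask(daily@structures, "bladder"))
  gi <- geometricIndices(wb, getMask(case@structures, "bladder"),
                         imageGrid(case@image))
  expect_gte(gi@dice, 0.98)
})

test_that("self deformable registration yields a near-zero field", {
  case <- planning_case_96()
  fld <- registerHybridDeformable(case@image, case@image, case@structures,
                                  case@structures,
                                  cfg = registrationConfig())
  expect_lt(maxDisplacement(fld), 0.2)
})

test_that("hybrid registration recovers a smooth truth field", {
  case <- planning_case_96()
  daily <- deformed_daily_96()
  fld <- hybrid_field_96()
  g <- imageGrid(case@image)
  w <- warpMask(fld, getMask(daily@structures, "PTV_eval"))
  gi <- geometricIndices(w, getMask(case@structures, "PTV_eval"), g)
  expect_gte(gi@dice, 0.95)
  expect_lte(gi@hdMeanMm, 1.5)                   # one voxel
  # cost decreases monotonically within every pyramid level
  for (trace in attr(fld, "costTrace")) {
    expect_true(all(diff(trace) <= 1e-12))
    expect_gt(length(trace), 1)
  }
})

test_that("the contour term alone aligns structures (intensity weight 0)", {
  case <- planning_case_96()
  daily <- deformed_daily_96()
  g <- imageGrid(case@image)
  cfg <- registrationConfig(intensityWeight = 0, contourWeight = 1,
                            structures = c("PTV_eval", "rectum", "bladder"))
  fld <- registerHybridDeformable(case@image, daily@image, case@structures,
                                  daily@structures, cfg = cfg)
  w <- warpMask(fld, getMask(daily@structures, "rectum"))
  gi <- geometricIndices(w, getMask(case@structures, "rectum"), g)
  expect_lte(gi@hdMeanMm, 1.5)                   # one voxel
})

test_that("structures missing from one side are skipped with a warning", {
  case <- planning_case_96()
  daily <- deformed_daily_96()
  partial <- structureSet(daily@structures@masks[c("PTV_eval", "rectum")],
                          daily@structures@grid)
  expect_warning(
    registerHybridDeformable(case@image, daily@image, case@structures,
                             partial,
                             cfg = registrationConfig(
                               pyramidLevels = 1L, maxIterations = 2L)),
    "skipped")
})
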