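# Orchestration: per-fraction stage sequence, error containment, report
# determinism, and the manual-vs-automated comparison machinery.

test_that("an identity daily case leaves the composite at the plan", {
  case <- planning_case_96()
  daily <- generateDailyCase(case, identity_deform_spec(), 1L)
  state <- compositeState(case@planDose, case@nFractions)
  out <- runFraction(case, daily, state, light_workflow_config())
  expect_true(out$result$ok)
  expect_lt(max(abs(voxels(compositeDose(out$state)) -
                      voxels(case@planDose))), 1e-6)
  expect_false(out$result$adaptationFlag)
  # stage order follows the pipeline
  expect_equal(out$result$stages,
               c("focus_box", "rigid", "deformable", "warp_dose",
                 "composite", "evaluate"))
})

test_that("a deformed fraction recovers the truth-warped target", {
  case <- planning_case_96()
  daily <- deformed_daily_96()
  state <- compositeState(case@planDose, case@nFractions)
  cfg <- workflowConfig()                        # default registration
  out <- runFraction(case, daily, state, cfg)
  expect_true(out$result$ok)
  w_est <- warpMask(out$result$field, getMask(daily@structures, "PTV_eval"))
  w_truth <- warpMask(daily@truthField, getMask(daily@structures, "PTV_eval"))
  gi <- geometricIndices(w_est, w_truth, imageGrid(case@image))
  expect_gte(gi@dice, 0.95)
})

test_that("a duplicate fraction aborts and leaves the state unchanged", {
  case <- planning_case_96()
  daily <- generateDailyCase(case, identity_deform_spec(), 1L)
  state <- compositeState(case@planDose, case@nFractions)
  cfg <- light_workflow_config()
  out1 <- runFraction(case, daily, state, cfg)
  out2 <- runFraction(case, daily, out1$state, cfg)
  expect_false(out2$result$ok)
  expect_match(out2$result$error, "already")
  expect_identical(voxels(compositeDose(out2$state)),
                   voxels(compositeDose(out1$state)))
})

test_that("a patient with a missing fraction yields a partial report", {
  case <- planning_case_96()
  dailies <- lapply(1:5, function(k)
    generateDailyCase(case, identity_deform_spec(), k))
  dailies[3] <- list(NULL)
  rep_ <- runPatient(list(planning = case, dailies = dailies, label = "px"),
                     light_workflow_config())
  expect_true(rep_$partial)
  expect_false(rep_$fractions[[3]]$ok)
  expect_equal(rep_$nAccumulated, 4L)
  expect_true(all(vapply(rep_$fractions[c(1, 2, 4, 5)],
                         function(f) f$ok, logical(1))))
})

test_that("identity patients report zero discrepancies end to end", {
  case <- planning_case_96()
  dailies <- lapply(1:5, function(k)
    generateDailyCase(case, identity_deform_spec(), k))
  rep_ <- runPatient(list(planning = case, dailies = dailies, label = "p0"),
                     light_workflow_config())
  expect_false(rep_$partial)
  expect_equal(unlist(rep_$percentDiscrepancy), c("V34.4Gy" = 0,
                                                  "V36.25Gy" = 0))
  expect_equal(unlist(rep_$doseDifferencesGy),
               c("D95%" = 0, "D0.03cc" = 0))
  expect_equal(rep_$gammaPassRatePct, 100)
  expect_false(rep_$adaptationFlag)
})

test_that("reports are byte-identical across reruns up to the timestamp", {
  case <- planning_case_96()
  dailies <- lapply(1:2, function(k)
    generateDailyCase(case, truth_deform_spec(), k))
  shrink <- function(case, dailies) {
    planning <- case
    planning@nFractions <- 2L
    list(planning = planning, dailies = dailies, label = "pdet")
  }
  cfg <- light_workflow_config()
  r1 <- runPatient(shrink(case, dailies), cfg)
  r2 <- runPatient(shrink(case, dailies), cfg)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- writeReport(r1, d1); p2 <- writeReport(r2, d2)
  j1 <- jsonlite::read_json(p1); j2 <- jsonlite::read_json(p2)
  j1$timestamp <- j2$timestamp <- NULL
  j1$fractions <- lapply(j1$fractions, function(f) { f$timingsSec <- NULL; f })
  j2$fractions <- lapply(j2$fractions, function(f) { f$timingsSec <- NULL; f })
  expect_identical(j1, j2)
})

test_that("comparing a workflow with itself gives perfect agreement", {
  case <- planning_case_96()
  daily <- deformed_daily_96()
  fields <- list(daily@truthField, daily@truthField)
  cmp <- compareWorkflows(fields, fields,
                          structures = daily@structures,
                          dosesA = list(case@planDose, case@planDose),
                          dosesB = list(case@planDose, case@planDose),
                          dvhMask = getMask(case@structures, "PTV_eval"))
  expect_true(all(cmp$geometric$dice == 1))
  expect_true(all(cmp$geometric$hdMaxMm == 0))
  expect_true(all(cmp$tTest == 1))
  expect_error(compareWorkflows(fields, fields[1], daily@structures),
               "equal fraction")
})

test_that("computed-vs-truth comparison aggregates per-fraction indices", {
  case <- planning_case_96()
  daily <- deformed_daily_96()
  est <- hybrid_field_96()
  cmp <- compareWorkflows(list(est), list(daily@truthField),
                          structures = structureSet(
                            daily@structures@masks[c("PTV_eval", "bladder")],
                            daily@structures@grid))
  expect_equal(nrow(cmp$geometric), 2L)
  # aggregation matches direct recomputation
  for (nm in c("PTV_eval", "bladder")) {
    ga <- warpMask(est, getMask(daily@structures, nm))
    gb <- warpMask(daily@truthField, getMask(daily@structures, nm))
    gi <- geometricIndices(ga, gb, imageGrid(case@image))
    row <- cmp$aggregate[cmp$aggregate$structure == nm, ]
    expect_equal(row$diceMean, gi@dice)
    expect_equal(row$hdMaxMeanMm, gi@hdMaxMm)
  }
  expect_gte(min(cmp$geometric$dice), 0.9)
})
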