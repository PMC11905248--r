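# Shared fixtures, built once per test run and cached. Desk-scale grids:
# 96^3 at the phantom's native 1.5 mm spacing for registration-bearing
# tests, smaller grids for arithmetic-only tests.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, builder(), envir = .fixture_cache)
  .fixture_cache[[key]]
}

planning_case_96 <- function() {
  .cached("case96", function()
    generatePlanningCase(phantomSpec(gridShape = c(96, 96, 96), seed = 1L)))
}

# a moderate (<= 8 mm) ground-truth deformation and its daily case
truth_deform_spec <- function() {
  deformationSpec(bladderFillScale = 1.06, rectalBumpMm = 6,
                  randomFieldAmpMm = 4, randomFieldCorrMm = 40, seed = 7L)
}

deformed_daily_96 <- function() {
  .cached("daily96", function()
    generateDailyCase(planning_case_96(), truth_deform_spec(), 1L))
}

# hybrid registration of the deformed daily case (shared by the recovery
# tests and the acceptance suite)
hybrid_field_96 <- function() {
  .cached("hybrid96", function() {
    case <- planning_case_96()
    daily <- deformed_daily_96()
    box <- makeFocusBox(getMask(case@structures, "PTV_eval"),
                        imageGrid(case@image))
    rigid <- registerRigid(case@image, daily@image, box)
    registerHybridDeformable(case@image, daily@image, case@structures,
                             daily@structures, init = rigid,
                             cfg = registrationConfig(), box = box)
  })
}

# identity deformation (all amplitudes zero)
identity_deform_spec <- function() {
  deformationSpec(bladderFillScale = 1, rectalBumpMm = 0,
                  randomFieldAmpMm = 0, randomFieldCorrMm = 40, seed = 1L)
}

# light registration settings for multi-patient batch runs
light_workflow_config <- function() {
  workflowConfig(
    registration = registrationConfig(pyramidLevels = 2L,
                                      maxIterations = c(15L, 5L),
                                      structures = c("PTV_eval", "rectum",
                                                     "bladder")),
    rigid = list(maxIterations = 60L, strideVox = 3L, startRangeMm = 6,
                 startStepMm = 6))
}

# small uniform-dose helper
uniform_dose <- function(value, shape = c(12, 12, 12), spacing = 1) {
  imageVolume(array(value, shape), gridDescriptor(shape, spacing))
}
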