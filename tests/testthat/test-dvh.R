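# DVH engine: examples with analytic answers, the voxel-sorting oracle,
# metric monotonicity/consistency, discrepancy arithmetic and the
# replanning trigger.

# brute-force voxel-sorting oracle for Dx% (minimum dose to the hottest x%)
sorted_dx <- function(vals, x) {
  s <- sort(vals, decreasing = TRUE)
  s[max(1L, ceiling(length(s) * x / 100))]
}

test_that("uniform and ramp doses give analytic DVH values", {
  g <- gridDescriptor(c(10, 10, 10), 1, origin = c(0, 0, 0))
  mask <- array(TRUE, c(10, 10, 10))
  uni <- imageVolume(array(10, c(10, 10, 10)), g)
  curve <- computeDVH(uni, mask)
  expect_equal(curve@totalVolumeCc, 1.0)
  expect_equal(dvhMetric(curve, "V10Gy"), 100)
  expect_equal(dvhMetric(curve, "V10Gy", unit = "cc"), 1.0)
  expect_equal(dvhMetric(curve, "V10.01Gy"), 0)
  expect_equal(dvhMetric(curve, "V0Gy"), 100)

  ramp_vals <- array(rep(seq(0, 40, length.out = 1000)), c(10, 10, 10))
  ramp <- imageVolume(ramp_vals, g)
  rc <- computeDVH(ramp, mask)
  expect_lt(abs(dvhMetric(rc, "V20Gy") - 50), 0.15)
  expect_lt(abs(dvhMetric(rc, "D50%") - 20), 0.05)
  # uniform prescription structure reads back the prescription
  rx <- computeDVH(imageVolume(array(36.25, c(10, 10, 10)), g), mask)
  expect_lt(abs(dvhMetric(rx, "D95%") - 36.25), 0.005 + 1e-9)
})

test_that("empty masks and out-of-range metrics raise errors", {
  uni <- uniform_dose(5)
  expect_error(computeDVH(uni, array(FALSE, c(12, 12, 12)),
                          structure = "rectum"), "rectum")
  curve <- computeDVH(uni, array(TRUE, c(12, 12, 12)))
  expect_error(dvhMetric(curve, "D99999cc"), "exceeds")
  expect_error(dvhMetric(curve, "Q5%"), "unrecognized")
})

test_that("the binned engine matches the sorting oracle on random fields", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(50:400, 1)
    vals <- runif(n, 0, 45)
    g <- gridDescriptor(c(n, 1, 1), 1)
    dose <- imageVolume(array(vals, c(n, 1, 1)), g)
    curve <- computeDVH(dose, array(TRUE, c(n, 1, 1)))
    x <- runif(1, 5, 95)
    expect_lt(abs(dvhMetric(curve, sprintf("D%.6g%%", x)) -
                    sorted_dx(vals, x)), 0.01 + 1e-9)
  }
})

test_that("DVH metrics are monotone and self-consistent", {
  set.seed(7)
  vals <- rgamma(4000, shape = 6, scale = 4)
  g <- gridDescriptor(c(4000, 1, 1), 1)
  curve <- computeDVH(imageVolume(array(vals, c(4000, 1, 1)), g),
                      array(TRUE, c(4000, 1, 1)))
  xs <- seq(5, 95, by = 5)
  dx <- vapply(xs, function(x) dvhMetric(curve, sprintf("D%g%%", x)),
               numeric(1))
  expect_true(all(diff(dx) <= 1e-12))            # Dx non-increasing in x
  ds <- seq(1, 40, by = 1)
  vx <- vapply(ds, function(d) dvhMetric(curve, sprintf("V%gGy", d)),
               numeric(1))
  expect_true(all(diff(vx) <= 1e-12))            # Vd non-increasing in d
  expect_true(all(diff(curve@volumeCc) <= 1e-12))
  # V at Dx recovers at least x (within a bin)
  for (x in c(20, 50, 80)) {
    d <- dvhMetric(curve, sprintf("D%g%%", x))
    expect_gte(dvhMetric(curve, sprintf("V%.6gGy", d)), x - 0.5)
  }
})

test_that("percent volume discrepancy follows its defining formula", {
  expect_equal(percentVolumeDiscrepancy(98.2, 100), -1.8)
  expect_equal(percentVolumeDiscrepancy(100, 100), 0)
  expect_equal(percentVolumeDiscrepancy(150, 100), 50)
  expect_error(percentVolumeDiscrepancy(10, 0), "undefined")
})

test_that("template evaluation flags violations with signed deviations", {
  g <- gridDescriptor(c(12, 12, 12), 1)
  mask <- array(FALSE, g@shape)
  mask[1:10, 1:10, 1:10] <- TRUE                  # 1 cc
  # rectum V34.4Gy forced to 3.5 cc against the 3.00 cc bound
  big <- array(FALSE, c(30, 30, 30))
  big[1:20, 1:20, 1:20] <- TRUE
  gb <- gridDescriptor(c(30, 30, 30), 1)
  dose_vals <- array(0, c(30, 30, 30))
  hot <- which(big)[1:3500]
  dose_vals[hot] <- 35
  rep_ <- evaluateTemplate(imageVolume(dose_vals, gb),
                           structureSet(list(rectum = big), gb),
                           list(constraint("rectum", 34.40, 3.00, "<=",
                                           "cc")))
  expect_false(rep_$pass)
  expect_equal(rep_$deviationPct, (3.5 - 3) / 3 * 100, tolerance = 1e-6)

  # zero dose: all <= constraints pass, all >= constraints fail
  zero <- imageVolume(array(0, g@shape), g)
  tpl <- list(constraint("s", 10, 50, "<=", "pct"),
              constraint("s", 10, 50, ">=", "pct"))
  r0 <- evaluateTemplate(zero, structureSet(list(s = mask), g), tpl)
  expect_true(r0$pass[r0$direction == "<="])
  expect_false(r0$pass[r0$direction == ">="])

  # missing structures are reported, not fatal
  rmiss <- evaluateTemplate(zero, structureSet(list(s = mask), g),
                            list(constraint("ghost", 10, 1, "<=", "cc")))
  expect_false(rmiss$evaluated)
})

test_that("the replanning trigger fires strictly above the tolerance", {
  mk_report <- function(devs)
    data.frame(structure = "s", metric = "V10Gy", unit = "pct",
               direction = "<=", bound = 50, achieved = 50 * (1 + devs / 100),
               deviationPct = devs, pass = devs <= 0, evaluated = TRUE)
  flags <- vapply(seq(0, 6, by = 0.5), function(d)
    adaptationFlag(mk_report(d))$flag, logical(1))
  expect_equal(flags, seq(0, 6, by = 0.5) > 3)
  # exactly 3% does not trigger; 4% does and names the constraint
  expect_false(adaptationFlag(mk_report(3))$flag)
  f4 <- adaptationFlag(mk_report(4))
  expect_true(f4$flag)
  expect_equal(nrow(f4$violating), 1L)
  expect_false(adaptationFlag(mk_report(c(2, 1, -5)))$flag)
})

test_that("the packaged template file matches the built-in template", {
  f <- system.file("extdata", "constraints_prostate_sbrt.yaml",
                   package = "doseAccum")
  expect_equal(readConstraintTemplate(f), defaultConstraintTemplate())
})

test_that("constraint templates round-trip through YAML and JSON", {
  tpl <- defaultConstraintTemplate()
  y <- tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(tpl, function(x) x[c("structure", "doseGy",
                                               "bound", "direction",
                                               "unit")]), y)
  expect_equal(readConstraintTemplate(y), tpl)
  j <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(tpl, function(x) x[c("structure", "doseGy",
                                                   "bound", "direction",
                                                   "unit")]), j,
                       auto_unbox = TRUE, digits = NA)
  expect_equal(readConstraintTemplate(j), tpl)
})
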