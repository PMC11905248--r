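# Geometric indices vs brute-force oracles, gamma analysis, and the
# two-sample t-test against an exact permutation oracle.

brute_force_hd <- function(a, b, spacing) {
  surf <- function(m) {
    idx <- which(doseAccum:::.surfaceVoxels(m), arr.ind = TRUE)
    sweep(idx, 2, spacing, `*`)
  }
  pa <- surf(a); pb <- surf(b)
  dmat <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)),
                Vectorize(function(i, j) sqrt(sum((pa[i, ] - pb[j, ])^2))))
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  list(hdMax = max(max(dab), max(dba)),
       hdMean = (sum(dab) + sum(dba)) / (length(dab) + length(dba)))
}

test_that("identical and disjoint masks give the boundary index values", {
  m <- array(FALSE, c(12, 12, 12)); m[3:8, 3:8, 3:8] <- TRUE
  gi <- geometricIndices(m, m, 1.5)
  expect_equal(gi@dice, 1); expect_equal(gi@jaccard, 1)
  expect_equal(gi@hdMaxMm, 0); expect_equal(gi@hdMeanMm, 0)
  n <- array(FALSE, c(12, 12, 12)); n[10:11, 10:11, 10:11] <- TRUE
  gj <- geometricIndices(m, n, 1.5)
  expect_equal(gj@dice, 0); expect_equal(gj@jaccard, 0)
  expect_error(geometricIndices(m, array(FALSE, c(12, 12, 12)), 1),
               "nonempty")
})

test_that("offset cubes match the analytic overlap and distance values", {
  a <- array(FALSE, c(20, 20, 20)); a[5:14, 5:14, 5:14] <- TRUE
  b <- array(FALSE, c(20, 20, 20)); b[7:16, 5:14, 5:14] <- TRUE
  gi <- geometricIndices(a, b, 1)
  expect_equal(gi@dice, 2 * (8 * 10 * 10) / 2000)
  expect_equal(gi@hdMaxMm, 2)
  bf <- brute_force_hd(a, b, c(1, 1, 1))
  expect_equal(gi@hdMaxMm, bf$hdMax, tolerance = 1e-12)
  expect_equal(gi@hdMeanMm, bf$hdMean, tolerance = 1e-12)
})

test_that("surface distances match the brute-force oracle on random blobs", {
  set.seed(33)
  for (rep in 1:5) {
    a <- array(FALSE, c(10, 10, 10))
    b <- array(FALSE, c(10, 10, 10))
    ca <- sample(3:8, 3); cb <- sample(3:8, 3)
    ax <- expand.grid(1:10, 1:10, 1:10)
    a[as.matrix(ax[rowSums(sweep(ax, 2, ca)^2) <= 9, ])] <- TRUE
    b[as.matrix(ax[rowSums(sweep(ax, 2, cb)^2) <= 6.25, ])] <- TRUE
    sp <- c(1.5, 1, 2)
    gi <- geometricIndices(a, b, sp)
    bf <- brute_force_hd(a, b, sp)
    expect_equal(gi@hdMaxMm, bf$hdMax, tolerance = 1e-9)
    expect_equal(gi@hdMeanMm, bf$hdMean, tolerance = 1e-9)
  }
})

test_that("jaccard = dice / (2 - dice) on random mask pairs", {
  set.seed(9)
  for (rep in 1:200) {
    a <- array(runif(512) < runif(1, 0.2, 0.8), c(8, 8, 8))
    b <- array(runif(512) < runif(1, 0.2, 0.8), c(8, 8, 8))
    if (!any(a) || !any(b)) next
    gi <- geometricIndices(a, b, 1)
    expect_lt(abs(gi@jaccard - gi@dice / (2 - gi@dice)), 1e-12)
  }
})

test_that("hd metrics are symmetric and scale with spacing", {
  a <- array(FALSE, c(12, 12, 12)); a[3:8, 4:9, 3:7] <- TRUE
  b <- array(FALSE, c(12, 12, 12)); b[5:10, 4:9, 4:8] <- TRUE
  g1 <- geometricIndices(a, b, 1)
  g2 <- geometricIndices(b, a, 1)
  expect_equal(g1@hdMaxMm, g2@hdMaxMm)
  expect_equal(g1@hdMeanMm, g2@hdMeanMm)
  g3 <- geometricIndices(a, b, 2)
  expect_equal(g3@hdMaxMm, 2 * g1@hdMaxMm)
  expect_equal(g3@hdMeanMm, 2 * g1@hdMeanMm)
})

test_that("gamma of a dose against itself is zero with full pass rate", {
  case <- planning_case_96()
  g <- gammaAnalysis(case@planDose, case@planDose,
                     normalizationGy = case@prescriptionGy)
  expect_equal(g@passRatePct, 100)
  expect_equal(max(g@map[g@evaluated]), 0)
})

test_that("a uniform 2% dose offset gives gamma 2/3 at 3%/3mm", {
  case <- planning_case_96()
  off <- imageVolume(voxels(case@planDose) + 0.02 * 36.25,
                     imageGrid(case@planDose))
  g <- gammaAnalysis(case@planDose, off, dosePct = 3, dtaMm = 3,
                     normalizationGy = 36.25)
  expect_equal(g@passRatePct, 100)
  expect_lte(max(g@map[g@evaluated]), 2 / 3 + 1e-9)
})

test_that("a 5 mm shift fails gamma in low-gradient regions (slice oracle)", {
  # ramp + plateau dose; evaluated against an exhaustive search oracle
  g <- gridDescriptor(c(40, 12, 8), c(1.5, 1.5, 1.5))
  ax <- expand.grid(x = 0:39, y = 0:11, z = 0:7)
  w <- worldCoords(g, as.matrix(ax))
  prof <- function(x) 36.25 * pmin(1, pmax(0.05, (x + 20) / 30))
  ref <- imageVolume(array(prof(w[, 1]), g@shape), g)
  ev <- imageVolume(array(prof(w[, 1] - 5), g@shape), g)
  res <- gammaAnalysis(ref, ev, normalizationGy = 36.25)

  # brute-force gamma on the central slice, same criteria and step
  step <- 0.75; radius <- 9; dta <- 3; dc <- 0.03 * 36.25
  offs <- expand.grid(dx = seq(-radius, radius, by = step),
                      dy = seq(-radius, radius, by = step),
                      dz = seq(-radius, radius, by = step))
  offs <- offs[rowSums(offs^2) <= radius^2, ]
  k <- 4
  for (i in c(5L, 20L, 35L)) for (j in c(3L, 8L)) {
    p <- worldCoords(g, cbind(i, j, k))
    cand <- sweep(as.matrix(offs), 2, as.numeric(p), `+`)
    dev <- sampleVolume(ev, cand, fill = NA)
    ok <- !is.na(dev) &
      cand[, 1] >= gridOrigin(g)[1] &
      cand[, 1] <= gridOrigin(g)[1] + 39 * 1.5
    g2 <- (rowSums(offs^2) / dta^2)[ok] +
      ((dev[ok] - voxels(ref)[i + 1, j + 1, k + 1]) / dc)^2
    expect_equal(res@map[i + 1, j + 1, k + 1], sqrt(min(g2)),
                 tolerance = 1e-9)
  }
  # plateau region (gradient-free): the 5 mm shift leaves dose untouched,
  # gamma 0; the upstream ramp fails
  plateau <- voxels(ref) >= 36.24 & array(w[, 1], g@shape) > 15
  expect_lt(max(res@map[plateau]), 0.1)
  ramp_mid <- array(w[, 1], g@shape) > -12 & array(w[, 1], g@shape) < 0
  expect_gt(max(res@map[ramp_mid & res@evaluated]), 1)
  expect_lt(res@passRatePct, 100)
})

test_that("gamma pass rate is monotone in both criteria", {
  case <- planning_case_96()
  set.seed(4)
  noisy <- imageVolume(voxels(case@planDose) *
                         (1 + array(rnorm(length(voxels(case@planDose)),
                                          sd = 0.04),
                                    dim(voxels(case@planDose)))),
                       imageGrid(case@planDose))
  rates <- sapply(c(1, 2, 3), function(dp)
    gammaAnalysis(case@planDose, noisy, dosePct = dp, dtaMm = 2,
                  normalizationGy = 36.25)@passRatePct)
  expect_true(all(diff(rates) >= 0))
})

test_that("degenerate gamma inputs are rejected", {
  z <- uniform_dose(0)
  expect_error(gammaAnalysis(z, z), "normalization")
})

test_that("Welch t-test matches the exact permutation oracle", {
  x <- 1:5; y <- 2:6
  res <- twoSampleTTest(x, y)
  pooled <- c(x, y)
  combs <- utils::combn(10, 5)
  obs <- abs(mean(x) - mean(y))
  perm <- apply(combs, 2, function(ix)
    abs(mean(pooled[ix]) - mean(pooled[-ix])))
  # mid-p correction for the heavily tied discrete permutation distribution
  p_perm <- (mean(perm >= obs - 1e-12) + mean(perm > obs + 1e-12)) / 2
  expect_lt(abs(res$pValue - p_perm), 0.05)
  expect_equal(res$statistic, -1, tolerance = 1e-12)
})

test_that("t-test edge cases: identical, degenerate and separated samples", {
  expect_equal(twoSampleTTest(c(2, 2, 2), c(2, 2, 2))$pValue, 1)
  set.seed(11)
  x <- rnorm(10, 0, 1); y <- rnorm(10, 10, 1)
  expect_lt(twoSampleTTest(x, y)$pValue, 1e-6)
  expect_true(is.finite(twoSampleTTest(x, y, variant = "pooled")$statistic))
  expect_error(twoSampleTTest(1, 1:3), "two observations")
})
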