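test_that("invalid specifications are rejected naming the offending field", {
  expect_error(networkSpec(branchProb = 1.5), "branchProb")
  expect_error(networkSpec(imageSizePx = c(32L, 64L)), "imageSizePx")
  expect_error(networkSpec(widthJitter = 0.6), "widthJitter")
  expect_error(networkSpec(noiseSd = -0.1), "noiseSd")
  expect_error(generateCohort(networkSpec(), networkSpec(), 1),
               "nImagesPerGroup")
})

test_that("an empty network yields background only and zero ground truth", {
  out <- generateNetwork(networkSpec(imageSizePx = c(64L, 64L), nSeeds = 0L,
                                     seed = 1L))
  expect_identical(out$truth@totalLengthUm, 0)
  expect_identical(out$truth@nBranchPoints, 0L)
  expect_identical(out$truth@trueAreaFractionPct, 0)
  expect_length(out$truth@polylines, 0)
  expect_s4_class(out$image, "CalibratedImage")
})

test_that("a single straight fiber has analytic ground truth", {
  sp <- networkSpec(imageSizePx = c(128L, 128L), umPerPx = 1, nSeeds = 1L,
                    branchProb = 0, fiberWidthUm = 5, widthJitter = 0,
                    fiberLengthUm = 100, curvatureSd = 0, noiseSd = 0,
                    shadingAmplitude = 0, seed = 42L)
  out <- generateNetwork(sp)
  tr <- out$truth
  expect_equal(tr@totalLengthUm, 100, tolerance = 1e-9)
  expect_identical(tr@nBranchPoints, 0L)
  expect_equal(tr@meanWidthUm, 5, tolerance = 1e-12)
  # geometry/raster consistency: area / length agrees with the width
  expect_lt(abs(tr@foregroundAreaUm2 / tr@totalLengthUm - 5) / 5, 0.1)
})

test_that("the same seed reproduces image and ground truth bit-for-bit", {
  sp <- networkSpec(imageSizePx = c(96L, 96L), nSeeds = 3L,
                    targetAreaFractionPct = 5, nBlobArtifacts = 2L,
                    seed = 42L)
  a <- generateNetwork(sp)
  b <- generateNetwork(sp)
  expect_identical(imageMatrix(a$image), imageMatrix(b$image))
  expect_identical(a$truth@polylines, b$truth@polylines)
  expect_identical(a$truth@totalLengthUm, b$truth@totalLengthUm)
  expect_identical(a$truth@nBranchPoints, b$truth@nBranchPoints)
  expect_identical(a$truth@foregroundAreaUm2, b$truth@foregroundAreaUm2)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generateNetwork(networkSpec(imageSizePx = c(64L, 64L),
                                        nSeeds = 1L, seed = 5L)))
  expect_identical(.Random.seed, before)
})

test_that("the coverage target is met within 20% relative", {
  for (nm in c("tlf", "gluteal")) {
    sp <- presetSpec(nm, imageSizePx = c(256L, 256L), seed = 8L)
    tr <- generateNetwork(sp, render = FALSE)$truth
    expect_lt(abs(tr@trueAreaFractionPct - sp@targetAreaFractionPct) /
                sp@targetAreaFractionPct, 0.2)
  }
})

test_that("geometry/raster consistency holds on branching networks", {
  sp <- presetSpec("gluteal", imageSizePx = c(256L, 256L), seed = 21L)
  tr <- generateNetwork(sp, render = FALSE)$truth
  ratio <- tr@foregroundAreaUm2 / tr@totalLengthUm
  expect_lt(abs(ratio - tr@meanWidthUm) / tr@meanWidthUm, 0.1)
})

test_that("halving the pixel size leaves physical ground truth unchanged", {
  mk <- function(umpp, npx) networkSpec(imageSizePx = c(npx, npx),
    umPerPx = umpp, nSeeds = 3L, branchProb = 0.01,
    targetAreaFractionPct = 5, noiseSd = 0, shadingAmplitude = 0,
    seed = 31L)
  a <- generateNetwork(mk(1, 128L), render = FALSE)$truth
  b <- generateNetwork(mk(0.5, 256L), render = FALSE)$truth
  expect_identical(a@totalLengthUm, b@totalLengthUm)
  expect_identical(a@meanWidthUm, b@meanWidthUm)
  expect_identical(a@nBranchPoints, b@nBranchPoints)
  # physical area agrees; pixel counts scale by ~4x
  expect_lt(abs(a@foregroundAreaUm2 - b@foregroundAreaUm2) /
              b@foregroundAreaUm2, 0.05)
  pxA <- a@foregroundAreaUm2 / 1^2
  pxB <- b@foregroundAreaUm2 / 0.5^2
  expect_lt(abs(pxB / pxA - 4), 0.25)
})

test_that("cohorts are reproducible and ordered as specified", {
  spA <- presetSpec("tlf", imageSizePx = c(192L, 192L))
  spB <- presetSpec("gluteal", imageSizePx = c(192L, 192L))
  c1 <- generateCohort(spA, spB, 3, seed = 7L, render = FALSE)
  c2 <- generateCohort(spA, spB, 3, seed = 7L, render = FALSE)
  expect_identical(cohortTruthTable(c1), cohortTruthTable(c2))
  tt <- cohortTruthTable(c1)
  expect_identical(nrow(tt), 6L)
  mA <- mean(tt$true_area_fraction_pct[tt$group == "A"])
  mB <- mean(tt$true_area_fraction_pct[tt$group == "B"])
  expect_gt(mA, mB)
})

test_that("identical specs give no systematic group difference", {
  sp <- presetSpec("tlf", imageSizePx = c(128L, 128L))
  rej <- 0L
  for (r in seq_len(40)) {
    co <- generateCohort(sp, sp, 6, seed = 1000L + r, render = FALSE)
    tt <- cohortTruthTable(co)
    p <- tTestGroups(tt$true_area_fraction_pct[tt$group == "A"],
                     tt$true_area_fraction_pct[tt$group == "B"])@pValue
    if (p < 0.01) rej <- rej + 1L
  }
  expect_lte(rej, 3L)
})
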