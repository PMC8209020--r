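test_that("thinning reduces a bar to a single unit-width centerline", {
  m <- matrix(FALSE, 20, 110)
  m[8:12, 6:105] <- TRUE
  sk <- skeletonize(mkMask(m))
  s <- imageMatrix(sk)
  npx <- sum(s)
  # thinning erodes the rounded ends by a couple of pixels
  expect_gte(npx, 93)
  expect_lte(npx, 100)
  # unit width: no fully set 2x2 block
  expect_identical(sum(s[-1, -1] & s[-20, -1] & s[-1, -110] & s[-20, -110]),
                   0L)
  # single component, inside the source mask
  expect_identical(bruteComponentCount(s), 1L)
  expect_true(all(m[s]))
})

test_that("thinning is idempotent on thin input and preserves topology", {
  d <- matrix(FALSE, 12, 12)
  d[cbind(1:12, 1:12)] <- TRUE
  expect_identical(imageMatrix(skeletonize(mkMask(d))), d)
  # two separate bars stay two components
  m <- matrix(FALSE, 30, 30)
  m[5:8, 2:28] <- TRUE
  m[20:23, 2:28] <- TRUE
  sk <- imageMatrix(skeletonize(mkMask(m)))
  expect_identical(bruteComponentCount(sk), 2L)
  # empty in, empty out
  expect_identical(nForegroundPx(skeletonize(mkMask(matrix(FALSE, 8, 8)))),
                   0L)
})

test_that("junction detection counts merged clusters, not pixels", {
  line <- matrix(FALSE, 9, 9); line[5, ] <- TRUE
  expect_identical(nrow(branchPoints(findBranchPoints(mkSkel(line)))), 0L)
  plus <- matrix(FALSE, 21, 21)
  plus[11, 3:19] <- TRUE; plus[3:19, 11] <- TRUE
  bp <- branchPoints(findBranchPoints(mkSkel(plus)))
  expect_identical(nrow(bp), 1L)
  expect_identical(unname(bp[1, ]), c(11L, 11L))
  # Y junction: three arms meeting at one point
  y <- matrix(FALSE, 21, 21)
  y[11:20, 11] <- TRUE
  y[cbind(10:3, 10:3)] <- TRUE
  y[cbind(10:3, 12:19)] <- TRUE
  y[11, 11] <- TRUE
  bpY <- branchPoints(findBranchPoints(mkSkel(y)))
  expect_identical(nrow(bpY), 1L)
  expect_identical(nrow(bpY), bruteBranchCount(y) |> as.integer())
})

test_that("a non-thin skeleton triggers a warning, not an error", {
  thick <- matrix(FALSE, 10, 10)
  thick[4:6, 2:9] <- TRUE
  expect_warning(findBranchPoints(mkSkel(thick)), "unit-width")
  expect_silent(findBranchPoints(mkSkel(thick), checkThin = FALSE))
})

test_that("length weighs orthogonal and diagonal adjacencies correctly", {
  h <- matrix(FALSE, 3, 101); h[2, ] <- TRUE
  expect_equal(measureLength(mkSkel(h)), 0.1)  # 100 um
  d <- matrix(FALSE, 101, 101); d[cbind(1:101, 1:101)] <- TRUE
  expect_equal(measureLength(mkSkel(d)) * 1000, 100 * sqrt(2))
  # isolated pixels contribute nothing
  iso <- matrix(FALSE, 9, 9); iso[cbind(c(2, 5, 8), c(2, 5, 8))] <- FALSE
  iso[2, 2] <- TRUE; iso[5, 5] <- TRUE
  expect_identical(measureLength(mkSkel(iso)), 0)
  # pixel-count estimator
  expect_equal(measureLength(mkSkel(h), "pixel-count"), 101 / 1000)
})

test_that("length matches the brute-force oracle on random skeletons", {
  for (s in 1:20) {
    set.seed(s)
    m <- matrix(runif(10 * 10) < 0.3, 10, 10)
    expect_equal(measureLength(mkSkel(m)) * 1000, bruteLengthUm(m),
                 tolerance = 1e-12)
  }
})

test_that("the morphometric summary reproduces direct arithmetic", {
  m <- matrix(FALSE, 100, 100)
  m[seq_len(900)] <- TRUE
  sk <- findBranchPoints(skeletonize(mkMask(m)), checkThin = FALSE)
  s <- summarizeMorphometry(mkMask(m), sk)
  expect_equal(s@positiveAreaPct, 9.0)
  # bar: thickness recovers the true width within 15%
  bar <- matrix(FALSE, 20, 110)
  bar[8:12, 6:105] <- TRUE
  skb <- findBranchPoints(skeletonize(mkMask(bar)))
  sb <- summarizeMorphometry(mkMask(bar), skb)
  expect_lt(abs(sb@meanThicknessUm - 5) / 5, 0.15)
  # identity: thickness x length == area, exactly
  expect_equal(sb@meanThicknessUm * sb@totalLengthMm * 1000,
               sb@nForegroundPx * 1^2, tolerance = 1e-12)
})

test_that("an empty mask summarizes to zeros with undefined thickness", {
  e <- mkMask(matrix(FALSE, 32, 32))
  s <- summarizeMorphometry(e, skeletonize(e))
  expect_identical(s@positiveAreaPct, 0)
  expect_identical(s@bpDensityPerMm2, 0)
  expect_identical(s@totalLengthMm, 0)
  expect_false(s@thicknessDefined)
  expect_true(is.na(s@meanThicknessUm))
})

test_that("summaries transform correctly under a calibration change", {
  set.seed(2)
  m <- matrix(runif(64 * 64) < 0.1, 64, 64)
  sk1 <- findBranchPoints(skeletonize(mkMask(m, 1)), checkThin = FALSE)
  s1 <- summarizeMorphometry(mkMask(m, 1), sk1)
  sk2 <- mkSkel(imageMatrix(sk1), 2)
  sk2@branchPoints <- branchPoints(sk1)
  s2 <- summarizeMorphometry(mkMask(m, 2), sk2)
  expect_equal(s2@totalLengthMm, 2 * s1@totalLengthMm)
  expect_equal(s2@meanThicknessUm, 2 * s1@meanThicknessUm)
  expect_equal(s2@imageAreaMm2, 4 * s1@imageAreaMm2)
  expect_equal(s2@bpDensityPerMm2, s1@bpDensityPerMm2 / 4)
  expect_identical(s2@positiveAreaPct, s1@positiveAreaPct)
  expect_error(summarizeMorphometry(mkMask(m, 1), sk2), "calibration")
})

test_that("spur pruning removes short twigs but not real branches", {
  m <- matrix(FALSE, 15, 40)
  m[8, 2:39] <- TRUE
  m[5:7, 20] <- TRUE  # 3-px twig
  pruned <- pruneSpurs(mkSkel(m), 5)
  expect_identical(sum(imageMatrix(pruned)), sum(m[8, ]))
  expect_identical(nrow(branchPoints(findBranchPoints(pruned))), 0L)
  # a 12-px genuine branch survives pruning at 5
  m2 <- matrix(FALSE, 25, 40)
  m2[20, 2:39] <- TRUE
  m2[8:19, 20] <- TRUE
  pruned2 <- pruneSpurs(mkSkel(m2), 5)
  expect_identical(sum(imageMatrix(pruned2)), sum(m2))
  # free-standing short segments are not spurs
  seg <- matrix(FALSE, 9, 9); seg[5, 3:6] <- TRUE
  expect_identical(imageMatrix(pruneSpurs(mkSkel(seg), 5)), seg)
})

test_that("branch-point counting matches brute force on random masks", {
  for (s in 1:200) {
    set.seed(s)
    m <- matrix(FALSE, 8, 8)
    m[sample(64, sample(0:12, 1))] <- TRUE
    got <- nrow(branchPoints(findBranchPoints(mkSkel(m),
                                              checkThin = FALSE)))
    expect_identical(got, bruteBranchCount(m))
  }
})
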