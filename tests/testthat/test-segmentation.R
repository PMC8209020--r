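brightImg <- function(m, umpp = 1)
  new("CalibratedImage", pixels = m, umPerPx = umpp, polarity = "bright",
      provenance = "test")

test_that("a constant image thresholds to an empty mask", {
  img <- brightImg(matrix(0.5, 32, 32))
  expect_identical(nForegroundPx(adaptiveThreshold(img, 15L, 0.01)), 0L)
})

test_that("an isolated bright pixel is recovered exactly", {
  m <- matrix(0, 15, 15)
  m[8, 8] <- 1
  mask <- adaptiveThreshold(brightImg(m), 15L, 0.1)
  expect_identical(which(imageMatrix(mask)), which(m == 1))
  # cross-check the local mean against the brute-force oracle
  expect_equal(nervemorph:::localMean(m, 15L), bruteLocalMean(m, 15L),
               tolerance = 1e-12)
})

test_that("the fast local mean matches brute force on random grids", {
  for (s in 1:3) {
    set.seed(s)
    m <- matrix(runif(9 * 11), 9, 11)
    for (w in c(3L, 5L, 7L))
      expect_equal(nervemorph:::localMean(m, w), bruteLocalMean(m, w),
                   tolerance = 1e-12)
  }
})

test_that("masks are nested in the offset and shift-invariant", {
  set.seed(4)
  m <- matrix(runif(48 * 48, 0, 0.5), 48, 48)
  img <- brightImg(m)
  lo <- imageMatrix(adaptiveThreshold(img, 9L, 0.02))
  hi <- imageMatrix(adaptiveThreshold(img, 9L, 0.1))
  expect_true(all(lo[hi]))  # mask(offset2) subset of mask(offset1)
  shifted <- brightImg(m + 0.3)
  expect_identical(imageMatrix(adaptiveThreshold(shifted, 9L, 0.05)),
                   imageMatrix(adaptiveThreshold(img, 9L, 0.05)))
})

test_that("window validation rejects even or tiny windows", {
  img <- brightImg(matrix(0.5, 16, 16))
  expect_error(adaptiveThreshold(img, 14L), "odd")
  expect_error(adaptiveThreshold(img, 1L), "odd")
})

test_that("the size filter removes small components", {
  m <- matrix(FALSE, 32, 32)
  m[5:6, 5:9] <- TRUE  # 10 px
  out <- removeArtifacts(mkMask(m), minObjectPx = 50,
                         circularityCutoff = NA)
  expect_identical(nForegroundPx(out), 0L)
})

test_that("the circularity filter drops disks but keeps elongated fibers", {
  m <- matrix(FALSE, 60, 240)
  m[10, 11:210] <- TRUE                       # 200-px line
  for (r in 1:60) for (cc in 1:60)
    if ((r - 40)^2 + (cc - 40)^2 <= 8^2) m[r, cc] <- TRUE  # ~200-px disk
  out <- removeArtifacts(mkMask(m), minObjectPx = 50, circularityCutoff = 0.5)
  expect_true(all(imageMatrix(out)[10, 11:210]))
  expect_false(any(imageMatrix(out)[30:50, 30:50]))
  # brute-force circularity of both components confirms the ordering
  line <- matrix(FALSE, 60, 240); line[10, 11:210] <- TRUE
  disk <- m & !line
  circ <- function(comp) {
    co <- which(comp, arr.ind = TRUE)
    per <- 0
    for (i in seq_len(nrow(co))) {
      for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
        r <- co[i, 1] + d[1]; cc <- co[i, 2] + d[2]
        if (r < 1 || r > nrow(comp) || cc < 1 || cc > ncol(comp) ||
            !comp[r, cc]) per <- per + 1
      }
    }
    4 * pi * nrow(co) / per^2
  }
  expect_gt(circ(disk), 0.5)
  expect_lt(circ(line), 0.5)
})

test_that("the no-op configuration is the identity", {
  set.seed(9)
  m <- matrix(runif(32 * 32) < 0.2, 32, 32)
  out <- removeArtifacts(mkMask(m), minObjectPx = 0, circularityCutoff = NA)
  expect_identical(imageMatrix(out), m)
})

test_that("exclusion masks clear their pixels and must match in shape", {
  m <- matrix(TRUE, 16, 16)
  ex <- matrix(FALSE, 16, 16)
  ex[1:8, ] <- TRUE
  out <- removeArtifacts(mkMask(m), minObjectPx = 0, circularityCutoff = NA,
                         exclusionMask = mkMask(ex))
  expect_false(any(imageMatrix(out)[1:8, ]))
  expect_true(all(imageMatrix(out)[9:16, ]))
  expect_error(removeArtifacts(mkMask(m), exclusionMask =
                                 mkMask(matrix(FALSE, 8, 8))),
               "shape")
})

test_that("artifact removal never adds foreground", {
  set.seed(11)
  m <- matrix(runif(64 * 64) < 0.3, 64, 64)
  out <- imageMatrix(removeArtifacts(mkMask(m), minObjectPx = 10,
                                     circularityCutoff = 0.5))
  expect_true(all(m[out]))
})

test_that("hole filling closes small holes and leaves meshes open", {
  m <- matrix(FALSE, 40, 40)
  m[10:20, 10:20] <- TRUE
  m[14:16, 14:16] <- FALSE     # 9-px hole
  out <- fillHoles(mkMask(m), 50)
  expect_true(all(imageMatrix(out)[10:20, 10:20]))
  big <- matrix(FALSE, 60, 60)
  big[10:50, 10:50] <- TRUE
  big[15:45, 15:45] <- FALSE   # 961-px mesh
  out2 <- fillHoles(mkMask(big), 50)
  expect_false(any(imageMatrix(out2)[20:40, 20:40]))
  expect_true(all(imageMatrix(out2)[big]))  # never removes foreground
})

test_that("segmentation recovers the true mask with F1 >= 0.8", {
  for (nm in c("tlf", "gluteal")) {
    sp <- presetSpec(nm, imageSizePx = c(256L, 256L), seed = 23L)
    g <- generateNetwork(sp)
    truth <- imageMatrix(trueMask(sp))
    got <- imageMatrix(analyzeImage(g$image, presetConfig())$mask)
    tp <- sum(got & truth)
    f1 <- 2 * tp / (2 * tp + sum(got & !truth) + sum(!got & truth))
    expect_gt(f1, 0.8)
  }
})
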