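#' Construct a synthetic network specification
#'
#' Builds and validates a \code{\linkS4class{NetworkSpec}}. All fiber
#' geometry is expressed in physical units (µm); see the class documentation
#' for the meaning and admissible range of every parameter. Two growth modes
#' exist: with \code{targetAreaFractionPct} set, fibers are grown until
#' their accumulated centerline-length x width budget reaches the target
#' coverage; otherwise each primary fiber is grown to \code{fiberLengthUm}.
#'
#' @param imageSizePx integer (rows, cols), each >= 64.
#' @param umPerPx micrometres per pixel.
#' @param nSeeds number of initial primary fibers.
#' @param branchProb branch probability per µm of growth, [0, 1].
#' @param fiberWidthUm mean fiber width, µm.
#' @param widthJitter relative s.d. of per-fiber width, [0, 0.5).
#' @param targetAreaFractionPct target coverage in %, or \code{NA}.
#' @param fiberLengthUm fixed primary fiber length (µm) when no area target
#'   is set (default 100).
#' @param curvatureSd s.d. of per-step turning, radians (0 = straight).
#' @param stainContrast foreground attenuation relative to background, [0, 1].
#' @param shadingAmplitude relative amplitude of multiplicative shading,
#'   [0, 0.5].
#' @param noiseSd additive Gaussian noise s.d. (fraction of dynamic range).
#' @param nBlobArtifacts number of non-nervous blob artifacts.
#' @param seed RNG seed.
#' @return a validated \code{\linkS4class{NetworkSpec}}.
#' @examples
#' networkSpec(nSeeds = 2L, targetAreaFractionPct = 5, seed = 7L)
#' @export
networkSpec <- function(imageSizePx = c(512L, 512L), umPerPx = 1,
                        nSeeds = 5L, branchProb = 0.02, fiberWidthUm = 5,
                        widthJitter = 0.1, targetAreaFractionPct = NA_real_,
                        fiberLengthUm = NA_real_, curvatureSd = 0.25,
                        stainContrast = 0.6, shadingAmplitude = 0.2,
                        noiseSd = 0.05, nBlobArtifacts = 0L, seed = 1L) {
  spec <- new("NetworkSpec",
    imageSizePx = as.integer(imageSizePx), umPerPx = as.numeric(umPerPx),
    nSeeds = as.integer(nSeeds), branchProb = as.numeric(branchProb),
    fiberWidthUm = as.numeric(fiberWidthUm),
    widthJitter = as.numeric(widthJitter),
    targetAreaFractionPct = as.numeric(targetAreaFractionPct),
    fiberLengthUm = as.numeric(fiberLengthUm),
    curvatureSd = as.numeric(curvatureSd),
    stainContrast = as.numeric(stainContrast),
    shadingAmplitude = as.numeric(shadingAmplitude),
    noiseSd = as.numeric(noiseSd),
    nBlobArtifacts = as.integer(nBlobArtifacts), seed = as.integer(seed))
  validObject(spec)
  spec
}

#' Preset network specifications
#'
#' Ready-made \code{\linkS4class{NetworkSpec}}s emulating the two tissue
#' regimes of the study design: a densely innervated aponeurotic fascia
#' ("tlf", ~9\% S100-positive area) and a sparsely innervated epimysial
#' fascia ("gluteal", ~2.8\%), plus a very sparse sympathetic-marker regime
#' ("th", ~0.08\%). Fields are 512 x 512 px at 1 µm/px (0.26 mm^2), sized
#' so that the dense preset carries well over ten true branch points per
#' image. Presets use noise s.d. 0.05 and shading amplitude 0.2.
#'
#' @param name \code{"tlf"}, \code{"gluteal"} or \code{"th"}.
#' @param imageSizePx,umPerPx field geometry overrides.
#' @param seed RNG seed.
#' @return a \code{\linkS4class{NetworkSpec}}.
#' @export
presetSpec <- function(name = c("tlf", "gluteal", "th"),
                       imageSizePx = c(512L, 512L), umPerPx = 1,
                       seed = 1L) {
  name <- match.arg(name)
  base <- list(imageSizePx = imageSizePx, umPerPx = umPerPx, seed = seed,
               widthJitter = 0.12, curvatureSd = 0.25, stainContrast = 0.6,
               shadingAmplitude = 0.2, noiseSd = 0.05)
  pars <- switch(name,
    tlf = list(nSeeds = 8L, branchProb = 0.032, fiberWidthUm = 5.8,
               targetAreaFractionPct = 9.01, nBlobArtifacts = 6L),
    gluteal = list(nSeeds = 4L, branchProb = 0.0245, fiberWidthUm = 4.9,
                   targetAreaFractionPct = 2.78, nBlobArtifacts = 6L),
    th = list(nSeeds = 2L, branchProb = 0.004, fiberWidthUm = 3.5,
              targetAreaFractionPct = 0.08, nBlobArtifacts = 2L))
  do.call(networkSpec, c(base, pars))
}

# --- fiber growth ---------------------------------------------------------

# Grows the fiber geometry for one image, in physical (µm) coordinates so
# that the same seed yields the same physical network at any pixel size.
# Returns list(polys = list(matrix x,y µm), widths, isChild, nBranch).
growNetwork <- function(spec) {
  H <- spec@imageSizePx[1L] * spec@umPerPx
  W <- spec@imageSizePx[2L] * spec@umPerPx
  budgetMode <- !is.na(spec@targetAreaFractionPct)
  areaBudget <- if (budgetMode)
    spec@targetAreaFractionPct / 100 * H * W else Inf
  fixedLen <- if (is.na(spec@fiberLengthUm)) 100 else spec@fiberLengthUm
  stepLen <- 3
  margin <- min(spec@fiberWidthUm, min(H, W) / 4)

  # occupancy store: segment midpoints with owning polyline id + half-width
  occX <- numeric(4096); occY <- numeric(4096)
  occHw <- numeric(4096); occId <- integer(4096)
  occN <- 0L
  occAdd <- function(x, y, hw, id) {
    if (occN == length(occX)) {
      occX <<- c(occX, numeric(occN)); occY <<- c(occY, numeric(occN))
      occHw <<- c(occHw, numeric(occN)); occId <<- c(occId, integer(occN))
    }
    occN <<- occN + 1L
    occX[occN] <<- x; occY[occN] <<- y
    occHw[occN] <<- hw; occId[occN] <<- id
  }
  # clearance keeps distinct fibers at least ~2.5 µm apart surface to
  # surface, so rasterized fibers stay resolvable and never bridge
  checkFree <- function(p, hw, ownId, exemptParent, parentId) {
    if (occN == 0L) return(TRUE)
    sel <- seq_len(occN)
    d2 <- (occX[sel] - p[1L])^2 + (occY[sel] - p[2L])^2
    conflict <- d2 < (occHw[sel] + hw + 2.5)^2
    own <- occId[sel] == ownId
    conflict <- conflict & !(own & sel > occN - 6L)  # own recent trail
    if (exemptParent && !is.na(parentId))
      conflict <- conflict & occId[sel] != parentId
    !any(conflict)
  }

  sampleWidth <- function()
    spec@fiberWidthUm *
      min(max(1 + spec@widthJitter * stats::rnorm(1), 0.7), 1.3)
  newPrimary <- function() list(
    start = c(stats::runif(1, margin, W - margin),
              stats::runif(1, margin, H - margin)),
    dir = stats::runif(1, 0, 2 * pi), width = sampleWidth(),
    maxLen = if (budgetMode) stats::runif(1, 80, 160) else fixedLen,
    child = FALSE, parent = NA_integer_)

  queue <- vector("list", 64L); qHead <- 1L; qTail <- 0L
  qPush <- function(task) {
    if (qTail == length(queue)) queue <<- c(queue, vector("list", qTail))
    qTail <<- qTail + 1L
    queue[[qTail]] <<- task
  }
  for (i in seq_len(spec@nSeeds)) qPush(newPrimary())

  drawnArea <- 0
  done <- FALSE
  nextId <- 0L
  polys <- list(); widths <- numeric(0); isChild <- logical(0)
  nBranch <- 0L

  reflectStep <- function(cur, dir, step, hw) {
    for (attempt in 1:4) {
      prop <- cur + step * c(cos(dir), sin(dir))
      inx <- prop[1L] >= hw && prop[1L] <= W - hw
      iny <- prop[2L] >= hw && prop[2L] <= H - hw
      if (inx && iny) return(list(p = prop, dir = dir))
      if (!inx) dir <- pi - dir
      if (!iny) dir <- -dir
    }
    NULL
  }

  minKeepLen <- 12  # fibers shorter than this (µm) are not kept
  growOne <- function(task) {
    nextId <<- nextId + 1L
    id <- nextId
    hw <- task$width / 2
    cur <- task$start
    dir <- task$dir
    pts <- matrix(NA_real_, 256L, 2L)
    np <- 1L
    pts[1L, ] <- cur
    remaining <- task$maxLen
    stepI <- 0L
    occStart <- occN
    areaStart <- drawnArea
    pending <- list()
    repeat {
      stepCap <- min(stepLen, remaining)
      if (budgetMode)
        stepCap <- min(stepCap, max(0, areaBudget - drawnArea) / task$width)
      if (stepCap < 1e-9) {
        if (budgetMode && areaBudget - drawnArea < 1e-9) done <<- TRUE
        break
      }
      stepI <- stepI + 1L
      dirP <- dir + stats::rnorm(1, 0, spec@curvatureSd)
      rs <- reflectStep(cur, dirP, stepCap, hw)
      # fibers terminate rather than cross or fold onto existing ones
      if (is.null(rs) ||
          !checkFree(rs$p, hw, id, stepI <= 5L, task$parent)) break
      dir <- rs$dir
      occAdd((cur[1L] + rs$p[1L]) / 2, (cur[2L] + rs$p[2L]) / 2, hw, id)
      cur <- rs$p
      np <- np + 1L
      if (np > nrow(pts)) pts <- rbind(pts, matrix(NA_real_, nrow(pts), 2L))
      pts[np, ] <- cur
      drawnArea <<- drawnArea + stepCap * task$width
      remaining <- remaining - stepCap
      if (stats::runif(1) < spec@branchProb * stepCap) {
        ang <- stats::runif(1, pi / 4, pi / 2) * sample(c(-1, 1), 1L)
        # children are drawn slightly thinner than the cohort mean; the
        # discount is relative to the spec width, not the parent's, so
        # deep branching does not drive widths to zero
        pending[[length(pending) + 1L]] <-
          list(start = cur, dir = dir + ang,
               width = 0.85 * sampleWidth(),
               maxLen = stats::runif(1, 40, 100),
               child = TRUE, parent = id,
               spawnLen = task$maxLen - remaining)
      }
      if (remaining < 1e-9) break
    }
    grownLen <- task$maxLen - remaining
    if (np >= 2L && grownLen >= min(minKeepLen, task$maxLen)) {
      polys[[length(polys) + 1L]] <<- pts[seq_len(np), , drop = FALSE]
      widths <<- c(widths, task$width)
      isChild <<- c(isChild, task$child)
      if (task$child) nBranch <<- nBranch + 1L
      for (tk in pending) {
        # a child attached within a half-step of where the parent ends
        # continues the parent as an elbow rather than branching off it;
        # it is grown and rendered but not counted as a branch point
        if (grownLen - tk$spawnLen < 9) tk$child <- FALSE
        qPush(tk)
      }
    } else {
      # too short to be a detectable fiber: roll back its strokes, its
      # area contribution and its queued children
      occN <<- occStart
      drawnArea <<- areaStart
    }
  }

  extraSeeds <- 0L
  while (!done) {
    if (qHead > qTail) {
      if (budgetMode && spec@nSeeds > 0L &&
          drawnArea < 0.985 * areaBudget && extraSeeds < 300L) {
        qPush(newPrimary())
        extraSeeds <- extraSeeds + 1L
      } else break
    }
    task <- queue[[qHead]]
    queue[qHead] <- list(NULL)
    qHead <- qHead + 1L
    growOne(task)
  }

  list(polys = polys, widths = widths, isChild = isChild,
       nBranch = nBranch)
}

# --- rasterization --------------------------------------------------------

# paint thick line segments (round caps) onto a logical raster; pixel (r,c)
# has its center at x = (c - 0.5) * px, y = (r - 0.5) * px
paintStrokes <- function(fg, polys, halfWidths, px) {
  nr <- nrow(fg); nc <- ncol(fg)
  for (k in seq_along(polys)) {
    pts <- polys[[k]]
    hw <- halfWidths[k]
    for (s in seq_len(nrow(pts) - 1L)) {
      p0 <- pts[s, ]; p1 <- pts[s + 1L, ]
      c1 <- max(1L, floor((min(p0[1L], p1[1L]) - hw) / px))
      c2 <- min(nc, ceiling((max(p0[1L], p1[1L]) + hw) / px) + 1L)
      r1 <- max(1L, floor((min(p0[2L], p1[2L]) - hw) / px))
      r2 <- min(nr, ceiling((max(p0[2L], p1[2L]) + hw) / px) + 1L)
      if (c1 > c2 || r1 > r2) next
      xs <- (c1:c2 - 0.5) * px
      ys <- (r1:r2 - 0.5) * px
      vx <- p1[1L] - p0[1L]; vy <- p1[2L] - p0[2L]
      L2 <- vx * vx + vy * vy
      dx <- matrix(xs - p0[1L], length(ys), length(xs), byrow = TRUE)
      dy <- matrix(ys - p0[2L], length(ys), length(xs))
      if (L2 > 0) {
        tt <- (dx * vx + dy * vy) / L2
        tt[tt < 0] <- 0; tt[tt > 1] <- 1
        d2 <- (dx - tt * vx)^2 + (dy - tt * vy)^2
      } else d2 <- dx^2 + dy^2
      fg[r1:r2, c1:c2] <- fg[r1:r2, c1:c2] | (d2 <= hw * hw)
    }
  }
  fg
}

# block-average an (ss*nr) x (ss*nc) matrix down to nr x nc
blockMean <- function(m, ss) {
  nr <- nrow(m) %/% ss; nc <- ncol(m) %/% ss
  a <- colSums(array(m, dim = c(ss, nr, ss * nc)))      # nr x (ss*nc)
  b <- colSums(aperm(array(a, dim = c(nr, ss, nc)), c(2L, 1L, 3L)))
  b / (ss * ss)
}

#' Generate a synthetic stained-nerve micrograph with ground truth
#'
#' Grows a branching fiber network by curvature-limited random walks in
#' physical coordinates (children attach to a growing parent and inherit a
#' reduced width; fibers bounce off the field border and terminate rather
#' than cross one another), rasterizes it at 4x supersampling, and renders
#' a DAB-like micrograph: dark fibers on a bright background, degraded by a
#' smooth multiplicative illumination field, additive Gaussian noise and
#' optional non-nervous blob artifacts. Ground truth (centerline polylines,
#' total length, branch attachment count, area-weighted mean width, and
#' supersampled foreground area) is computed from the geometry before any
#' degradation is applied. The same spec (including its seed) reproduces
#' the identical image and ground truth.
#'
#' @param spec a \code{\linkS4class{NetworkSpec}}.
#' @param render set \code{FALSE} to skip image synthesis (the returned
#'   \code{image} is \code{NULL}) when only ground truth is needed; the
#'   ground truth is identical either way.
#' @return a list with elements \code{image} (a
#'   \code{\linkS4class{CalibratedImage}} with dark signal, or \code{NULL})
#'   and \code{truth} (a \code{\linkS4class{GroundTruth}}).
#' @examples
#' out <- generateNetwork(networkSpec(nSeeds = 0L, seed = 1L))
#' out$truth
#' @export
generateNetwork <- function(spec, render = TRUE) {
  stopifnot(is(spec, "NetworkSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    nr <- spec@imageSizePx[1L]; nc <- spec@imageSizePx[2L]
    umPx <- spec@umPerPx
    net <- growNetwork(spec)

    segLen <- function(p) sum(sqrt(rowSums(diff(p)^2)))
    lens <- vapply(net$polys, segLen, numeric(1))
    totalLen <- sum(lens)
    lw <- lens * net$widths
    meanWidth <- if (totalLen > 0) sum(lw * net$widths) / sum(lw) else 0

    ss <- 4L
    fgSS <- matrix(FALSE, nr * ss, nc * ss)
    fgSS <- paintStrokes(fgSS, net$polys, net$widths / 2, umPx / ss)
    fgArea <- sum(fgSS) / ss^2 * umPx^2
    fieldArea <- nr * nc * umPx^2

    pxPolys <- lapply(net$polys, function(p)
      cbind(row = p[, 2L] / umPx + 0.5, col = p[, 1L] / umPx + 0.5))
    truth <- new("GroundTruth", polylines = pxPolys,
                 widthsUm = net$widths, totalLengthUm = totalLen,
                 nBranchPoints = net$nBranch, meanWidthUm = meanWidth,
                 foregroundAreaUm2 = fgArea,
                 trueAreaFractionPct = 100 * fgArea / fieldArea)

    img <- NULL
    if (render) {
      cov <- blockMean(fgSS + 0, ss)
      blobCov <- 0
      if (spec@nBlobArtifacts > 0L) {
        H <- nr * umPx; W <- nc * umPx
        blobSS <- matrix(FALSE, nr * ss, nc * ss)
        placed <- 0L
        mids <- do.call(rbind, lapply(net$polys, function(p)
          (p[-1L, , drop = FALSE] + p[-nrow(p), , drop = FALSE]) / 2))
        for (tryI in seq_len(spec@nBlobArtifacts * 50L)) {
          if (placed >= spec@nBlobArtifacts) break
          r <- stats::runif(1, 4.5, 6.5)
          ctr <- c(stats::runif(1, r, W - r), stats::runif(1, r, H - r))
          if (!is.null(mids) && nrow(mids) > 0) {
            d2 <- (mids[, 1L] - ctr[1L])^2 + (mids[, 2L] - ctr[2L])^2
            if (min(d2) < (r + max(net$widths, 0) / 2 + 2)^2) next
          }
          blobSS <- paintStrokes(blobSS, list(rbind(ctr, ctr)), r,
                                 umPx / ss)
          placed <- placed + 1L
        }
        blobCov <- blockMean(blobSS + 0, ss)
      }
      bgLevel <- 0.82
      atten <- pmin(cov + 0.85 * blobCov, 1)
      clean <- bgLevel * (1 - spec@stainContrast * atten)
      if (spec@shadingAmplitude > 0) {
        xg <- seq(-1, 1, length.out = nc)
        yg <- seq(-1, 1, length.out = nr)
        cf <- stats::runif(5, -1, 1)
        X <- matrix(xg, nr, nc, byrow = TRUE)
        Y <- matrix(yg, nr, nc)
        F <- cf[1] * X + cf[2] * Y + cf[3] * X * Y + cf[4] * X^2 +
          cf[5] * Y^2
        mxF <- max(abs(F))
        if (mxF > 0) F <- F / mxF
        clean <- clean * (1 + spec@shadingAmplitude * F)
      }
      if (spec@noiseSd > 0)
        clean <- clean + stats::rnorm(nr * nc, 0, spec@noiseSd)
      img <- new("CalibratedImage", pixels = clip01(clean), umPerPx = umPx,
                 polarity = "dark", provenance = "synthetic")
    }
    list(image = img, truth = truth)
  })
}

#' Generate a two-group cohort of synthetic micrographs
#'
#' Mirrors the study design of a two-tissue comparison: \code{nImagesPerGroup}
#' images per group, with per-image seeds derived deterministically from the
#' cohort seed, so the whole cohort is reproducible from one integer. The
#' two groups differ only by their network specifications.
#'
#' @param specA,specB \code{\linkS4class{NetworkSpec}}s for the two groups
#'   (their \code{seed} slots are overridden by the derived per-image seeds).
#' @param nImagesPerGroup images per group, >= 2.
#' @param seed cohort seed.
#' @param groupNames length-2 character vector of group labels.
#' @param render passed to \code{\link{generateNetwork}}.
#' @return a list of cohort entries, each a list with elements \code{group},
#'   \code{seed}, \code{image} and \code{truth}.
#' @seealso \code{\link{cohortTruthTable}}, \code{\link{writeCohort}}
#' @export
generateCohort <- function(specA, specB, nImagesPerGroup, seed = 1L,
                           groupNames = c("A", "B"), render = TRUE) {
  stopifnot(is(specA, "NetworkSpec"), is(specB, "NetworkSpec"))
  if (nImagesPerGroup < 2L)
    stop("'nImagesPerGroup' must be >= 2")
  n <- as.integer(nImagesPerGroup)
  seeds <- withSeed(seed, sample.int(2147483646L, 2L * n))
  out <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    grp <- if (i <= n) 1L else 2L
    spec <- if (grp == 1L) specA else specB
    spec@seed <- seeds[i]
    gen <- generateNetwork(spec, render = render)
    out[[i]] <- list(group = groupNames[grp], seed = seeds[i],
                     image = gen$image, truth = gen$truth)
  }
  out
}

#' Tabulate the ground truth of a cohort
#'
#' @param cohort a list as returned by \code{\link{generateCohort}}.
#' @return a data.frame with one row per image: group, seed, total length
#'   (µm), branch-point count, true area fraction (%), mean width (µm).
#' @export
cohortTruthTable <- function(cohort) {
  data.frame(
    group = vapply(cohort, `[[`, character(1), "group"),
    seed = vapply(cohort, `[[`, integer(1), "seed"),
    total_length_um = vapply(cohort, function(e) e$truth@totalLengthUm,
                             numeric(1)),
    n_branch_points = vapply(cohort, function(e) e$truth@nBranchPoints,
                             integer(1)),
    true_area_fraction_pct = vapply(cohort,
                                    function(e) e$truth@trueAreaFractionPct,
                                    numeric(1)),
    mean_width_um = vapply(cohort, function(e) e$truth@meanWidthUm,
                           numeric(1)),
    stringsAsFactors = FALSE)
}
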