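# Zhang-Suen neighbor order P2..P9 = N, NE, E, SE, S, SW, W, NW as
# (dr, dc) shifts for shiftMat (out[r,c] = m[r-dr, c-dc])
ZS_SHIFTS <- list(c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L),
                  c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L))

#' Skeletonize a binary mask
#'
#' Deterministic Zhang-Suen binary thinning: iteratively peels boundary
#' pixels whose removal cannot disconnect the local neighborhood, until the
#' mask is reduced to a unit-width, 8-connected centerline. Thinning is
#' topology-preserving (the number of 8-connected components is unchanged)
#' and idempotent on already-thin input; an empty mask yields an empty
#' skeleton. Branch points are not detected here — see
#' \code{\link{findBranchPoints}}.
#'
#' @param mask a \code{\linkS4class{BinaryMask}}.
#' @return a \code{\linkS4class{SkeletonImage}} (with an empty branch-point
#'   table).
#' @references Zhang, T.Y. and Suen, C.Y. (1984) A fast parallel algorithm
#'   for thinning digital patterns. Communications of the ACM 27, 236-239.
#' @export
skeletonize <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  m <- mask@mask
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P <- lapply(ZS_SHIFTS, function(s) shiftMat(m, s[1L], s[2L], FALSE))
      B <- Reduce(`+`, P)
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in seq_len(8L)) {
        nxt <- if (k == 8L) 1L else k + 1L
        A <- A + (!P[[k]] & P[[nxt]])
      }
      if (sub == 1L) {
        cA <- !(P[[1L]] & P[[3L]] & P[[5L]])  # P2*P4*P6 == 0
        cB <- !(P[[3L]] & P[[5L]] & P[[7L]])  # P4*P6*P8 == 0
      } else {
        cA <- !(P[[1L]] & P[[3L]] & P[[7L]])  # P2*P4*P8 == 0
        cB <- !(P[[1L]] & P[[5L]] & P[[7L]])  # P2*P6*P8 == 0
      }
      del <- m & B >= 2L & B <= 6L & A == 1L & cA & cB
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m <- thinSequential(m)
  new("SkeletonImage", skeleton = m, umPerPx = mask@umPerPx)
}

# Sequential simple-point removal: deletes non-endpoint pixels whose Yokoi
# connectivity number (count of 8-connected foreground components in the
# 8-neighborhood) equals 1, i.e., whose removal provably preserves the
# local topology. Cleans up the shoulder/staircase residues the parallel
# passes leave, which would otherwise double-count length and fake
# junctions. Endpoints (single neighbor) anchor the curve and are kept.
thinSequential <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  # neighbor order x1..x8 = E, NE, N, NW, W, SW, S, SE (Yokoi indexing)
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  repeat {
    changed <- FALSE
    idx <- which(m)
    for (j in idx) {
      if (!m[j]) next
      r <- (j - 1L) %% nr + 1L
      cc <- (j - 1L) %/% nr + 1L
      x <- integer(8L)
      for (k in 1:8) {
        rr <- r + dr[k]; c2 <- cc + dc[k]
        x[k] <- rr >= 1L && rr <= nr && c2 >= 1L && c2 <= nc &&
          m[rr, c2]
      }
      B <- sum(x)
      if (B < 2L) next  # endpoint or isolated pixel
      xb <- 1L - x
      xb9 <- c(xb, xb[1L])
      c8 <- sum(xb9[c(1L, 3L, 5L, 7L)] -
                  xb9[c(1L, 3L, 5L, 7L)] * xb9[c(2L, 4L, 6L, 8L)] *
                  xb9[c(3L, 5L, 7L, 9L)])
      if (c8 == 1L) {
        m[j] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# walk the skeleton from one endpoint; returns the pixel path of a spur
# (everything that can be deleted without disconnecting the anchoring
# structure) or NULL if the branch is longer than maxLen or free-standing
traceSpur <- function(m, start, maxLen) {
  nr <- nrow(m); nc <- ncol(m)
  path <- integer(0)
  cur <- start
  for (step in seq_len(maxLen)) {
    path <- c(path, cur)
    r <- (cur - 1L) %% nr + 1L
    cc <- (cur - 1L) %/% nr + 1L
    outs <- integer(0)
    for (k in seq_len(8L)) {
      rr <- r + NBR8[k, 1L]; ccc <- cc + NBR8[k, 2L]
      if (rr >= 1L && rr <= nr && ccc >= 1L && ccc <= nc) {
        j <- rr + (ccc - 1L) * nr
        if (m[j] && !(j %in% path)) outs <- c(outs, j)
      }
    }
    if (length(outs) == 0L) return(NULL)  # free-standing segment: keep
    if (length(outs) == 1L) {             # plain curve pixel: walk on
      cur <- outs[1L]
      next
    }
    # several neighbors ahead: count their mutual 8-adjacency clusters
    or <- (outs - 1L) %% nr + 1L
    oc <- (outs - 1L) %/% nr + 1L
    nclust <- length(unique(clusterCoords8(cbind(or, oc))))
    # one cluster: the anchor continues past cur, so cur itself is still
    # spur; several clusters: cur joins separate structures and must stay
    return(if (nclust == 1L) path else path[-length(path)])
  }
  NULL
}

#' Prune short skeleton spurs
#'
#' Removes terminal skeleton twigs shorter than \code{maxLengthPx} that
#' attach to a junction. Such spurs arise from boundary roughness of the
#' binary mask under noise and would otherwise inflate the branching-point
#' count; genuine branches, which are much longer than the fiber half-width,
#' are untouched. Free-standing short segments (no junction at either end)
#' are also left in place — they are fibers, not spurs.
#'
#' @param skel a \code{\linkS4class{SkeletonImage}}.
#' @param maxLengthPx prune spurs of up to this many pixels; 0 is a no-op.
#' @return a pruned \code{\linkS4class{SkeletonImage}}.
#' @export
pruneSpurs <- function(skel, maxLengthPx = 5) {
  stopifnot(is(skel, "SkeletonImage"))
  maxLengthPx <- as.integer(maxLengthPx)
  if (maxLengthPx <= 0L) return(skel)
  m <- skel@skeleton
  B <- neighborCount8(m)
  ends <- which(m & B == 1L)
  for (e in ends) {
    if (!m[e]) next
    path <- traceSpur(m, e, maxLengthPx)
    if (length(path)) m[path] <- FALSE
  }
  new("SkeletonImage", skeleton = m, umPerPx = skel@umPerPx)
}

# single-linkage clustering of pixel coordinates under 8-adjacency
clusterCoords8 <- function(co) {
  n <- nrow(co)
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i]) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(lab == 0L & abs(co[, 1L] - co[j, 1L]) <= 1L &
                    abs(co[, 2L] - co[j, 2L]) <= 1L)
      if (length(nb)) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

#' Identify branching points of a skeleton
#'
#' A skeleton pixel is a junction pixel when it has at least three skeleton
#' neighbors in its 8-neighborhood. Because a single anatomical bifurcation
#' can produce a small cluster of mutually adjacent junction pixels, 8-adjacent
#' junction pixels are merged into one branching point, represented by the
#' cluster pixel closest to the cluster centroid. The returned object carries
#' the merged branch-point table.
#'
#' @param skel a \code{\linkS4class{SkeletonImage}}; expected unit-width.
#'   A non-thin skeleton triggers a warning (counts may inflate), not an
#'   error.
#' @param checkThin set \code{FALSE} to skip the thinness check (useful in
#'   tight loops over many small skeletons).
#' @return the \code{\linkS4class{SkeletonImage}} with its
#'   \code{branchPoints} slot filled; retrieve the table with
#'   \code{\link{branchPoints}}.
#' @export
findBranchPoints <- function(skel, checkThin = TRUE) {
  stopifnot(is(skel, "SkeletonImage"))
  m <- skel@skeleton
  if (checkThin && nrow(m) > 1L && ncol(m) > 1L) {
    sq <- m[-1L, -1L] & m[-nrow(m), -1L] & m[-1L, -ncol(m)] &
      m[-nrow(m), -ncol(m)]
    if (any(sq))
      warning("skeleton is not unit-width; branch-point counts may inflate")
  }
  B <- neighborCount8(m)
  jn <- which(m & B >= 3L)
  bp <- matrix(integer(), ncol = 2L,
               dimnames = list(NULL, c("row", "col")))
  if (length(jn)) {
    co <- cbind(row = (jn - 1L) %% nrow(m) + 1L,
                col = (jn - 1L) %/% nrow(m) + 1L)
    lab <- clusterCoords8(co)
    reps <- vapply(seq_len(max(lab)), function(l) {
      idx <- which(lab == l)
      ctr <- colMeans(co[idx, , drop = FALSE])
      d2 <- (co[idx, 1L] - ctr[1L])^2 + (co[idx, 2L] - ctr[2L])^2
      idx[which.min(d2)]
    }, integer(1))
    bp <- co[reps, , drop = FALSE]
  }
  new("SkeletonImage", skeleton = m, branchPoints = bp,
      umPerPx = skel@umPerPx)
}

#' Total skeleton length
#'
#' Sums the physical length of the skeleton as an adjacency-weighted count:
#' every unique pair of 8-adjacent skeleton pixels contributes 1 pixel unit
#' when orthogonally adjacent and sqrt(2) when diagonally adjacent, scaled
#' by the pixel size. This estimator is exact on axis-aligned and on
#' diagonal digital lines. Isolated single pixels contribute zero length.
#' A plain pixel-count estimator (\code{nPx * umPerPx}) is available for
#' sensitivity analysis.
#'
#' @param skel a \code{\linkS4class{SkeletonImage}}.
#' @param estimator \code{"adjacency"} (default) or \code{"pixel-count"}.
#' @return total length in millimetres.
#' @examples
#' s <- matrix(FALSE, 3, 101); s[2, ] <- TRUE
#' sk <- new("SkeletonImage", skeleton = s, umPerPx = 1)
#' measureLength(sk)  # 100 um = 0.1 mm
#' @export
measureLength <- function(skel, estimator = c("adjacency", "pixel-count")) {
  stopifnot(is(skel, "SkeletonImage"))
  estimator <- match.arg(estimator)
  m <- skel@skeleton
  umPx <- skel@umPerPx
  if (estimator == "pixel-count")
    return(sum(m) * umPx / 1000)
  nr <- nrow(m); nc <- ncol(m)
  horiz <- if (nc > 1L) sum(m[, -1L] & m[, -nc]) else 0L
  vert <- if (nr > 1L) sum(m[-1L, ] & m[-nr, ]) else 0L
  diag1 <- if (nr > 1L && nc > 1L) sum(m[-1L, -1L] & m[-nr, -nc]) else 0L
  diag2 <- if (nr > 1L && nc > 1L) sum(m[-1L, -nc] & m[-nr, -1L]) else 0L
  ((horiz + vert) + sqrt(2) * (diag1 + diag2)) * umPx / 1000
}

#' Morphometric summary of a segmented image
#'
#' Computes the four morphometric parameters from a binary mask and its
#' skeleton: positive area fraction (foreground pixels / total pixels x
#' 100), branching-point density (branch points / image area in mm^2),
#' total network length (mm, from \code{\link{measureLength}}), and mean
#' fiber thickness (foreground area in µm^2 divided by skeleton length in
#' µm). When the skeleton length is zero the thickness is undefined and
#' reported as \code{NA} with the \code{thicknessDefined} flag cleared, so
#' that it can be excluded (not zero-counted) from group statistics.
#'
#' By construction \code{meanThicknessUm x length(µm) == foreground area
#' (µm^2)} exactly, for every image.
#'
#' @param mask a \code{\linkS4class{BinaryMask}}.
#' @param skel the matching \code{\linkS4class{SkeletonImage}} (same shape
#'   and calibration), ideally after \code{\link{findBranchPoints}}.
#' @param lengthEstimator passed to \code{\link{measureLength}}.
#' @return a \code{\linkS4class{MorphometrySummary}}.
#' @export
summarizeMorphometry <- function(mask, skel,
                                 lengthEstimator = c("adjacency",
                                                     "pixel-count")) {
  stopifnot(is(mask, "BinaryMask"), is(skel, "SkeletonImage"))
  if (!identical(dim(mask@mask), dim(skel@skeleton)))
    stop("mask and skeleton shapes differ")
  if (!isTRUE(all.equal(mask@umPerPx, skel@umPerPx)))
    stop("mask and skeleton calibrations differ")
  umPx <- mask@umPerPx
  nPx <- prod(dim(mask@mask))
  nFg <- sum(mask@mask)
  nSk <- sum(skel@skeleton)
  nBp <- nrow(skel@branchPoints)
  areaMm2 <- nPx * (umPx / 1000)^2
  lengthMm <- measureLength(skel, match.arg(lengthEstimator))
  fgAreaUm2 <- nFg * umPx^2
  lengthUm <- lengthMm * 1000
  thick <- if (lengthUm > 0) fgAreaUm2 / lengthUm else NA_real_
  new("MorphometrySummary",
      positiveAreaPct = 100 * nFg / nPx,
      bpDensityPerMm2 = nBp / areaMm2,
      totalLengthMm = lengthMm,
      meanThicknessUm = thick,
      thicknessDefined = lengthUm > 0,
      nForegroundPx = as.integer(nFg),
      nSkeletonPx = as.integer(nSk),
      nBranchPoints = as.integer(nBp),
      imageAreaMm2 = areaMm2,
      umPerPx = umPx)
}
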