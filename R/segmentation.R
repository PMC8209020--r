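#' Adaptive local-mean thresholding
#'
#' Classifies a pixel as nerve foreground when its intensity strictly
#' exceeds the mean intensity of its surrounding \code{windowPx} x
#' \code{windowPx} neighborhood plus a fixed offset. The local mean is
#' computed with symmetric-reflect padding at the borders, so edge rows are
#' thresholded against a sensible neighborhood rather than zeros. Ties go to
#' background, which makes the behavior on constant images unambiguous
#' (empty mask for any positive offset).
#'
#' Because the rule compares each pixel with its own neighborhood mean, it
#' is invariant to adding a constant to the whole image, and masks are
#' nested in the offset: a larger offset always yields a subset.
#'
#' @param img a \code{\linkS4class{CalibratedImage}} with bright signal.
#' @param windowPx odd neighborhood size in pixels (default 15).
#' @param offset offset threshold constant on the [0, 1] intensity scale.
#'   The default 0.05 suits low-noise images; for noisy input it should be
#'   set to at least ~2.5x the noise s.d. (see the package vignette).
#' @return a \code{\linkS4class{BinaryMask}}.
#' @examples
#' img <- normalizeAndOrient(matrix(0.5, 64, 64), umPerPx = 1,
#'                           polarity = "bright")
#' nForegroundPx(adaptiveThreshold(img, offset = 0.01))  # 0
#' @export
adaptiveThreshold <- function(img, windowPx = 15L, offset = 0.05) {
  stopifnot(is(img, "CalibratedImage"))
  windowPx <- as.integer(windowPx)
  if (length(windowPx) != 1L || is.na(windowPx) || windowPx < 3L ||
      windowPx %% 2L == 0L)
    stop("'windowPx' must be an odd integer >= 3")
  if (offset < 0) stop("'offset' must be >= 0")
  lm <- localMean(img@pixels, windowPx)
  new("BinaryMask", mask = img@pixels > lm + offset, umPerPx = img@umPerPx)
}

# per-component area and perimeter (boundary edge count against background
# or image border), for the circularity filter
componentShape <- function(labels) {
  nlab <- max(labels)
  area <- tabulate(labels[labels > 0L], nbins = nlab)
  perim <- numeric(nlab)
  mask <- labels > 0L
  for (sh in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
    # boundary where the 4-neighbor is background or off-image
    nbr <- shiftMat(mask, sh[1L], sh[2L], FALSE)
    edge <- mask & !nbr
    perim <- perim + tabulate(labels[edge], nbins = nlab)
  }
  list(area = area, perimeter = perim)
}

#' Fill small enclosed holes in a binary mask
#'
#' Noise can punch single-pixel to few-pixel holes into otherwise solid
#' stained profiles; thinning such a mask produces spurious loops that
#' inflate both length and branch-point counts. This fills enclosed
#' background components of at most \code{maxHolePx} pixels (4-connected
#' background, matching 8-connected foreground). Genuine meshes of the
#' network — enclosed regions far larger than a fiber cross-section — are
#' left open.
#'
#' @param mask a \code{\linkS4class{BinaryMask}}.
#' @param maxHolePx largest hole area filled, px; 0 is a no-op.
#' @return a \code{\linkS4class{BinaryMask}} with \code{mask} as a subset.
#' @export
fillHoles <- function(mask, maxHolePx = 50) {
  stopifnot(is(mask, "BinaryMask"))
  if (maxHolePx <= 0 || !any(mask@mask)) return(mask)
  m <- mask@mask
  bgLab <- EBImage::bwlabel(!m)  # 4-connected background
  nlab <- max(bgLab)
  if (nlab == 0L) return(mask)
  areas <- tabulate(bgLab[bgLab > 0L], nbins = nlab)
  border <- unique(c(bgLab[1L, ], bgLab[nrow(m), ], bgLab[, 1L],
                     bgLab[, ncol(m)]))
  fill <- areas <= maxHolePx
  fill[border[border > 0L]] <- FALSE
  if (any(fill)) m[bgLab > 0L & fill[pmax(bgLab, 1L)]] <- TRUE
  new("BinaryMask", mask = m, umPerPx = mask@umPerPx)
}

#' Remove non-nervous artifacts from a binary mask
#'
#' Deterministic stand-in for interactive artifact editing: removes
#' 8-connected components smaller than \code{minObjectPx}, removes blob-like
#' components whose circularity \eqn{4 \pi A / P^2} exceeds
#' \code{circularityCutoff} (elongated fibers score near 0, disks near 1),
#' and clears any pixels under a user-supplied exclusion mask (e.g.,
#' adipocytes or vessels outlined by an expert). The result is always a
#' subset of the input mask.
#'
#' @param mask a \code{\linkS4class{BinaryMask}}.
#' @param minObjectPx minimum component area in pixels; 0 keeps everything.
#' @param circularityCutoff components with circularity above this are
#'   dropped; \code{NA} disables the filter.
#' @param exclusionMask optional \code{\linkS4class{BinaryMask}} (same
#'   shape); \code{TRUE} pixels are forced to background.
#' @param minCircularityAreaPx circularity is only assessed for components
#'   at least this large, so that tiny fragments (whose digital perimeter is
#'   unreliable) are governed by the size filter alone.
#' @return a filtered \code{\linkS4class{BinaryMask}}.
#' @export
removeArtifacts <- function(mask, minObjectPx = 25, circularityCutoff = 0.5,
                            exclusionMask = NULL,
                            minCircularityAreaPx = 20) {
  stopifnot(is(mask, "BinaryMask"))
  if (minObjectPx < 0) stop("'minObjectPx' must be >= 0")
  m <- mask@mask
  if (!is.null(exclusionMask)) {
    stopifnot(is(exclusionMask, "BinaryMask"))
    if (!identical(dim(exclusionMask@mask), dim(m)))
      stop("'exclusionMask' shape does not match the mask")
    m <- m & !exclusionMask@mask
  }
  if (any(m) && (minObjectPx > 0 || !is.na(circularityCutoff))) {
    labels <- labelComponents8(m)
    shape <- componentShape(labels)
    drop <- shape$area < minObjectPx
    if (!is.na(circularityCutoff)) {
      circ <- 4 * pi * shape$area / pmax(shape$perimeter, 1)^2
      drop <- drop | (circ > circularityCutoff &
                      shape$area >= minCircularityAreaPx)
    }
    if (any(drop)) m[labels > 0L & drop[pmax(labels, 1L)]] <- FALSE
  }
  new("BinaryMask", mask = m, umPerPx = mask@umPerPx)
}
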