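#' Normalize intensities and orient the stain signal bright
#'
#' Scales a raw 8- or 16-bit grayscale grid to [0, 1] and, if the stain is
#' dark on a bright background (the usual DAB appearance), inverts the image
#' so that downstream operators can always assume bright signal. The original
#' polarity is recorded in the result. Already-normalized bright-signal input
#' passes through unchanged.
#'
#' Polarity detection (\code{polarity = "auto"}) assumes the stain occupies a
#' minority of pixels: when the median intensity sits above the midpoint of
#' the intensity range, the background is bright and the signal is taken to
#' be dark.
#'
#' @param raw numeric or integer matrix: raw intensities. Values above 1 are
#'   treated as integer codes of the given bit depth; values already in
#'   [0, 1] are used as-is.
#' @param umPerPx physical pixel size, micrometres per pixel.
#' @param polarity \code{"auto"}, \code{"dark"} or \code{"bright"}: where the
#'   stain signal sits in \code{raw}.
#' @param bitDepth \code{"auto"}, 8 or 16. With \code{"auto"}, values above
#'   255 imply 16-bit, otherwise 8-bit.
#' @return a \code{\linkS4class{CalibratedImage}} with bright signal.
#' @examples
#' img <- normalizeAndOrient(matrix(255L, 64, 64), umPerPx = 1)
#' range(imageMatrix(img))
#' @export
normalizeAndOrient <- function(raw, umPerPx,
                               polarity = c("auto", "dark", "bright"),
                               bitDepth = "auto") {
  polarity <- match.arg(polarity)
  if (is.array(raw) && length(dim(raw)) == 3L) {
    if (dim(raw)[3L] == 1L) raw <- raw[, , 1L]
    else stop("multi-channel (RGB) input is not supported; ",
              "convert the image to single-channel grayscale first")
  }
  if (!is.matrix(raw) || !is.numeric(raw))
    stop("input must be a 2-D numeric matrix of intensities")
  if (any(!is.finite(raw))) stop("input contains non-finite intensities")
  mx <- max(raw)
  if (mx > 1) {
    depth <- if (identical(bitDepth, "auto")) {
      if (mx > 255) 16L else 8L
    } else as.integer(bitDepth)
    if (!depth %in% c(8L, 16L))
      stop("bit depth must be 8 or 16")
    scale <- 2^depth - 1
    if (mx > scale)
      stop(sprintf("intensities exceed the %d-bit range", depth))
    px <- raw / scale
  } else {
    if (min(raw) < 0) stop("negative intensities are not supported")
    px <- raw
  }
  rng <- range(px)
  signalDark <- switch(polarity,
    dark = TRUE,
    bright = FALSE,
    auto = diff(rng) > 0 && stats::median(px) > mean(rng))
  origPolarity <- if (signalDark) "dark" else "bright"
  if (signalDark) px <- 1 - px
  new("CalibratedImage", pixels = px, umPerPx = umPerPx,
      polarity = origPolarity, provenance = "normalize")
}

#' Flatten uneven illumination and remove background signal
#'
#' Estimates a smooth background by a morphological opening with a disk
#' element much larger than any fiber and subtracts it, removing both
#' vignetting-style shading and diffuse background staining in one step.
#' Operates on bright-signal images; the result is re-clipped to [0, 1].
#'
#' @param img a \code{\linkS4class{CalibratedImage}} with bright signal.
#' @param backgroundScalePx diameter (px) of the background structuring
#'   element; must exceed the fiber width by a wide margin (>= 5x).
#' @param expectedFiberWidthPx optional expected fiber width (px); when
#'   given and \code{backgroundScalePx} is less than 5x that width a warning
#'   is issued.
#' @return a \code{\linkS4class{CalibratedImage}}; constant input maps to a
#'   (near-)zero image.
#' @export
flattenIllumination <- function(img, backgroundScalePx = 50,
                                expectedFiberWidthPx = NULL) {
  stopifnot(is(img, "CalibratedImage"))
  if (backgroundScalePx <= 0)
    stop("'backgroundScalePx' must be > 0")
  if (!is.null(expectedFiberWidthPx) &&
      backgroundScalePx < 5 * expectedFiberWidthPx)
    warning("'backgroundScalePx' is less than 5x the expected fiber width; ",
            "the background estimate may eat into the fibers")
  size <- 2L * (as.integer(backgroundScalePx) %/% 2L) + 1L  # odd
  bg <- EBImage::opening(img@pixels, EBImage::makeBrush(size, "disc"))
  new("CalibratedImage", pixels = clip01(img@pixels - bg),
      umPerPx = img@umPerPx, polarity = img@polarity,
      provenance = c(img@provenance, "flatten"))
}

#' Top-hat contrast enhancement
#'
#' White morphological top-hat (image minus its opening) with a disk
#' structuring element: retains bright structures narrower than about twice
#' the element radius — the nerve fibers — while suppressing the background
#' and any structure wider than the element, sharpening the contrast between
#' the fiber network and everything else.
#'
#' @param img a \code{\linkS4class{CalibratedImage}} with bright signal.
#' @param elementRadiusPx radius (px) of the structuring disk; should be
#'   comfortably larger than the half-width of the widest fiber of interest.
#' @return a \code{\linkS4class{CalibratedImage}}; output is pointwise
#'   less than or equal to the input and a constant image maps to zero.
#' @export
tophatEnhance <- function(img, elementRadiusPx = 8) {
  stopifnot(is(img, "CalibratedImage"))
  if (elementRadiusPx < 1)
    stop("'elementRadiusPx' must be >= 1")
  size <- 2L * as.integer(round(elementRadiusPx)) + 1L
  th <- EBImage::whiteTopHat(img@pixels, EBImage::makeBrush(size, "disc"))
  new("CalibratedImage", pixels = clip01(th),
      umPerPx = img@umPerPx, polarity = img@polarity,
      provenance = c(img@provenance, "tophat"))
}
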