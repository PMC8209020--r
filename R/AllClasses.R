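#' @import methods
NULL

#' Calibrated grayscale micrograph
#'
#' A 2-D intensity grid in [0, 1] together with its physical pixel size and a
#' record of the processing steps applied so far. Every stage of the pipeline
#' consumes and produces this container, so physical calibration can never be
#' lost between steps. The \code{polarity} flag records whether the stain
#' signal is bright or dark in \code{pixels}; all enhancement operators in
#' this package expect bright signal (see \code{\link{normalizeAndOrient}}).
#'
#' @slot pixels numeric matrix, intensities in [0, 1].
#' @slot umPerPx physical pixel size, micrometres per pixel.
#' @slot polarity \code{"bright"} or \code{"dark"}: where the stain signal
#'   currently sits relative to the background.
#' @slot provenance character vector of step names, append-only.
#'
#' @seealso \code{\link{normalizeAndOrient}}, \code{\link{flattenIllumination}},
#'   \code{\link{tophatEnhance}}
#' @exportClass CalibratedImage
setClass("CalibratedImage",
  representation(
    pixels = "matrix",
    umPerPx = "numeric",
    polarity = "character",
    provenance = "character"
  ),
  prototype(polarity = "bright", provenance = character())
)

setValidity("CalibratedImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p) || length(dim(p)) != 2L)
    return("'pixels' must be a 2-D numeric matrix")
  if (any(!is.finite(p)))
    return("'pixels' contains non-finite values")
  if (min(p) < 0 || max(p) > 1)
    return("'pixels' must lie within [0, 1]")
  if (length(object@umPerPx) != 1L || !is.finite(object@umPerPx) ||
      object@umPerPx <= 0)
    return("'umPerPx' must be a single positive number")
  if (!object@polarity %in% c("bright", "dark"))
    return("'polarity' must be \"bright\" or \"dark\"")
  TRUE
})

#' Binary nerve-network mask
#'
#' Per-pixel foreground/background labeling of a micrograph, carrying the same
#' physical calibration as its source image. Foreground pixels are those
#' classified as stained nerve tissue.
#'
#' @slot mask logical matrix; \code{TRUE} = nerve foreground.
#' @slot umPerPx micrometres per pixel.
#'
#' @seealso \code{\link{adaptiveThreshold}}, \code{\link{removeArtifacts}}
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(mask = "matrix", umPerPx = "numeric")
)

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@mask) || length(dim(object@mask)) != 2L)
    return("'mask' must be a 2-D logical matrix")
  if (any(is.na(object@mask)))
    return("'mask' contains NA")
  if (length(object@umPerPx) != 1L || !is.finite(object@umPerPx) ||
      object@umPerPx <= 0)
    return("'umPerPx' must be a single positive number")
  TRUE
})

#' Skeleton of a binary nerve network
#'
#' Unit-width, 8-connected centerline of a \code{\linkS4class{BinaryMask}},
#' with the identified branching points. Branch points are stored as
#' (row, col) pixel coordinates of one representative skeleton pixel per
#' merged junction cluster.
#'
#' @slot skeleton logical matrix, thin 8-connected centerline.
#' @slot branchPoints integer matrix with columns \code{row}, \code{col};
#'   zero rows when the skeleton has no junctions.
#' @slot umPerPx micrometres per pixel.
#'
#' @seealso \code{\link{skeletonize}}, \code{\link{findBranchPoints}},
#'   \code{\link{measureLength}}
#' @exportClass SkeletonImage
setClass("SkeletonImage",
  representation(skeleton = "matrix", branchPoints = "matrix",
                 umPerPx = "numeric"),
  prototype(branchPoints = matrix(integer(), ncol = 2,
                                  dimnames = list(NULL, c("row", "col"))))
)

setValidity("SkeletonImage", function(object) {
  if (!is.logical(object@skeleton) || length(dim(object@skeleton)) != 2L)
    return("'skeleton' must be a 2-D logical matrix")
  bp <- object@branchPoints
  if (ncol(bp) != 2L)
    return("'branchPoints' must have two columns (row, col)")
  if (nrow(bp) > 0) {
    if (any(bp[, 1] < 1 | bp[, 1] > nrow(object@skeleton) |
            bp[, 2] < 1 | bp[, 2] > ncol(object@skeleton)))
      return("branch-point coordinates fall outside the image")
    if (any(!object@skeleton[bp]))
      return("branch-point coordinates must lie on the skeleton")
  }
  if (length(object@umPerPx) != 1L || object@umPerPx <= 0)
    return("'umPerPx' must be a single positive number")
  TRUE
})

#' Morphometric summary of one image
#'
#' The four morphometric parameters of the nerve-network analysis —
#' positive area fraction (%), branching-point density (/mm^2), total network
#' length (mm) and mean fiber thickness (µm) — plus the raw pixel tallies
#' they derive from. Mean thickness is foreground area divided by skeleton
#' length; when the skeleton has zero length the thickness is undefined and
#' reported as \code{NA} with \code{thicknessDefined = FALSE}.
#'
#' @slot positiveAreaPct percentage of image area covered by the mask.
#' @slot bpDensityPerMm2 branching points per square millimetre.
#' @slot totalLengthMm skeleton length, millimetres.
#' @slot meanThicknessUm foreground area / skeleton length, micrometres
#'   (\code{NA} when undefined).
#' @slot thicknessDefined logical flag.
#' @slot nForegroundPx,nSkeletonPx,nBranchPoints raw counts.
#' @slot imageAreaMm2 physical image area, mm^2.
#' @slot umPerPx micrometres per pixel.
#'
#' @seealso \code{\link{summarizeMorphometry}}
#' @exportClass MorphometrySummary
setClass("MorphometrySummary",
  representation(
    positiveAreaPct = "numeric",
    bpDensityPerMm2 = "numeric",
    totalLengthMm = "numeric",
    meanThicknessUm = "numeric",
    thicknessDefined = "logical",
    nForegroundPx = "integer",
    nSkeletonPx = "integer",
    nBranchPoints = "integer",
    imageAreaMm2 = "numeric",
    umPerPx = "numeric"
  )
)

setValidity("MorphometrySummary", function(object) {
  num <- c(object@positiveAreaPct, object@bpDensityPerMm2,
           object@totalLengthMm, object@imageAreaMm2)
  if (any(!is.finite(num)) || any(num < 0))
    return("summary values must be finite and non-negative")
  if (object@thicknessDefined && (!is.finite(object@meanThicknessUm) ||
                                  object@meanThicknessUm < 0))
    return("'meanThicknessUm' must be non-negative when defined")
  cnt <- c(object@nForegroundPx, object@nSkeletonPx, object@nBranchPoints)
  if (any(cnt < 0))
    return("pixel counts must be non-negative")
  TRUE
})

#' Specification of a synthetic nerve-network micrograph
#'
#' Parameter set for \code{\link{generateNetwork}}: field geometry, fiber
#' geometry, density target, and the optical degradations (stain contrast,
#' illumination shading, sensor noise, non-nervous blob artifacts) that the
#' rendered image carries. All fiber geometry is defined in physical units
#' (µm), so the same seed produces the same physical network at any pixel
#' size.
#'
#' @slot imageSizePx integer of length 2: (rows, cols), each >= 64.
#' @slot umPerPx micrometres per pixel, > 0.
#' @slot nSeeds number of initial primary fibers.
#' @slot branchProb probability per µm of fiber growth of spawning a child
#'   branch, in [0, 1].
#' @slot fiberWidthUm mean fiber width (orthogonal to the centerline), µm.
#' @slot widthJitter relative s.d. of per-fiber width, in [0, 0.5).
#' @slot targetAreaFractionPct target foreground coverage, %; \code{NA} to
#'   grow fibers to \code{fiberLengthUm} instead.
#' @slot fiberLengthUm fixed length per primary fiber, µm (used when no area
#'   target is set); \code{NA} otherwise.
#' @slot curvatureSd s.d. of the per-step turning angle, radians; 0 gives
#'   straight fibers.
#' @slot stainContrast foreground/background intensity separation, [0, 1].
#' @slot shadingAmplitude relative amplitude of the smooth multiplicative
#'   illumination field, [0, 0.5].
#' @slot noiseSd additive Gaussian noise s.d. as a fraction of dynamic range.
#' @slot nBlobArtifacts number of non-nervous blob structures.
#' @slot seed RNG seed (integer).
#'
#' @seealso \code{\link{networkSpec}}, \code{\link{presetSpec}}
#' @exportClass NetworkSpec
setClass("NetworkSpec",
  representation(
    imageSizePx = "integer",
    umPerPx = "numeric",
    nSeeds = "integer",
    branchProb = "numeric",
    fiberWidthUm = "numeric",
    widthJitter = "numeric",
    targetAreaFractionPct = "numeric",
    fiberLengthUm = "numeric",
    curvatureSd = "numeric",
    stainContrast = "numeric",
    shadingAmplitude = "numeric",
    noiseSd = "numeric",
    nBlobArtifacts = "integer",
    seed = "integer"
  )
)

setValidity("NetworkSpec", function(object) {
  if (length(object@imageSizePx) != 2L || any(object@imageSizePx < 64L))
    return("'imageSizePx' must be two integers, each >= 64")
  if (object@umPerPx <= 0) return("'umPerPx' must be > 0")
  if (object@nSeeds < 0L) return("'nSeeds' must be >= 0")
  if (object@branchProb < 0 || object@branchProb > 1)
    return("'branchProb' must lie in [0, 1]")
  if (object@fiberWidthUm <= 0) return("'fiberWidthUm' must be > 0")
  if (object@widthJitter < 0 || object@widthJitter >= 0.5)
    return("'widthJitter' must lie in [0, 0.5)")
  if (!is.na(object@targetAreaFractionPct) &&
      (object@targetAreaFractionPct <= 0 ||
       object@targetAreaFractionPct > 100))
    return("'targetAreaFractionPct' must lie in (0, 100]")
  if (!is.na(object@fiberLengthUm) && object@fiberLengthUm <= 0)
    return("'fiberLengthUm' must be > 0")
  if (object@curvatureSd < 0) return("'curvatureSd' must be >= 0")
  if (object@stainContrast < 0 || object@stainContrast > 1)
    return("'stainContrast' must lie in [0, 1]")
  if (object@shadingAmplitude < 0 || object@shadingAmplitude > 0.5)
    return("'shadingAmplitude' must lie in [0, 0.5]")
  if (object@noiseSd < 0 || object@noiseSd > 0.5)
    return("'noiseSd' must lie in [0, 0.5]")
  if (object@nBlobArtifacts < 0L) return("'nBlobArtifacts' must be >= 0")
  TRUE
})

#' Ground truth of a synthetic network
#'
#' Analytic description of a generated fiber network, computed from the
#' geometry before shading, noise or artifacts are applied: the centerline
#' polylines, total centerline length, number of branch attachment events,
#' area-weighted mean width, and the rendered foreground area measured on a
#' supersampled rasterization of the noiseless geometry.
#'
#' @slot polylines list of n-by-2 matrices of (row, col) pixel coordinates
#'   (fractional), one per fiber.
#' @slot widthsUm per-polyline fiber width, µm.
#' @slot totalLengthUm summed centerline length, µm.
#' @slot nBranchPoints number of child polylines attached to a parent.
#' @slot meanWidthUm area-weighted mean fiber width, µm.
#' @slot foregroundAreaUm2 rendered foreground area, µm^2 (4x supersampled).
#' @slot trueAreaFractionPct foreground area / image area x 100.
#'
#' @seealso \code{\link{generateNetwork}}
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    polylines = "list",
    widthsUm = "numeric",
    totalLengthUm = "numeric",
    nBranchPoints = "integer",
    meanWidthUm = "numeric",
    foregroundAreaUm2 = "numeric",
    trueAreaFractionPct = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  if (length(object@polylines) != length(object@widthsUm))
    return("'polylines' and 'widthsUm' lengths differ")
  if (object@totalLengthUm < 0 || object@foregroundAreaUm2 < 0)
    return("lengths and areas must be non-negative")
  if (object@nBranchPoints < 0L) return("'nBranchPoints' must be >= 0")
  TRUE
})

#' Per-group summary of one morphometric parameter
#'
#' Sample count, mean and standard error of the mean (sample s.d. with the
#' n - 1 denominator, divided by sqrt(n)) for one parameter in one group.
#'
#' @slot n sample count (>= 2).
#' @slot mean arithmetic mean.
#' @slot sem standard error of the mean.
#' @slot parameterName which morphometric parameter.
#' @slot units one of \code{"\%"}, \code{"/mm2"}, \code{"mm"}, \code{"um"},
#'   or free text.
#'
#' @seealso \code{\link{groupSummary}}, \code{\link{tTestGroups}}
#' @exportClass GroupStats
setClass("GroupStats",
  representation(n = "integer", mean = "numeric", sem = "numeric",
                 parameterName = "character", units = "character"),
  prototype(parameterName = "", units = "")
)

setValidity("GroupStats", function(object) {
  if (object@n < 2L) return("'n' must be >= 2")
  if (!is.finite(object@mean)) return("'mean' must be finite")
  if (!is.finite(object@sem) || object@sem < 0)
    return("'sem' must be finite and >= 0")
  TRUE
})

#' Two-sample t-test result
#'
#' @slot tStatistic the t statistic.
#' @slot df degrees of freedom.
#' @slot pValue two-tailed p value in [0, 1].
#' @slot variant \code{"student"} (pooled df) or \code{"welch"}.
#' @slot source \code{"raw-values"} or \code{"summary-stats"}.
#'
#' @seealso \code{\link{tTestGroups}}
#' @exportClass TTestResult
setClass("TTestResult",
  representation(tStatistic = "numeric", df = "numeric", pValue = "numeric",
                 variant = "character", source = "character")
)

setValidity("TTestResult", function(object) {
  if (is.na(object@pValue) || object@pValue < 0 || object@pValue > 1)
    return("'pValue' must lie in [0, 1]")
  if (!is.na(object@df) && object@df <= 0)
    return("'df' must be > 0")
  TRUE
})

#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis, in one serializable,
#' hashable object. Every run's effective configuration hash is embedded in
#' the outputs so that results can be traced to the exact parameter set.
#'
#' @slot umPerPx micrometres per pixel of the input images.
#' @slot backgroundScalePx diameter (px) of the background-estimation element
#'   used by \code{\link{flattenIllumination}}; should be well above the
#'   fiber width (at least 5x).
#' @slot tophatRadiusPx radius (px) of the top-hat structuring disk.
#' @slot thresholdWindowPx odd window size of the local-mean threshold
#'   (default 15).
#' @slot thresholdOffset offset added to the local mean, on the [0, 1]
#'   intensity scale.
#' @slot minObjectPx minimum connected-component area kept, px.
#' @slot circularityCutoff components with circularity (4 pi A / P^2) above
#'   this are removed as blob artifacts; \code{NA} disables the filter.
#' @slot fillHolesPx enclosed mask holes up to this area (px) are filled
#'   before skeletonization; 0 disables filling.
#' @slot spurPrunePx skeleton spurs shorter than this (px) are pruned before
#'   branch-point detection; 0 disables pruning.
#' @slot lengthEstimator \code{"adjacency"} (orthogonal steps count 1,
#'   diagonal steps sqrt(2)) or \code{"pixel-count"}.
#' @slot ttestVariant \code{"student"} or \code{"welch"}.
#' @slot seed RNG seed recorded with the run.
#'
#' @seealso \code{\link{pipelineConfig}}, \code{\link{runPipeline}}
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(
    umPerPx = "numeric",
    backgroundScalePx = "numeric",
    tophatRadiusPx = "numeric",
    thresholdWindowPx = "integer",
    thresholdOffset = "numeric",
    minObjectPx = "numeric",
    circularityCutoff = "numeric",
    fillHolesPx = "numeric",
    spurPrunePx = "numeric",
    lengthEstimator = "character",
    ttestVariant = "character",
    seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  if (object@umPerPx <= 0) return("'umPerPx' must be > 0")
  if (object@backgroundScalePx <= 0) return("'backgroundScalePx' must be > 0")
  if (object@tophatRadiusPx < 1) return("'tophatRadiusPx' must be >= 1")
  w <- object@thresholdWindowPx
  if (w < 3L || w %% 2L == 0L)
    return("'thresholdWindowPx' must be an odd integer >= 3")
  if (object@thresholdOffset < 0) return("'thresholdOffset' must be >= 0")
  if (object@minObjectPx < 0) return("'minObjectPx' must be >= 0")
  if (object@fillHolesPx < 0) return("'fillHolesPx' must be >= 0")
  if (object@spurPrunePx < 0) return("'spurPrunePx' must be >= 0")
  if (!object@lengthEstimator %in% c("adjacency", "pixel-count"))
    return("'lengthEstimator' must be \"adjacency\" or \"pixel-count\"")
  if (!object@ttestVariant %in% c("student", "welch"))
    return("'ttestVariant' must be \"student\" or \"welch\"")
  TRUE
})
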