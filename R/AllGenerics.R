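#' Accessor generics
#'
#' Small accessor generics shared by the image containers: the pixel grid,
#' the physical calibration, the provenance trail, foreground tallies and
#' branch points. Accessors are the supported way to read object state;
#' slots are internal.
#'
#' @param x an object of one of the package's classes.
#' @return \code{imageMatrix}: the underlying matrix (numeric or logical);
#'   \code{umPerPx}: micrometres per pixel; \code{provenance}: character
#'   vector of applied steps; \code{nForegroundPx}: integer foreground pixel
#'   count; \code{branchPoints}: integer matrix of (row, col) coordinates.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageMatrix", function(x) standardGeneric("imageMatrix"))

#' @rdname accessors
#' @export
setGeneric("umPerPx", function(x) standardGeneric("umPerPx"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("nForegroundPx", function(x) standardGeneric("nForegroundPx"))

#' @rdname accessors
#' @export
setGeneric("branchPoints", function(x) standardGeneric("branchPoints"))

#' @rdname accessors
#' @export
setMethod("imageMatrix", "CalibratedImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("imageMatrix", "BinaryMask", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("imageMatrix", "SkeletonImage", function(x) x@skeleton)

#' @rdname accessors
#' @export
setMethod("umPerPx", "CalibratedImage", function(x) x@umPerPx)

#' @rdname accessors
#' @export
setMethod("umPerPx", "BinaryMask", function(x) x@umPerPx)

#' @rdname accessors
#' @export
setMethod("umPerPx", "SkeletonImage", function(x) x@umPerPx)

#' @rdname accessors
#' @export
setMethod("provenance", "CalibratedImage", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("nForegroundPx", "BinaryMask", function(x) sum(x@mask))

#' @rdname accessors
#' @export
setMethod("nForegroundPx", "SkeletonImage", function(x) sum(x@skeleton))

#' @rdname accessors
#' @export
setMethod("branchPoints", "SkeletonImage", function(x) x@branchPoints)

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CalibratedImage: %d x %d px at %.4g um/px (%s signal)\n",
              d[1], d[2], object@umPerPx, object@polarity))
  cat(sprintf("  intensity range [%.3f, %.3f]\n",
              min(object@pixels), max(object@pixels)))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@mask)
  npx <- sum(object@mask)
  cat(sprintf("BinaryMask: %d x %d px at %.4g um/px\n", d[1], d[2],
              object@umPerPx))
  cat(sprintf("  foreground: %d px (%.2f%%)\n", npx,
              100 * npx / prod(d)))
})

setMethod("show", "SkeletonImage", function(object) {
  d <- dim(object@skeleton)
  cat(sprintf("SkeletonImage: %d x %d px at %.4g um/px\n", d[1], d[2],
              object@umPerPx))
  cat(sprintf("  skeleton: %d px; branch points: %d\n",
              sum(object@skeleton), nrow(object@branchPoints)))
})

setMethod("show", "MorphometrySummary", function(object) {
  cat("MorphometrySummary\n")
  cat(sprintf("  positive area:    %8.3f %%\n", object@positiveAreaPct))
  cat(sprintf("  BP density:       %8.2f /mm^2\n", object@bpDensityPerMm2))
  cat(sprintf("  total length:     %8.4f mm\n", object@totalLengthMm))
  if (object@thicknessDefined)
    cat(sprintf("  mean thickness:   %8.3f um\n", object@meanThicknessUm))
  else
    cat("  mean thickness:   undefined (zero-length skeleton)\n")
  cat(sprintf("  image area:       %8.4f mm^2 (%d fg px, %d skel px, %d BP)\n",
              object@imageAreaMm2, object@nForegroundPx, object@nSkeletonPx,
              object@nBranchPoints))
})

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf("NetworkSpec: %d x %d px at %.4g um/px, seed %d\n",
              object@imageSizePx[1], object@imageSizePx[2], object@umPerPx,
              object@seed))
  tgt <- if (is.na(object@targetAreaFractionPct)) "none"
         else sprintf("%.2f%%", object@targetAreaFractionPct)
  cat(sprintf("  %d seeds, branchProb %.3g /um, width %.2f um (jitter %.2f), area target %s\n",
              object@nSeeds, object@branchProb, object@fiberWidthUm,
              object@widthJitter, tgt))
  cat(sprintf("  contrast %.2f, shading %.2f, noise %.3f, %d blob artifacts\n",
              object@stainContrast, object@shadingAmplitude, object@noiseSd,
              object@nBlobArtifacts))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d fibers, %.1f um total length, %d branch points\n",
              length(object@polylines), object@totalLengthUm,
              object@nBranchPoints))
  cat(sprintf("  mean width %.2f um, foreground %.1f um^2 (%.3f%% of field)\n",
              object@meanWidthUm, object@foregroundAreaUm2,
              object@trueAreaFractionPct))
})

setMethod("show", "GroupStats", function(object) {
  nm <- if (nzchar(object@parameterName)) object@parameterName else "value"
  cat(sprintf("GroupStats: %s = %.4g +/- %.4g (%s), n = %d\n",
              nm, object@mean, object@sem,
              if (nzchar(object@units)) object@units else "unitless",
              object@n))
})

setMethod("show", "TTestResult", function(object) {
  cat(sprintf("TTestResult (%s, %s): t = %.4g, df = %.4g, p = %.4g\n",
              object@variant, object@source, object@tStatistic, object@df,
              object@pValue))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  umPerPx %.4g | background %g px | tophat r %g px\n",
              object@umPerPx, object@backgroundScalePx,
              object@tophatRadiusPx))
  cat(sprintf("  threshold window %d px, offset %.3f | minObject %g px | circularity %s\n",
              object@thresholdWindowPx, object@thresholdOffset,
              object@minObjectPx,
              ifelse(is.na(object@circularityCutoff), "off",
                     sprintf("%.2f", object@circularityCutoff))))
  cat(sprintf("  spur prune %g px | length: %s | t-test: %s | seed %d\n",
              object@spurPrunePx, object@lengthEstimator,
              object@ttestVariant, object@seed))
  cat(sprintf("  hash: %s\n", configHash(object)))
})
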