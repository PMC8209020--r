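#' Construct a pipeline configuration
#'
#' Builds and validates a \code{\linkS4class{PipelineConfig}}. The defaults
#' suit fibers a handful of pixels wide on low-noise images; the
#' \code{\link{presetConfig}} variants carry the parameters calibrated for
#' the synthetic tissue presets.
#'
#' @param umPerPx micrometres per pixel of the input images.
#' @param backgroundScalePx background-estimation element diameter, px.
#' @param tophatRadiusPx top-hat disk radius, px.
#' @param thresholdWindowPx odd local-mean window, px (default 15).
#' @param thresholdOffset offset threshold constant on the [0, 1] scale.
#' @param minObjectPx minimum component area kept, px.
#' @param circularityCutoff blob-circularity cutoff (NA = off).
#' @param fillHolesPx largest enclosed mask hole filled, px.
#' @param spurPrunePx maximum skeleton-spur length pruned, px.
#' @param lengthEstimator \code{"adjacency"} or \code{"pixel-count"}.
#' @param ttestVariant \code{"student"} or \code{"welch"}.
#' @param seed seed recorded with the run.
#' @return a validated \code{\linkS4class{PipelineConfig}}.
#' @export
pipelineConfig <- function(umPerPx = 1, backgroundScalePx = 50,
                           tophatRadiusPx = 8, thresholdWindowPx = 15L,
                           thresholdOffset = 0.05, minObjectPx = 25,
                           circularityCutoff = 0.5, fillHolesPx = 50,
                           spurPrunePx = 5,
                           lengthEstimator = "adjacency",
                           ttestVariant = "student", seed = 1L) {
  cfg <- new("PipelineConfig", umPerPx = umPerPx,
             backgroundScalePx = backgroundScalePx,
             tophatRadiusPx = tophatRadiusPx,
             thresholdWindowPx = as.integer(thresholdWindowPx),
             thresholdOffset = thresholdOffset, minObjectPx = minObjectPx,
             circularityCutoff = circularityCutoff,
             fillHolesPx = fillHolesPx, spurPrunePx = spurPrunePx, lengthEstimator = lengthEstimator,
             ttestVariant = ttestVariant, seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Pipeline configuration calibrated for the synthetic tissue presets
#'
#' Parameters matched to the \code{\link{presetSpec}} imaging regime
#' (1 µm/px, fibers ~5-6 px wide, noise s.d. 0.05): background element 31 px
#' (>= 5x fiber width), top-hat radius 12 px (~2x fiber width), the printed
#' 15 x 15 threshold window, offset 0.12 (2.4x the noise s.d., so residual
#' background false positives are isolated pixels removable by the
#' size filter), minimum object 25 px, circularity cutoff 0.45, hole
#' filling up to 50 px, spur pruning 5 px.
#'
#' @param seed seed recorded with the run.
#' @return a \code{\linkS4class{PipelineConfig}}.
#' @export
presetConfig <- function(seed = 1L) {
  pipelineConfig(umPerPx = 1, backgroundScalePx = 31, tophatRadiusPx = 12,
                 thresholdWindowPx = 15L, thresholdOffset = 0.12,
                 minObjectPx = 25, circularityCutoff = 0.45,
                 fillHolesPx = 50, spurPrunePx = 5, seed = seed)
}

#' Hash of the effective configuration
#'
#' MD5 over a canonical text rendering of every parameter, embedded in all
#' outputs so that results are traceable to the exact parameter set. Two
#' different configurations never share a hash (up to MD5 collisions).
#'
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @return a 32-character hex string.
#' @export
configHash <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  slots <- slotNames(config)
  txt <- vapply(slots, function(s) {
    v <- slot(config, s)
    sprintf("%s=%s", s,
            if (is.numeric(v)) sprintf("%.17g", v) else as.character(v))
  }, character(1))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Segment one calibrated image
#'
#' The segmentation stages of the pipeline in their fixed order: flatten
#' illumination, top-hat enhancement, adaptive local-mean thresholding,
#' artifact removal.
#'
#' @param img a bright-signal \code{\linkS4class{CalibratedImage}}.
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @param exclusionMask optional \code{\linkS4class{BinaryMask}} of regions
#'   to exclude.
#' @return a \code{\linkS4class{BinaryMask}}.
#' @export
segmentImage <- function(img, config, exclusionMask = NULL) {
  stopifnot(is(img, "CalibratedImage"), is(config, "PipelineConfig"))
  img <- flattenIllumination(img, config@backgroundScalePx)
  img <- tophatEnhance(img, config@tophatRadiusPx)
  mask <- adaptiveThreshold(img, config@thresholdWindowPx,
                            config@thresholdOffset)
  mask <- removeArtifacts(mask, config@minObjectPx,
                          config@circularityCutoff, exclusionMask)
  if (config@fillHolesPx > 0) mask <- fillHoles(mask, config@fillHolesPx)
  mask
}

#' Analyze one image end to end
#'
#' Runs normalize/orient, segmentation, skeletonization, spur pruning,
#' branch-point identification and morphometric summary on a single image.
#'
#' @param image a raw intensity matrix, a
#'   \code{\linkS4class{CalibratedImage}}, or a file path readable by
#'   \code{\link{readImageGray}}.
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @param exclusionMask optional \code{\linkS4class{BinaryMask}}.
#' @return a list with elements \code{mask}, \code{skeleton} (branch points
#'   filled in) and \code{summary} (a
#'   \code{\linkS4class{MorphometrySummary}}).
#' @export
analyzeImage <- function(image, config, exclusionMask = NULL) {
  stopifnot(is(config, "PipelineConfig"))
  if (is.character(image)) image <- readImageGray(image)
  if (is(image, "CalibratedImage")) {
    img <- if (image@polarity == "dark")
      new("CalibratedImage", pixels = 1 - image@pixels,
          umPerPx = image@umPerPx, polarity = "dark",
          provenance = c(image@provenance, "normalize"))
    else image
  } else {
    img <- normalizeAndOrient(image, config@umPerPx)
  }
  mask <- segmentImage(img, config, exclusionMask)
  skel <- skeletonize(mask)
  if (config@spurPrunePx > 0) skel <- pruneSpurs(skel, config@spurPrunePx)
  skel <- findBranchPoints(skel)
  list(mask = mask, skeleton = skel,
       summary = summarizeMorphometry(mask, skel, config@lengthEstimator))
}

summaryRow <- function(name, group, s, hash) {
  data.frame(image = name, group = group,
             positive_area_pct = s@positiveAreaPct,
             bp_density_per_mm2 = s@bpDensityPerMm2,
             total_length_mm = s@totalLengthMm,
             mean_thickness_um = if (s@thicknessDefined)
               s@meanThicknessUm else NA_real_,
             n_branch_points = s@nBranchPoints,
             image_area_mm2 = s@imageAreaMm2,
             parameters_hash = hash, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline over a set of images
#'
#' Executes the whole chain — normalize, flatten, top-hat, adaptive
#' threshold, artifact removal, skeletonize, branch points, morphometric
#' summary — on every image, then compares the groups parameter by
#' parameter when exactly two groups are present. The run is deterministic
#' for fixed inputs and configuration; all outputs embed the configuration
#' hash. Physical units only (\%, /mm^2, mm, µm) appear in the reports;
#' undefined thickness propagates as \code{NA} and is excluded from group
#' statistics.
#'
#' Unreadable images are skipped with a warning; the run fails only if no
#' image can be processed.
#'
#' @param images either a character vector of image paths, a data.frame
#'   with columns \code{path} and \code{group}, or a list of
#'   \code{\linkS4class{CalibratedImage}} objects.
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @param groups group label per image (recycled if length 1); ignored when
#'   \code{images} is a data.frame.
#' @param outDir optional directory; when given, \code{per_image.csv},
#'   \code{group_stats.csv} and \code{report.json} are written there.
#' @param saveIntermediates when \code{TRUE} (and \code{outDir} is set),
#'   the binary mask and skeleton of every image are saved as TIFFs.
#' @return a list with \code{perImage} (data.frame),
#'   \code{groupStats} (data.frame or NULL), \code{configHash}, and
#'   \code{config}.
#' @export
runPipeline <- function(images, config = pipelineConfig(), groups = "all",
                        outDir = NULL, saveIntermediates = FALSE) {
  stopifnot(is(config, "PipelineConfig"))
  if (is.data.frame(images)) {
    groups <- images$group
    names <- images$path
    images <- as.list(images$path)
  } else if (is.character(images)) {
    names <- images
    images <- as.list(images)
  } else {
    names <- sprintf("image_%03d", seq_along(images))
  }
  if (length(groups) == 1L) groups <- rep(groups, length(images))
  stopifnot(length(groups) == length(images))
  hash <- configHash(config)
  if (!is.null(outDir))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  results <- list()
  for (i in seq_along(images)) {
    res <- tryCatch(analyzeImage(images[[i]], config),
                    error = function(e) {
                      warning(sprintf("skipping '%s': %s", names[i],
                                      conditionMessage(e)))
                      NULL
                    })
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- summaryRow(names[i], groups[i],
                                            res$summary, hash)
    results[[length(results) + 1L]] <- res
    if (isTRUE(saveIntermediates) && !is.null(outDir)) {
      base <- file.path(outDir, sprintf("%03d", i))
      writeImageGray(res$mask, paste0(base, "_mask.tif"))
      writeImageGray(res$skeleton@skeleton, paste0(base, "_skeleton.tif"))
    }
  }
  if (length(rows) == 0L)
    stop("no image could be processed")
  perImage <- do.call(rbind, rows)
  groupStats <- NULL
  grps <- unique(perImage$group)
  if (length(grps) == 2L && all(table(perImage$group) >= 2L))
    groupStats <- compareGroups(perImage, variant = config@ttestVariant)
  out <- list(perImage = perImage, groupStats = groupStats,
              configHash = hash, config = config)
  if (!is.null(outDir)) {
    utils::write.csv(perImage, file.path(outDir, "per_image.csv"),
                     row.names = FALSE)
    if (!is.null(groupStats))
      utils::write.csv(groupStats, file.path(outDir, "group_stats.csv"),
                       row.names = FALSE)
    report <- list(
      software = paste0("nervemorph ",
                        as.character(utils::packageVersion("nervemorph"))),
      config_hash = hash,
      config = configAsList(config),
      coordinate_convention = "(row, col), 0-based, origin top-left",
      n_images = nrow(perImage),
      per_image = perImage)
    if (!is.null(groupStats)) report$group_stats <- groupStats
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

configAsList <- function(config) {
  out <- lapply(slotNames(config), function(s) slot(config, s))
  names(out) <- slotNames(config)
  out
}
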