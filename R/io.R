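#' Read a grayscale micrograph
#'
#' Reads a single-page grayscale TIFF (8- or 16-bit) or grayscale PNG into
#' a raw intensity matrix. TIFFs are returned as native integer codes; PNGs
#' as intensities in [0, 1] (the PNG reader does not expose bit depth).
#' Multi-channel (RGB/RGBA) images are rejected with instructions to
#' convert to grayscale first.
#'
#' @param path file path ending in .tif/.tiff or .png.
#' @return a numeric matrix of raw intensities.
#' @export
readImageGray <- function(path) {
  if (!file.exists(path))
    stop(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    x <- png::readPNG(path)
  } else {
    stop(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  }
  if (length(dim(x)) == 3L) {
    if (dim(x)[3L] == 1L) x <- x[, , 1L]
    else stop("multi-channel (RGB) images are not supported; ",
              "convert to single-channel grayscale first")
  }
  storage.mode(x) <- "double"
  x
}

#' Write a grayscale image
#'
#' Writes a [0, 1] intensity matrix (or a binary mask, written as 0/255) as
#' a single-channel 8- or 16-bit TIFF.
#'
#' @param img a numeric matrix in [0, 1], a
#'   \code{\linkS4class{CalibratedImage}} or a
#'   \code{\linkS4class{BinaryMask}}.
#' @param path output path (.tif/.tiff).
#' @param bitDepth 8 or 16.
#' @return the path, invisibly.
#' @export
writeImageGray <- function(img, path, bitDepth = 8L) {
  if (is(img, "CalibratedImage")) img <- img@pixels
  if (is(img, "BinaryMask")) img <- img@mask + 0
  if (is.logical(img)) img <- img + 0
  stopifnot(is.matrix(img), min(img) >= 0, max(img) <= 1)
  if (!bitDepth %in% c(8L, 16L)) stop("bit depth must be 8 or 16")
  tiff::writeTIFF(img, path, bits.per.sample = as.integer(bitDepth))
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Writes each image as a single-channel TIFF with a JSON ground-truth
#' sidecar, plus a cohort-level CSV manifest (columns: image_path, group,
#' seed, total_length_um, n_branch_points, true_area_fraction_pct,
#' mean_width_um). Coordinates in the sidecars are (row, col), 0-based,
#' origin top-left.
#'
#' @param cohort a list from \code{\link{generateCohort}} (rendered).
#' @param dir output directory (created if needed).
#' @param bitDepth TIFF bit depth, 8 or 16.
#' @return the manifest data.frame, invisibly.
#' @export
writeCohort <- function(cohort, dir, bitDepth = 8L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    e <- cohort[[i]]
    if (is.null(e$image))
      stop("cohort was generated with render = FALSE; no images to write")
    fname <- sprintf("%s_%03d.tif", e$group, i)
    writeImageGray(e$image, file.path(dir, fname), bitDepth)
    tr <- e$truth
    sidecar <- list(
      group = e$group, seed = e$seed,
      um_per_px = e$image@umPerPx,
      total_length_um = tr@totalLengthUm,
      n_branch_points = tr@nBranchPoints,
      mean_width_um = tr@meanWidthUm,
      foreground_area_um2 = tr@foregroundAreaUm2,
      true_area_fraction_pct = tr@trueAreaFractionPct,
      coordinate_convention = "(row, col), 0-based, origin top-left",
      polylines_rowcol0 = lapply(tr@polylines, function(p) unname(p) - 1))
    jsonlite::write_json(sidecar,
                         file.path(dir, sub("\\.tif$", ".json", fname)),
                         auto_unbox = TRUE, digits = NA)
    rows[[i]] <- data.frame(
      image_path = fname, group = e$group, seed = e$seed,
      total_length_um = tr@totalLengthUm,
      n_branch_points = tr@nBranchPoints,
      true_area_fraction_pct = tr@trueAreaFractionPct,
      mean_width_um = tr@meanWidthUm, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
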