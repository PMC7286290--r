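#' @include layout.R
NULL

#' Write a volume as a multi-page 16-bit TIFF
#'
#' One page per Z slice; the voxel size is stored in a JSON sidecar
#' (\code{<file>.json}) because baseline TIFF has no 3D calibration tag.
#'
#' @param stack a [VolumeStack-class]
#' @param file output path (.tif)
#' @return the file path, invisibly
#' @export
writeVolumeTIFF <- function(stack, file) {
  v <- stack@data
  mx <- max(v, 1)
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]) / mx)
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  jsonlite::write_json(
    list(voxelSize = stack@voxelSize, view = stack@view,
         timepoint = stack@timepoint, intensityScale = mx),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a volume written by [writeVolumeTIFF()]
#' @param file path to the .tif
#' @return a [VolumeStack-class]
#' @export
readVolumeTIFF <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  v <- array(0, d)
  for (k in seq_along(pages)) v[, , k] <- t(pages[[k]])
  VolumeStack(v * meta$intensityScale, meta$voxelSize, view = meta$view,
              timepoint = meta$timepoint)
}

#' Write per-frame, per-view scene stacks
#'
#' Renders and writes every frame of a scene as
#' \code{pos\{P\}_t\{T\}_view\{A|B\}.tif} plus the ground truth: the nuclei
#' table as CSV and transform/PSF/drift as JSON.
#'
#' @param scene a [GroundTruthScene-class]
#' @param optics an [OpticsParams-class]
#' @param dir output directory (created if missing)
#' @param frames frames to write (default all)
#' @param position position index used in the file names
#' @param seed render seed
#' @return the directory, invisibly
#' @export
writeSceneTIFF <- function(scene, optics, dir, frames = NULL, position = 1L,
                           seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(frames)) frames <- sort(unique(scene@nuclei$frame))
  for (f in frames) {
    views <- renderDualView(scene, optics, f, seed = seed)
    for (v in c("A", "B")) {
      fn <- file.path(dir, sprintf("pos%d_t%03d_view%s.tif", position, f, v))
      writeVolumeTIFF(views[[paste0("view", v)]], fn)
    }
  }
  write.csv(scene@nuclei, file.path(dir, "ground_truth_nuclei.csv"),
            row.names = FALSE)
  tt <- trueViewTransform(scene, optics)
  jsonlite::write_json(
    list(transform = list(linear = as.vector(t(tt@linear)),
                          translation = tt@translation),
         drift = scene@drift,
         frameInterval = scene@params@frameInterval),
    file.path(dir, "ground_truth_calibration.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Serialize / restore an affine transform as JSON
#'
#' Row-major linear part, translation and residual, as
#' \code{spimscreen register} writes it.
#'
#' @param transform an [AffineTransform3D-class]
#' @param file path
#' @return the path ([writeTransformJSON()]) or the transform
#'   ([readTransformJSON()])
#' @export
writeTransformJSON <- function(transform, file) {
  jsonlite::write_json(
    list(linear = as.vector(t(transform@linear)),
         translation = transform@translation,
         residualRMS = transform@residualRMS,
         nCorrespondences = transform@nCorrespondences),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeTransformJSON
#' @export
readTransformJSON <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  affineTransform3D(matrix(j$linear, 3, 3, byrow = TRUE), j$translation,
                    residualRMS = if (is.null(j$residualRMS)) NA_real_ else j$residualRMS,
                    nCorrespondences = if (is.null(j$nCorrespondences)) 0L else j$nCorrespondences)
}

#' Write a PSF kernel as TIFF + JSON sidecar
#' @param psf a [PSFModel-class]
#' @param file path (.tif)
#' @return the path, invisibly
#' @export
writePSF <- function(psf, file) {
  writeVolumeTIFF(VolumeStack(psf@kernel, rep(psf@voxelSize, 3),
                              view = psf@view), file)
}

#' Class-coloured maximum projection overlay
#'
#' Writes a PNG of the XY maximum projection with segment outlines tinted
#' by cell-cycle phase (interphase white, prophase green, metaphase
#' yellow, anaphase red) for visual quality control of a classified frame.
#'
#' @param volume intensity volume
#' @param labels [LabelVolume-class]
#' @param phases data.frame with \code{id} and \code{phase} (as from
#'   [classifyVolume()])
#' @param file output PNG path
#' @return the path, invisibly
#' @export
writePhaseOverlayPNG <- function(volume, labels, phases, file) {
  if (is(volume, "VolumeStack")) volume <- volume@data
  proj <- apply(volume, c(1, 2), max)
  proj <- proj / max(proj, 1)
  lproj <- apply(labels@labels, c(1, 2), max)
  cols <- c(interphase = "#FFFFFF", prophase = "#00CC00",
            metaphase = "#FFD700", anaphase = "#FF3030")
  rgb <- array(rep(proj, 3), c(dim(proj), 3))
  for (i in seq_len(nrow(phases))) {
    sel <- lproj == phases$id[i]
    if (!any(sel)) next
    cc <- grDevices::col2rgb(cols[[as.character(phases$phase[i])]]) / 255
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[sel] <- 0.5 * plane[sel] + 0.5 * cc[ch]
      rgb[, , ch] <- plane
    }
  }
  png::writePNG(aperm(rgb, c(2, 1, 3)), file)
  invisible(file)
}

#' Write nucleus records as CSV with a fixed column order
#'
#' @param records nucleus record data.frame
#' @param file output path
#' @return the path, invisibly
#' @export
writeNucleusCSV <- function(records, file) {
  lead <- intersect(c("timepoint", "id", "track", "parentTrack", "spheroid",
                      "x", "y", "z", "volume", "meanIntensity",
                      "totalIntensity", "phase", "radialDistance"),
                    names(records))
  rest <- setdiff(names(records), lead)
  write.csv(records[, c(lead, rest), drop = FALSE], file, row.names = FALSE)
  invisible(file)
}
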