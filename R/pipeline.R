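#' @include io.R
NULL

#' Estimate registration and per-view PSFs from a bead calibration frame
#'
#' The dual-view bead stack plays the role of the dedicated bead spot on
#' the screening plate: beads are detected in both views, the
#' view-B-to-view-A affine transform is fitted by iterated closest points,
#' view B is resampled onto the reference grid, and a PSF is extracted per
#' view -- the view-B PSF from the *resampled* stack, so its anisotropy
#' axis is expressed in the fused frame.
#'
#' @param beadFrame list with \code{viewA} and \code{viewB}
#'   ([VolumeStack-class]), e.g. one frame of [renderBeadCalibration()]
#' @param optics the [OpticsParams-class] used for acquisition
#' @param psfRadius PSF window half-width, um
#' @param snrThreshold bead detection threshold
#' @return list: \code{transform} ([AffineTransform3D-class]), \code{psfA},
#'   \code{psfB} ([PSFModel-class]), \code{beadsA}, \code{beadsB}
#' @export
calibrateFromBeads <- function(beadFrame, optics, psfRadius = 2.2,
                               snrThreshold = 8) {
  beadsA <- detectBeads(beadFrame$viewA, snrThreshold = snrThreshold)
  beadsB <- detectBeads(beadFrame$viewB, snrThreshold = snrThreshold)
  transform <- estimateRegistration(beadsA, beadsB, fov = .fovA(optics))
  bRes <- resampleToReference(beadFrame$viewB, transform,
                              gridDim = optics@gridDim,
                              gridVoxel = .cameraVoxel(optics))
  beadsBres <- detectBeads(bRes, snrThreshold = snrThreshold)
  psfA <- extractPSF(beadFrame$viewA, beadsA, radius = psfRadius)
  psfB <- extractPSF(bRes, beadsBres, radius = psfRadius)
  psfB@view <- "B"
  list(transform = transform, psfA = psfA, psfB = psfB,
       beadsA = beadsA, beadsB = beadsB)
}

#' Process one dual-view frame to classified nucleus records
#'
#' Resample view B onto the reference grid with the calibration transform,
#' jointly deconvolve the two views, segment nuclei, and classify each
#' segment with the slice CNN.
#'
#' @param views list with \code{viewA}, \code{viewB}
#' @param calib output of [calibrateFromBeads()]
#' @param bundle cnn [ClassifierBundle-class]
#' @param nIter Richardson-Lucy iterations
#' @param planes slice selection for classification
#' @param segmentArgs extra arguments for [segmentNuclei()]
#' @return list: \code{records} (geometry + phase per nucleus),
#'   \code{fused} ([FusedVolume-class]), \code{labels}
#'   ([LabelVolume-class])
#' @export
processFrame <- function(views, calib, bundle, nIter = 3L,
                         planes = "central", segmentArgs = list()) {
  optsDim <- dim(views$viewA@data)
  bRes <- resampleToReference(views$viewB, calib$transform,
                              gridDim = optsDim,
                              gridVoxel = views$viewA@voxelSize)
  fused <- jointDeconvolve(views$viewA, bRes, calib$psfA, calib$psfB,
                           nIter = nIter)
  labels <- do.call(segmentNuclei, c(list(fused), segmentArgs))
  geo <- computeGeometry(labels, fused)
  if (nrow(geo) && !is.null(bundle)) {
    cls <- classifyVolume(bundle, fused, labels, planes = planes)
    geo <- merge(geo, cls, by = "id", sort = TRUE)
  }
  list(records = geo, fused = fused, labels = labels)
}

#' Simulate, image and analyse a control spheroid population
#'
#' The full desk-scale pipeline on a simulated untreated population:
#' simulate the scene, calibrate once from a bead frame (the plate's bead
#' spot), then for every frame render both views, fuse, segment and
#' classify, and finally assemble phase fractions over all nucleus-frames.
#'
#' @param params [SceneParams-class] for the control population
#' @param optics [OpticsParams-class]; default [deskOptics()]
#' @param bundle trained cnn [ClassifierBundle-class]
#' @param seed seed for rendering and calibration
#' @param nIter Richardson-Lucy iterations per frame
#' @param frames frames to process (default: all frames of the scene)
#' @param keepVolumes keep per-frame fused volumes and labels (memory!)
#' @return list: \code{records} (all classified nucleus-frames),
#'   \code{fractions} (named fractions over the four phases),
#'   \code{truthFractions} (ground-truth occupancy of the same frames),
#'   \code{scene}, \code{calib}; plus \code{volumes} and \code{labels} when
#'   \code{keepVolumes = TRUE}
#' @export
runControlPipeline <- function(params, optics = deskOptics(), bundle,
                               seed = 1L, nIter = 3L, frames = NULL,
                               keepVolumes = FALSE) {
  scene <- simulateTimelapse(params)
  if (is.null(frames)) frames <- sort(unique(scene@nuclei$frame))
  calibScene <- renderBeadCalibration(12L, optics, nFrames = 1L,
                                      seed = .subSeed(seed, 777),
                                      transform = trueViewTransform(scene, optics))
  calib <- calibrateFromBeads(calibScene$frames[[1]], optics)
  recs <- vector("list", length(frames))
  vols <- if (keepVolumes) vector("list", length(frames)) else NULL
  labs <- if (keepVolumes) vector("list", length(frames)) else NULL
  for (w in seq_along(frames)) {
    f <- frames[w]
    views <- renderDualView(scene, optics, f, seed = seed)
    pf <- processFrame(views, calib, bundle, nIter = nIter)
    if (nrow(pf$records)) pf$records$timepoint <- f
    recs[[w]] <- pf$records
    if (keepVolumes) {
      vols[[w]] <- pf$fused
      labs[[w]] <- pf$labels
    }
  }
  records <- do.call(rbind, recs)
  fractions <- phaseFractions(records$phase, .PHASES)
  truth <- scene@nuclei[scene@nuclei$frame %in% frames, ]
  out <- list(records = records, fractions = fractions,
              truthFractions = phaseFractions(truth$phase, .PHASES),
              scene = scene, calib = calib)
  if (keepVolumes) {
    out$volumes <- vols
    out$labels <- labs
  }
  out
}
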