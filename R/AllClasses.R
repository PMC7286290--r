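#' @include spimscreen-package.R
NULL

# ---------------------------------------------------------------------------
# Parameter classes
# ---------------------------------------------------------------------------

#' Scene parameters for the synthetic spheroid time lapse
#'
#' Describes the biology of the simulated clonal spheroid: population size,
#' cell-cycle timing, nucleus geometry, packing and stage drift. Defaults
#' encode the screening conditions the package targets: MCF10A-like cells with
#' a ~21 h (1260 min) cycle, mitotic phase durations of 11.3 min (prophase),
#' 15.1 min (metaphase) and 40.3 min (anaphase) -- interphase is the remainder
#' -- imaged every 5 min for 24 h (289 time points).
#'
#' @slot nInitialCells number of nuclei at the first frame
#' @slot cycleLength full cell-cycle length in minutes
#' @slot phaseDurations named numeric, minutes spent in \code{prophase},
#'   \code{metaphase}, \code{anaphase}; interphase is
#'   \code{cycleLength - sum(phaseDurations)}
#' @slot frameInterval time between frames, minutes
#' @slot nFrames number of frames
#' @slot nucleusRadiusMean,nucleusRadiusSD nucleus radius distribution, um
#' @slot packingDistance preferred centre-to-centre distance between
#'   neighbouring nuclei, um
#' @slot driftPerFrame stage drift per frame, um in X, Y, Z
#' @slot seed integer seed for the stochastic parts of the simulation
#' @export
setClass("SceneParams", representation(
  nInitialCells = "integer",
  cycleLength = "numeric",
  phaseDurations = "numeric",
  frameInterval = "numeric",
  nFrames = "integer",
  nucleusRadiusMean = "numeric",
  nucleusRadiusSD = "numeric",
  packingDistance = "numeric",
  driftPerFrame = "numeric",
  seed = "integer"
))

setValidity("SceneParams", function(object) {
  pd <- object@phaseDurations
  msg <- character()
  if (!all(c("prophase", "metaphase", "anaphase") %in% names(pd)))
    msg <- c(msg, "phaseDurations must name prophase, metaphase and anaphase")
  if (any(pd <= 0)) msg <- c(msg, "all phase durations must be > 0")
  if (sum(pd) >= object@cycleLength)
    msg <- c(msg, "mitotic phase durations must sum to less than cycleLength")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@nInitialCells < 1L) msg <- c(msg, "nInitialCells must be >= 1")
  if (length(object@driftPerFrame) != 3L) msg <- c(msg, "driftPerFrame must have length 3")
  if (length(msg)) msg else TRUE
})

#' @param nInitialCells,cycleLength,phaseDurations,frameInterval,nFrames
#'   see slot documentation
#' @param nucleusRadiusMean,nucleusRadiusSD,packingDistance,driftPerFrame,seed
#'   see slot documentation
#' @rdname SceneParams-class
#' @export
SceneParams <- function(nInitialCells = 40L,
                        cycleLength = 1260,
                        phaseDurations = c(prophase = 11.3, metaphase = 15.1,
                                           anaphase = 40.3),
                        frameInterval = 5,
                        nFrames = 289L,
                        nucleusRadiusMean = 3.8,
                        nucleusRadiusSD = 0.35,
                        packingDistance = 8.5,
                        driftPerFrame = c(0, 0, 0),
                        seed = 1L) {
  if (nFrames < 1 || nInitialCells < 1)
    stop("nFrames and nInitialCells must be at least 1")
  new("SceneParams",
      nInitialCells = as.integer(nInitialCells), cycleLength = cycleLength,
      phaseDurations = phaseDurations, frameInterval = frameInterval,
      nFrames = as.integer(nFrames), nucleusRadiusMean = nucleusRadiusMean,
      nucleusRadiusSD = nucleusRadiusSD, packingDistance = packingDistance,
      driftPerFrame = as.numeric(driftPerFrame), seed = as.integer(seed))
}

#' Optical parameters of the virtual dual-view microscope
#'
#' The rendering model: grid geometry, per-view anisotropic Gaussian PSF
#' sigmas, photon budget and camera noise. The hardware-scale defaults mirror
#' the acquisition geometry of the real instrument (0.1625 um/px laterally,
#' 0.5 um slice spacing, 1024 x 1024 x 260 stacks, 16 bit); [deskOptics()]
#' returns the small isotropic configuration used throughout the examples and
#' tests.
#'
#' @slot voxelSizeXY lateral pixel size, um
#' @slot sliceSpacing axial slice spacing, um
#' @slot gridDim integer stack dimensions (nx, ny, nz) of view A; view B uses
#'   the same grid rotated by the true transform
#' @slot psfSigmaLateral,psfSigmaAxial per-view Gaussian PSF sigmas, um; named
#'   vectors with entries \code{A} and \code{B}
#' @slot photonScale expected photon count per unit chromatin density
#' @slot readNoiseSD Gaussian read noise, counts
#' @slot background flat background density added before shot noise
#' @slot bitDepth camera bit depth
#' @export
setClass("OpticsParams", representation(
  voxelSizeXY = "numeric",
  sliceSpacing = "numeric",
  gridDim = "integer",
  psfSigmaLateral = "numeric",
  psfSigmaAxial = "numeric",
  photonScale = "numeric",
  readNoiseSD = "numeric",
  background = "numeric",
  bitDepth = "integer"
))

setValidity("OpticsParams", function(object) {
  msg <- character()
  if (object@voxelSizeXY <= 0 || object@sliceSpacing <= 0)
    msg <- c(msg, "voxel sizes must be positive")
  if (any(object@psfSigmaAxial < object@psfSigmaLateral))
    msg <- c(msg, "axial PSF sigma must be >= lateral sigma")
  if (object@photonScale < 0) msg <- c(msg, "photonScale must be >= 0")
  if (length(object@gridDim) != 3L) msg <- c(msg, "gridDim must have length 3")
  if (length(msg)) msg else TRUE
})

#' @param voxelSizeXY,sliceSpacing,gridDim,psfSigmaLateral,psfSigmaAxial
#'   see slot documentation
#' @param photonScale,readNoiseSD,background,bitDepth see slot documentation
#' @rdname OpticsParams-class
#' @export
OpticsParams <- function(voxelSizeXY = 0.1625,
                         sliceSpacing = 0.5,
                         gridDim = c(1024L, 1024L, 260L),
                         psfSigmaLateral = c(A = 0.35, B = 0.35),
                         psfSigmaAxial = c(A = 1.5, B = 1.5),
                         photonScale = 300,
                         readNoiseSD = 2,
                         background = 0.02,
                         bitDepth = 16L) {
  new("OpticsParams", voxelSizeXY = voxelSizeXY, sliceSpacing = sliceSpacing,
      gridDim = as.integer(gridDim), psfSigmaLateral = psfSigmaLateral,
      psfSigmaAxial = psfSigmaAxial, photonScale = photonScale,
      readNoiseSD = readNoiseSD, background = background,
      bitDepth = as.integer(bitDepth))
}

#' Desk-scale optics
#'
#' Small isotropic rendering configuration for CPU-scale runs: 0.7 um voxels
#' on a 112 x 112 x 64 grid (a 78 x 78 x 45 um field of view that holds a
#' mid-size spheroid), with the same anisotropic per-view PSF model as the
#' full-scale instrument.
#'
#' @param gridDim stack dimensions, default \code{c(112L, 112L, 64L)}
#' @param voxelSize isotropic voxel size in um, default 0.7
#' @param ... passed on to [OpticsParams()]
#' @return an [OpticsParams-class] object
#' @export
deskOptics <- function(gridDim = c(112L, 112L, 64L), voxelSize = 0.7, ...) {
  OpticsParams(voxelSizeXY = voxelSize, sliceSpacing = voxelSize,
               gridDim = gridDim, ...)
}

# ---------------------------------------------------------------------------
# Geometry / calibration classes
# ---------------------------------------------------------------------------

#' Affine transform between the two views
#'
#' Maps view-B coordinates (um) into the view-A frame:
#' \code{pA = linear \%*\% pB + translation}.
#'
#' @slot linear 3 x 3 linear part
#' @slot translation length-3 translation, um
#' @slot residualRMS root-mean-square fit residual of the bead
#'   correspondences, um (NA when constructed rather than estimated)
#' @slot nCorrespondences number of bead pairs used in the fit
#' @export
setClass("AffineTransform3D", representation(
  linear = "matrix",
  translation = "numeric",
  residualRMS = "numeric",
  nCorrespondences = "integer"
))

setValidity("AffineTransform3D", function(object) {
  msg <- character()
  if (!all(dim(object@linear) == c(3L, 3L))) msg <- c(msg, "linear part must be 3 x 3")
  else if (abs(det(object@linear)) <= 1e-9) msg <- c(msg, "linear part must be invertible")
  if (length(object@translation) != 3L) msg <- c(msg, "translation must have length 3")
  if (length(msg)) msg else TRUE
})

#' @param linear,translation,residualRMS,nCorrespondences see slot
#'   documentation
#' @rdname AffineTransform3D-class
#' @export
affineTransform3D <- function(linear = diag(3), translation = c(0, 0, 0),
                              residualRMS = NA_real_, nCorrespondences = 0L) {
  new("AffineTransform3D", linear = linear, translation = as.numeric(translation),
      residualRMS = residualRMS, nCorrespondences = as.integer(nCorrespondences))
}

#' Point spread function model
#'
#' A normalized 3D kernel on an isotropic grid, extracted from isolated
#' fiducial beads. Nonnegative, sums to one, centred to within half a voxel.
#'
#' @slot kernel 3D array, nonnegative, sums to 1
#' @slot voxelSize kernel voxel size, um (scalar; the grid is isotropic)
#' @slot view view tag, e.g. "A" or "B"
#' @export
setClass("PSFModel", representation(
  kernel = "array",
  voxelSize = "numeric",
  view = "character"
))

setValidity("PSFModel", function(object) {
  k <- object@kernel
  msg <- character()
  if (length(dim(k)) != 3L) msg <- c(msg, "kernel must be a 3D array")
  if (any(k < 0)) msg <- c(msg, "kernel must be nonnegative")
  if (abs(sum(k) - 1) > 1e-6) msg <- c(msg, "kernel must sum to 1")
  ctr <- (dim(k) - 1) / 2
  cen <- vapply(1:3, function(a) {
    idx <- slice.index(k, a) - 1
    sum(idx * k)
  }, numeric(1))
  if (any(abs(cen - ctr) > 0.5))
    msg <- c(msg, "kernel centroid must lie within 0.5 voxel of the centre")
  if (length(msg)) msg else TRUE
})

#' Per-frame global stage drift
#'
#' Offsets (um) of every frame relative to frame 1, as tracked from
#' stationary fiducial beads.
#'
#' @slot offsets n x 3 matrix of XYZ offsets, um; first row is (0,0,0)
#' @slot nBeadsUsed per-frame number of bead matches behind each estimate
#' @export
setClass("DriftSeries", representation(
  offsets = "matrix",
  nBeadsUsed = "integer"
))

setValidity("DriftSeries", function(object) {
  msg <- character()
  if (ncol(object@offsets) != 3L) msg <- c(msg, "offsets must have 3 columns")
  if (nrow(object@offsets) >= 1L && any(object@offsets[1L, ] != 0))
    msg <- c(msg, "first-frame offset must be (0,0,0)")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Volume classes
# ---------------------------------------------------------------------------

#' One 3D intensity stack
#'
#' @slot data 3D numeric array (nx, ny, nz); voxel (i,j,k) is centred at
#'   ((i-1) vx, (j-1) vy, (k-1) vz) um
#' @slot voxelSize length-3 voxel size, um
#' @slot view view tag ("A", "B", or "fused")
#' @slot timepoint acquisition frame index (1-based)
#' @export
setClass("VolumeStack", representation(
  data = "array",
  voxelSize = "numeric",
  view = "character",
  timepoint = "integer"
))

setValidity("VolumeStack", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be a 3D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive numbers")
  if (length(msg)) msg else TRUE
})

#' @param data,voxelSize,view,timepoint see slot documentation
#' @rdname VolumeStack-class
#' @export
VolumeStack <- function(data, voxelSize, view = "A", timepoint = 1L) {
  new("VolumeStack", data = data, voxelSize = as.numeric(voxelSize),
      view = view, timepoint = as.integer(timepoint))
}

#' Fused, deconvolved volume
#'
#' A [VolumeStack-class] on an isotropic grid produced by joint
#' Richardson-Lucy deconvolution of the two registered views, with the
#' iteration log attached.
#'
#' @slot iterations number of RL iterations applied
#' @slot dataFit per-iteration Poisson data-fit objective, one column per view
#' @slot validMask logical/integer array marking voxels seen by both views
#' @export
setClass("FusedVolume", contains = "VolumeStack", representation(
  iterations = "integer",
  dataFit = "matrix",
  validMask = "array"
))

setValidity("FusedVolume", function(object) {
  msg <- character()
  if (any(object@data < 0)) msg <- c(msg, "fused volume must be nonnegative")
  if (length(unique(object@voxelSize)) != 1L)
    msg <- c(msg, "fused grid must be isotropic")
  if (length(msg)) msg else TRUE
})

#' Label volume from nuclei segmentation
#'
#' Integer labels aligned to the volume they were segmented from; 0 is
#' background, labels 1..K are 26-connected components.
#'
#' @slot labels 3D integer array
#' @slot voxelSize length-3 voxel size, um
#' @export
setClass("LabelVolume", representation(
  labels = "array",
  voxelSize = "numeric"
))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be a 3D array")
  lab <- object@labels
  k <- max(lab)
  if (k > 0) {
    present <- sort(unique(as.integer(lab[lab > 0])))
    if (!identical(present, seq_len(k)))
      msg <- c(msg, "labels must be contiguous 1..K")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Scene, classifier and phenotype classes
# ---------------------------------------------------------------------------

#' Ground-truthed synthetic scene
#'
#' Output of [simulateTimelapse()]: the full per-frame truth that downstream
#' stages are validated against.
#'
#' @slot nuclei data.frame with one row per nucleus per frame: \code{frame},
#'   \code{id}, \code{parent}, \code{x}, \code{y}, \code{z} (um, sample
#'   frame), \code{radius} (um), \code{phase} (factor: interphase, prophase,
#'   metaphase, anaphase), \code{phaseFrac} (progress through the current
#'   phase), \code{axisX/Y/Z} (division axis), \code{spheroid}
#' @slot beads data.frame of per-frame bead positions (um, stage frame --
#'   i.e. drift applied): \code{frame}, \code{bead}, \code{x}, \code{y},
#'   \code{z}
#' @slot transform the true view-B-to-view-A [AffineTransform3D-class]
#' @slot drift true per-frame offsets (nFrames x 3, um)
#' @slot params the [SceneParams-class] used
#' @export
setClass("GroundTruthScene", representation(
  nuclei = "data.frame",
  beads = "data.frame",
  transform = "AffineTransform3D",
  drift = "matrix",
  params = "SceneParams"
))

#' Slice set of a segmented nucleus
#'
#' 2D patches cut through one nucleus along the three orthogonal
#' orientations, masked to the segment, zero-padded square, resized and
#' min-max normalized to [0, 1].
#'
#' @slot patches array (patchSize, patchSize, nSlices)
#' @slot orientation character vector per slice: "XY", "XZ" or "YZ"
#' @slot sliceIndex integer plane index per slice (1-based within the volume)
#' @slot nucleusId the nucleus label
#' @export
setClass("SliceSet", representation(
  patches = "array",
  orientation = "character",
  sliceIndex = "integer",
  nucleusId = "integer"
))

setValidity("SliceSet", function(object) {
  msg <- character()
  if (length(dim(object@patches)) != 3L) msg <- c(msg, "patches must be a 3D array")
  if (dim(object@patches)[3] != length(object@orientation))
    msg <- c(msg, "one orientation tag per patch required")
  if (!all(c("XY", "XZ", "YZ") %in% object@orientation))
    msg <- c(msg, "at least one slice per orientation is required")
  if (length(msg)) msg else TRUE
})

#' Trained phase classifier
#'
#' @slot kind "rf" or "cnn"
#' @slot model the fitted model object (randomForest fit, or the CNN weight
#'   list)
#' @slot classOrder class labels in their fixed serialization order;
#'   probability columns and tie-breaks follow this order
#' @slot metadata list: training sizes per class, seed, holdout accuracy
#' @export
setClass("ClassifierBundle", representation(
  kind = "character",
  model = "ANY",
  classOrder = "character",
  metadata = "list"
))

#' Centred, scaled phenotype feature matrix
#'
#' @slot values samples x features matrix after centring/scaling
#' @slot center,scale per-feature centring and scaling constants
#' @slot excluded data.frame of dropped/masked features with reasons
#' @export
setClass("PhenotypeMatrix", representation(
  values = "matrix",
  center = "numeric",
  scale = "numeric",
  excluded = "data.frame"
))

setValidity("PhenotypeMatrix", function(object) {
  v <- object@values
  if (ncol(v) == 0 || nrow(v) < 2) return("need >= 2 samples and >= 1 feature")
  mu <- colMeans(v, na.rm = TRUE)
  sdv <- apply(v, 2, sd, na.rm = TRUE)
  if (any(abs(mu) > 1e-9) || any(abs(sdv - 1) > 1e-9))
    return("columns must have mean 0 and sd 1")
  TRUE
})

#' Spot grid of the imaging plate
#'
#' @slot centers total-spots x 2 matrix of plate coordinates, mm
#' @slot nColumns,nRows grid size
#' @slot spotsPerSample replicate spots per sample
#' @slot pitch spot pitch, mm
#' @slot sampleMap integer sample index per spot
#' @export
setClass("SpotGrid", representation(
  centers = "matrix",
  nColumns = "integer",
  nRows = "integer",
  spotsPerSample = "integer",
  pitch = "numeric",
  sampleMap = "integer"
))

setValidity("SpotGrid", function(object) {
  msg <- character()
  if (nrow(object@centers) != object@nColumns * object@nRows)
    msg <- c(msg, "centers must have nColumns * nRows rows")
  if (anyDuplicated(object@centers)) msg <- c(msg, "spot centers must be unique")
  if (length(msg)) msg else TRUE
})

#' Acquisition accounting plan
#'
#' Exact integer bookkeeping of an acquisition pass: how many images a
#' position scan produces and how many bytes a dual-view stack occupies.
#'
#' @slot nPositions,nSlices,nViews,imageWidth,imageHeight,bytesPerPixel,nTimepoints
#'   acquisition counts
#' @slot imagesPerPass nPositions * nSlices * nViews
#' @slot bytesPerPositionTimepoint nViews * width * height * nSlices * bytesPerPixel
#' @slot totalBytes bytesPerPositionTimepoint * nPositions * nTimepoints
#' @export
setClass("AcquisitionPlan", representation(
  nPositions = "numeric", nSlices = "numeric", nViews = "numeric",
  imageWidth = "numeric", imageHeight = "numeric", bytesPerPixel = "numeric",
  nTimepoints = "numeric", imagesPerPass = "numeric",
  bytesPerPositionTimepoint = "numeric", totalBytes = "numeric"
))

setValidity("AcquisitionPlan", function(object) {
  counts <- c(object@nPositions, object@nSlices, object@nViews,
              object@imageWidth, object@imageHeight, object@bytesPerPixel,
              object@nTimepoints)
  if (any(counts < 1)) return("all counts must be >= 1")
  if (object@imagesPerPass != object@nPositions * object@nSlices * object@nViews)
    return("imagesPerPass must be the exact product")
  TRUE
})
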