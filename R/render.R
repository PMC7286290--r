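#' @include synthetic-scene.R
NULL

# Phase-specific chromatin rendering parameters (density scale, texture
# amplitude, texture grain in um) for interphase / prophase / metaphase /
# anaphase. Interphase chromatin is diffuse with faint large-scale texture;
# prophase condenses into high-contrast fine speckles inside a slightly
# swollen envelope; the metaphase plate and the separating anaphase masses
# are compact, bright and moderately textured; prophase density (1.35) sits
# midway between diffuse (1.0) and fully condensed (1.8) chromatin. These
# encodings are what the texture and CNN classifiers learn to separate.
.PHASE_RENDER <- list(
  base = c(1.0, 1.35, 1.8, 1.8),
  amp = c(0.08, 0.55, 0.30, 0.30),
  grain = c(2.2, 1.4, 0.7, 0.7),
  edge = 0.35
)

# voxel sizes of a camera grid for given optics
.cameraVoxel <- function(optics) {
  c(optics@voxelSizeXY, optics@voxelSizeXY, optics@sliceSpacing)
}

# field of view (um) of view A
.fovA <- function(optics) .cameraVoxel(optics) * (optics@gridDim - 1L)

# view-B grid dimensions: the rotated FOV divided by the camera voxel sizes
.gridB <- function(optics, linear = .rot90Y()) {
  fovB <- abs(as.vector(linear %*% .fovA(optics)))
  as.integer(round(fovB / .cameraVoxel(optics)) + 1L)
}

# camera pipeline: optical blur, photon shot noise, read noise, quantization
.cameraImage <- function(density, optics, view, applyNoise, quantize,
                         blur = TRUE) {
  vox <- .cameraVoxel(optics)
  sl <- optics@psfSigmaLateral[[view]]
  sa <- optics@psfSigmaAxial[[view]]
  blurred <- if (blur)
    .gaussBlur3d(density, c(sl / vox[1], sl / vox[2], sa / vox[3]))
  else density
  img <- optics@photonScale * (optics@background + blurred)
  if (applyNoise) {
    img[] <- rpois(length(img), pmax(img, 0))
    if (optics@readNoiseSD > 0)
      img <- img + rnorm(length(img), 0, optics@readNoiseSD)
  }
  if (quantize) {
    img <- round(pmin(pmax(img, 0), 2^optics@bitDepth - 1))
  } else {
    img <- pmax(img, 0)
  }
  img
}

# nucleus table of one frame as the matrix layout cpp_rasterize_nuclei wants,
# with positions mapped into the target raster frame
.nucleusMatrix <- function(nuc, originOffset, toFrame = NULL) {
  pos <- as.matrix(nuc[, c("x", "y", "z")]) +
    rep(originOffset, each = nrow(nuc))
  ax <- as.matrix(nuc[, c("axisX", "axisY", "axisZ")])
  if (!is.null(toFrame)) {
    inv <- invertTransform(toFrame)
    pos <- applyTransform(inv, pos)
    ax <- t(solve(toFrame@linear) %*% t(ax))
    ax <- ax / pmax(sqrt(rowSums(ax^2)), 1e-12)
  }
  cbind(pos, nuc$radius, as.integer(nuc$phase), ax, nuc$phaseFrac)
}

#' Render the two camera views of one scene frame
#'
#' Rasterizes the phase-dependent chromatin density of every nucleus, then
#' images it through the two virtual cameras: view A on the reference grid,
#' view B on its own grid rotated 90 degrees about the Y axis (the true
#' scene transform). Each view is blurred with its own anisotropic Gaussian
#' PSF along its detection axis, scaled to photons, degraded with Poisson
#' shot noise and Gaussian read noise, and quantized to the camera bit
#' depth. Stage drift shifts the whole sample on both grids.
#'
#' The same world-anchored chromatin texture is sampled by both views, so
#' the two stacks are genuinely two projections of one object.
#'
#' @param scene a [GroundTruthScene-class]
#' @param optics an [OpticsParams-class]
#' @param frame frame index (1-based)
#' @param seed seed for the stochastic texture and noise
#' @param applyNoise set \code{FALSE} for the noise-free density (photon
#'   scaling still applies)
#' @param quantize set \code{FALSE} to keep continuous intensities
#' @return list with elements \code{viewA} and \code{viewB}
#'   ([VolumeStack-class]); the view-A origin offset of the scene is attached
#'   as attribute \code{originOffset} so ground-truth coordinates can be
#'   mapped onto the grid
#' @export
renderDualView <- function(scene, optics, frame, seed = 1L,
                           applyNoise = TRUE, quantize = TRUE) {
  validObject(optics)
  nuc <- scene@nuclei[scene@nuclei$frame == frame, , drop = FALSE]
  if (!nrow(nuc)) stop("frame ", frame, " does not exist in the scene")
  vox <- .cameraVoxel(optics)
  originOffset <- .fovA(optics) / 2 + scene@drift[frame, ]
  trueT <- trueViewTransform(scene, optics)
  dimB <- .gridB(optics, trueT@linear)

  rasterSeed <- .subSeed(seed, frame)
  densA <- withr::with_seed(rasterSeed, {
    cpp_rasterize_nuclei(optics@gridDim, vox,
                         .nucleusMatrix(nuc, originOffset), .PHASE_RENDER,
                         diag(3))
  })
  # identical RNG stream => identical per-nucleus texture lattices
  densB <- withr::with_seed(rasterSeed, {
    cpp_rasterize_nuclei(dimB, vox,
                         .nucleusMatrix(nuc, originOffset, toFrame = trueT),
                         .PHASE_RENDER, trueT@linear)
  })
  withr::with_seed(.subSeed(seed, frame + 100003), {
    imgA <- .cameraImage(densA, optics, "A", applyNoise, quantize)
    imgB <- .cameraImage(densB, optics, "B", applyNoise, quantize)
    out <- list(viewA = VolumeStack(imgA, vox, view = "A", timepoint = frame),
                viewB = VolumeStack(imgB, vox, view = "B", timepoint = frame))
    attr(out, "originOffset") <- originOffset
    attr(out, "trueTransform") <- trueT
    out
  })
}

#' Render a dual-view bead calibration series
#'
#' Scatters sub-resolution fluorescent beads through the field of view and
#' images them with both cameras over a series of frames. Bead positions at
#' frame t are the frame-1 positions plus \code{(t-1) * drift}: beads are the
#' stationary fiducials used for view registration, PSF extraction and stage
#' drift tracking.
#'
#' @param nBeads number of beads (at least 4, not coplanar, for downstream
#'   registration)
#' @param optics an [OpticsParams-class]
#' @param drift per-frame stage drift, um XYZ
#' @param nFrames number of calibration frames
#' @param seed seed for placement and noise
#' @param brightness bead amplitude in chromatin-density units
#' @param transform true view-B-to-view-A transform; defaults to the nominal
#'   90 degree rotation for the given optics
#' @param applyNoise,quantize as in [renderDualView()]
#' @return list with \code{frames} (per frame: list of \code{viewA},
#'   \code{viewB}), \code{positions} (per frame matrix of true bead positions
#'   in the view-A frame, um) and \code{transform}
#' @export
renderBeadCalibration <- function(nBeads, optics, drift = c(0, 0, 0),
                                  nFrames = 1L, seed = 1L, brightness = 40,
                                  transform = NULL, applyNoise = TRUE,
                                  quantize = TRUE) {
  if (nBeads < 1) stop("nBeads must be at least 1")
  validObject(optics)
  vox <- .cameraVoxel(optics)
  fov <- .fovA(optics)
  if (is.null(transform)) transform <- .nominalViewTransform(fov)
  dimB <- .gridB(optics, transform@linear)
  withr::with_seed(seed, {
    # rejection-sample beads in the interior, min 6 um apart
    pos <- matrix(NA_real_, 0, 3)
    guard <- 0
    while (nrow(pos) < nBeads && guard < 10000) {
      cand <- runif(3, 0.15, 0.85) * fov
      if (!nrow(pos) || min(sqrt(rowSums((pos - rep(cand, each = nrow(pos)))^2))) > 6)
        pos <- rbind(pos, cand)
      guard <- guard + 1
    }
    if (nrow(pos) < nBeads) stop("could not place ", nBeads, " beads")
    frames <- vector("list", nFrames)
    positions <- vector("list", nFrames)
    inv <- invertTransform(transform)
    # beads are sub-resolution point sources: their camera image is the PSF
    # itself, so they are drawn analytically at the exact continuous
    # position (bead size 0.15 um added in quadrature) rather than
    # rasterized and blurred
    beadSize <- 0.15
    sigA <- sqrt(c(optics@psfSigmaLateral[["A"]], optics@psfSigmaLateral[["A"]],
                   optics@psfSigmaAxial[["A"]])^2 + beadSize^2)
    sigB <- sqrt(c(optics@psfSigmaLateral[["B"]], optics@psfSigmaLateral[["B"]],
                   optics@psfSigmaAxial[["B"]])^2 + beadSize^2)
    for (f in seq_len(nFrames)) {
      p <- pos + rep((f - 1) * drift, each = nBeads)
      positions[[f]] <- p
      densA <- cpp_add_points(numeric(prod(optics@gridDim)), optics@gridDim,
                              vox, p, rep(brightness, nBeads), sigA)
      pB <- applyTransform(inv, p)
      densB <- cpp_add_points(numeric(prod(dimB)), dimB, vox, pB,
                              rep(brightness, nBeads), sigB)
      frames[[f]] <- list(
        viewA = VolumeStack(.cameraImage(densA, optics, "A", applyNoise,
                                         quantize, blur = FALSE),
                            vox, view = "A", timepoint = f),
        viewB = VolumeStack(.cameraImage(densB, optics, "B", applyNoise,
                                         quantize, blur = FALSE),
                            vox, view = "B", timepoint = f))
    }
    list(frames = frames, positions = positions, transform = transform)
  })
}
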