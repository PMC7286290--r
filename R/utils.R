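#' @include AllClasses.R
NULL

# canonical 4-class order; ties in summed-likelihood voting resolve to the
# earliest entry
.PHASES <- c("interphase", "prophase", "metaphase", "anaphase")
# extended 6-class set for the 2D pre-screen variant
.PHASES6 <- c(.PHASES, "macronuclei", "apoptotic_condensed_DNA")

# 1D Gaussian kernel sampled at voxel centres, truncated at 3 sigma,
# normalized; sigma in voxels. sigma = 0 returns the delta kernel.
.gauss1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur of a 3D array; sigma per axis in voxels
.gaussBlur3d <- function(vol, sigma) {
  if (all(sigma <= 0)) return(vol)
  cpp_conv_sep(vol, dim(vol), .gauss1d(sigma[1]), .gauss1d(sigma[2]),
               .gauss1d(sigma[3]))
}

# rotation matrix for a 90 degree rotation about the Y axis (the nominal
# relation between the two camera views)
.rot90Y <- function() {
  matrix(c(0, 0, -1,
           0, 1, 0,
           1, 0, 0), nrow = 3, byrow = TRUE)
}

# nominal view-B->A transform for a given A-grid field of view (um):
# rotation about the FOV centre so that the rotated grid covers the same
# sample region
.nominalViewTransform <- function(fovA) {
  R <- .rot90Y()
  cA <- fovA / 2
  fovB <- abs(as.vector(R %*% fovA))
  cB <- fovB / 2
  affineTransform3D(R, cA - as.vector(R %*% cB))
}

# grid dims of view B given view A dims (90 deg rotation about Y swaps the
# X and Z extents)
.viewBGrid <- function(gridDimA) gridDimA[c(3, 2, 1)]

# full width at half maximum of a 1D profile by linear interpolation of the
# half-maximum crossings; x in physical units
.fwhm1d <- function(x, y) {
  y <- y - min(y)
  pk <- which.max(y)
  half <- y[pk] / 2
  left <- NA_real_
  for (i in seq(pk, 2)) {
    if (y[i - 1] <= half) {
      f <- (half - y[i - 1]) / (y[i] - y[i - 1])
      left <- x[i - 1] + f * (x[i] - x[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in seq(pk, length(y) - 1)) {
    if (y[i + 1] <= half) {
      f <- (y[i] - half) / (y[i] - y[i + 1])
      right <- x[i] + f * (x[i + 1] - x[i])
      break
    }
  }
  right - left
}

#' Measure the FWHM of a point image along each axis
#'
#' Extracts axis-parallel intensity profiles through the brightest voxel and
#' interpolates the half-maximum crossings. Used to quantify PSF anisotropy
#' and the resolution-isotropy gain of dual-view fusion.
#'
#' @param volume a [VolumeStack-class] or 3D array
#' @param voxelSize voxel size (um), required when \code{volume} is an array
#' @param center optional voxel index (1-based, length 3) of the point;
#'   defaults to the global maximum
#' @return named numeric: FWHM along x, y, z in um
#' @export
measureFWHM <- function(volume, voxelSize = NULL, center = NULL) {
  if (is(volume, "VolumeStack")) {
    voxelSize <- volume@voxelSize
    volume <- volume@data
  }
  if (is.null(center)) {
    center <- arrayInd(which.max(volume), dim(volume))[1, ]
  }
  d <- dim(volume)
  c(x = .fwhm1d((seq_len(d[1]) - 1) * voxelSize[1], volume[, center[2], center[3]]),
    y = .fwhm1d((seq_len(d[2]) - 1) * voxelSize[2], volume[center[1], , center[3]]),
    z = .fwhm1d((seq_len(d[3]) - 1) * voxelSize[3], volume[center[1], center[2], ]))
}

# deterministic sub-seed derivation (stays below 2^31)
.subSeed <- function(seed, salt) {
  (as.numeric(seed) * 7919 + salt * 104729) %% 2147483629
}
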