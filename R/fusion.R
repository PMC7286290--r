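#' @include beads.R
NULL

#' Resample a stack onto a reference grid
#'
#' Pull-back trilinear interpolation: every voxel centre of the output grid
#' is mapped through the inverse of \code{transform} into the input stack
#' and interpolated. Voxels whose support falls outside the input stack are
#' zero and flagged invalid in the attached mask.
#'
#' @param stack the [VolumeStack-class] to resample (e.g. view B)
#' @param transform [AffineTransform3D-class] mapping stack coordinates into
#'   reference coordinates (view B to view A); the resampler applies its
#'   inverse
#' @param gridDim integer dimensions of the reference grid
#' @param gridVoxel voxel size of the reference grid, um
#' @return a [VolumeStack-class] on the reference grid; attribute
#'   \code{validMask} holds the 0/1 coverage mask
#' @export
resampleToReference <- function(stack, transform,
                                gridDim = dim(stack@data),
                                gridVoxel = stack@voxelSize) {
  if (abs(det(transform@linear)) <= 1e-9)
    stop("transform is not invertible")
  inv <- invertTransform(transform)
  rs <- cpp_affine_resample(stack@data, dim(stack@data), stack@voxelSize,
                            as.integer(gridDim), as.numeric(gridVoxel),
                            inv@linear, inv@translation)
  out <- VolumeStack(rs$volume, gridVoxel, view = stack@view,
                     timepoint = stack@timepoint)
  attr(out@data, "validMask") <- NULL
  attr(out, "validMask") <- rs$mask
  out
}

# Poisson data-fit objective sum(pred - obs*log(pred)) over the valid region
.poissonFit <- function(pred, obs, mask, epsilon) {
  p <- pred[mask]
  o <- obs[mask]
  sum(p - o * log(p + epsilon))
}

#' Joint Richardson-Lucy deconvolution of two registered views
#'
#' Alternating multiplicative Richardson-Lucy with both views' PSFs: the
#' estimate is initialized with the mean of the two views, then per
#' iteration updated first against view A and then against view B
#' (\code{ratio = view / (estimate * psf)}; \code{estimate <- estimate *
#' (ratio * psf-mirrored)}), each update masked to that view's valid
#' footprint. Because the two PSFs are anisotropic along different axes
#' after resampling, the fixed point approaches isotropic resolution.
#'
#' @param viewA,viewB [VolumeStack-class] objects on a common isotropic grid
#'   (view B typically from [resampleToReference()])
#' @param psfA,psfB [PSFModel-class] kernels for the two views on the fused
#'   grid
#' @param nIter number of joint iterations; 0 returns the initialization
#' @param epsilon small constant guarding divisions
#' @param maskA,maskB optional 0/1 validity arrays; default taken from the
#'   \code{validMask} attribute or all-valid
#' @return a [FusedVolume-class] with the per-iteration, per-view Poisson
#'   data-fit log
#' @export
jointDeconvolve <- function(viewA, viewB, psfA, psfB, nIter = 10L,
                            epsilon = 1e-6, maskA = NULL, maskB = NULL) {
  if (!all(dim(viewA@data) == dim(viewB@data)))
    stop("views must live on the same grid")
  if (!isTRUE(all.equal(viewA@voxelSize, viewB@voxelSize)))
    stop("views must share a voxel size")
  a <- viewA@data
  b <- viewB@data
  if (is.null(maskA)) maskA <- attr(viewA, "validMask")
  if (is.null(maskB)) maskB <- attr(viewB, "validMask")
  if (is.null(maskA)) maskA <- array(1L, dim(a))
  if (is.null(maskB)) maskB <- array(1L, dim(b))
  mA <- maskA == 1L
  mB <- maskB == 1L
  d <- dim(a)
  kA <- psfA@kernel
  kB <- psfB@kernel
  # initialization: mean of the views where both are valid, else the valid one
  est <- (a * mA + b * mB) / pmax(mA + mB, 1L)
  est <- pmax(est, 0)
  fit <- matrix(NA_real_, 0, 2, dimnames = list(NULL, c("A", "B")))
  # one multiplicative update against a view; the data-fit objective is
  # evaluated on the prediction of the incoming estimate, so successive log
  # entries of a view compare like with like
  oneView <- function(est, view, m, kern) {
    eps <- 1e-3 * max(kern)  # prune negligible kernel taps
    pred <- cpp_conv3(est, d, kern, dim(kern), FALSE, eps)
    ratio <- view / (pred + epsilon)
    ratio[!m] <- 1
    corr <- cpp_conv3(ratio, d, kern, dim(kern), TRUE, eps)
    list(est = est * pmax(corr, 0), fit = .poissonFit(pred, view, m, epsilon))
  }
  for (it in seq_len(nIter)) {
    upA <- oneView(est, a, mA, kA)
    est <- upA$est
    upB <- oneView(est, b, mB, kB)
    est <- upB$est
    fit <- rbind(fit, c(upA$fit, upB$fit))
  }
  new("FusedVolume",
      data = pmax(est, 0), voxelSize = viewA@voxelSize, view = "fused",
      timepoint = viewA@timepoint, iterations = as.integer(nIter),
      dataFit = fit, validMask = array(as.integer(mA & mB), d))
}

#' Translate a volume series to cancel stage drift
#'
#' Shifts every frame by minus its drift offset (trilinear interpolation);
#' the first frame is unchanged.
#'
#' @param volumes list of [VolumeStack-class] objects, one per frame
#' @param drift a [DriftSeries-class] covering every frame
#' @return list of corrected [VolumeStack-class] objects
#' @export
applyDriftCorrection <- function(volumes, drift) {
  nF <- length(volumes)
  if (nrow(drift@offsets) < nF)
    stop("drift series does not cover every frame")
  lapply(seq_len(nF), function(f) {
    off <- drift@offsets[f, ]
    if (all(off == 0)) return(volumes[[f]])
    v <- volumes[[f]]
    # output voxel p reads input at p + offset (content moves by -offset)
    rs <- cpp_affine_resample(v@data, dim(v@data), v@voxelSize,
                              dim(v@data), v@voxelSize, diag(3), off)
    out <- VolumeStack(rs$volume, v@voxelSize, view = v@view,
                       timepoint = v@timepoint)
    attr(out, "validMask") <- rs$mask
    out
  })
}
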