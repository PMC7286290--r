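#' @include render.R
NULL

#' Detect fiducial beads in a stack
#'
#' Finds strict 26-neighbourhood local maxima above
#' \code{background + snrThreshold * noise} (median / MAD estimates), refines
#' each candidate to a subvoxel position by the intensity-weighted centroid
#' of a local background-subtracted window, and suppresses candidates closer
#' than \code{minSeparation}, keeping the brighter one.
#'
#' @param stack a [VolumeStack-class]
#' @param minSeparation minimum centre-to-centre distance, um
#' @param snrThreshold detection threshold in units of the background noise
#' @param window half-width (voxels) of the centroid refinement window
#' @return data.frame with columns \code{x}, \code{y}, \code{z} (um),
#'   \code{peak} and \code{quality} (peak over noise); attributes \code{view}
#'   and \code{timepoint} carry the stack provenance. May have zero rows.
#' @export
detectBeads <- function(stack, minSeparation = 4, snrThreshold = 8,
                        window = 4L) {
  vol <- stack@data
  vox <- stack@voxelSize
  bg <- median(vol)
  noise <- mad(vol)
  if (noise == 0) {
    # noiseless data: any clearly-above-background maximum is a candidate
    noise <- 0.05 * (max(vol) - bg) / max(snrThreshold, 1)
  }
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      peak = numeric(0), quality = numeric(0))
  attr(empty, "view") <- stack@view
  attr(empty, "timepoint") <- stack@timepoint
  if (noise == 0) return(empty)
  thr <- bg + snrThreshold * noise
  pk <- cpp_local_maxima(vol, dim(vol), thr)
  if (!nrow(pk)) return(empty)

  d <- dim(vol)
  wdim <- rep(2L * window + 1L, 3)
  widx <- (seq_len(2L * window + 1L) - 1L) - window
  res <- matrix(NA_real_, nrow(pk), 5)
  for (n in seq_len(nrow(pk))) {
    ctr <- pk[n, ] + 1L  # to 1-based
    # iterated interpolated-window centroid: recentring the window on the
    # running estimate removes the truncation bias of a fixed window
    cen <- (ctr - 1) * vox
    okBead <- TRUE
    for (it in 1:3) {
      rs <- cpp_affine_resample(vol, d, vox, wdim, vox, diag(3),
                                cen - window * vox)
      w <- pmax(rs$volume - bg, 0)
      tot <- sum(w)
      if (tot <= 0) { okBead <- FALSE; break }
      cen <- cen + c(sum(apply(w, 1, sum) * widx) * vox[1],
                     sum(apply(w, 2, sum) * widx) * vox[2],
                     sum(apply(w, 3, sum) * widx) * vox[3]) / tot
    }
    if (!okBead) next
    res[n, ] <- c(cen, vol[ctr[1], ctr[2], ctr[3]],
                  (vol[ctr[1], ctr[2], ctr[3]] - bg) / noise)
  }
  res <- res[stats::complete.cases(res), , drop = FALSE]
  if (!nrow(res)) return(empty)
  # brighter-wins suppression of close pairs
  ord <- order(res[, 4], decreasing = TRUE)
  keep <- logical(nrow(res))
  for (i in ord) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dd <- sqrt(rowSums((res[keep, 1:3, drop = FALSE] -
                          rep(res[i, 1:3], each = sum(keep)))^2))
    if (min(dd) >= minSeparation) keep[i] <- TRUE
  }
  out <- data.frame(x = res[keep, 1], y = res[keep, 2], z = res[keep, 3],
                    peak = res[keep, 4], quality = res[keep, 5])
  out <- out[order(out$x, out$y, out$z), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "view") <- stack@view
  attr(out, "timepoint") <- stack@timepoint
  out
}

# least-squares affine fit A -> pA ~ L pB + t given matched point sets
.fitAffine <- function(pB, pA) {
  X <- cbind(pB, 1)
  beta <- solve(crossprod(X), crossprod(X, pA))  # 4 x 3
  L <- t(beta[1:3, , drop = FALSE])
  dimnames(L) <- NULL
  affineTransform3D(L, as.numeric(beta[4, ]))
}

#' Estimate the view-B-to-view-A registration transform from beads
#'
#' Iterated closest-point matching on the two bead sets: apply the current
#' transform to the view-B beads, match each to its nearest view-A bead
#' (rejecting matches beyond \code{maxMatchDist}), refit the least-squares
#' affine transform, and repeat until the assignment is stable. The initial
#' transform defaults to the nominal 90 degree view rotation for the given
#' field of view.
#'
#' @param beadsA,beadsB bead tables from [detectBeads()] (um coordinates)
#' @param init optional initial [AffineTransform3D-class]; when \code{NULL} a
#'   nominal 90 degree rotation is constructed from \code{fov}
#' @param fov view-A field of view (um), needed only to build the default
#'   initialization
#' @param maxMatchDist matches farther than this after initialization are
#'   rejected, um
#' @param maxIter iteration cap
#' @return an [AffineTransform3D-class] with residual RMS and the number of
#'   correspondences filled in
#' @export
estimateRegistration <- function(beadsA, beadsB, init = NULL, fov = NULL,
                                 maxMatchDist = 5, maxIter = 50L) {
  pA <- as.matrix(beadsA[, c("x", "y", "z")])
  pB <- as.matrix(beadsB[, c("x", "y", "z")])
  if (nrow(pA) < 4 || nrow(pB) < 4)
    stop("degenerate calibration: need at least 4 beads per view")
  if (is.null(init)) {
    if (is.null(fov)) stop("provide either init or fov")
    init <- .nominalViewTransform(fov)
  }
  cur <- init
  match <- integer(0)
  for (it in seq_len(maxIter)) {
    pBt <- applyTransform(cur, pB)
    # nearest view-A bead for every transformed view-B bead
    nn <- vapply(seq_len(nrow(pBt)), function(i) {
      dd <- sqrt(rowSums((pA - rep(pBt[i, ], each = nrow(pA)))^2))
      j <- which.min(dd)
      c(j, dd[j])
    }, numeric(2))
    ok <- nn[2, ] <= maxMatchDist
    # one-to-one: keep the closest claimant of each A bead
    newMatch <- rep(NA_integer_, nrow(pB))
    for (j in unique(nn[1, ok])) {
      claim <- which(ok & nn[1, ] == j)
      newMatch[claim[which.min(nn[2, claim])]] <- j
    }
    use <- which(!is.na(newMatch))
    if (length(use) < 4)
      stop("degenerate calibration: fewer than 4 usable correspondences")
    ctr <- scale(pB[use, , drop = FALSE], scale = FALSE)
    if (qr(ctr)$rank < 3)
      stop("degenerate calibration: correspondences are coplanar")
    fit <- .fitAffine(pB[use, , drop = FALSE], pA[newMatch[use], , drop = FALSE])
    stable <- identical(newMatch, match)
    cur <- fit
    match <- newMatch
    if (stable) break
  }
  use <- which(!is.na(match))
  resid <- applyTransform(cur, pB[use, , drop = FALSE]) -
    pA[match[use], , drop = FALSE]
  cur@residualRMS <- sqrt(mean(rowSums(resid^2)))
  cur@nCorrespondences <- length(use)
  validObject(cur)
  cur
}

#' Extract the point spread function from isolated beads
#'
#' Cuts a window of the given radius around every isolated bead (no
#' neighbour within twice the radius), recentres it on the subvoxel bead
#' position by trilinear interpolation, subtracts the local background
#' (median of the window border), averages across beads, clips at zero and
#' normalizes to unit sum. Anisotropic input grids are resampled to an
#' isotropic kernel grid at the finest voxel size.
#'
#' @param stack a [VolumeStack-class]
#' @param beads bead table from [detectBeads()]
#' @param radius kernel half-width, um
#' @return a [PSFModel-class]
#' @export
extractPSF <- function(stack, beads, radius = 2.5) {
  p <- as.matrix(beads[, c("x", "y", "z")])
  if (!nrow(p)) stop("no beads supplied")
  iso <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    dd <- sqrt(rowSums((p[-i, , drop = FALSE] - rep(p[i, ], each = nrow(p) - 1))^2))
    iso[i] <- !length(dd) || min(dd) >= 2 * radius
  }
  if (!any(iso)) stop("no isolated bead (no neighbour within 2*radius) found")
  vox <- stack@voxelSize
  kv <- min(vox)
  half <- ceiling(radius / kv)
  side <- 2L * half + 1L
  kdim <- c(side, side, side)
  acc <- array(0, kdim)
  nUsed <- 0L
  for (i in which(iso)) {
    # pull-back sampling: kernel voxel (a,b,c) reads the stack at
    # bead + (index - half) * kv, expressed in stack voxel units
    tr <- p[i, ] - half * kv
    rs <- cpp_affine_resample(stack@data, dim(stack@data), vox,
                              kdim, c(kv, kv, kv), diag(3), tr)
    win <- rs$volume
    if (!all(rs$mask == 1L)) next  # window clipped by the stack boundary
    border <- win
    border[2:(side - 1), 2:(side - 1), 2:(side - 1)] <- NA
    win <- win - median(border, na.rm = TRUE)
    acc <- acc + pmax(win, 0)
    nUsed <- nUsed + 1L
  }
  if (nUsed == 0L) stop("no isolated bead with a full window inside the stack")
  acc <- acc / sum(acc)
  new("PSFModel", kernel = acc, voxelSize = kv, view = stack@view)
}

#' Track global stage drift from bead detections over time
#'
#' Matches beads between consecutive frames by nearest neighbour within a
#' gate, accumulates per-frame displacements, and reports the per-axis
#' median offset of every frame relative to the first. Frames without any
#' match inherit the previous offset.
#'
#' @param beadsByTime list of bead tables ([detectBeads()] output), one per
#'   frame in temporal order
#' @param gate maximum per-frame bead displacement considered a match, um
#' @return a [DriftSeries-class]
#' @export
trackDrift <- function(beadsByTime, gate = 3) {
  if (!length(beadsByTime)) stop("empty bead series")
  nF <- length(beadsByTime)
  offsets <- matrix(0, nF, 3)
  nUsed <- integer(nF)
  prev <- as.matrix(beadsByTime[[1]][, c("x", "y", "z")])
  nUsed[1] <- nrow(prev)
  for (f in seq_len(nF)[-1]) {
    cur <- as.matrix(beadsByTime[[f]][, c("x", "y", "z")])
    step <- c(0, 0, 0)
    nm <- 0L
    if (nrow(cur) && nrow(prev)) {
      disp <- matrix(NA_real_, 0, 3)
      for (i in seq_len(nrow(cur))) {
        dd <- sqrt(rowSums((prev - rep(cur[i, ], each = nrow(prev)))^2))
        j <- which.min(dd)
        if (dd[j] <= gate) disp <- rbind(disp, cur[i, ] - prev[j, ])
      }
      if (nrow(disp)) {
        step <- apply(disp, 2, median)
        nm <- nrow(disp)
      }
    }
    offsets[f, ] <- offsets[f - 1, ] + step
    nUsed[f] <- nm
    if (nrow(cur)) prev <- cur
  }
  new("DriftSeries", offsets = offsets, nBeadsUsed = nUsed)
}
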