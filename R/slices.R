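#' @include haralick.R
NULL

# zero-pad a 2D matrix to a centred square of side >= s
.padSquare <- function(m, s = max(dim(m))) {
  s <- max(s, dim(m))
  out <- matrix(0, s, s)
  o1 <- floor((s - nrow(m)) / 2)
  o2 <- floor((s - ncol(m)) / 2)
  out[o1 + seq_len(nrow(m)), o2 + seq_len(ncol(m))] <- m
  out
}

# square patch -> patchSize x patchSize in [0, 1]; scale = NULL applies
# per-patch min-max, otherwise intensities are divided by the reference
# scale and clipped
.normPatch <- function(m, patchSize, scale = NULL, side = max(dim(m))) {
  m <- .padSquare(m, side)
  if (nrow(m) != patchSize)
    m <- as.matrix(EBImage::resize(EBImage::Image(m), w = patchSize, h = patchSize))
  if (is.null(scale)) {
    rng <- range(m)
    if (diff(rng) > 0) (m - rng[1]) / diff(rng) else matrix(0, patchSize, patchSize)
  } else {
    pmin(pmax(m / scale, 0), 1)
  }
}

#' Reference intensity for volume-anchored patch normalization
#'
#' 1.8 times the mode of the foreground (segmented-voxel) intensity
#' histogram. The mode sits on the diffuse interphase chromatin level --
#' the most common voxel intensity in any nucleus-bearing volume -- so the
#' reference does not move with the mitotic fraction, the spheroid size or
#' the segment edge-voxel share, and patches from different volumes share
#' one brightness scale.
#'
#' @param volume intensity volume (object or array)
#' @param labels the matching [LabelVolume-class]
#' @return scalar reference intensity
#' @export
volumeNormScale <- function(volume, labels) {
  if (is(volume, "VolumeStack")) volume <- volume@data
  fg <- volume[labels@labels > 0L]
  if (!length(fg)) stop("no foreground voxels")
  d <- stats::density(fg, n = 512)
  1.8 * d$x[which.max(d$y)]
}

#' Extract 2D slices of one segmented nucleus
#'
#' Cuts the nucleus' bounding box (plus a small margin) into 2D planes along
#' the three orthogonal orientations (XY, XZ, YZ). Each plane is masked to
#' the segment, zero-padded square, resized to \code{patchSize} and
#' normalized to \eqn{[0,1]}. The default normalization divides by a
#' volume-wide reference intensity ([volumeNormScale()]: 1.8 times the mode
#' of the foreground intensity histogram, which sits on diffuse interphase
#' chromatin and is insensitive to the volume's mitotic fraction; clipped
#' at 1), so the absolute brightness of condensed mitotic chromatin
#' relative to diffuse interphase chromatin survives into the patch;
#' \code{normalize = "patch"} applies per-patch min-max instead.
#' With \code{planes = "central"} only the plane through the segment
#' centroid is taken per orientation (three patches per nucleus); with
#' \code{"all"}, every plane of the bounding box that intersects the
#' segment contributes one patch.
#'
#' @param volume intensity volume ([FusedVolume-class]/[VolumeStack-class]
#'   or array)
#' @param labels the matching [LabelVolume-class]
#' @param nucleusId segment label to extract
#' @param patchSize output patch side, pixels
#' @param mask if \code{TRUE} (default) voxels outside the segment are zeroed
#' @param planes "all" or "central"
#' @param margin in-plane margin around the bounding box, voxels
#' @param normalize "volume" (default) or "patch"
#' @param normScale precomputed reference intensity (see
#'   [volumeNormScale()]); computed from the volume when \code{NULL}
#' @return a [SliceSet-class]
#' @export
extractSlices <- function(volume, labels, nucleusId, patchSize = 64L,
                          mask = TRUE, planes = c("all", "central"),
                          margin = 2L, normalize = c("volume", "patch"),
                          normScale = NULL) {
  planes <- match.arg(planes)
  normalize <- match.arg(normalize)
  if (is(volume, "VolumeStack")) volume <- volume@data
  lab <- labels@labels
  if (normalize == "volume" && is.null(normScale))
    normScale <- volumeNormScale(volume, labels)
  scale <- if (normalize == "volume") normScale else NULL
  d <- dim(lab)
  idx <- which(lab == nucleusId)
  if (!length(idx)) stop("nucleus ", nucleusId, " is empty")
  idx3 <- arrayInd(idx, d)
  lo <- pmax(apply(idx3, 2, min) - margin, 1L)
  hi <- pmin(apply(idx3, 2, max) + margin, d)
  ctr <- round(colMeans(idx3))

  # pad all planes to the cubic extent of the segment so the relative size
  # of structures is comparable across orientations (a face-on metaphase
  # plate fills its patch; a face-on anaphase lobe does not)
  cubeSide <- max(hi - lo + 1L)
  vols <- volume[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  labs <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (mask) vols[labs != nucleusId] <- 0

  patches <- list()
  orient <- character(0)
  sliceIdx <- integer(0)
  addPlane <- function(m, seg, tag, planeIdx) {
    if (!any(seg)) return(FALSE)
    patches[[length(patches) + 1L]] <<- .normPatch(m, patchSize, scale, cubeSide)
    orient <<- c(orient, tag)
    sliceIdx <<- c(sliceIdx, planeIdx)
    TRUE
  }
  planeRange <- function(axis) {
    if (planes == "central") ctr[axis] else lo[axis]:hi[axis]
  }
  for (k in planeRange(3)) {
    kk <- k - lo[3] + 1L
    addPlane(vols[, , kk], labs[, , kk] == nucleusId, "XY", as.integer(k))
  }
  for (j in planeRange(2)) {
    jj <- j - lo[2] + 1L
    addPlane(vols[, jj, ], labs[, jj, ] == nucleusId, "XZ", as.integer(j))
  }
  for (i in planeRange(1)) {
    ii <- i - lo[1] + 1L
    addPlane(vols[ii, , ], labs[ii, , ] == nucleusId, "YZ", as.integer(i))
  }
  if (planes == "central" && length(patches) < 3L) {
    # a centroid plane can miss the segment for very concave shapes; fall
    # back to the nearest populated plane per missing orientation
    for (tag in setdiff(c("XY", "XZ", "YZ"), orient)) {
      axis <- switch(tag, XY = 3L, XZ = 2L, YZ = 1L)
      for (off in seq_len(max(d))) {
        done <- FALSE
        for (p in c(ctr[axis] - off, ctr[axis] + off)) {
          if (p < lo[axis] || p > hi[axis]) next
          pp <- p - lo[axis] + 1L
          m <- switch(tag, XY = vols[, , pp], XZ = vols[, pp, ], YZ = vols[pp, , ])
          sg <- switch(tag, XY = labs[, , pp], XZ = labs[, pp, ], YZ = labs[pp, , ]) == nucleusId
          if (addPlane(m, sg, tag, as.integer(p))) { done <- TRUE; break }
        }
        if (done) break
      }
    }
  }
  arr <- array(0, c(patchSize, patchSize, length(patches)))
  for (s in seq_along(patches)) arr[, , s] <- patches[[s]]
  new("SliceSet", patches = arr, orientation = orient,
      sliceIndex = sliceIdx, nucleusId = as.integer(nucleusId))
}
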