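#' @include fusion.R
NULL

# crop a logical/integer array to the bounding box of its nonzero voxels
.bbox <- function(idx3, d) {
  lo <- pmax(apply(idx3, 2, min), 1L)
  hi <- pmin(apply(idx3, 2, max), d)
  list(lo = lo, hi = hi)
}

# Split one connected component by iterative erosion. The erosion-depth map
# of the binary component is scanned from the deepest level down: every
# depth plateau that does not already contain a marker opens a new core
# (the classical ultimate-erosion markers, capped at maxErosions). A thin
# condensed object (a metaphase plate) merged with a neighbouring diffuse
# nucleus erodes away before it separates, so connected regions of the
# condensed-chromatin mask that carry no marker yet open additional cores.
# All cores are grown back through the component by breadth-first region
# growing. Undersized pieces surrender their marker one at a time (smallest
# first) and the growth is repeated, so the two chromatin lobes of one
# late-anaphase nucleus collapse back into a single segment instead of
# being cut into half-nuclei. Returns the relabelled array, or NULL when no
# acceptable split exists.
.erosionSplit <- function(compMask, maxErosions, minCoreVox, minPieceVox,
                          condensed = NULL, minCondVox = minPieceVox) {
  if (maxErosions < 1L) return(NULL)
  d <- dim(compMask)
  D <- array(0L, d)
  m <- compMask
  for (s in seq_len(maxErosions)) {
    m <- cpp_erode6(m, d)
    if (!any(m == 1L)) break
    D[m == 1L] <- s
  }
  maxD <- max(D)
  if (maxD < 1L) return(NULL)
  markers <- array(0L, d)
  nm <- 0L
  markerCond <- logical(0)
  for (s in seq(maxD, 1L)) {
    cc <- cpp_label3d(array(as.integer(D >= s), d), d, 26L)
    for (c in seq_len(max(cc))) {
      sel <- cc == c
      if (sum(sel) < minCoreVox) next
      if (!any(markers[sel] > 0L)) {
        nm <- nm + 1L
        markers[sel] <- nm
        markerCond <- c(markerCond, FALSE)
      }
    }
  }
  if (!is.null(condensed) && any(condensed == 1L)) {
    # group condensed voxels across small gaps (the dimmer chromatin
    # bridge between two anaphase lobes) so one mitotic figure yields one
    # marker; 2 voxels of dilation bridges ~2.8 um, far below the packing
    # distance of adjacent nuclei
    grp <- cpp_dilate6(condensed, d)
    grp <- cpp_dilate6(grp, d)
    cc <- cpp_label3d(grp, d, 26L)
    for (c in seq_len(max(cc))) {
      sel <- cc == c & condensed == 1L & compMask == 1L
      if (sum(sel) < minCoreVox) next
      # the whole dilated group must be unmarked: condensed speckles inside
      # an already-marked nucleus must not fragment it
      if (!any(markers[cc == c & compMask == 1L] > 0L)) {
        nm <- nm + 1L
        markers[sel] <- nm
        markerCond <- c(markerCond, TRUE)
      }
    }
  }
  if (nm < 2L) return(NULL)
  # two-stage growth: markers first claim condensed voxels among
  # themselves, so a condensed object (lobes plus bridge) is assigned as a
  # whole before diffuse neighbours expand into it
  growAll <- function(markers) {
    if (!is.null(condensed) && any(condensed == 1L)) {
      condMask <- array(as.integer(condensed == 1L | markers > 0L), d)
      markers <- cpp_geodesic_grow(markers, condMask, d)
    }
    cpp_geodesic_grow(markers, compMask, d)
  }
  repeat {
    grown <- growAll(markers)
    pieces <- tabulate(grown[grown > 0L], nbins = nm)
    # condensation-seeded pieces (compact mitotic chromatin) may be
    # genuinely small; depth-seeded pieces must be nucleus-sized
    lim <- ifelse(markerCond, minCondVox, minPieceVox)
    bad <- which(pieces > 0L & pieces < lim)
    if (!length(bad)) break
    drop <- bad[which.min(pieces[bad])]
    keep <- setdiff(seq_len(nm), drop)
    if (length(keep) < 2L) return(NULL)
    relab <- array(0L, d)
    for (w in seq_along(keep)) relab[markers == keep[w]] <- w
    markers <- relab
    markerCond <- markerCond[keep]
    nm <- length(keep)
  }
  grown
}

#' Segment nuclei in a 3D volume
#'
#' Gaussian smoothing, global Otsu thresholding, 26-connected component
#' labelling, erosion-based splitting of merged nuclei (components whose
#' iterative erosion separates into two or more sufficiently large cores are
#' re-split by marker-based region growing constrained to the component),
#' and removal of components below the minimum size.
#'
#' Because a thin condensed object (a metaphase plate, an anaphase mass)
#' merged with a neighbouring diffuse nucleus can erode away before it
#' separates, voxels above 1.3 times the foreground intensity mode (the
#' diffuse-chromatin level, stable however small the mitotic fraction is)
#' mark condensed chromatin, and unmarked condensed regions seed
#' additional cores.
#' A split is accepted only when every resulting piece is at least
#' \code{splitMinSize}; undersized pieces surrender their marker (smallest
#' first), which keeps genuinely touching nuclei apart while not cutting
#' the two chromatin masses of a late-anaphase nucleus into spurious
#' halves.
#'
#' @param volume a [FusedVolume-class]/[VolumeStack-class] or 3D array
#' @param voxelSize voxel size (um), required for arrays
#' @param sigma Gaussian smoothing sigma, um
#' @param minSize minimum segment volume, um^3
#' @param maxErosions erosion steps attempted when splitting
#' @param splitMinSize minimum volume of each piece for an accepted split,
#'   um^3
#' @param splitMinSizeCondensed minimum piece volume for
#'   condensation-seeded pieces, um^3 (compact mitotic chromatin is
#'   smaller than a whole nucleus)
#' @return a [LabelVolume-class]
#' @export
segmentNuclei <- function(volume, voxelSize = NULL, sigma = 0.8,
                          minSize = 30, maxErosions = 5L,
                          splitMinSize = 120, splitMinSizeCondensed = 40) {
  if (is(volume, "VolumeStack")) {
    voxelSize <- volume@voxelSize
    volume <- volume@data
  }
  if (is.null(voxelSize)) stop("voxelSize required for raw arrays")
  rng <- range(volume)
  if (diff(rng) == 0) stop("no foreground: volume has zero dynamic range")
  d <- dim(volume)
  voxVol <- prod(voxelSize)
  sm <- .gaussBlur3d(volume, sigma / voxelSize)
  nrm <- (sm - min(sm)) / diff(range(sm))
  thr <- EBImage::otsu(EBImage::Image(as.numeric(nrm), dim = c(length(nrm), 1L)))
  mask <- array(as.integer(nrm > thr), d)
  lab <- cpp_label3d(mask, d, 26L)
  # condensed-chromatin mask: voxels well above the foreground intensity
  # mode. The mode sits on diffuse interphase chromatin however small the
  # mitotic fraction is (a class-balance-free alternative to a second Otsu
  # split, which needs a substantial bright class to find the boundary);
  # condensed mitotic chromatin renders at ~1.8x the diffuse level but the
  # point-spread blur of small bright objects dilutes it to ~1.4x in fused
  # data, so the cut sits at 1.3x -- above the ~1.2x that interphase
  # texture and noise reach after smoothing. Seeds extra split markers for
  # thin condensed objects.
  condensed <- NULL
  fg <- nrm[mask == 1L]
  if (length(fg) > 100L) {
    dens <- stats::density(fg, n = 512)
    fgMode <- dens$x[which.max(dens$y)]
    thr2 <- 1.3 * fgMode
    if (any(fg > thr2)) {
      condensed <- array(as.integer(mask == 1L & nrm > thr2), d)
    }
  }
  nLab <- max(lab)
  if (nLab == 0L) {
    return(new("LabelVolume", labels = array(0L, d), voxelSize = as.numeric(voxelSize)))
  }
  minCoreVox <- 8L
  minPieceVox <- max(1L, floor(splitMinSize / voxVol))
  minCondVox <- max(1L, floor(splitMinSizeCondensed / voxVol))
  out <- array(0L, d)
  nextLab <- 0L
  idxAll <- which(lab > 0L)
  idx3All <- arrayInd(idxAll, d)
  labAll <- lab[idxAll]
  for (L in seq_len(nLab)) {
    sel <- labAll == L
    idx3 <- idx3All[sel, , drop = FALSE]
    bb <- .bbox(idx3, d)
    sub <- lab[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
    compMask <- array(as.integer(sub == L), dim(sub))
    condSub <- if (is.null(condensed)) NULL else {
      cs <- condensed[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2],
                      bb$lo[3]:bb$hi[3], drop = FALSE]
      array(as.integer(cs == 1L & compMask == 1L), dim(sub))
    }
    grown <- .erosionSplit(compMask, maxErosions, minCoreVox, minPieceVox,
                           condensed = condSub, minCondVox = minCondVox)
    if (is.null(grown)) grown <- compMask
    for (piece in seq_len(max(grown))) {
      vox <- sum(grown == piece)
      if (vox * voxVol < minSize) next
      nextLab <- nextLab + 1L
      block <- out[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]]
      block[grown == piece] <- nextLab
      out[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- block
    }
  }
  new("LabelVolume", labels = out, voxelSize = as.numeric(voxelSize))
}

#' Per-nucleus geometry and intensity features
#'
#' @param labels a [LabelVolume-class]
#' @param volume the intensity volume the labels refer to
#'   ([FusedVolume-class], [VolumeStack-class] or array)
#' @return data.frame sorted by id with columns \code{id}, \code{timepoint},
#'   \code{voxels}, \code{volume} (um^3), \code{x}, \code{y}, \code{z}
#'   (intensity-weighted centroid, um), \code{meanIntensity},
#'   \code{totalIntensity}
#' @export
computeGeometry <- function(labels, volume) {
  tp <- 1L
  if (is(volume, "VolumeStack")) {
    tp <- volume@timepoint
    volume <- volume@data
  }
  lab <- labels@labels
  vox <- labels@voxelSize
  d <- dim(lab)
  idx <- which(lab > 0L)
  if (!length(idx)) {
    return(data.frame(id = integer(0), timepoint = integer(0),
                      voxels = integer(0), volume = numeric(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      meanIntensity = numeric(0), totalIntensity = numeric(0)))
  }
  li <- lab[idx]
  wi <- volume[idx]
  idx3 <- arrayInd(idx, d)
  nvox <- tapply(wi, li, length)
  tot <- tapply(wi, li, sum)
  wx <- tapply(wi * (idx3[, 1] - 1), li, sum) / tot * vox[1]
  wy <- tapply(wi * (idx3[, 2] - 1), li, sum) / tot * vox[2]
  wz <- tapply(wi * (idx3[, 3] - 1), li, sum) / tot * vox[3]
  ids <- as.integer(names(nvox))
  out <- data.frame(id = ids, timepoint = tp, voxels = as.integer(nvox),
                    volume = as.numeric(nvox) * prod(vox),
                    x = as.numeric(wx), y = as.numeric(wy), z = as.numeric(wz),
                    meanIntensity = as.numeric(tot / nvox),
                    totalIntensity = as.numeric(tot))
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
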