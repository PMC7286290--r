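#' @include phenotype.R
NULL

#' Generate the plate spot grid
#'
#' Spot centres on a regular grid at 1536-well pitch (2.25 mm by default),
#' with replicate spots of each sample laid out as contiguous subarrays
#' (two columns by four rows for the default eight spots per sample, as on
#' the screening plate: 40 columns x 8 rows = 320 spots = 40 samples).
#'
#' @param nColumns,nRows grid size
#' @param spotsPerSample replicate spots per sample; must divide the total
#' @param pitch centre-to-centre spot distance, mm
#' @return a [SpotGrid-class]
#' @export
generateSpotGrid <- function(nColumns = 40L, nRows = 8L,
                             spotsPerSample = 8L, pitch = 2.25) {
  if (nColumns < 1 || nRows < 1 || spotsPerSample < 1)
    stop("counts must be >= 1")
  total <- nColumns * nRows
  if (total %% spotsPerSample != 0)
    stop("spotsPerSample must divide the total spot count")
  col <- rep(seq_len(nColumns), each = nRows)
  row <- rep(seq_len(nRows), times = nColumns)
  centers <- cbind(x = (col - 1) * pitch, y = (row - 1) * pitch)
  # contiguous subarrays: 2 columns x 4 rows when spotsPerSample is 8 and
  # the row count allows it, otherwise consecutive spots in column order
  if (spotsPerSample == 8L && nRows %% 4L == 0L && nColumns %% 2L == 0L) {
    blockCol <- (col - 1) %/% 2L
    blockRow <- (row - 1) %/% 4L
    sampleMap <- blockCol * (nRows %/% 4L) + blockRow + 1L
  } else {
    sampleMap <- (seq_len(total) - 1L) %/% spotsPerSample + 1L
  }
  new("SpotGrid", centers = centers, nColumns = as.integer(nColumns),
      nRows = as.integer(nRows), spotsPerSample = as.integer(spotsPerSample),
      pitch = pitch, sampleMap = as.integer(sampleMap))
}

#' Acquisition accounting
#'
#' Exact arithmetic of an acquisition pass: images per pre-screen pass
#' (positions x slices x views) and raw bytes per dual-view position
#' stack (views x width x height x slices x bytes per pixel).
#'
#' @param nPositions stage positions per pass
#' @param nSlices slices per stack
#' @param nViews camera views per position
#' @param imageWidth,imageHeight image size, px
#' @param bytesPerPixel bytes per pixel (2 for 16-bit)
#' @param nTimepoints time points of the screen
#' @return an [AcquisitionPlan-class]
#' @export
planAcquisition <- function(nPositions, nSlices, nViews = 2,
                            imageWidth = 1024, imageHeight = 1024,
                            bytesPerPixel = 2, nTimepoints = 1) {
  obj <- new("AcquisitionPlan",
             nPositions = nPositions, nSlices = nSlices, nViews = nViews,
             imageWidth = imageWidth, imageHeight = imageHeight,
             bytesPerPixel = bytesPerPixel, nTimepoints = nTimepoints,
             imagesPerPass = nPositions * nSlices * nViews,
             bytesPerPositionTimepoint =
               nViews * imageWidth * imageHeight * nSlices * bytesPerPixel,
             totalBytes =
               nViews * imageWidth * imageHeight * nSlices * bytesPerPixel *
               nPositions * nTimepoints)
  validObject(obj)
  obj
}

#' Detect candidate cell clusters in a low-resolution pre-screen stack
#'
#' Thresholds the smoothed stack (Otsu), labels connected components and
#' summarizes each as a pre-screen candidate: centroid, volume, principal
#' axis lengths (2 sigma of the voxel PCA), aspect ratio (longest over
#' shortest axis) and flatness (intermediate over shortest).
#'
#' @param stack a [VolumeStack-class]
#' @param sigma smoothing sigma, um
#' @param minVoxels discard components smaller than this
#' @return data.frame of candidates: \code{x}, \code{y}, \code{z} (um),
#'   \code{size} (um^3), \code{axis1}, \code{axis2}, \code{axis3} (um),
#'   \code{aspect}, \code{flatness}
#' @export
detectPrescreenClusters <- function(stack, sigma = 2, minVoxels = 27L) {
  lab <- segmentNuclei(stack, sigma = sigma,
                       minSize = minVoxels * prod(stack@voxelSize),
                       maxErosions = 0L)
  K <- max(lab@labels)
  if (K == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      size = numeric(0), axis1 = numeric(0),
                      axis2 = numeric(0), axis3 = numeric(0),
                      aspect = numeric(0), flatness = numeric(0)))
  d <- dim(lab@labels)
  vox <- lab@voxelSize
  rows <- lapply(seq_len(K), function(L) {
    idx <- which(lab@labels == L)
    p <- (arrayInd(idx, d) - 1) * rep(vox, each = length(idx))
    ctr <- colMeans(p)
    ev <- eigen(cov(p), symmetric = TRUE, only.values = TRUE)$values
    ax <- 2 * sqrt(pmax(ev, min(vox)^2 / 12))
    data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
               size = length(idx) * prod(vox),
               axis1 = ax[1], axis2 = ax[2], axis3 = ax[3],
               aspect = ax[1] / ax[3], flatness = ax[2] / ax[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select spheroids for high-resolution imaging
#'
#' Applies the pre-screen exclusion rules -- too small, too flat, too
#' elongated -- and ranks the surviving candidates of each spot by their Z
#' coordinate, selecting the deepest ones (least obstruction of the
#' light-sheet paths).
#'
#' @param candidates data.frame as returned by
#'   [detectPrescreenClusters()], with an optional \code{spot} column
#' @param minSize minimum cluster volume, um^3
#' @param maxAspect maximum aspect ratio
#' @param maxFlatness maximum flatness
#' @param nSelect candidates to keep per spot
#' @return the selected rows, with added \code{rank} (Z rank within the
#'   spot); spots with no surviving candidate are reported via the
#'   \code{unselectable} attribute
#' @export
selectSpheroids <- function(candidates, minSize = 2e4, maxAspect = 2.5,
                            maxFlatness = 3, nSelect = 1L) {
  if (!"spot" %in% names(candidates)) candidates$spot <- 1L
  ok <- candidates$size >= minSize &
    candidates$aspect <= maxAspect &
    candidates$flatness <= maxFlatness
  surv <- candidates[ok, , drop = FALSE]
  sel <- list()
  unselectable <- setdiff(unique(candidates$spot), unique(surv$spot))
  for (s in unique(surv$spot)) {
    rows <- surv[surv$spot == s, , drop = FALSE]
    rows <- rows[order(rows$z, decreasing = TRUE), , drop = FALSE]
    rows$rank <- seq_len(nrow(rows))
    sel[[length(sel) + 1L]] <- head(rows, nSelect)
  }
  out <- if (length(sel)) do.call(rbind, sel) else
    surv[0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unselectable") <- unselectable
  out
}
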