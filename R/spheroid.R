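#' @include benchmark.R
NULL

#' Cluster nuclei into spheroids
#'
#' Per frame, nuclei are agglomerated by single linkage on the Euclidean
#' distance of their centroids and the tree is cut at \code{cutoff}:
#' chains of nuclei closer than the cutoff form one spheroid. Spheroid
#' identities are kept stable across frames by matching cluster centres to
#' the previous frame's spheroid centres (nearest centre within
#' \code{2 * cutoff}); unmatched clusters open new spheroid ids.
#'
#' @param records data.frame with columns \code{timepoint}, \code{x},
#'   \code{y}, \code{z} (um)
#' @param cutoff single-linkage cut height, um (default 25, about two
#'   nucleus diameters)
#' @return integer spheroid id per row of \code{records}
#' @export
clusterIntoSpheroids <- function(records, cutoff = 25) {
  if (!nrow(records)) stop("no nuclei supplied")
  out <- integer(nrow(records))
  centres <- matrix(NA_real_, 0, 3)
  nextId <- 0L
  for (f in sort(unique(records$timepoint))) {
    rows <- which(records$timepoint == f)
    p <- as.matrix(records[rows, c("x", "y", "z")])
    cl <- if (length(rows) == 1L) 1L else
      cutree(hclust(dist(p), method = "single"), h = cutoff)
    ids <- integer(max(cl))
    # match this frame's clusters one-to-one against the previous frames'
    # spheroid centres (a snapshot: clusters of one frame never merge ids)
    claimed <- logical(nrow(centres))
    newCentres <- centres
    for (c in seq_len(max(cl))) {
      ctr <- colMeans(p[cl == c, , drop = FALSE])
      match <- NA_integer_
      if (nrow(centres)) {
        dd <- sqrt(rowSums((centres - rep(ctr, each = nrow(centres)))^2))
        dd[claimed] <- Inf
        j <- which.min(dd)
        if (is.finite(dd[j]) && dd[j] <= 2 * cutoff) match <- j
      }
      if (is.na(match)) {
        nextId <- nextId + 1L
        newCentres <- rbind(newCentres, ctr)
        ids[c] <- nextId
      } else {
        claimed[match] <- TRUE
        newCentres[match, ] <- ctr
        ids[c] <- match
      }
    }
    centres <- newCentres
    out[rows] <- ids[cl]
  }
  out
}

#' Track nuclei across frames
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames within
#' a displacement gate. Unmatched nuclei in the later frame start new
#' tracks; when new nuclei appear within the gate of a nucleus that
#' vanished in the previous frame (a division), the children record that
#' nucleus' track as their parent.
#'
#' @param records data.frame with \code{timepoint}, \code{id} (unique within
#'   a frame), \code{x}, \code{y}, \code{z}; extra columns (e.g.
#'   \code{phase}, \code{spheroid}) are carried through
#' @param maxGate maximum per-frame displacement, um
#' @return \code{records} with added columns \code{track},
#'   \code{parentTrack} and \code{step} (displacement from the previous
#'   frame on the same track, um; NA at track starts)
#' @export
trackNuclei <- function(records, maxGate = 10) {
  records <- records[order(records$timepoint, records$id), , drop = FALSE]
  records$track <- NA_integer_
  records$parentTrack <- NA_integer_
  records$step <- NA_real_
  frames <- sort(unique(records$timepoint))
  nextTrack <- 0L
  prevRows <- which(records$timepoint == frames[1])
  records$track[prevRows] <- seq_along(prevRows)
  nextTrack <- length(prevRows)
  for (fi in seq_along(frames)[-1]) {
    curRows <- which(records$timepoint == frames[fi])
    pPrev <- as.matrix(records[prevRows, c("x", "y", "z")])
    pCur <- as.matrix(records[curRows, c("x", "y", "z")])
    D <- as.matrix(dist(rbind(pPrev, pCur)))[seq_len(nrow(pPrev)),
                                             nrow(pPrev) + seq_len(nrow(pCur)),
                                             drop = FALSE]
    matchedPrev <- logical(nrow(pPrev))
    matchedCur <- logical(nrow(pCur))
    repeat {
      D2 <- D
      D2[matchedPrev, ] <- Inf
      D2[, matchedCur] <- Inf
      m <- which.min(D2)
      if (!length(m) || !is.finite(D2[m])) break
      ij <- arrayInd(m, dim(D2))
      if (D2[m] > maxGate) break
      i <- ij[1]; j <- ij[2]
      matchedPrev[i] <- TRUE
      matchedCur[j] <- TRUE
      records$track[curRows[j]] <- records$track[prevRows[i]]
      records$step[curRows[j]] <- D[i, j]
    }
    # new tracks; division handling: a new nucleus within the gate of a
    # previous nucleus makes that nucleus a parent -- whether it vanished
    # or was claimed as a continuation by the sibling. In the latter case
    # the sibling is split off onto its own child track too, so both
    # children of a division carry the parent link and the parent track
    # ends at the division.
    for (j in which(!matchedCur)) {
      nextTrack <- nextTrack + 1L
      records$track[curRows[j]] <- nextTrack
      dd <- D[, j]
      v <- which.min(dd)
      if (length(v) && dd[v] <= maxGate) {
        parentTrack <- records$track[prevRows[v]]
        records$parentTrack[curRows[j]] <- parentTrack
        if (matchedPrev[v]) {
          sib <- which(records$track[curRows] == parentTrack &
                         records$timepoint[curRows] == frames[fi])
          if (length(sib) == 1L) {
            nextTrack <- nextTrack + 1L
            records$track[curRows[sib]] <- nextTrack
            records$parentTrack[curRows[sib]] <- parentTrack
            records$step[curRows[sib]] <- NA_real_
          }
        }
      }
    }
    prevRows <- curRows
  }
  records
}

#' Median migration speed per spheroid
#'
#' Per-step speed is the tracked displacement divided by the frame
#' interval; each spheroid's value is the median over all steps of its
#' member tracks.
#'
#' @param tracks output of [trackNuclei()]
#' @param frameInterval minutes between frames
#' @return data.frame \code{spheroid}, \code{medianSpeed} (um/min),
#'   \code{nSteps}; a single row with \code{spheroid = NA} when the input
#'   has no spheroid column
#' @export
migrationSpeed <- function(tracks, frameInterval) {
  steps <- tracks[!is.na(tracks$step), , drop = FALSE]
  if (!nrow(steps))
    return(data.frame(spheroid = NA_integer_, medianSpeed = NA_real_,
                      nSteps = 0L))
  grp <- if ("spheroid" %in% names(steps)) steps$spheroid else
    rep(NA_integer_, nrow(steps))
  sp <- steps$step / frameInterval
  agg <- tapply(sp, grp, median)
  data.frame(spheroid = as.integer(names(agg)),
             medianSpeed = as.numeric(agg),
             nSteps = as.integer(tapply(sp, grp, length)))
}

#' Distance of every nucleus from its spheroid centre
#'
#' The spheroid centre is the mean of the member nucleus centroids at the
#' same timepoint.
#'
#' @param records data.frame with \code{timepoint}, \code{spheroid},
#'   \code{x}, \code{y}, \code{z}
#' @return numeric distance (um) per row
#' @export
radialDistances <- function(records) {
  out <- numeric(nrow(records))
  key <- interaction(records$timepoint, records$spheroid, drop = TRUE)
  for (k in levels(key)) {
    rows <- which(key == k)
    p <- as.matrix(records[rows, c("x", "y", "z")])
    ctr <- colMeans(p)
    out[rows] <- sqrt(rowSums((p - rep(ctr, each = nrow(p)))^2))
  }
  out
}

#' Phase occupancy fractions
#'
#' Fraction of nucleus-frames in each cell-cycle phase over all frames.
#'
#' @param phases factor (or character) of per-nucleus-frame phase calls
#' @param classOrder class order of the output; defaults to the factor
#'   levels or the canonical phase order
#' @return named numeric fractions summing to 1
#' @export
phaseFractions <- function(phases, classOrder = NULL) {
  if (!length(phases)) stop("no classified nucleus-frames")
  if (is.null(classOrder))
    classOrder <- if (is.factor(phases)) levels(phases) else .PHASES
  phases <- factor(as.character(phases), levels = classOrder)
  tab <- table(phases)
  setNames(as.numeric(tab) / sum(tab), classOrder)
}

.VALID_TRANSITIONS <- matrix(c(
  "interphase", "prophase",
  "prophase", "metaphase",
  "metaphase", "anaphase",
  "anaphase", "interphase"), ncol = 2, byrow = TRUE)

#' Detect cell-cycle transitions and flag improper ones
#'
#' Emits an event wherever consecutive phase calls along a track differ,
#' plus a division event linking each child track's first call to its
#' parent's last call. Valid transitions are interphase to prophase,
#' prophase to metaphase, metaphase to anaphase, anaphase to interphase,
#' and a division exiting from anaphase; everything else is flagged
#' improper (e.g. the prophase-to-interphase signature of apoptotic
#' nuclei).
#'
#' @param tracks output of [trackNuclei()] with a \code{phase} column
#' @return list with \code{events} (data.frame: \code{track}, \code{frame},
#'   \code{from}, \code{to}, \code{division}, \code{improper}) and
#'   \code{summary} (counts of total events, improper events, and of
#'   nuclei/tracks with at least one transition)
#' @export
detectTransitions <- function(tracks) {
  stopifnot("phase" %in% names(tracks))
  tracks <- tracks[order(tracks$track, tracks$timepoint), , drop = FALSE]
  ph <- as.character(tracks$phase)
  ev <- list()
  isValid <- function(from, to) {
    any(.VALID_TRANSITIONS[, 1] == from & .VALID_TRANSITIONS[, 2] == to)
  }
  for (tr in unique(tracks$track)) {
    rows <- which(tracks$track == tr)
    if (length(rows) > 1L) {
      for (w in seq_along(rows)[-1]) {
        a <- ph[rows[w - 1]]
        b <- ph[rows[w]]
        if (a != b)
          ev[[length(ev) + 1L]] <- data.frame(
            track = tr, frame = tracks$timepoint[rows[w]], from = a, to = b,
            division = FALSE, improper = !isValid(a, b))
      }
    }
    parent <- tracks$parentTrack[rows[1]]
    if (!is.na(parent)) {
      pRows <- which(tracks$track == parent)
      if (length(pRows)) {
        a <- ph[pRows[length(pRows)]]
        # a division exiting from anaphase is a valid transition
        ev[[length(ev) + 1L]] <- data.frame(
          track = tr, frame = tracks$timepoint[rows[1]], from = a,
          to = "division", division = TRUE, improper = a != "anaphase")
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(track = integer(0), frame = integer(0), from = character(0),
               to = character(0), division = logical(0), improper = logical(0))
  list(events = events,
       summary = data.frame(
         totalEvents = nrow(events),
         improperEvents = sum(events$improper),
         nTransitioningNuclei = length(unique(events$track))))
}

#' Instantaneous growth rate of a count or volume series
#'
#' The series is smoothed with locally weighted regression
#' (\code{stats::lowess} with span \code{f}, \code{iter} robustifying
#' iterations and \code{delta = deltaFrac * diff(range(series))}) and
#' differentiated with first differences.
#'
#' @param series numeric series (e.g. nuclei counts per frame), at least 4
#'   points
#' @param f lowess span fraction (default 1/3)
#' @param iter lowess robustifying iterations (default 3)
#' @param deltaFrac fraction of the series range used as the lowess delta
#'   (default 0.01)
#' @return numeric rate series of length \code{length(series) - 1}, per
#'   frame interval
#' @export
growthRate <- function(series, f = 1/3, iter = 3L, deltaFrac = 0.01) {
  if (length(series) < 4L) stop("need at least 4 timepoints")
  if (f <= 0 || f > 1) stop("f must be in (0, 1]")
  delta <- deltaFrac * diff(range(series))
  # robustness iterations reweight by the residual scale; on an exactly
  # fitted series that scale is zero and the reweighting degenerates, so
  # they are skipped when the plain fit is already exact
  sm0 <- lowess(seq_along(series), series, f = f, iter = 0L, delta = delta)
  resid <- series - sm0$y
  scale <- max(abs(series), 1)
  sm <- if (iter > 0L && median(abs(resid)) > 1e-9 * scale) {
    lowess(seq_along(series), series, f = f, iter = iter, delta = delta)
  } else sm0
  diff(sm$y)
}

#' Shape descriptors of a spheroid mask
#'
#' \itemize{
#'   \item sphericity: \eqn{\pi^{1/3} (6V)^{2/3} / A} with \eqn{V} the voxel
#'     volume of the mask and \eqn{A} the convex-hull surface area
#'   \item convexity: \eqn{V / V_{hull}}
#'   \item compactness: \eqn{V} over the volume of the minimal bounding
#'     sphere of the hull vertices
#' }
#' All three are scale invariant and clipped to at most 1 (voxelization can
#' otherwise push a digital ball marginally above 1). Definitions are
#' attached as the \code{definitions} attribute.
#'
#' @param mask logical or 0/1 3D array
#' @param voxelSize voxel size, um
#' @return named numeric: \code{sphericity}, \code{convexity},
#'   \code{compactness}, \code{volume} (um^3), \code{hullVolume} (um^3)
#' @export
shapeDescriptors <- function(mask, voxelSize) {
  mask <- array(as.integer(mask != 0), dim(mask))
  if (!any(mask == 1L)) stop("empty mask")
  d <- dim(mask)
  voxVol <- prod(voxelSize)
  V <- sum(mask) * voxVol
  core <- cpp_erode6(mask, d)
  surf <- which(mask == 1L & core == 0L)
  if (!length(surf)) surf <- which(mask == 1L)
  pts <- (arrayInd(surf, d) - 1) * rep(voxelSize, each = length(surf))
  hull <- cpp_convhull3d(pts)
  if (hull$degenerate) {
    out <- c(sphericity = NA_real_, convexity = NA_real_,
             compactness = NA_real_, volume = V, hullVolume = NA_real_)
    return(out)
  }
  # minimal bounding sphere of the hull vertices (Ritter, then tighten)
  hv <- pts[hull$vertices, , drop = FALSE]
  ctr <- colMeans(hv)
  r <- sqrt(max(rowSums((hv - rep(ctr, each = nrow(hv)))^2)))
  for (it in 1:50) {
    dd <- sqrt(rowSums((hv - rep(ctr, each = nrow(hv)))^2))
    w <- which.max(dd)
    if (dd[w] <= r * (1 + 1e-9)) break
    shift <- (dd[w] - r) / 2
    ctr <- ctr + shift * (hv[w, ] - ctr) / dd[w]
    r <- (dd[w] + r) / 2
  }
  out <- c(sphericity = min(1, pi^(1 / 3) * (6 * V)^(2 / 3) / hull$area),
           convexity = min(1, V / hull$volume),
           compactness = min(1, V / (4 / 3 * pi * r^3)),
           volume = V, hullVolume = hull$volume)
  attr(out, "definitions") <- c(
    sphericity = "pi^(1/3)*(6V)^(2/3)/A_hull",
    convexity = "V/V_hull",
    compactness = "V/V_boundingSphere")
  out
}

#' Spheroid-level time series
#'
#' Assembles classified, spheroid-assigned nucleus records (and optionally
#' the per-frame label volumes) into one row per spheroid and timepoint:
#' centre, nuclei count, spheroid volume (convex hull of the union of the
#' member nucleus segments), shape descriptors, mean cell volume (spheroid
#' volume over nuclei count) and, per spheroid, the lowess growth rate of
#' the nuclei count.
#'
#' @param records nucleus records with \code{timepoint}, \code{id},
#'   \code{spheroid}, \code{x}, \code{y}, \code{z}
#' @param labelVolumes optional list of [LabelVolume-class], one per frame
#'   in timepoint order; when present, hull-based volume and shape columns
#'   are filled
#' @param f,iter,deltaFrac growth-rate smoothing parameters, see
#'   [growthRate()]
#' @return data.frame, one row per spheroid-timepoint
#' @export
spheroidTimeSeries <- function(records, labelVolumes = NULL, f = 1/3,
                               iter = 3L, deltaFrac = 0.01) {
  frames <- sort(unique(records$timepoint))
  rows <- list()
  for (s in sort(unique(records$spheroid))) {
    for (fi in seq_along(frames)) {
      sel <- records$timepoint == frames[fi] & records$spheroid == s
      if (!any(sel)) next
      p <- as.matrix(records[sel, c("x", "y", "z")])
      n <- nrow(p)
      row <- data.frame(spheroid = s, timepoint = frames[fi],
                        x = mean(p[, 1]), y = mean(p[, 2]), z = mean(p[, 3]),
                        nNuclei = n, spheroidVolume = NA_real_,
                        meanCellVolume = NA_real_, sphericity = NA_real_,
                        convexity = NA_real_, compactness = NA_real_)
      if (!is.null(labelVolumes)) {
        lv <- labelVolumes[[fi]]
        ids <- records$id[sel]
        msk <- array(as.integer(lv@labels %in% ids), dim(lv@labels))
        if (sum(msk) >= 4) {
          sh <- shapeDescriptors(msk, lv@voxelSize)
          row$spheroidVolume <- sh[["hullVolume"]]
          row$meanCellVolume <- sh[["hullVolume"]] / n
          row$sphericity <- sh[["sphericity"]]
          row$convexity <- sh[["convexity"]]
          row$compactness <- sh[["compactness"]]
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$growthRate <- NA_real_
  for (s in unique(out$spheroid)) {
    sel <- which(out$spheroid == s)
    if (length(sel) >= 4L) {
      gr <- growthRate(out$nNuclei[sel], f = f, iter = iter,
                       deltaFrac = deltaFrac)
      out$growthRate[sel[-1]] <- gr
    }
  }
  rownames(out) <- NULL
  out
}
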