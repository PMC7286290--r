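#' @include AllClasses.R AllGenerics.R utils.R
NULL

# phase of a cell given its age within the cycle (minutes)
.phaseOfAge <- function(age, cycleLength, pd) {
  iDur <- cycleLength - sum(pd)
  bounds <- cumsum(c(iDur, pd["prophase"], pd["metaphase"], pd["anaphase"]))
  if (age < bounds[1]) {
    list(phase = "interphase", frac = age / bounds[1])
  } else if (age < bounds[2]) {
    list(phase = "prophase", frac = (age - bounds[1]) / pd[["prophase"]])
  } else if (age < bounds[3]) {
    list(phase = "metaphase", frac = (age - bounds[2]) / pd[["metaphase"]])
  } else {
    list(phase = "anaphase", frac = (age - bounds[3]) / pd[["anaphase"]])
  }
}

.randomUnit <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

# soft-sphere relaxation keeping the spheroid roughly ball-shaped: push
# overlapping neighbours to the packing distance, pull outliers toward the
# centroid
.relaxPositions <- function(pos, packing, iterations = 3) {
  n <- nrow(pos)
  if (n < 2) return(pos)
  for (it in seq_len(iterations)) {
    ctr <- colMeans(pos)
    disp <- matrix(0, n, 3)
    d <- as.matrix(dist(pos))
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (d[i, j] < packing && d[i, j] > 1e-9) {
          push <- 0.35 * (packing - d[i, j]) / d[i, j] * (pos[i, ] - pos[j, ])
          disp[i, ] <- disp[i, ] + push
          disp[j, ] <- disp[j, ] - push
        }
      }
    }
    rmax <- packing * (n / 2)^(1 / 3)
    rad <- sqrt(rowSums((pos - rep(ctr, each = n))^2))
    out <- rad > rmax
    if (any(out)) {
      pull <- 0.2 * (rad[out] - rmax) / rad[out]
      disp[out, ] <- disp[out, ] - pull * (pos[out, , drop = FALSE] - rep(ctr, each = sum(out)))
    }
    pos <- pos + disp
  }
  pos
}

#' Simulate a ground-truthed clonal spheroid time lapse
#'
#' Runs the asynchronous cell-cycle clock of every nucleus forward over the
#' requested frames. Each cell starts at a uniformly random position of its
#' cycle, traverses interphase, prophase, metaphase and anaphase, and at the
#' end of anaphase is replaced by exactly two children displaced along the
#' division axis. Nuclei diffuse slightly, are kept at the packing distance
#' by soft-sphere relaxation, and the whole stage drifts linearly when a
#' drift vector is set. Fiducial beads are static in the sample and move only
#' with the stage drift.
#'
#' Scene coordinates are um, centred on the spheroid seed point; rendering
#' places the origin at the centre of the view-A field of view.
#'
#' @param params a [SceneParams-class]
#' @param nBeads number of fiducial beads carried in the scene ground truth
#' @return a [GroundTruthScene-class]
#' @examples
#' sc <- simulateTimelapse(SceneParams(nInitialCells = 5L, nFrames = 10L))
#' head(sc@nuclei)
#' @export
simulateTimelapse <- function(params, nBeads = 10L) {
  validObject(params)
  pd <- params@phaseDurations[c("prophase", "metaphase", "anaphase")]
  withr::with_seed(params@seed, {
    n0 <- params@nInitialCells
    state <- data.frame(
      id = seq_len(n0), parent = NA_integer_,
      x = 0, y = 0, z = 0,
      radius = pmax(1.5, rnorm(n0, params@nucleusRadiusMean, params@nucleusRadiusSD)),
      age = runif(n0, 0, params@cycleLength),
      spheroid = 1L
    )
    axis <- t(vapply(seq_len(n0), function(i) .randomUnit(), numeric(3)))
    # initial packing: random directions, then relax
    if (n0 > 1) {
      pos <- t(vapply(seq_len(n0), function(i) .randomUnit(), numeric(3))) *
        params@packingDistance * 0.5 * (n0^(1 / 3)) * runif(n0)^(1 / 3)
      pos <- .relaxPositions(pos, params@packingDistance, iterations = 15)
      state[, c("x", "y", "z")] <- pos
    }
    beadBox <- 0.38 * params@packingDistance * max(4, n0^(1 / 3)) + 12
    beads0 <- matrix(runif(3 * nBeads, -beadBox, beadBox), ncol = 3)

    nextId <- n0 + 1L
    frames <- vector("list", params@nFrames)
    beadFrames <- vector("list", params@nFrames)
    drift <- outer(0:(params@nFrames - 1L), params@driftPerFrame)

    for (f in seq_len(params@nFrames)) {
      if (f > 1L) {
        state$age <- state$age + params@frameInterval
        # divisions: age past the full cycle replaces the cell by two children
        dividing <- which(state$age >= params@cycleLength)
        if (length(dividing)) {
          kids <- vector("list", length(dividing))
          kidAxis <- vector("list", length(dividing))
          for (w in seq_along(dividing)) {
            i <- dividing[w]
            u <- axis[i, ]
            off <- 0.8 * state$radius[i]
            carry <- state$age[i] - params@cycleLength
            kid <- state[c(i, i), ]
            kid$id <- c(nextId, nextId + 1L)
            kid$parent <- state$id[i]
            kid$age <- carry
            kid$radius <- pmax(1.5, rnorm(2, params@nucleusRadiusMean,
                                          params@nucleusRadiusSD))
            kid[, c("x", "y", "z")] <- rbind(
              unlist(state[i, c("x", "y", "z")]) + off * u,
              unlist(state[i, c("x", "y", "z")]) - off * u)
            nextId <- nextId + 2L
            kids[[w]] <- kid
            kidAxis[[w]] <- rbind(.randomUnit(), .randomUnit())
          }
          state <- rbind(state[-dividing, , drop = FALSE], do.call(rbind, kids))
          axis <- rbind(axis[-dividing, , drop = FALSE], do.call(rbind, kidAxis))
        }
        # a fresh division axis is drawn when a cell enters prophase
        iDur <- params@cycleLength - sum(pd)
        entering <- which(state$age >= iDur &
                            state$age - params@frameInterval < iDur)
        for (i in entering) axis[i, ] <- .randomUnit()
        # slight diffusive motion plus packing relaxation
        pos <- as.matrix(state[, c("x", "y", "z")])
        pos <- pos + matrix(rnorm(3 * nrow(pos), 0, 0.12), ncol = 3)
        pos <- .relaxPositions(pos, params@packingDistance, iterations = 2)
        state[, c("x", "y", "z")] <- pos
      }
      ph <- lapply(state$age, .phaseOfAge, cycleLength = params@cycleLength, pd = pd)
      frames[[f]] <- data.frame(
        frame = f, id = state$id, parent = state$parent,
        x = state$x, y = state$y, z = state$z, radius = state$radius,
        phase = vapply(ph, `[[`, character(1), "phase"),
        phaseFrac = vapply(ph, `[[`, numeric(1), "frac"),
        axisX = axis[, 1], axisY = axis[, 2], axisZ = axis[, 3],
        spheroid = state$spheroid
      )
      beadFrames[[f]] <- data.frame(
        frame = f, bead = seq_len(nBeads),
        x = beads0[, 1] + drift[f, 1],
        y = beads0[, 2] + drift[f, 2],
        z = beads0[, 3] + drift[f, 3]
      )
    }
    nuclei <- do.call(rbind, frames)
    nuclei$phase <- factor(nuclei$phase, levels = .PHASES)
    new("GroundTruthScene",
        nuclei = nuclei,
        beads = do.call(rbind, beadFrames),
        transform = affineTransform3D(.rot90Y(), c(1.2, -0.8, 0.6)),
        drift = drift,
        params = params)
  })
}

#' True view transform of a scene on a given camera grid
#'
#' The scene stores the abstract view-B-to-view-A relation (rotation plus a
#' small translation). On an actual camera grid the rotation acts about the
#' field-of-view centre, so the grid-level transform depends on the optics.
#' This helper returns the effective [AffineTransform3D-class] that maps
#' view-B grid coordinates (um) into view-A grid coordinates, i.e. the
#' transform bead registration is expected to recover.
#'
#' @param scene a [GroundTruthScene-class]
#' @param optics the [OpticsParams-class] used for rendering
#' @return an [AffineTransform3D-class]
#' @export
trueViewTransform <- function(scene, optics) {
  L <- scene@transform@linear
  tr <- scene@transform@translation
  fov <- .fovA(optics)
  cA <- fov / 2
  cB <- abs(as.vector(L %*% fov)) / 2
  affineTransform3D(L, cA - as.vector(L %*% cB) + tr)
}

#' Expected asynchronous phase occupancy
#'
#' Closed-form stationary occupancy of each phase for an asynchronous
#' population: duration divided by cycle length.
#'
#' @param params a [SceneParams-class]
#' @return named numeric occupancy fractions summing to 1
#' @export
expectedPhaseOccupancy <- function(params) {
  pd <- params@phaseDurations[c("prophase", "metaphase", "anaphase")]
  iDur <- params@cycleLength - sum(pd)
  out <- c(interphase = iDur, pd) / params@cycleLength
  names(out) <- .PHASES
  out
}
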