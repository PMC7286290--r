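#' @include classify.R
NULL

#' Optics preset for the classifier benchmark renderer
#'
#' The desk-scale dual-view optics on a wider grid that holds one batch of
#' benchmark nuclei (160 packed into a spheroid, or an isolated grid).
#'
#' @return an [OpticsParams-class]
#' @export
benchmarkOptics <- function() {
  deskOptics(gridDim = c(140L, 140L, 96L))
}

# static single-frame scene holding the given nuclei (scene coordinates are
# centred on the field of view)
.staticScene <- function(nuc, params) {
  new("GroundTruthScene", nuclei = nuc,
      beads = data.frame(frame = integer(0), bead = integer(0),
                         x = numeric(0), y = numeric(0), z = numeric(0)),
      transform = affineTransform3D(.rot90Y(), c(1.2, -0.8, 0.6)),
      drift = matrix(0, 1, 3), params = params)
}

# pack a batch of nuclei into a relaxed spheroid around the FOV centre
# (um, world frame), at the scene generator's packing distance
.benchmarkPacking <- function(n, optics, packing) {
  pos <- t(vapply(seq_len(n), function(i) .randomUnit(), numeric(3))) *
    packing * 0.5 * (n^(1 / 3)) * runif(n)^(1 / 3)
  pos <- .relaxPositions(pos, packing, iterations = 12)
  pos + rep(.fovA(optics) / 2, each = n)
}

# benchmark grid positions (um, world frame) inside the field of view
.benchmarkPositions <- function(optics, spacing = 12.5, margin = 10) {
  fov <- .fovA(optics)
  ax <- lapply(fov, function(f) {
    n <- max(1L, floor((f - 2 * margin) / spacing) + 1L)
    margin + (seq_len(n) - 1L) * spacing
  })
  as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
}

#' Default synthetic 4-class nucleus-morphology benchmark
#'
#' Builds the annotated nucleus set both classifiers are trained and scored
#' on: the in-silico analogue of a manually annotated nucleus set. Nuclei
#' with the four phase morphologies (balanced proportions) are packed into
#' spheroids at the scene generator's packing density (the default
#' \code{layout = "packed"}; \code{"grid"} places them isolated on a
#' well-separated grid instead), imaged through the *full* dual-view
#' pipeline -- two rotated camera views with per-view anisotropic PSF, shot
#' and read noise, bead-calibrated registration, resampling and joint
#' Richardson-Lucy fusion -- then segmented. The extracted Haralick
#' features and slice patches therefore carry the texture, packing and
#' processing artefacts (deconvolution noise amplification,
#' neighbour-truncated segment masks, point-spread bleed-through) that
#' pipeline data carry; training on isolated nuclei instead produces
#' classifiers that misread packing artefacts as chromatin condensation.
#'
#' Radii follow the scene generator's nucleus size distribution; mitotic
#' progress (anaphase lobe separation etc.) is uniform. Segments are
#' matched back to the intended positions; nuclei whose segment is lost or
#' merged are dropped, so per-class counts can fall marginally below
#' \code{nPerClass}.
#'
#' @param nPerClass nuclei per phase (default 800)
#' @param seed RNG seed
#' @param patchSize CNN patch side
#' @param optics renderer preset, defaults to [benchmarkOptics()]
#' @param planes slice selection per nucleus ("central": one per
#'   orientation)
#' @param nIter Richardson-Lucy iterations, matching the pipeline default
#' @param layout "packed" (spheroid-density batches) or "grid" (isolated)
#' @param perBatch nuclei per batch volume
#' @return list: \code{features} (matrix n x 13), \code{slices} (list of
#'   [SliceSet-class]), \code{labels} (factor, canonical phase order),
#'   \code{radius}, \code{phaseFrac}
#' @export
makePhaseBenchmark <- function(nPerClass = 800L, seed = 1L, patchSize = 64L,
                               optics = benchmarkOptics(),
                               planes = "central", nIter = 3L,
                               layout = c("packed", "grid"),
                               perBatch = 160L) {
  layout <- match.arg(layout)
  n <- 4L * nPerClass
  phases <- rep(.PHASES, nPerClass)  # interleaved: batches stay balanced
  if (layout == "grid") {
    pos0 <- .benchmarkPositions(optics)
    perBatch <- nrow(pos0)
  }
  params <- SceneParams(nInitialCells = 1L, nFrames = 1L, seed = seed)
  withr::with_seed(seed, {
    radius <- pmax(1.5, rnorm(n, params@nucleusRadiusMean,
                              params@nucleusRadiusSD))
    phaseFrac <- runif(n)
    axes <- t(vapply(seq_len(n), function(i) .randomUnit(), numeric(3)))

    # one bead calibration for all batches (the plate's bead spot)
    trueT <- trueViewTransform(.staticScene(data.frame(), params), optics)
    calibScene <- renderBeadCalibration(12L, optics,
                                        seed = .subSeed(seed, 991),
                                        transform = trueT)
    calib <- calibrateFromBeads(calibScene$frames[[1]], optics)

    feats <- matrix(NA_real_, n, 13, dimnames = list(NULL, .HARALICK_NAMES))
    slices <- vector("list", n)
    ok <- logical(n)
    off <- .fovA(optics) / 2
    nBatches <- ceiling(n / perBatch)
    for (b in seq_len(nBatches)) {
      idx <- ((b - 1L) * perBatch + 1L):min(b * perBatch, n)
      world <- if (layout == "packed") {
        .benchmarkPacking(length(idx), optics, params@packingDistance)
      } else {
        pos0[seq_along(idx), , drop = FALSE] +
          matrix(runif(3 * length(idx), -1, 1), ncol = 3)
      }
      nuc <- data.frame(
        frame = 1L, id = seq_along(idx), parent = NA_integer_,
        x = world[, 1] - off[1], y = world[, 2] - off[2],
        z = world[, 3] - off[3],
        radius = radius[idx],
        phase = factor(phases[idx], levels = .PHASES),
        phaseFrac = phaseFrac[idx],
        axisX = axes[idx, 1], axisY = axes[idx, 2], axisZ = axes[idx, 3],
        spheroid = 1L)
      scene <- .staticScene(nuc, params)
      views <- renderDualView(scene, optics, 1L, seed = .subSeed(seed, b))
      pf <- processFrame(views, calib, bundle = NULL, nIter = nIter)
      if (!nrow(pf$records)) next
      har <- computeHaralick(pf$labels, pf$fused)
      ns <- volumeNormScale(pf$fused, pf$labels)
      segPos <- as.matrix(pf$records[, c("x", "y", "z")])
      usedSeg <- logical(nrow(segPos))
      for (w in seq_along(idx)) {
        dd <- sqrt(rowSums((segPos - rep(world[w, ], each = nrow(segPos)))^2))
        dd[usedSeg] <- Inf
        j <- which.min(dd)
        if (!is.finite(dd[j]) || dd[j] > radius[idx[w]]) next
        usedSeg[j] <- TRUE
        segId <- pf$records$id[j]
        feats[idx[w], ] <- har[segId, ]
        slices[[idx[w]]] <- extractSlices(pf$fused, pf$labels, segId,
                                          patchSize = patchSize,
                                          planes = planes, normScale = ns)
        ok[idx[w]] <- TRUE
      }
    }
    list(features = feats[ok, , drop = FALSE],
         slices = slices[ok],
         labels = factor(phases[ok], levels = .PHASES),
         radius = radius[ok], phaseFrac = phaseFrac[ok])
  })
}
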