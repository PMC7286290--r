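# the scene generator: lineage rules, occupancy, rendering physics

test_that("a single-cell single-frame scene is the identity case", {
  sc <- simulateTimelapse(SceneParams(nInitialCells = 1L, nFrames = 1L))
  expect_equal(nrow(sc@nuclei), 1L)
  expect_equal(sc@nuclei$spheroid, 1L)
  expect_error(SceneParams(nFrames = 0L))
  expect_error(SceneParams(nInitialCells = 0L))
})

test_that("simulation is deterministic for a fixed seed", {
  p <- SceneParams(nInitialCells = 8L, nFrames = 25L, seed = 42L)
  s1 <- simulateTimelapse(p)
  s2 <- simulateTimelapse(p)
  expect_identical(s1@nuclei, s2@nuclei)
  expect_identical(s1@beads, s2@beads)
})

test_that("lineages never skip phases and divisions yield exactly two children", {
  p <- SceneParams(nInitialCells = 25L, nFrames = 80L, seed = 7L,
                   cycleLength = 300,
                   phaseDurations = c(prophase = 20, metaphase = 25,
                                      anaphase = 35))
  sc <- simulateTimelapse(p)
  nuc <- sc@nuclei
  ord <- c(interphase = 1L, prophase = 2L, metaphase = 3L, anaphase = 4L)
  for (id in unique(nuc$id)) {
    ph <- ord[as.character(nuc$phase[nuc$id == id])]
    step <- diff(ph)
    # within a lifetime the phase index only stays or advances by one,
    # except the wrap anaphase -> interphase (a cell finishing its cycle
    # without division never occurs: division ends the id)
    expect_true(all(step %in% c(0L, 1L)))
  }
  parents <- nuc$parent[!is.na(nuc$parent)]
  kids <- unique(nuc[!is.na(nuc$parent), c("id", "parent")])
  counts <- table(kids$parent)
  expect_true(all(counts == 2L))
  expect_gt(length(counts), 0L)
  # a parent disappears when its children appear
  for (pid in as.integer(names(counts))) {
    lastParent <- max(nuc$frame[nuc$id == pid])
    firstKids <- min(nuc$frame[nuc$parent %in% pid])
    expect_equal(firstKids, lastParent + 1L)
  }
})

test_that("asynchronous occupancy approaches duration over cycle length", {
  p <- SceneParams()
  occ <- expectedPhaseOccupancy(p)
  expect_equal(sum(occ), 1)
  expect_equal(unname(occ["interphase"]), (1260 - 66.7) / 1260,
               tolerance = 1e-12)
  expect_equal(unname(occ["anaphase"]), 40.3 / 1260, tolerance = 1e-12)
  # finite-sample occupancy of a non-dividing window: drop post-division
  # lineage tails by using a window shorter than the shortest phase path
  sim <- simulateTimelapse(SceneParams(nInitialCells = 120L, nFrames = 40L,
                                       seed = 5L))
  frac <- phaseFractions(sim@nuclei$phase)
  expect_equal(unname(frac["interphase"]), unname(occ["interphase"]),
               tolerance = 0.03)
})

test_that("bead ground truth moves only by the drift vector", {
  opt <- deskOptics()
  still <- renderBeadCalibration(5, opt, drift = c(0, 0, 0), nFrames = 4L,
                                 seed = 2L, applyNoise = FALSE)
  expect_identical(still$positions[[1]], still$positions[[4]])
  mov <- renderBeadCalibration(5, opt, drift = c(0.2, 0, 0), nFrames = 11L,
                               seed = 2L)
  disp <- mov$positions[[11]] - mov$positions[[1]]
  expect_equal(unname(disp[, 1]), rep(2.0, 5))
  expect_equal(unname(disp[, 2]), rep(0, 5))
})

test_that("noise-free rendering is linear in source density", {
  opt <- deskOptics(gridDim = c(48L, 48L, 32L))
  b1 <- renderBeadCalibration(3, opt, seed = 9L, brightness = 10,
                              applyNoise = FALSE, quantize = FALSE)
  b2 <- renderBeadCalibration(3, opt, seed = 9L, brightness = 20,
                              applyNoise = FALSE, quantize = FALSE)
  bg <- opt@photonScale * opt@background
  expect_equal(b2$frames[[1]]$viewA@data - bg,
               2 * (b1$frames[[1]]$viewA@data - bg), tolerance = 1e-10)
})

test_that("rendered point sources show the anisotropic PSF", {
  # fine sampling: the lateral FWHM (~0.9 um) needs sub-0.5-um voxels
  opt <- deskOptics(gridDim = c(60L, 60L, 48L), voxelSize = 0.25)
  b <- renderBeadCalibration(1, opt, seed = 3L, applyNoise = FALSE,
                             quantize = FALSE)
  fw <- measureFWHM(b$frames[[1]]$viewA)
  sigEff <- sqrt(c(opt@psfSigmaLateral[["A"]], opt@psfSigmaAxial[["A"]])^2 +
                   0.15^2)
  expect_gt(fw["z"], fw["x"])
  expect_equal(unname(fw["x"]), 2.355 * sigEff[1], tolerance = 0.1)
  expect_equal(unname(fw["z"]), 2.355 * sigEff[2], tolerance = 0.1)
})

test_that("zero photon scale yields an all-background stack", {
  opt <- deskOptics(gridDim = c(32L, 32L, 24L), photonScale = 0)
  sc <- simulateTimelapse(SceneParams(nInitialCells = 2L, nFrames = 1L))
  v <- renderDualView(sc, opt, 1, applyNoise = FALSE, quantize = FALSE)
  expect_true(all(v$viewA@data == 0))
})

test_that("delta-PSF noiseless view A equals the raw density raster", {
  opt <- OpticsParams(voxelSizeXY = 0.7, sliceSpacing = 0.7,
                      gridDim = c(40L, 40L, 32L),
                      psfSigmaLateral = c(A = 0, B = 0),
                      psfSigmaAxial = c(A = 0, B = 0),
                      photonScale = 100, readNoiseSD = 0, background = 0)
  sc <- simulateTimelapse(SceneParams(nInitialCells = 2L, nFrames = 1L,
                                      seed = 4L))
  v <- renderDualView(sc, opt, 1, seed = 6L, applyNoise = FALSE,
                      quantize = FALSE)
  dens <- withr::with_seed(spimscreen:::.subSeed(6L, 1), {
    spimscreen:::cpp_rasterize_nuclei(
      opt@gridDim, rep(0.7, 3),
      spimscreen:::.nucleusMatrix(sc@nuclei[sc@nuclei$frame == 1, ],
                                  spimscreen:::.fovA(opt) / 2),
      spimscreen:::.PHASE_RENDER, diag(3))
  })
  expect_equal(v$viewA@data, array(100 * dens, dim(dens)), tolerance = 1e-12)
})
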