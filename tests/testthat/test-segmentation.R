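# nuclei segmentation and geometric features

test_that("degenerate volumes are handled", {
  expect_error(segmentNuclei(array(5, c(10, 10, 10)), voxelSize = rep(1, 3)),
               "no foreground")
  # background with sparse shot-noise spikes and no nuclei: everything
  # above threshold is tiny and falls to the minimum-size filter
  withr::with_seed(9, {
    noise <- array(10 + rnorm(20^3, 0, 0.2), rep(20, 3))
    noise[sample(20^3, 30)] <- 100
  })
  lab <- segmentNuclei(noise, voxelSize = rep(1, 3), sigma = 0.5,
                       minSize = 30)
  expect_equal(max(lab@labels), 0L)
})

test_that("well-separated nuclei are each recovered with accurate centroids", {
  centres <- as.matrix(expand.grid(c(10, 25, 40), c(10, 30), c(10, 22)))[1:10, ]
  v <- ballPhantom(centres, radiusVox = 4, dim = c(50, 40, 32))
  lab <- segmentNuclei(v, voxelSize = rep(1, 3), sigma = 1, minSize = 30)
  expect_equal(max(lab@labels), 10L)
  geo <- computeGeometry(lab, v)
  for (i in seq_len(10)) {
    dd <- sqrt(rowSums((as.matrix(geo[, c("x", "y", "z")]) -
                          rep(centres[i, ] - 1, each = 10))^2))
    expect_lt(min(dd), 1)
  }
  # partition: foreground + background voxel counts add up
  expect_equal(sum(geo$voxels) + sum(lab@labels == 0L), length(v))
})

test_that("a touching pair is split into two segments by erosion", {
  r <- 5.5
  centres <- rbind(c(16, 16, 16), c(16 + 1.8 * r, 16, 16))
  v <- ballPhantom(centres, radiusVox = r, dim = c(42, 32, 32))
  # confirm the phantom is one connected component before splitting
  mask <- array(as.integer(v > 100), dim(v))
  cc <- spimscreen:::cpp_label3d(mask, dim(v), 26L)
  expect_equal(max(cc), 1L)
  lab <- segmentNuclei(v, voxelSize = rep(0.7, 3), sigma = 0.7, minSize = 30)
  expect_equal(max(lab@labels), 2L)
  geo <- computeGeometry(lab, v)
  expect_equal(geo$voxels[1], geo$voxels[2], tolerance = 0.15)
})

test_that("geometry arithmetic is exact on a digital cube", {
  lab <- array(0L, c(12, 12, 12))
  lab[4:8, 4:8, 4:8] <- 1L
  lv <- new("LabelVolume", labels = lab, voxelSize = rep(0.5, 3))
  v <- array(2, c(12, 12, 12))
  geo <- computeGeometry(lv, v)
  expect_equal(geo$volume, 125 * 0.5^3)  # 15.625 um^3
  expect_equal(geo$x, 5 * 0.5)  # symmetric centroid at the cube centre
  expect_equal(geo$meanIntensity, 2)
})

test_that("total intensity is invariant to label renumbering", {
  withr::with_seed(10, v <- array(runif(16^3, 0, 100), rep(16, 3)))
  lab <- array(0L, rep(16, 3))
  lab[2:6, 2:6, 2:6] <- 1L
  lab[10:14, 10:14, 10:14] <- 2L
  lv <- new("LabelVolume", labels = lab, voxelSize = rep(1, 3))
  g1 <- computeGeometry(lv, v)
  relab <- array(0L, rep(16, 3))
  relab[lab == 1L] <- 2L
  relab[lab == 2L] <- 1L
  g2 <- computeGeometry(new("LabelVolume", labels = relab,
                            voxelSize = rep(1, 3)), v)
  expect_equal(sort(g1$totalIntensity), sort(g2$totalIntensity))
})

test_that("segmentation recall and precision reach 0.95 on the default spheroid", {
  opt <- deskOptics()
  sc <- simulateTimelapse(SceneParams(nInitialCells = 40L, nFrames = 1L,
                                      seed = 3L))
  bc <- renderBeadCalibration(12, opt, seed = 5L,
                              transform = trueViewTransform(sc, opt))
  calib <- calibrateFromBeads(bc$frames[[1]], opt)
  v <- renderDualView(sc, opt, 1, seed = 2L)
  pf <- processFrame(v, calib, bundle = NULL, nIter = 4L)
  geo <- pf$records
  tr <- sc@nuclei[sc@nuclei$frame == 1, ]
  off <- attr(v, "originOffset")
  tp <- cbind(tr$x + off[1], tr$y + off[2], tr$z + off[3])
  used <- logical(nrow(geo))
  matched <- 0L
  for (i in seq_len(nrow(tp))) {
    dd <- sqrt(rowSums((as.matrix(geo[, c("x", "y", "z")]) -
                          rep(tp[i, ], each = nrow(geo)))^2))
    dd[used] <- Inf
    j <- which.min(dd)
    if (dd[j] < tr$radius[i]) {
      matched <- matched + 1L
      used[j] <- TRUE
    }
  }
  expect_gte(matched / nrow(tp), 0.95)   # recall
  expect_gte(matched / nrow(geo), 0.95)  # precision
})
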