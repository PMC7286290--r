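# resampling, joint Richardson-Lucy fusion, drift correction

deltaPSF <- function(view = "A") {
  k <- array(0, c(3, 3, 3)); k[2, 2, 2] <- 1
  new("PSFModel", kernel = k, voxelSize = 1, view = view)
}

test_that("identity resampling returns the input", {
  withr::with_seed(5, v <- VolumeStack(array(runif(24 * 20 * 16), c(24, 20, 16)),
                                       rep(1, 3)))
  out <- resampleToReference(v, affineTransform3D())
  expect_equal(out@data, v@data, tolerance = 1e-12)
})

test_that("integer-voxel translation is an exact shift in the interior", {
  withr::with_seed(6, v <- VolumeStack(array(runif(20^3), rep(20, 3)), rep(1, 3)))
  tf <- affineTransform3D(diag(3), c(3, 0, 0))  # B->A shift +3 um = 3 voxels
  out <- resampleToReference(v, tf)
  # output voxel i reads input at i - 3
  expect_equal(out@data[5:20, , ], v@data[2:17, , ], tolerance = 1e-12)
  expect_error(resampleToReference(v, affineTransform3D(matrix(0, 3, 3) + diag(3) * 0)),
               "invertible")
})

test_that("rotating 90 degrees and back recovers the volume", {
  d <- c(30, 30, 30)
  withr::with_seed(7, {
    v0 <- gaussBlob(d, c(15, 14, 16), c(3, 4, 5), amp = 100) +
      gaussBlob(d, c(20, 20, 12), c(4, 2, 3), amp = 70)
  })
  st <- VolumeStack(v0, rep(1, 3))
  ctr <- (d - 1) / 2
  R <- rot90Y()
  tf <- affineTransform3D(R, ctr - as.vector(R %*% ctr))
  fwd <- resampleToReference(st, tf)
  back <- resampleToReference(fwd, invertTransform(tf))
  m <- attr(back, "validMask") == 1
  err <- mean(abs(back@data[m] - v0[m]))
  expect_lt(err, 0.02 * diff(range(v0)))
})

test_that("joint RL with delta PSFs is a fixed point and nIter 0 returns the mean", {
  withr::with_seed(8, x <- array(runif(16^3, 1, 10), rep(16, 3)))
  va <- VolumeStack(x, rep(1, 3))
  vb <- VolumeStack(x, rep(1, 3))
  f0 <- jointDeconvolve(va, vb, deltaPSF("A"), deltaPSF("B"), nIter = 0L)
  expect_equal(f0@data, x, tolerance = 1e-12)
  f5 <- jointDeconvolve(va, vb, deltaPSF("A"), deltaPSF("B"), nIter = 5L)
  expect_equal(f5@data, x, tolerance = 1e-6)
  vb2 <- VolumeStack(x * 3, rep(1, 3))
  finit <- jointDeconvolve(va, vb2, deltaPSF("A"), deltaPSF("B"), nIter = 0L)
  expect_equal(finit@data, 2 * x, tolerance = 1e-12)
  expect_error(jointDeconvolve(va, VolumeStack(x[1:8, , ], rep(1, 3)),
                               deltaPSF(), deltaPSF()), "grid")
})

test_that("fusion improves FWHM isotropy over either single view", {
  d <- c(40, 40, 40)
  ctr <- c(20, 20, 20)
  # the same point imaged with complementary anisotropy
  va <- VolumeStack(gaussBlob(d, ctr, c(1, 1, 3), amp = 500) + 2, rep(1, 3))
  vb <- VolumeStack(gaussBlob(d, ctr, c(3, 1, 1), amp = 500) + 2, rep(1, 3))
  gk <- function(sig) {
    g <- gaussBlob(c(17, 17, 17), c(9, 9, 9), sig, amp = 1)
    g / sum(g)
  }
  psfA <- new("PSFModel", kernel = gk(c(1, 1, 3)), voxelSize = 1, view = "A")
  psfB <- new("PSFModel", kernel = gk(c(3, 1, 1)), voxelSize = 1, view = "B")
  fused <- jointDeconvolve(va, vb, psfA, psfB, nIter = 20L)
  ratio <- function(v) {
    fw <- measureFWHM(v, voxelSize = rep(1, 3), center = ctr)
    max(fw[c("x", "z")]) / min(fw[c("x", "z")])
  }
  expect_lt(ratio(fused@data), ratio(va@data))
  expect_lt(ratio(fused@data), ratio(vb@data))
  # per-view Poisson data fit is non-increasing across iterations
  expect_true(all(diff(fused@dataFit[, "A"]) <= 1e-6 * abs(fused@dataFit[1, "A"])))
  expect_true(all(diff(fused@dataFit[, "B"]) <= 1e-6 * abs(fused@dataFit[1, "B"])))
  # nonnegativity and photometric sanity in the doubly-valid region
  expect_true(all(fused@data >= 0))
  expect_equal(sum(fused@data), mean(c(sum(va@data), sum(vb@data))),
               tolerance = 0.1)
})

test_that("drift correction restores stationary beads and commutes with scaling", {
  opt <- deskOptics(gridDim = c(48L, 48L, 32L))
  drift <- c(0.9, -0.6, 0.45)
  bc <- renderBeadCalibration(4, opt, drift = drift, nFrames = 4L, seed = 61L)
  vols <- lapply(bc$frames, `[[`, "viewA")
  det <- lapply(vols, detectBeads)
  ds <- trackDrift(det)
  corr <- applyDriftCorrection(vols, ds)
  d0 <- detectBeads(corr[[1]])
  d3 <- detectBeads(corr[[4]])
  expect_equal(nrow(d3), nrow(d0))
  for (i in seq_len(nrow(d0))) {
    dd <- sqrt(rowSums((as.matrix(d3[, 1:3]) -
                          rep(unlist(d0[i, 1:3]), each = nrow(d3)))^2))
    expect_lt(min(dd) / opt@voxelSizeXY, 0.3)
  }
  # zero drift is the identity
  zero <- new("DriftSeries", offsets = matrix(0, 4, 3), nBeadsUsed = rep(4L, 4))
  same <- applyDriftCorrection(vols, zero)
  expect_identical(same[[2]]@data, vols[[2]]@data)
  # commutes with intensity scaling
  scaled <- lapply(vols, function(v) VolumeStack(v@data * 2.5, v@voxelSize))
  cs <- applyDriftCorrection(scaled, ds)
  expect_equal(cs[[4]]@data, corr[[4]]@data * 2.5, tolerance = 1e-9)
  expect_error(applyDriftCorrection(vols,
                                    new("DriftSeries", offsets = matrix(0, 2, 3),
                                        nBeadsUsed = c(1L, 1L))), "cover")
})
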