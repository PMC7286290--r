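# bead detection, affine registration, PSF extraction, drift tracking

test_that("a blank stack yields no detections", {
  v <- VolumeStack(array(10, c(20, 20, 12)), rep(1, 3))
  expect_equal(nrow(detectBeads(v)), 0L)
})

test_that("rendered beads are all detected within 0.3 voxel of truth", {
  opt <- deskOptics()
  for (noise in c(FALSE, TRUE)) {
    bc <- renderBeadCalibration(5, opt, seed = 21L, applyNoise = noise)
    det <- detectBeads(bc$frames[[1]]$viewA)
    expect_equal(nrow(det), 5L)
    tr <- bc$positions[[1]]
    for (i in seq_len(nrow(det))) {
      dd <- sqrt(rowSums((tr - rep(unlist(det[i, 1:3]), each = 5))^2))
      expect_lt(min(dd) / opt@voxelSizeXY, 0.3)
    }
  }
})

test_that("candidates closer than the separation keep only the brighter", {
  v <- gaussBlob(c(40, 40, 20), c(18, 20, 10), c(1.2, 1.2, 1.2), amp = 100) +
    gaussBlob(c(40, 40, 20), c(24, 20, 10), c(1.2, 1.2, 1.2), amp = 60)
  st <- VolumeStack(v + 1, rep(1, 3))
  det <- detectBeads(st, minSeparation = 10, snrThreshold = 3)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 17), 1.5)  # the brighter one (0-based coordinate)
  det2 <- detectBeads(st, minSeparation = 3, snrThreshold = 3)
  expect_equal(nrow(det2), 2L)
})

test_that("identical bead sets register to the identity", {
  withr::with_seed(1, {
    p <- matrix(runif(24, 5, 50), ncol = 3)
  })
  tf <- estimateRegistration(beadTable(p), beadTable(p),
                             init = affineTransform3D())
  expect_equal(tf@linear, diag(3), tolerance = 1e-9)
  expect_equal(tf@translation, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(tf@residualRMS, 1e-9)
})

test_that("a known rotation + translation is recovered exactly from points", {
  withr::with_seed(2, {
    pA <- matrix(runif(24, 5, 60), ncol = 3)
  })
  R <- rot90Y()
  tr <- c(3.2, -1.1, 2.5)
  # pA = R pB + t  =>  pB = R^-1 (pA - t)
  pB <- t(solve(R) %*% (t(pA) - tr))
  tf <- estimateRegistration(beadTable(pA), beadTable(pB),
                             init = affineTransform3D(R, tr + 0.5))
  expect_equal(tf@linear, R, tolerance = 1e-6)
  expect_equal(tf@translation, tr, tolerance = 1e-6)
  expect_lt(tf@residualRMS, 1e-9)
  expect_equal(tf@nCorrespondences, 8L)
})

test_that("registration recovery from rendered noiseless beads is <= 0.05 um", {
  opt <- deskOptics()
  bc <- renderBeadCalibration(10, opt, seed = 31L, applyNoise = FALSE)
  calib <- estimateRegistration(detectBeads(bc$frames[[1]]$viewA),
                                detectBeads(bc$frames[[1]]$viewB),
                                fov = spimscreen:::.fovA(opt))
  expect_lt(max(abs(calib@translation - bc$transform@translation)), 0.05)
  # linear-part error expressed as displacement across the field of view
  lerr <- max(abs((calib@linear - bc$transform@linear) %*%
                    spimscreen:::.fovA(opt)))
  expect_lt(lerr, 0.05)
})

test_that("0.1 um bead noise keeps residual <= 0.2 um, translation error <= 0.05 um", {
  R <- rot90Y()
  tr <- c(2.0, -0.7, 1.3)
  resids <- terrs <- numeric(5)
  for (s in 1:5) {
    withr::with_seed(100 + s, {
      pA <- matrix(runif(36, 5, 70), ncol = 3)
      pB <- t(solve(R) %*% (t(pA) - tr)) + matrix(rnorm(36, 0, 0.1 / sqrt(3)),
                                                  ncol = 3)
    })
    tf <- estimateRegistration(beadTable(pA), beadTable(pB),
                               init = affineTransform3D(R, tr))
    resids[s] <- tf@residualRMS
    # translation accuracy where the transform is conditioned: the
    # prediction error at the bead-cloud centroid (the raw intercept of an
    # affine fit trades off against linear-part noise over a ~70 um lever)
    ctr <- colMeans(pB)
    terrs[s] <- sqrt(sum((as.numeric(applyTransform(tf, ctr)) -
                            as.numeric(R %*% ctr + tr))^2))
  }
  expect_lt(mean(resids), 0.2)
  expect_lt(mean(terrs), 0.05)
})

test_that("degenerate bead configurations are rejected", {
  withr::with_seed(3, {
    p <- matrix(runif(9, 0, 40), ncol = 3)
  })
  expect_error(estimateRegistration(beadTable(p), beadTable(p),
                                    init = affineTransform3D()),
               "at least 4")
  flat <- cbind(matrix(runif(10, 0, 40), ncol = 2), 7)[, c(1, 2, 2)]
  flat[, 3] <- 7  # coplanar in z
  expect_error(estimateRegistration(beadTable(flat), beadTable(flat),
                                    init = affineTransform3D()),
               "coplanar")
})

test_that("PSF extraction recovers kernel width, normalization and isolation", {
  d <- c(31, 31, 31)
  sig <- c(1, 1, 2.5)
  ctr <- c(16, 16, 16)
  v <- gaussBlob(d, ctr, sig, amp = 500) + 10
  st <- VolumeStack(v, rep(1, 3))
  beads <- beadTable(matrix(ctr - 1, 1))  # 0-based um at voxel 1 um
  psf <- extractPSF(st, beads, radius = 9)
  expect_equal(sum(psf@kernel), 1, tolerance = 1e-6)
  fw <- measureFWHM(psf@kernel, voxelSize = rep(1, 3))
  expect_equal(unname(fw["x"]), 2.355 * sig[1], tolerance = 0.1)
  expect_equal(unname(fw["z"]), 2.355 * sig[3], tolerance = 0.1)
  # intensity-scale invariance
  psf2 <- extractPSF(VolumeStack(v * 7, rep(1, 3)), beads, radius = 9)
  expect_equal(psf@kernel, psf2@kernel, tolerance = 1e-8)
  # two beads within 2*radius only -> no isolated bead
  two <- beadTable(rbind(ctr - 1, ctr - 1 + c(6, 0, 0)))
  expect_error(extractPSF(st, two, radius = 9), "isolated")
})

test_that("drift tracking is exact for static and linear motion and robust to outliers", {
  withr::with_seed(4, {
    base <- matrix(runif(15, 10, 60), ncol = 3)
  })
  static <- lapply(1:6, function(f) beadTable(base))
  ds <- trackDrift(static)
  expect_equal(ds@offsets, matrix(0, 6, 3))
  lin <- lapply(1:10, function(f) {
    beadTable(sweep(base, 2, (f - 1) * c(0.2, 0, 0), "+"))
  })
  dl <- trackDrift(lin)
  expect_equal(dl@offsets[10, ], c(1.8, 0, 0), tolerance = 0.05)
  # one runaway bead among five leaves the median untouched
  out <- lapply(1:6, function(f) {
    p <- base
    p[1, ] <- p[1, ] + (f - 1) * c(0.9, 0.9, 0)
    beadTable(p)
  })
  do <- trackDrift(out, gate = 10)
  expect_equal(do@offsets[6, ], c(0, 0, 0), tolerance = 1e-9)
  expect_error(trackDrift(list()), "empty")
})

test_that("the reported residual matches the realized bead alignment", {
  opt <- deskOptics()
  bc <- renderBeadCalibration(9, opt, seed = 41L)
  bA <- detectBeads(bc$frames[[1]]$viewA)
  bB <- detectBeads(bc$frames[[1]]$viewB)
  tf <- estimateRegistration(bA, bB, fov = spimscreen:::.fovA(opt))
  pBt <- applyTransform(tf, as.matrix(bB[, 1:3]))
  dmin <- vapply(seq_len(nrow(pBt)), function(i) {
    min(sqrt(rowSums((as.matrix(bA[, 1:3]) -
                        rep(pBt[i, ], each = nrow(bA)))^2)))
  }, numeric(1))
  expect_equal(sqrt(mean(dmin^2)), tf@residualRMS, tolerance = 1e-9)
})

test_that("the bead-spot calibration transfers to sample ground truth", {
  opt <- deskOptics()
  sc <- simulateTimelapse(SceneParams(nInitialCells = 6L, nFrames = 1L,
                                      seed = 11L))
  trueT <- trueViewTransform(sc, opt)
  bc <- renderBeadCalibration(10, opt, seed = 51L, transform = trueT)
  calib <- estimateRegistration(detectBeads(bc$frames[[1]]$viewA),
                                detectBeads(bc$frames[[1]]$viewB),
                                fov = spimscreen:::.fovA(opt))
  # nuclei rendered in view B map back onto their view-A positions
  off <- spimscreen:::.fovA(opt) / 2
  pWorld <- as.matrix(sc@nuclei[, c("x", "y", "z")]) + rep(off, each = 6)
  pB <- applyTransform(invertTransform(trueT), pWorld)
  pBack <- applyTransform(calib, pB)
  err <- sqrt(rowSums((pBack - pWorld)^2))
  expect_lt(max(err), max(2 * calib@residualRMS, 0.05))
})
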