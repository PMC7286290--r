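# plate layout, acquisition accounting, pre-screen selection

test_that("the default plate layout matches the screen geometry", {
  g <- generateSpotGrid()
  expect_equal(nrow(g@centers), 320L)
  expect_equal(length(unique(g@sampleMap)), 40L)
  expect_true(all(table(g@sampleMap) == 8L))
  # replicate spots form a contiguous 2 x 4 subarray
  first <- g@centers[g@sampleMap == 1L, ]
  expect_equal(sort(unique(first[, 1])), c(0, 2.25))
  expect_equal(sort(unique(first[, 2])), c(0, 2.25, 4.5, 6.75))
  expect_equal(nrow(generateSpotGrid(1, 1, 1)@centers), 1L)
  expect_error(generateSpotGrid(5, 5, 8), "divide")
})

test_that("acquisition accounting is exact arithmetic", {
  pre <- planAcquisition(nPositions = 40, nSlices = 1200, nViews = 2)
  expect_identical(pre@imagesPerPass, 96000)
  hi <- planAcquisition(nPositions = 1, nSlices = 260, nViews = 2,
                        imageWidth = 1024, imageHeight = 1024,
                        bytesPerPixel = 2)
  expect_identical(hi@bytesPerPositionTimepoint, 2 * 1024^2 * 260 * 2)
  expect_equal(hi@bytesPerPositionTimepoint / 1e9, 1.09, tolerance = 0.01)
  one <- planAcquisition(1, 1, 1, 10, 10, 2)
  expect_identical(one@imagesPerPass, 1)
  expect_error(planAcquisition(0, 10, 2))
})

test_that("acquisition plans serialize losslessly", {
  plan <- planAcquisition(40, 1200, 2, nTimepoints = 290)
  f <- tempfile(fileext = ".json")
  slots <- slotNames(plan)
  jsonlite::write_json(setNames(lapply(slots, function(s) slot(plan, s)),
                                slots), f, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  for (s in slots) expect_identical(as.numeric(back[[s]]), slot(plan, s))
})

test_that("transforms serialize losslessly", {
  tf <- affineTransform3D(rot90Y() * 1.01, c(1.25, -0.375, 2.5),
                          residualRMS = 0.125, nCorrespondences = 9L)
  f <- tempfile(fileext = ".json")
  writeTransformJSON(tf, f)
  back <- readTransformJSON(f)
  expect_identical(back@linear, tf@linear)
  expect_identical(back@translation, tf@translation)
  expect_identical(back@residualRMS, tf@residualRMS)
})

test_that("pre-screen selection excludes by rule and ranks by depth", {
  cand <- data.frame(
    x = 1:5, y = 1, z = c(10, 50, 30, 40, 20),
    size = c(5e4, 6e4, 1e3, 7e4, 8e4),
    axis1 = c(20, 22, 18, 80, 21), axis2 = c(18, 20, 15, 30, 20),
    axis3 = c(16, 18, 12, 20, 7),
    spot = 1L)
  cand$aspect <- cand$axis1 / cand$axis3
  cand$flatness <- cand$axis2 / cand$axis3
  sel <- selectSpheroids(cand, minSize = 2e4, maxAspect = 2.5,
                         maxFlatness = 3, nSelect = 1L)
  # candidate 3 too small, 4 too elongated (aspect 4), 5 too flat;
  # of the survivors (z = 10, 50) the deepest wins
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$z, 50)
  # a lone round large candidate is selected
  lone <- cand[1, ]
  expect_equal(nrow(selectSpheroids(lone)), 1L)
  # no survivor -> reported unselectable
  none <- cand[3, ]
  out <- selectSpheroids(none)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "unselectable"), 1L)
  # never returns an excluded candidate
  sel2 <- selectSpheroids(cand, nSelect = 5L)
  expect_true(all(sel2$size >= 2e4 & sel2$aspect <= 2.5 & sel2$flatness <= 3))
})

test_that("pre-screen cluster detection summarizes simple blobs", {
  v <- ballPhantom(rbind(c(12, 12, 10), c(34, 30, 22)), radiusVox = 5,
                   dim = c(46, 40, 30))
  st <- VolumeStack(v, rep(2, 3))
  cand <- detectPrescreenClusters(st, sigma = 2, minVoxels = 27L)
  expect_equal(nrow(cand), 2L)
  expect_true(all(abs(cand$aspect - 1) < 0.3))
  expect_equal(sort(cand$z), sort(c(9, 21) * 2), tolerance = 0.05)
})
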