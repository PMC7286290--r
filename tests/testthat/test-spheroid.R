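# spheroid assembly: clustering, tracking, speeds, transitions, growth, shape

test_that("spatial clustering matches a brute-force single-linkage oracle", {
  # two groups far apart
  g1 <- matrix(rnorm(15, 0, 2), ncol = 3)
  g2 <- matrix(rnorm(15, 0, 2), ncol = 3) + 80
  rec <- data.frame(timepoint = 1L, x = c(g1[, 1], g2[, 1]),
                    y = c(g1[, 2], g2[, 2]), z = c(g1[, 3], g2[, 3]))
  cl <- clusterIntoSpheroids(rec, cutoff = 25)
  expect_equal(length(unique(cl)), 2L)
  # a single nucleus is one spheroid
  one <- data.frame(timepoint = 1L, x = 0, y = 0, z = 0)
  expect_equal(clusterIntoSpheroids(one), 1L)
  # a chain spaced at 0.9 * cutoff stays one spheroid under single linkage
  chain <- data.frame(timepoint = 1L, x = (0:8) * 0.9 * 25, y = 0, z = 0)
  expect_equal(length(unique(clusterIntoSpheroids(chain, cutoff = 25))), 1L)
  # random configurations against the union-find oracle
  withr::with_seed(18, {
    for (rep in 1:5) {
      p <- matrix(runif(45, 0, 60), ncol = 3)
      rec <- data.frame(timepoint = 1L, x = p[, 1], y = p[, 2], z = p[, 3])
      ours <- clusterIntoSpheroids(rec, cutoff = 18)
      oracle <- bruteSingleLinkage(p, 18)
      expect_equal(length(unique(ours)), length(unique(oracle)))
      # same partition up to relabelling
      expect_true(all(table(ours, oracle) %in%
                        c(0, table(oracle)[unique(oracle)])))
    }
  })
})

test_that("spheroid identities stay stable across frames", {
  rec <- do.call(rbind, lapply(1:5, function(f) {
    data.frame(timepoint = f,
               x = c(0, 3, 100, 103) + f * 0.5, y = 0, z = 0)
  }))
  cl <- clusterIntoSpheroids(rec, cutoff = 25)
  m <- matrix(cl, ncol = 5)
  expect_true(all(m[1, ] == m[1, 1]))
  expect_true(all(m[3, ] == m[3, 1]))
  expect_true(m[1, 1] != m[3, 1])
})

test_that("static and moving nuclei are tracked with recovered speeds", {
  withr::with_seed(19, base <- matrix(runif(18, 0, 50), ncol = 3))
  static <- do.call(rbind, lapply(1:6, function(f) {
    data.frame(timepoint = f, id = 1:6, x = base[, 1], y = base[, 2],
               z = base[, 3], spheroid = 1L)
  }))
  tr <- trackNuclei(static, maxGate = 10)
  expect_equal(length(unique(tr$track)), 6L)
  expect_true(all(tr$step[!is.na(tr$step)] == 0))
  sp <- migrationSpeed(tr, frameInterval = 5)
  expect_equal(sp$medianSpeed, 0)
  # constant velocity at half the gate
  vel <- c(4, 2, 1)  # |v| ~ 4.6 um/frame < 0.5 * 10
  moving <- do.call(rbind, lapply(1:8, function(f) {
    data.frame(timepoint = f, id = 1:6, x = base[, 1] + f * vel[1],
               y = base[, 2] + f * vel[2], z = base[, 3] + f * vel[3],
               spheroid = 1L)
  }))
  trm <- trackNuclei(moving, maxGate = 10)
  expect_equal(length(unique(trm$track)), 6L)
  spm <- migrationSpeed(trm, frameInterval = 5)
  expect_equal(spm$medianSpeed, sqrt(sum(vel^2)) / 5, tolerance = 0.05)
  # all moving 1 um per 5-min frame -> 0.2 um/min
  unit <- do.call(rbind, lapply(1:4, function(f) {
    data.frame(timepoint = f, id = 1:3, x = c(0, 20, 40) + f, y = 0, z = 0,
               spheroid = 1L)
  }))
  expect_equal(migrationSpeed(trackNuclei(unit), 5)$medianSpeed, 0.2)
})

test_that("a division links both children to the parent track", {
  rec <- rbind(
    data.frame(timepoint = 1L, id = 1L, x = 10, y = 10, z = 10),
    data.frame(timepoint = 2L, id = 1L, x = 10, y = 10, z = 10),
    data.frame(timepoint = 3L, id = 2L, x = 7, y = 10, z = 10),
    data.frame(timepoint = 3L, id = 3L, x = 13, y = 10, z = 10))
  tr <- trackNuclei(rec, maxGate = 10)
  kids <- tr[tr$timepoint == 3L, ]
  parentTrack <- tr$track[tr$timepoint == 1L]
  # the parent track ends at the division; both children open new tracks
  # that record the parent
  expect_true(all(kids$track != parentTrack))
  expect_equal(kids$parentTrack, rep(parentTrack, 2))
  expect_equal(length(unique(kids$track)), 2L)
})

test_that("radial distances follow geometry and translation invariance", {
  shell <- data.frame(timepoint = 1L, spheroid = 1L,
                      x = c(5, -5, 0, 0, 0, 0), y = c(0, 0, 5, -5, 0, 0),
                      z = c(0, 0, 0, 0, 5, -5))
  expect_equal(radialDistances(shell), rep(5, 6))
  ctr <- data.frame(timepoint = 1L, spheroid = 1L, x = 3, y = 4, z = 5)
  expect_equal(radialDistances(ctr), 0)
  moved <- shell
  moved[, c("x", "y", "z")] <- moved[, c("x", "y", "z")] +
    rep(c(11, -7, 3), each = 6)
  expect_equal(radialDistances(moved), radialDistances(shell))
})

test_that("phase fractions are exact proportions", {
  ph <- factor(rep(c("interphase", "prophase", "metaphase", "anaphase"),
                   c(94, 1, 1, 4)),
               levels = c("interphase", "prophase", "metaphase", "anaphase"))
  fr <- phaseFractions(ph)
  expect_equal(unname(fr), c(0.94, 0.01, 0.01, 0.04))
  expect_equal(sum(fr), 1)
  expect_error(phaseFractions(character(0)), "no classified")
})

test_that("transition detection applies the full validity rule table", {
  mkTrack <- function(phases, track = 1L, parent = NA_integer_) {
    data.frame(timepoint = seq_along(phases), id = 1L, track = track,
               parentTrack = parent, phase = phases,
               x = 0, y = 0, z = 0, step = NA_real_)
  }
  full <- detectTransitions(mkTrack(c("interphase", "prophase", "metaphase",
                                      "anaphase", "interphase")))
  expect_equal(nrow(full$events), 4L)
  expect_equal(sum(full$events$improper), 0L)
  # the apoptosis signature: prophase falling back to interphase
  bad <- detectTransitions(mkTrack(c("prophase", "interphase")))
  expect_equal(nrow(bad$events), 1L)
  expect_true(bad$events$improper)
  # single-frame flicker: P, M, P emits an improper M->P
  flick <- detectTransitions(mkTrack(c("prophase", "metaphase", "prophase")))
  expect_equal(nrow(flick$events), 2L)
  expect_equal(flick$events$improper, c(FALSE, TRUE))
  # division exiting anaphase is valid; from metaphase it is not
  div <- rbind(mkTrack(c("metaphase", "anaphase")),
               within(mkTrack("interphase", track = 2L, parent = 1L),
                      timepoint <- 3L))
  dt <- detectTransitions(div)
  expect_equal(sum(dt$events$division), 1L)
  expect_false(dt$events$improper[dt$events$division])
  expect_equal(dt$summary$totalEvents, 2L)
  expect_equal(dt$summary$nTransitioningNuclei, 2L)
})

test_that("lowess growth rate reproduces lines and tracks exponentials", {
  expect_equal(growthRate(rep(7, 20)), rep(0, 19))
  lin <- 3 + 0.8 * (1:30)
  expect_equal(growthRate(lin), rep(0.8, 29), tolerance = 1e-6)
  withr::with_seed(20, {
    t <- 1:60
    expo <- 20 * exp(0.03 * t)
    noisy <- expo + rnorm(60, 0, 1.5)
  })
  gr <- growthRate(noisy)
  trueRate <- diff(expo)
  expect_true(all(gr[5:55] > 0))
  expect_gt(cor(gr, trueRate), 0.9)
  expect_error(growthRate(1:3), "4 timepoints")
  expect_error(growthRate(1:10, f = 0), "f must")
})

test_that("shape descriptors behave on analytic solids", {
  ball <- ballMask(8)
  sh <- shapeDescriptors(ball, rep(1, 3))
  expect_equal(unname(sh["sphericity"]), 1, tolerance = 0.05)
  expect_equal(unname(sh["convexity"]), 1, tolerance = 0.05)
  # two disjoint balls treated as one spheroid are far from convex
  two <- array(0L, c(40, 18, 18))
  b <- ballMask(5, side = 15L)
  two[2:16, 2:16, 2:16] <- b
  two[25:39, 2:16, 2:16] <- b
  sh2 <- shapeDescriptors(two, rep(1, 3))
  expect_lt(sh2[["convexity"]], 0.8)
  # scale invariance: same mask, different voxel size
  shHalf <- shapeDescriptors(ball, rep(0.5, 3))
  expect_equal(sh[c("sphericity", "convexity", "compactness")],
               shHalf[c("sphericity", "convexity", "compactness")],
               tolerance = 1e-9)
  expect_equal(shHalf[["volume"]], sh[["volume"]] / 8)
  expect_error(shapeDescriptors(array(0L, c(4, 4, 4)), rep(1, 3)), "empty")
})

test_that("the convex hull is exact on known polytopes", {
  # unit cube corners plus interior points
  withr::with_seed(21, inner <- matrix(runif(60, 0.1, 0.9), ncol = 3))
  cube <- rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)), inner)
  h <- spimscreen:::cpp_convhull3d(cube)
  expect_equal(h$volume, 1, tolerance = 1e-9)
  expect_equal(h$area, 6, tolerance = 1e-9)
  # a known tetrahedron: volume 1/6, and degenerate input flagged
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ht <- spimscreen:::cpp_convhull3d(tet)
  expect_equal(ht$volume, 1 / 6, tolerance = 1e-9)
  flat <- cbind(matrix(runif(20), ncol = 2), 0.5)
  expect_true(spimscreen:::cpp_convhull3d(flat)$degenerate)
})

test_that("the spheroid time series assembles counts and growth", {
  rec <- do.call(rbind, lapply(1:8, function(f) {
    n <- 3 + f  # one new nucleus per frame
    data.frame(timepoint = f, id = seq_len(n), spheroid = 1L,
               x = runif(n, 0, 20), y = runif(n, 0, 20), z = runif(n, 0, 20))
  }))
  ts <- spheroidTimeSeries(rec)
  expect_equal(ts$nNuclei, 4:11)
  expect_equal(sum(is.na(ts$growthRate)), 1L)  # only the first frame
  expect_true(all(ts$growthRate[-1] > 0))
})
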