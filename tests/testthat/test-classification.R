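# slice extraction, classifiers, summed-likelihood voting

makeBallScene <- function(radiusVox = 6, side = 24L) {
  v <- array(1, rep(side, 3))
  ctr <- rep(side / 2, 3)
  idx <- arrayInd(seq_len(side^3), rep(side, 3))
  d2 <- rowSums(sweep(idx, 2, ctr)^2)
  v[d2 <= radiusVox^2] <- 100
  lab <- array(0L, rep(side, 3))
  lab[d2 <= radiusVox^2] <- 1L
  list(v = v, lab = new("LabelVolume", labels = lab, voxelSize = rep(1, 3)))
}

test_that("every bounding-box plane of a nucleus yields a patch", {
  s <- makeBallScene(radiusVox = 5.2)
  sl <- extractSlices(s$v, s$lab, 1L, patchSize = 32L, planes = "all")
  expect_gte(sum(sl@orientation == "XY"), 10L)  # spans >= 10 Z planes
  expect_true(all(c("XY", "XZ", "YZ") %in% sl@orientation))
  expect_true(all(sl@patches >= 0 & sl@patches <= 1))
  # determinism
  sl2 <- extractSlices(s$v, s$lab, 1L, patchSize = 32L, planes = "all")
  expect_identical(sl@patches, sl2@patches)
  expect_error(extractSlices(s$v, s$lab, 99L), "empty")
})

test_that("central patches of a spherically symmetric nucleus agree across orientations", {
  s <- makeBallScene(radiusVox = 6)
  sl <- extractSlices(s$v, s$lab, 1L, patchSize = 32L, planes = "central")
  expect_equal(dim(sl@patches)[3], 3L)
  xy <- sl@patches[, , sl@orientation == "XY"]
  xz <- sl@patches[, , sl@orientation == "XZ"]
  expect_lt(mean(abs(xy - xz)), 0.05)
})

test_that("summed-likelihood voting follows the documented arithmetic and tie rules", {
  probs <- rbind(c(0.6, 0.4), c(0.6, 0.4), c(0.2, 0.8))
  colnames(probs) <- c("a", "b")
  cl <- classifySegment(probs)
  expect_equal(unname(cl$sums), c(1.4, 1.6))
  expect_equal(cl$phase, "b")
  expect_equal(sum(cl$probabilities), 1)
  # unanimous slices
  un <- rbind(c(0.9, 0.1), c(0.8, 0.2))
  colnames(un) <- c("a", "b")
  expect_equal(classifySegment(un)$phase, "a")
  # exact tie -> first class in declared order
  tie <- rbind(c(0.5, 0.5))
  colnames(tie) <- c("interphase", "anaphase")
  expect_equal(classifySegment(tie)$phase, "interphase")
  # invariant to slice order and duplication
  perm <- classifySegment(probs[c(3, 1, 2), ])
  expect_equal(perm$phase, cl$phase)
  expect_equal(perm$probabilities, cl$probabilities)
  dup <- classifySegment(probs[rep(1:3, 2), ])
  expect_equal(dup$probabilities, cl$probabilities)
  expect_error(classifySegment(probs[0, , drop = FALSE]), "no slice")
})

test_that("the random forest separates separable features and collapses under permuted labels", {
  withr::with_seed(13, {
    n <- 1700L
    f1 <- rbind(matrix(rnorm(n * 3, 0), ncol = 3),
                matrix(rnorm(n * 3, 8), ncol = 3),
                matrix(rnorm(n * 3, -8), ncol = 3),
                matrix(rnorm(n * 3, 16), ncol = 3))
    y <- factor(rep(c("a", "b", "c", "d"), each = n))
  })
  rf <- trainRF(f1, y, seed = 14L)
  expect_equal(rf@metadata$holdoutAccuracy, 1.0)
  pr <- classifyRF(rf, f1[1:8, , drop = FALSE])
  expect_equal(colnames(pr), rf@classOrder)
  expect_equal(unname(rowSums(pr)), rep(1, 8), tolerance = 1e-9)
  withr::with_seed(15, yPerm <- sample(y))
  rfP <- trainRF(f1, yPerm, seed = 14L)
  expect_lt(abs(rfP@metadata$holdoutAccuracy - 0.25), 0.05)
  expect_error(trainRF(f1, factor(rep("a", nrow(f1))), seed = 1L),
               "2 classes")
})

test_that("the CNN separates blank from bright-disc patches perfectly", {
  P <- 32L
  withr::with_seed(16, {
    mkDisc <- function() {
      m <- matrix(runif(P * P, 0, 0.08), P)
      idx <- expand.grid(1:P, 1:P)
      d2 <- (idx[, 1] - P / 2)^2 + (idx[, 2] - P / 2)^2
      m[d2 <= (P / 4)^2] <- runif(sum(d2 <= (P / 4)^2), 0.7, 1)
      m
    }
    mkBlank <- function() matrix(runif(P * P, 0, 0.15), P)
    sets <- c(lapply(1:40, function(i) {
      arr <- array(c(mkDisc(), mkDisc(), mkDisc()), c(P, P, 3))
      new("SliceSet", patches = arr, orientation = c("XY", "XZ", "YZ"),
          sliceIndex = 1:3, nucleusId = i)
    }), lapply(41:80, function(i) {
      arr <- array(c(mkBlank(), mkBlank(), mkBlank()), c(P, P, 3))
      new("SliceSet", patches = arr, orientation = c("XY", "XZ", "YZ"),
          sliceIndex = 1:3, nucleusId = i)
    }))
    y <- factor(rep(c("disc", "blank"), each = 40))
  })
  cnn <- trainCNN(sets, y, seed = 17L, epochs = 4L, batch = 32L)
  expect_equal(cnn@metadata$holdoutAccuracy, 1.0)
  # deterministic under a fixed seed (single-threaded execution)
  cnn2 <- trainCNN(sets, y, seed = 17L, epochs = 4L, batch = 32L)
  expect_identical(cnn@model$weights, cnn2@model$weights)
  # errors: single class; inconsistent patch sizes
  expect_error(trainCNN(sets[1:4], factor(rep("disc", 4)), seed = 1L),
               "2 classes")
  bad <- c(sets[1:4], fakeSliceSet(16L, c(0.2, 0.4, 0.6)))
  expect_error(trainCNN(bad, factor(c("a", "a", "b", "b", "a")), seed = 1L),
               "patch sizes")
})
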