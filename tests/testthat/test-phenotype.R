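# feature matrix scaling, rank-based clustering, enrichment flags

test_that("assembled matrices are centred, scaled, and prune bad columns", {
  withr::with_seed(22, m <- matrix(rnorm(60, 10, 4), 10,
                                   dimnames = list(NULL, paste0("f", 1:6))))
  pm <- assembleAndScale(m)
  expect_equal(colMeans(pm@values), rep(0, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(pm@values, 2, sd), rep(1, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  # scaling is idempotent
  pm2 <- assembleAndScale(pm@values)
  expect_equal(pm2@values, pm@values, tolerance = 1e-9)
  # constant column dropped with a warning
  m2 <- cbind(m, constant = 5)
  expect_warning(pmc <- assembleAndScale(m2), "constant")
  expect_false("constant" %in% colnames(pmc@values))
  expect_true("constant" %in% pmc@excluded$feature)
  # per-plate exclusions leave NA and are recorded
  excl <- data.frame(sample = 1, feature = "f1", reason = "plate drift")
  pme <- assembleAndScale(m, exclusions = excl)
  expect_true(is.na(pme@values[1, "f1"]))
  expect_equal(pme@excluded$reason, "plate drift")
  expect_error(assembleAndScale(m[1, , drop = FALSE]), ">= 2 samples")
})

test_that("rank clustering recovers planted groups under monotone distortion", {
  withr::with_seed(23, {
    a <- matrix(rnorm(40, 3, 0.5), 8)
    b <- matrix(rnorm(40, -3, 0.5), 8)
  })
  raw <- rbind(a, b)
  colnames(raw) <- paste0("f", 1:5)
  truth <- rep(1:2, each = 8)
  # strictly monotone per-feature distortions must not change the result
  distorted <- raw
  distorted[, 1] <- exp(raw[, 1])
  distorted[, 2] <- raw[, 2]^3
  distorted[, 3] <- atan(raw[, 3])
  r1 <- rankCluster(assembleAndScale(raw), nClusters = 2)
  r2 <- rankCluster(assembleAndScale(distorted), nClusters = 2)
  expect_equal(r1$assignment, r2$assignment)
  expect_equal(length(unique(paste(r1$assignment, truth))), 2L)
  expect_match(r1$newick, "^\\(")
})

test_that("degenerate clustering cases behave", {
  m <- matrix(rnorm(30), 10)
  m[2, ] <- m[1, ]  # identical rows merge at height 0
  r <- rankCluster(m, nClusters = 3)
  expect_equal(min(r$tree$height), 0)
  rs <- rankCluster(m, nClusters = 10)
  expect_equal(length(unique(rs$assignment)), 10L)
  expect_error(rankCluster(m, nClusters = 11), "more clusters")
})

test_that("cluster assignment is deterministic", {
  withr::with_seed(24, m <- matrix(rnorm(80), 16))
  expect_identical(rankCluster(m, 4)$assignment, rankCluster(m, 4)$assignment)
})

test_that("enrichment flags apply the fold-change rule and its edge case", {
  cond <- rbind(hit = c(a = 0.10, b = 0.06, c = 0.02),
                mild = c(a = 0.06, b = 0.05, c = 0))
  ctl <- c(a = 0.05, b = 0.05, c = 0)
  fl <- enrichmentFlags(cond, ctl)
  expect_equal(fl["hit", "a"], "enriched")    # 2.0 > 1.5
  expect_equal(fl["mild", "a"], "none")       # 1.2
  expect_equal(fl["hit", "b"], "none")        # 1.2
  expect_equal(fl["hit", "c"], "control-zero")
  expect_equal(fl["mild", "c"], "none")
  expect_equal(attr(fl, "fold")["hit", "a"], 2.0)
})
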