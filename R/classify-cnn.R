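#' @include classify-rf.R
NULL

# He-normal initialization of the fixed CNN topology
.cnnInit <- function(nClasses, patchSize) {
  if (patchSize %% 8L != 0L) stop("patchSize must be divisible by 8")
  he <- function(rows, cols) {
    matrix(rnorm(rows * cols, 0, sqrt(2 / cols)), rows, cols)
  }
  f <- 64L * (patchSize / 8L)^2
  list(W1 = he(16L, 9L), b1 = numeric(16L),
       W2 = he(32L, 144L), b2 = numeric(32L),
       W3 = he(64L, 288L), b3 = numeric(64L),
       W4 = he(128L, f), b4 = numeric(128L),
       W5 = he(nClasses, 128L), b5 = numeric(nClasses))
}

# stack a list of SliceSets into one (patch array, per-slice nucleus index)
.stackSlices <- function(sliceSets) {
  sizes <- vapply(sliceSets, function(s) dim(s@patches)[1], integer(1))
  if (length(unique(sizes)) != 1L) stop("inconsistent patch sizes")
  counts <- vapply(sliceSets, function(s) dim(s@patches)[3], integer(1))
  P <- sizes[1]
  X <- array(0, c(P, P, sum(counts)))
  at <- 0L
  for (s in seq_along(sliceSets)) {
    X[, , at + seq_len(counts[s])] <- sliceSets[[s]]@patches
    at <- at + counts[s]
  }
  list(X = X, nucleus = rep(seq_along(sliceSets), counts), patchSize = P)
}

#' Train the VGG-style slice CNN
#'
#' Trains the compact convolutional network (three 3x3 convolution blocks of
#' 16, 32 and 64 channels, each followed by 2x2 max pooling, a 128-unit
#' fully connected layer and a softmax head) on the 2D slices of annotated
#' nuclei. Slices inherit the label of their nucleus. A stratified 10%
#' holdout is split off by nucleus -- never by slice, so no nucleus
#' contributes to both sides -- and the per-slice holdout accuracy is stored
#' in the bundle, along with the per-nucleus summed-likelihood voted
#' holdout accuracy. Light augmentation (the eight axis rotations/flips) is
#' applied during training.
#'
#' Training is deterministic for a fixed seed and thread count.
#'
#' @param sliceSets list of [SliceSet-class] objects, one per annotated
#'   nucleus
#' @param labels factor of phase labels, one per nucleus
#' @param seed RNG seed (initialization, split, shuffling, augmentation)
#' @param epochs training epochs
#' @param batch minibatch size
#' @param lr Adam learning rate
#' @param momentum Adam first-moment decay (beta1)
#' @param augment apply rotation/flip augmentation
#' @param holdout holdout fraction of nuclei
#' @return a [ClassifierBundle-class] of kind "cnn"
#' @export
trainCNN <- function(sliceSets, labels, seed = 1L, epochs = 16L, batch = 128L,
                     lr = 1e-3, momentum = 0.9, augment = TRUE,
                     holdout = 0.1) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("training set must contain at least 2 classes")
  if (length(sliceSets) != length(labels))
    stop("one label per slice set required")
  st <- .stackSlices(sliceSets)
  withr::with_seed(seed, {
    hoNuc <- .stratifiedHoldout(labels, holdout)
    hoSlice <- which(st$nucleus %in% hoNuc)
    trSlice <- setdiff(seq_along(st$nucleus), hoSlice)
    y <- as.integer(labels)[st$nucleus] - 1L
    w <- .cnnInit(nlevels(labels), st$patchSize)
    Xtr <- st$X[, , trSlice, drop = FALSE]
    # step learning-rate schedule: full rate for the first half of the
    # epochs, then /3, then /10 (warm-restarted Adam per stage)
    stages <- c(ceiling(epochs * 0.5), ceiling(epochs * 0.3))
    stages <- c(stages, max(0L, epochs - sum(stages)))
    rates <- lr * c(1, 1 / 3, 1 / 10)
    loss <- numeric(0)
    for (s in seq_along(stages)) {
      if (stages[s] < 1L) next
      fit <- cpp_cnn_train(w, Xtr, dim(Xtr), y[trSlice],
                           as.integer(stages[s]), as.integer(batch),
                           rates[s], momentum, augment)
      w <- fit$weights
      loss <- c(loss, as.numeric(fit$loss))
    }
    fit <- list(weights = w, loss = loss)
    Xho <- st$X[, , hoSlice, drop = FALSE]
    pr <- cpp_cnn_predict(fit$weights, Xho, dim(Xho))
    acc <- mean(max.col(pr, ties.method = "first") == y[hoSlice] + 1L)
    # per-nucleus summed-likelihood vote over the holdout slices: the
    # accuracy of the deployed unit, comparable to the random forest's
    # per-nucleus accuracy
    hoNucOf <- st$nucleus[hoSlice]
    voted <- vapply(unique(hoNucOf), function(nid) {
      probs <- pr[hoNucOf == nid, , drop = FALSE]
      colnames(probs) <- levels(labels)
      classifySegment(probs)$phase == as.character(labels[nid])
    }, logical(1))
    new("ClassifierBundle", kind = "cnn",
        model = list(weights = fit$weights, patchSize = st$patchSize),
        classOrder = levels(labels),
        metadata = list(holdoutAccuracy = acc,
                        votedHoldoutAccuracy = mean(voted),
                        nPerClass = as.list(table(labels)),
                        nHoldoutSlices = length(hoSlice),
                        nHoldoutNuclei = length(unique(hoNucOf)),
                        epochs = epochs, seed = seed,
                        lossLog = as.numeric(fit$loss)))
  })
}

#' Per-slice phase probabilities from the CNN
#'
#' @param bundle a [ClassifierBundle-class] of kind "cnn"
#' @param slices a [SliceSet-class] or a (patchSize, patchSize, n) array
#' @return n x classes probability matrix, columns in the bundle's class
#'   order
#' @export
predictSlices <- function(bundle, slices) {
  stopifnot(bundle@kind == "cnn")
  X <- if (is(slices, "SliceSet")) slices@patches else slices
  if (dim(X)[1] != bundle@model$patchSize)
    stop("patch size does not match the trained network")
  pr <- cpp_cnn_predict(bundle@model$weights, X, dim(X))
  colnames(pr) <- bundle@classOrder
  pr
}
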