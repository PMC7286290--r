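#' @include slices.R
NULL

# stratified holdout split: returns indices of the holdout set
.stratifiedHoldout <- function(labels, fraction) {
  unlist(lapply(split(seq_along(labels), labels), function(ix) {
    n <- max(1L, round(length(ix) * fraction))
    sample(ix, n)
  }), use.names = FALSE)
}

#' Train the random forest phase classifier on Haralick features
#'
#' Fits a random forest (default 200 trees, sqrt(p) candidate features per
#' split, inverse-frequency class weights) on per-nucleus texture feature
#' vectors. A stratified 10% holdout is split off before training and its
#' accuracy stored in the returned bundle.
#'
#' @param features numeric matrix, one row per nucleus (e.g. from
#'   [computeHaralick()])
#' @param labels factor of phase labels, one per row
#' @param seed RNG seed for the split and the forest
#' @param holdout holdout fraction (default 0.1)
#' @param nTrees number of trees
#' @return a [ClassifierBundle-class] of kind "rf"
#' @export
trainRF <- function(features, labels, seed = 1L, holdout = 0.1,
                    nTrees = 200L) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("training set must contain at least 2 classes")
  ok <- stats::complete.cases(features)
  features <- features[ok, , drop = FALSE]
  labels <- labels[ok]
  withr::with_seed(seed, {
    ho <- .stratifiedHoldout(labels, holdout)
    tr <- setdiff(seq_along(labels), ho)
    cw <- 1 / table(labels[tr])
    cw <- cw / sum(cw)
    fit <- randomForest::randomForest(
      x = features[tr, , drop = FALSE], y = labels[tr],
      ntree = nTrees, mtry = max(1L, floor(sqrt(ncol(features)))),
      classwt = as.numeric(cw))
    pred <- predict(fit, features[ho, , drop = FALSE])
    acc <- mean(pred == labels[ho])
    new("ClassifierBundle", kind = "rf", model = fit,
        classOrder = levels(labels),
        metadata = list(holdoutAccuracy = acc,
                        nPerClass = as.list(table(labels[tr])),
                        nHoldout = length(ho), seed = seed))
  })
}

#' Phase probabilities from the random forest
#'
#' @param bundle a [ClassifierBundle-class] of kind "rf"
#' @param features feature matrix with the training columns
#' @return matrix of class probabilities, columns in the bundle's class
#'   order
#' @export
classifyRF <- function(bundle, features) {
  stopifnot(bundle@kind == "rf")
  p <- predict(bundle@model, features, type = "prob")
  p[, bundle@classOrder, drop = FALSE]
}
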