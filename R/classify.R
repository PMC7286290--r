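#' @include classify-cnn.R
NULL

#' Summed-likelihood phase call for one segment
#'
#' Sums the per-slice class probabilities over all slices of a nucleus and
#' selects the class with the highest sum as the nucleus' phase at this
#' time point. Aggregated probabilities are the normalized sums. Exact ties
#' resolve to the earliest class in the declared order (interphase first in
#' the canonical order).
#'
#' Invariant to slice order and to duplicating every slice.
#'
#' @param sliceProbs n x classes matrix of per-slice probabilities (e.g.
#'   from [predictSlices()]); column names define the class order when
#'   \code{classOrder} is missing
#' @param classOrder optional explicit class order
#' @return list with \code{phase} (character), \code{probabilities}
#'   (normalized summed likelihoods) and \code{sums} (raw sums)
#' @export
classifySegment <- function(sliceProbs, classOrder = NULL) {
  sliceProbs <- rbind(sliceProbs)
  if (!nrow(sliceProbs)) stop("no slice probabilities supplied")
  if (is.null(classOrder)) classOrder <- colnames(sliceProbs)
  if (is.null(classOrder)) classOrder <- as.character(seq_len(ncol(sliceProbs)))
  sums <- colSums(sliceProbs)
  names(sums) <- classOrder
  pick <- which.max(sums)  # first maximum: the declared-order tie-break
  list(phase = classOrder[pick],
       probabilities = sums / sum(sums),
       sums = sums)
}

#' Classify every segment of a volume
#'
#' Convenience wrapper: extracts slices for each segment, applies the slice
#' classifier and the summed-likelihood vote.
#'
#' @param bundle a cnn [ClassifierBundle-class]
#' @param volume intensity volume
#' @param labels [LabelVolume-class]
#' @param planes slice selection passed to [extractSlices()]
#' @return data.frame: \code{id}, \code{phase}, one probability column per
#'   class
#' @export
classifyVolume <- function(bundle, volume, labels, planes = "central") {
  K <- max(labels@labels)
  rows <- vector("list", K)
  ns <- volumeNormScale(volume, labels)
  for (L in seq_len(K)) {
    sl <- extractSlices(volume, labels, L, patchSize = bundle@model$patchSize,
                        planes = planes, normScale = ns)
    pr <- predictSlices(bundle, sl)
    cl <- classifySegment(pr, bundle@classOrder)
    rows[[L]] <- data.frame(id = L, phase = cl$phase,
                            t(cl$probabilities), check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  out$phase <- factor(out$phase, levels = bundle@classOrder)
  out
}
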