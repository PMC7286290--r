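#' @include segmentation.R
NULL

# the 13 unique 3D direction vectors at Chebyshev distance 1 (one per
# opposite pair of the 26-neighbourhood)
.GLCM_OFFSETS <- matrix(c(
  1, 0, 0,
  0, 1, 0,
  0, 0, 1,
  1, 1, 0,
  1, -1, 0,
  1, 0, 1,
  1, 0, -1,
  0, 1, 1,
  0, 1, -1,
  1, 1, 1,
  1, -1, 1,
  1, 1, -1,
  1, -1, -1), ncol = 3, byrow = TRUE)

.HARALICK_NAMES <- c("asm", "contrast", "correlation", "variance", "idm",
                     "sumAverage", "sumVariance", "sumEntropy", "entropy",
                     "diffVariance", "diffEntropy", "imc1", "imc2")

# the 13 Haralick statistics of one normalized symmetric GLCM (natural log)
.haralickStats <- function(P) {
  G <- nrow(P)
  i <- row(P)
  j <- col(P)
  px <- rowSums(P)
  mu <- sum(seq_len(G) * px)
  sig2 <- sum((seq_len(G) - mu)^2 * px)
  sig <- sqrt(sig2)
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
  psum <- tapply(as.vector(P), as.vector(i + j), sum)
  pdiff <- tapply(as.vector(P), as.vector(abs(i - j)), sum)
  ks <- as.numeric(names(psum))
  kd <- as.numeric(names(pdiff))
  f1 <- sum(P^2)
  f2 <- sum((i - j)^2 * P)
  f3 <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 0
  f4 <- sum((i - mu)^2 * P)
  f5 <- sum(P / (1 + (i - j)^2))
  f6 <- sum(ks * psum)
  f7 <- sum((ks - f6)^2 * psum)
  f8 <- -sum(xlogx(psum))
  f9 <- -sum(xlogx(P))
  mud <- sum(kd * pdiff)
  f10 <- sum((kd - mud)^2 * pdiff)
  f11 <- -sum(xlogx(pdiff))
  hx <- -sum(xlogx(px))
  pxy <- outer(px, px)
  hxy1 <- -sum(P * ifelse(pxy > 0, log(pxy), 0))
  hxy2 <- -sum(xlogx(pxy))
  f12 <- if (hx > 0) (f9 - hxy1) / hx else 0
  f13 <- sqrt(pmax(1 - exp(-2 * (hxy2 - f9)), 0))
  setNames(c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13),
           .HARALICK_NAMES)
}

# min-max quantization of intensities to 1..G within each segment
.quantizeBySegment <- function(lab, vol, G) {
  q <- array(0L, dim(lab))
  idx <- which(lab > 0L)
  if (!length(idx)) return(q)
  li <- lab[idx]
  vi <- vol[idx]
  lo <- tapply(vi, li, min)
  hi <- tapply(vi, li, max)
  key <- match(li, as.integer(names(lo)))
  rngv <- (hi - lo)[key]
  lov <- lo[key]
  qq <- ifelse(rngv > 0, pmin(floor((vi - lov) / rngv * G) + 1, G), 1L)
  q[idx] <- as.integer(qq)
  q
}

#' Haralick texture features of every segment
#'
#' For each labelled segment, intensities are min-max quantized to
#' \code{nGrayLevels} within the segment, symmetric grey-level co-occurrence
#' matrices are accumulated for each 3D offset (pairs where both voxels
#' belong to the segment), and the 13 classical Haralick statistics (angular
#' second moment, contrast, correlation, variance, inverse difference
#' moment, sum average, sum variance, sum entropy, entropy, difference
#' variance, difference entropy, and the two information measures of
#' correlation) are computed per offset and averaged over offsets.
#'
#' Per-segment quantization makes the features invariant to affine intensity
#' rescaling of a segment. Entropies use the natural logarithm. Segments
#' smaller than 8 voxels get a row of \code{NA}.
#'
#' @param labels a [LabelVolume-class]
#' @param volume the matching intensity volume
#' @param nGrayLevels quantization levels (default 32)
#' @param offsets m x 3 integer matrix of co-occurrence direction vectors;
#'   defaults to the 13 unique unit directions
#' @return numeric matrix, one row per segment id (rownames), 13 named
#'   columns
#' @export
computeHaralick <- function(labels, volume, nGrayLevels = 32L,
                            offsets = .GLCM_OFFSETS) {
  if (is(volume, "VolumeStack")) volume <- volume@data
  lab <- labels@labels
  d <- dim(lab)
  K <- max(lab)
  out <- matrix(NA_real_, K, 13, dimnames = list(seq_len(K), .HARALICK_NAMES))
  if (K == 0L) return(out)
  G <- as.integer(nGrayLevels)
  q <- .quantizeBySegment(lab, volume, G)
  counts <- cpp_glcm_all(as.integer(lab), q, d, offsets, G, K)
  sizes <- tabulate(lab[lab > 0L], nbins = K)
  m <- nrow(offsets)
  for (L in seq_len(K)) {
    if (sizes[L] < 8L) {
      message("segment ", L, " has fewer than 8 voxels; features set to NA")
      next
    }
    acc <- matrix(0, 1, 13)
    used <- 0L
    for (t in seq_len(m)) {
      cm <- counts[, , t, L]
      tot <- sum(cm)
      if (tot == 0) next
      acc <- acc + .haralickStats(cm / tot)
      used <- used + 1L
    }
    if (used > 0L) out[L, ] <- acc / used
  }
  out
}
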