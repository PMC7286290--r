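# shared fixtures and independent oracles

# a digital ball mask in a cubic array
ballMask <- function(radiusVox, side = 2L * ceiling(radiusVox) + 5L,
                     center = rep((side + 1) / 2, 3)) {
  idx <- arrayInd(seq_len(side^3), rep(side, 3))
  d2 <- rowSums((sweep(idx, 2, center))^2)
  array(as.integer(d2 <= radiusVox^2), rep(side, 3))
}

# analytic Gaussian blob volume
gaussBlob <- function(dim, center, sigma, amp = 100) {
  g <- array(0, dim)
  idx <- arrayInd(seq_len(prod(dim)), dim)
  e <- rowSums(sweep(sweep(idx, 2, center), 2, sigma, "/")^2)
  g[] <- amp * exp(-e / 2)
  g
}

# phantom with well-separated solid balls; returns volume and truth centres
ballPhantom <- function(centersVox, radiusVox, dim, intensity = 200,
                        bg = 5) {
  v <- array(bg, dim)
  idx <- arrayInd(seq_len(prod(dim)), dim)
  for (i in seq_len(nrow(centersVox))) {
    d2 <- rowSums(sweep(idx, 2, centersVox[i, ])^2)
    v[d2 <= radiusVox^2] <- intensity
  }
  v
}

# brute-force symmetric GLCM for one offset over a labelled region
bruteGLCM <- function(q, lab, id, offset, G) {
  d <- dim(q)
  P <- matrix(0, G, G)
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2]))
      for (i in seq_len(d[1])) {
        if (lab[i, j, k] != id) next
        ii <- i + offset[1]; jj <- j + offset[2]; kk <- k + offset[3]
        if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
          next
        if (lab[ii, jj, kk] != id) next
        a <- q[i, j, k]; b <- q[ii, jj, kk]
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
  P / max(sum(P), 1)
}

# brute-force single-linkage clustering at a cutoff (union-find)
bruteSingleLinkage <- function(pts, cutoff) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      if (sqrt(sum((pts[i, ] - pts[j, ])^2)) <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# bead detection tables from plain coordinate matrices
beadTable <- function(p) {
  data.frame(x = p[, 1], y = p[, 2], z = p[, 3],
             peak = rep(100, nrow(p)), quality = rep(50, nrow(p)))
}

# the nominal 90-degree rotation about Y used across registration tests
rot90Y <- function() matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, byrow = TRUE)

# tiny slice-set of constant patches, for voting/stacking tests
fakeSliceSet <- function(patchSize, values, id = 1L) {
  n <- length(values)
  arr <- array(rep(values, each = patchSize^2), c(patchSize, patchSize, n))
  ori <- rep(c("XY", "XZ", "YZ"), length.out = n)
  new("SliceSet", patches = arr, orientation = ori,
      sliceIndex = seq_len(n), nucleusId = as.integer(id))
}
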