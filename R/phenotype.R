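#' @include spheroid.R
NULL

#' Assemble, centre and scale the phenotype feature matrix
#'
#' Binds per-sample feature tables into one samples x features matrix,
#' masks features excluded for individual plates (set to \code{NA} and
#' recorded with a reason), drops all-missing and constant columns with a
#' warning, centres every remaining column by its mean and scales by its
#' standard deviation.
#'
#' @param features matrix or data.frame of raw features (rows = samples),
#'   or a list of such tables with identical columns to be row-bound
#' @param exclusions optional data.frame with columns \code{sample} (row
#'   name or index), \code{feature} and \code{reason}: per-plate feature
#'   exclusions applied before scaling
#' @return a [PhenotypeMatrix-class]
#' @export
assembleAndScale <- function(features, exclusions = NULL) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, features)
  m <- as.matrix(features)
  if (nrow(m) < 2L || ncol(m) < 1L) stop("need >= 2 samples and >= 1 feature")
  excluded <- data.frame(feature = character(0), reason = character(0))
  if (!is.null(exclusions)) {
    for (i in seq_len(nrow(exclusions))) {
      smp <- exclusions$sample[i]
      rows <- if (is.character(smp)) which(rownames(m) == smp) else as.integer(smp)
      m[rows, exclusions$feature[i]] <- NA
      excluded <- rbind(excluded,
                        data.frame(feature = exclusions$feature[i],
                                   reason = exclusions$reason[i]))
    }
  }
  allNA <- apply(m, 2, function(v) all(is.na(v)))
  if (any(allNA)) {
    warning("dropping all-missing feature(s): ",
            paste(colnames(m)[allNA], collapse = ", "))
    excluded <- rbind(excluded, data.frame(feature = colnames(m)[allNA],
                                           reason = "all missing"))
    m <- m[, !allNA, drop = FALSE]
  }
  sds <- apply(m, 2, sd, na.rm = TRUE)
  constant <- sds == 0 | is.na(sds)
  if (any(constant)) {
    warning("dropping constant feature(s): ",
            paste(colnames(m)[constant], collapse = ", "))
    excluded <- rbind(excluded, data.frame(feature = colnames(m)[constant],
                                           reason = "constant"))
    m <- m[, !constant, drop = FALSE]
  }
  if (!ncol(m)) stop("no usable features left")
  ctr <- colMeans(m, na.rm = TRUE)
  scl <- apply(m, 2, sd, na.rm = TRUE)
  scaled <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  new("PhenotypeMatrix", values = scaled, center = ctr, scale = scl,
      excluded = excluded)
}

#' Rank-based hierarchical clustering of phenotype profiles
#'
#' Replaces every feature column by its ranks across samples (average ranks
#' on ties), computes Euclidean distances between the rank rows, builds an
#' agglomerative hierarchy and cuts it at \code{nClusters}. Rank
#' transformation makes the result invariant to any strictly monotone
#' per-feature distortion of the raw values. A matrix-global rank mode
#' (ranking all entries jointly) is available behind \code{rankMode}.
#'
#' @param pm a [PhenotypeMatrix-class] (or plain matrix)
#' @param nClusters number of clusters to cut
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   "complete")
#' @param rankMode "column" (default) or "global"
#' @return list with \code{assignment} (integer per sample), \code{tree}
#'   (the hclust object), \code{ranks} (the rank matrix) and \code{newick}
#'   (the dendrogram as a Newick string)
#' @export
rankCluster <- function(pm, nClusters, linkage = "complete",
                        rankMode = c("column", "global")) {
  rankMode <- match.arg(rankMode)
  m <- if (is(pm, "PhenotypeMatrix")) pm@values else as.matrix(pm)
  if (nClusters > nrow(m)) stop("more clusters than samples requested")
  r <- if (rankMode == "column") apply(m, 2, rank) else
    array(rank(m), dim(m), dimnames = dimnames(m))
  if (is.null(rownames(r))) rownames(r) <- paste0("s", seq_len(nrow(r)))
  tree <- hclust(dist(r), method = linkage)
  assignment <- cutree(tree, k = nClusters)
  nw <- ape::write.tree(ape::as.phylo(tree))
  list(assignment = assignment, tree = tree, ranks = r, newick = nw)
}

#' Flag class enrichment against controls
#'
#' Flags a condition/class pair when its class fraction exceeds
#' \code{foldThreshold} times the control fraction. Classes absent from the
#' controls but present in a condition are flagged \code{"control-zero"}.
#'
#' @param condFractions conditions x classes matrix of class fractions
#' @param controlFractions named numeric control fractions (same classes)
#' @param foldThreshold enrichment threshold (default 1.5)
#' @return character matrix (conditions x classes) with entries
#'   \code{"enriched"}, \code{"none"} or \code{"control-zero"}; the fold
#'   changes are attached as attribute \code{fold}
#' @export
enrichmentFlags <- function(condFractions, controlFractions,
                            foldThreshold = 1.5) {
  condFractions <- rbind(condFractions)
  classes <- colnames(condFractions)
  if (is.null(classes)) classes <- names(controlFractions)
  ctl <- controlFractions[classes]
  fold <- sweep(condFractions, 2, ctl, "/")
  flags <- matrix("none", nrow(condFractions), ncol(condFractions),
                  dimnames = dimnames(condFractions))
  flags[fold > foldThreshold] <- "enriched"
  zero <- which(ctl == 0)
  for (j in zero)
    flags[, j] <- ifelse(condFractions[, j] > 0, "control-zero", "none")
  attr(flags, "fold") <- fold
  flags
}
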