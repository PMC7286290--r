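#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Generics and accessors
# ---------------------------------------------------------------------------

#' Voxel size accessor
#' @param x an object carrying a voxel grid
#' @return numeric voxel size in um
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "VolumeStack", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "LabelVolume", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "PSFModel", function(x) x@voxelSize)

#' View tag accessor
#' @param x an object carrying a view tag
#' @return character view tag
#' @export
setGeneric("viewTag", function(x) standardGeneric("viewTag"))

#' @rdname viewTag
#' @export
setMethod("viewTag", "VolumeStack", function(x) x@view)

#' @rdname viewTag
#' @export
setMethod("viewTag", "PSFModel", function(x) x@view)

#' Intensity / label array accessors
#'
#' @param x a [VolumeStack-class], [LabelVolume-class] or [PSFModel-class]
#' @return the underlying 3D array
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @rdname volumeData
#' @export
setMethod("volumeData", "VolumeStack", function(x) x@data)

#' @rdname volumeData
#' @export
setMethod("volumeData", "LabelVolume", function(x) x@labels)

#' @rdname volumeData
#' @export
setMethod("volumeData", "PSFModel", function(x) x@kernel)

#' @export
setMethod("dim", "VolumeStack", function(x) dim(x@data))

#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@labels))

#' Apply an affine transform to points
#'
#' @param transform an [AffineTransform3D-class]
#' @param points n x 3 matrix of coordinates, um
#' @return n x 3 matrix of transformed coordinates
#' @export
applyTransform <- function(transform, points) {
  points <- rbind(points)
  t(transform@linear %*% t(points) + transform@translation)
}

#' Invert an affine transform
#' @param transform an [AffineTransform3D-class]
#' @return the inverse [AffineTransform3D-class]
#' @export
invertTransform <- function(transform) {
  Li <- solve(transform@linear)
  affineTransform3D(Li, -Li %*% transform@translation,
                    residualRMS = transform@residualRMS,
                    nCorrespondences = transform@nCorrespondences)
}

#' Compose two affine transforms
#'
#' Returns the transform equivalent to applying \code{second} after
#' \code{first}.
#' @param first,second [AffineTransform3D-class] objects
#' @return the composed [AffineTransform3D-class]
#' @export
composeTransform <- function(second, first) {
  affineTransform3D(second@linear %*% first@linear,
                    second@linear %*% first@translation + second@translation)
}

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "SceneParams", function(object) {
  pd <- object@phaseDurations
  cat("SceneParams:", object@nInitialCells, "initial cells,",
      object@nFrames, "frames @", object@frameInterval, "min\n")
  cat("  cycle", object@cycleLength, "min; mitosis P/M/A =",
      paste(pd[c("prophase", "metaphase", "anaphase")], collapse = "/"), "min\n")
  cat("  nucleus radius", object@nucleusRadiusMean, "+/-",
      object@nucleusRadiusSD, "um; packing", object@packingDistance, "um\n")
})

setMethod("show", "OpticsParams", function(object) {
  cat("OpticsParams:", paste(object@gridDim, collapse = " x "), "voxels,",
      object@voxelSizeXY, "um XY /", object@sliceSpacing, "um Z\n")
  cat("  PSF sigma (lat/ax) A:", object@psfSigmaLateral["A"], "/",
      object@psfSigmaAxial["A"], "um  B:", object@psfSigmaLateral["B"], "/",
      object@psfSigmaAxial["B"], "um\n")
  cat("  photonScale", object@photonScale, ", read noise sd",
      object@readNoiseSD, ",", object@bitDepth, "bit\n")
})

setMethod("show", "VolumeStack", function(object) {
  cat(class(object), sprintf("view %s, t=%d:", object@view, object@timepoint),
      paste(dim(object@data), collapse = " x "), "voxels @",
      paste(signif(object@voxelSize, 4), collapse = "/"), "um\n")
})

setMethod("show", "FusedVolume", function(object) {
  callNextMethod()
  cat(" ", object@iterations, "RL iterations; final data fit",
      if (nrow(object@dataFit)) signif(sum(object@dataFit[nrow(object@dataFit), ]), 6)
      else NA, "\n")
})

setMethod("show", "AffineTransform3D", function(object) {
  cat("AffineTransform3D (B -> A):\n")
  m <- cbind(object@linear, object@translation)
  dimnames(m) <- list(c("x", "y", "z"), c("lx", "ly", "lz", "t"))
  print(signif(m, 6))
  cat("  residual RMS:", signif(object@residualRMS, 4), "um over",
      object@nCorrespondences, "correspondences\n")
})

setMethod("show", "PSFModel", function(object) {
  cat("PSFModel view", object@view, ":", paste(dim(object@kernel), collapse = " x "),
      "kernel @", signif(object@voxelSize, 4), "um\n")
})

setMethod("show", "DriftSeries", function(object) {
  n <- nrow(object@offsets)
  cat("DriftSeries over", n, "frames; final offset",
      paste(signif(object@offsets[n, ], 4), collapse = ", "), "um\n")
})

setMethod("show", "LabelVolume", function(object) {
  cat("LabelVolume:", paste(dim(object@labels), collapse = " x "),
      "voxels,", max(object@labels), "segments\n")
})

setMethod("show", "GroundTruthScene", function(object) {
  nf <- length(unique(object@nuclei$frame))
  cat("GroundTruthScene:", nf, "frames,",
      length(unique(object@nuclei$id)), "nuclei total,",
      length(unique(object@beads$bead)), "beads\n")
  print(table(object@nuclei$phase))
})

setMethod("show", "SliceSet", function(object) {
  cat("SliceSet for nucleus", object@nucleusId, ":",
      dim(object@patches)[3], "patches of",
      dim(object@patches)[1], "x", dim(object@patches)[2],
      sprintf("(XY %d, XZ %d, YZ %d)\n",
              sum(object@orientation == "XY"),
              sum(object@orientation == "XZ"),
              sum(object@orientation == "YZ")))
})

setMethod("show", "ClassifierBundle", function(object) {
  cat("ClassifierBundle:", object@kind, "on",
      length(object@classOrder), "classes:",
      paste(object@classOrder, collapse = ", "), "\n")
  if (!is.null(object@metadata$holdoutAccuracy))
    cat("  holdout accuracy:", signif(object@metadata$holdoutAccuracy, 4), "\n")
})

setMethod("show", "PhenotypeMatrix", function(object) {
  cat("PhenotypeMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "features (centred, scaled);",
      nrow(object@excluded), "excluded\n")
})

setMethod("show", "SpotGrid", function(object) {
  cat("SpotGrid:", object@nColumns, "x", object@nRows, "=",
      nrow(object@centers), "spots,", object@spotsPerSample,
      "spots/sample =>", nrow(object@centers) / object@spotsPerSample,
      "samples; pitch", object@pitch, "mm\n")
})

setMethod("show", "AcquisitionPlan", function(object) {
  cat("AcquisitionPlan:", object@imagesPerPass, "images/pass;",
      signif(object@bytesPerPositionTimepoint / 1e9, 4),
      "GB per position-timepoint;", signif(object@totalBytes / 1e12, 4),
      "TB total\n")
})
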