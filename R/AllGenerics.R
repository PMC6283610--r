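#' Accessors for tubeaniso classes
#'
#' `imageData` returns the raw array of a [VolumetricImage-class] or
#' the matrix of an [UnrolledImage-class]; `voxelSize` the physical
#' voxel edge lengths (um); `nFrames` the number of time frames (1 for
#' a plain 3D stack); `getFrame` one 3D time frame as a
#' VolumetricImage; `junctions`, `cellPolygons` and `medialAxis` the
#' components of a [JunctionGraph-class].
#'
#' @param x object.
#' @param i frame index (1-based).
#' @return See each accessor's description.
#' @name accessors
#' @examples
#' v <- VolumetricImage(array(1, c(2, 2, 2)), voxel = c(1, 1, 2))
#' voxelSize(v)
#' nFrames(v)
NULL

#' @rdname accessors
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname accessors
#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))

#' @rdname accessors
#' @export
setGeneric("cellPolygons", function(x) standardGeneric("cellPolygons"))

#' @rdname accessors
#' @export
setGeneric("medialAxis", function(x) standardGeneric("medialAxis"))

#' @rdname accessors
#' @export
setMethod("imageData", "VolumetricImage", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("imageData", "UnrolledImage", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("voxelSize", "VolumetricImage", function(x) x@voxel)

#' @rdname accessors
#' @export
setMethod("nFrames", "VolumetricImage", function(x) {
  d <- dim(x@data)
  if (length(d) == 4L) d[4] else 1L
})

#' @rdname accessors
#' @export
setMethod("getFrame", "VolumetricImage", function(x, i) {
  d <- dim(x@data)
  if (length(d) == 3L) {
    if (i != 1L) stop("single-frame stack")
    return(x)
  }
  VolumetricImage(x@data[, , , i, drop = FALSE][, , , 1],
                  voxel = x@voxel, origin = x@origin)
})

#' @rdname accessors
#' @export
setMethod("junctions", "JunctionGraph", function(x) x@junctions)

#' @rdname accessors
#' @export
setMethod("cellPolygons", "JunctionGraph", function(x) x@cells)

#' @rdname accessors
#' @export
setMethod("medialAxis", "JunctionGraph", function(x) x@medialAxis)

setMethod("show", "VolumetricImage", function(object) {
  d <- dim(object@data)
  cat("VolumetricImage:", paste(d, collapse = " x "),
      if (length(d) == 4L) "(x,y,z,t)" else "(x,y,z)", "\n")
  cat("  voxel (um):", paste(signif(object@voxel, 4), collapse = " x "),
      "\n")
  rng <- range(object@data, na.rm = TRUE)
  cat("  intensity range:", signif(rng[1], 4), "-", signif(rng[2], 4), "\n")
})

setMethod("show", "TubeSpec", function(object) {
  cat("TubeSpec: radius", object@radius, "um, length", object@length,
      "um,", object@nRings, "x", object@nAround, "cells\n")
  cat("  enrichment", object@enrichment, " baseIntensity",
      object@baseIntensity, "counts/um, CV", object@intensityCV, "\n")
  cat("  psfSigma", object@psfSigma, "um, voxel",
      paste(object@voxel, collapse = "x"), "um, curvature",
      object@curvature, "/um, seed", object@seed, "\n")
})

setMethod("show", "JunctionGraph", function(object) {
  tb <- table(object@junctions$class)
  cat("JunctionGraph:", nrow(object@junctions), "junctions (",
      paste(names(tb), as.integer(tb), collapse = ", "), "),",
      length(object@cells), "cells\n")
})

setMethod("show", "UnrolledImage", function(object) {
  cat("UnrolledImage:", nrow(object@data), "x", ncol(object@data),
      "px (longitudinal x circumferential),", object@pixelSize,
      "um/px, replication", object@replication, "\n")
})

setMethod("show", "FrapTrace", function(object) {
  cat("FrapTrace:", length(object@times), "frames (", object@nPre,
      "pre-bleach ), dt", signif(mean(diff(object@times)), 4), "s,",
      if (object@normalized) "normalized" else "raw", "\n")
})

setMethod("show", "FrapFit", function(object) {
  cat("FrapFit: Mf", signif(object@mf, 4), " tHalf",
      signif(object@tHalf, 4), "s  (Fb", signif(object@fB, 4),
      ", Finf", signif(object@fInf, 4), ", rms",
      signif(object@rms, 3), ")\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags,
      collapse = ", "), "\n")
})
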