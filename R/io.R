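# File formats: calibrated multi-page TIFF stacks, ROI JSON, run
# configuration YAML.
#
# TIFF samples are stored as 32-bit values scaled into [0, 1] by a
# recorded factor; voxel size, origin, axis layout and the intensity
# scale travel in a JSON sidecar next to the TIFF (<path>.json), since
# the installed TIFF writer exposes no tag interface. Reading a TIFF
# without its sidecar falls back to 1 um voxels with a warning.

#' Write / read a calibrated image stack
#'
#' `writeStack` writes a [VolumetricImage-class] (3D or 4D) as a
#' multi-page TIFF (z fastest, then t) plus a JSON metadata sidecar;
#' `readStack` reads the pair back. The round trip preserves voxel
#' calibration exactly and intensities to 32-bit quantization
#' (relative error below 3e-10).
#'
#' @param volume A [VolumetricImage-class].
#' @param path TIFF file path.
#' @return `readStack` returns a [VolumetricImage-class];
#'   `writeStack` returns `path` invisibly.
#' @examples
#' v <- VolumetricImage(array(runif(8), c(2, 2, 2)), voxel = c(1, 1, 2))
#' f <- file.path(tempdir(), "stack.tif")
#' writeStack(v, f)
#' all.equal(imageData(readStack(f)), imageData(v), tolerance = 1e-8)
#' @export
writeStack <- function(volume, path) {
  stopifnot(is(volume, "VolumetricImage"))
  arr <- volume@data
  arr[is.na(arr)] <- 0            # masked samples stored as zero
  d <- dim(arr)
  lo <- min(arr)
  hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  norm <- (arr - lo) / scale
  nz <- d[3]
  nt <- if (length(d) == 4L) d[4] else 1L
  pages <- vector("list", nz * nt)
  i <- 0L
  for (t in seq_len(nt)) {
    for (z in seq_len(nz)) {
      i <- i + 1L
      # TIFF rows are the y axis: transpose so x runs along columns
      pages[[i]] <- t(if (length(d) == 4L) norm[, , z, t] else
        norm[, , z])
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(format = "tubeaniso-stack", version = 1L,
               voxel = volume@voxel, origin = volume@origin,
               dim = d, nz = nz, nt = nt,
               intensityOffset = lo, intensityScale = scale,
               axisOrder = if (nt > 1L) "xyzt" else "xyz")
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecarPath <- function(path) paste0(path, ".json")

#' @rdname writeStack
#' @export
readStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- sidecarPath(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    voxel <- meta$voxel
    origin <- meta$origin
    off <- meta$intensityOffset
    sc <- meta$intensityScale
    nz <- meta$nz
    nt <- meta$nt
  } else {
    warning("no calibration sidecar for ", path,
            "; assuming 1 um voxels")
    voxel <- c(1, 1, 1)
    origin <- c(0, 0, 0)
    off <- 0
    sc <- 1
    nz <- length(pages)
    nt <- 1L
  }
  if (length(pages) != nz * nt) {
    stop("page count does not match metadata (", length(pages),
         " vs ", nz * nt, ")")
  }
  d2 <- dim(pages[[1]])
  arr <- array(NA_real_, c(d2[2], d2[1], nz, nt))
  i <- 0L
  for (t in seq_len(nt)) {
    for (z in seq_len(nz)) {
      i <- i + 1L
      arr[, , z, t] <- t(pages[[i]])
    }
  }
  arr <- arr * sc + off
  if (nt == 1L) {
    arr <- arr[, , , 1L, drop = FALSE]
    dim(arr) <- dim(arr)[1:3]
  }
  VolumetricImage(arr, voxel = voxel, origin = origin)
}

#' Write / read ROI files
#'
#' ROIs travel as a JSON array of objects with fields `id`, `type`
#' (one of polyline, polygon, line, ring), `vertices` (list of [x, y]
#' 0-based pixel coordinates; for a ring, `center` [x, y] and
#' `radius` instead) and optional free-form fields (embryo, channel,
#' frame). Validation errors name the offending ROI.
#'
#' @param rois list of ROI lists (id, type, vertices/center+radius,
#'   ...).
#' @param path JSON file path.
#' @return `readRois` returns the validated list of ROIs with
#'   `vertices` as Nx2 matrices; `writeRois` returns `path`
#'   invisibly.
#' @export
writeRois <- function(rois, path) {
  rois <- lapply(rois, function(r) {
    if (!is.null(r$vertices)) {
      r$vertices <- lapply(seq_len(nrow(as.matrix(r$vertices))),
        function(i) as.numeric(as.matrix(r$vertices)[i, ]))
    }
    r
  })
  validateRois(lapply(rois, normalizeRoi))
  jsonlite::write_json(rois, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRois
#' @export
readRois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rois <- lapply(raw, normalizeRoi)
  validateRois(rois)
  rois
}

normalizeRoi <- function(r) {
  if (!is.null(r$vertices)) {
    v <- r$vertices
    if (is.list(v)) {
      v <- do.call(rbind, lapply(v, function(p) as.numeric(unlist(p))))
    }
    r$vertices <- matrix(as.numeric(v), ncol = 2)
  }
  if (!is.null(r$center)) r$center <- as.numeric(unlist(r$center))
  r
}

validateRois <- function(rois) {
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    label <- if (!is.null(r$id)) r$id else sprintf("#%d", i)
    if (is.null(r$type) ||
        !r$type %in% c("polyline", "polygon", "line", "ring")) {
      stop("ROI ", label, ": type must be polyline, polygon, line or ring")
    }
    if (r$type == "ring") {
      if (is.null(r$center) || length(r$center) != 2L ||
          is.null(r$radius) || r$radius <= 0) {
        stop("ROI ", label, ": ring needs center [x, y] and radius > 0")
      }
    } else {
      minV <- switch(r$type, polygon = 3L, polyline = 2L, line = 2L)
      if (is.null(r$vertices) || nrow(r$vertices) < minV) {
        stop("ROI ", label, ": ", r$type, " needs at least ", minV,
             " vertices")
      }
    }
  }
  invisible(TRUE)
}

#' Write the full ground truth of a synthetic tube as JSON
#'
#' Serializes everything downstream stages can be checked against:
#' the per-junction table with plane and 3D polylines, the cell
#' polygons with true areas and orientations, the medial axis, and
#' the generator parameters that produced them.
#'
#' @param graph A [JunctionGraph-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(graph, path) {
  sp <- graph@spec
  params <- list(radius = sp@radius, length = sp@length,
                 nRings = sp@nRings, nAround = sp@nAround,
                 vertexJitter = sp@vertexJitter,
                 enrichment = sp@enrichment,
                 baseIntensity = sp@baseIntensity,
                 intensityCV = sp@intensityCV, psfSigma = sp@psfSigma,
                 shotScale = sp@shotScale, readSD = sp@readSD,
                 voxel = sp@voxel, curvature = sp@curvature,
                 seed = sp@seed)
  j <- graph@junctions
  junc <- lapply(seq_len(nrow(j)), function(i) {
    list(id = j$id[i], class = j$class[i], angleDeg = j$angleDeg[i],
         lengthUm = j$lengthUm[i], density = j$density[i],
         polylinePlane = graph@polylinesPlane[[i]],
         polyline3D = graph@polylines3D[[i]])
  })
  cells <- lapply(seq_along(graph@cells), function(i) {
    list(id = graph@cellInfo$id[i],
         areaUm2 = graph@cellInfo$areaUm2[i],
         phiDeg = graph@cellInfo$phiDeg[i],
         polygon = graph@cells[[i]])
  })
  jsonlite::write_json(list(parameters = params, junctions = junc,
                            cells = cells,
                            medialAxis = graph@medialAxis),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export ground-truth junctions as an ROI file
#'
#' Writes the (projected) junction polylines of a
#' [JunctionGraph-class] in the standard ROI JSON schema, so the
#' synthetic ground truth can be fed to the same entry points as
#' manually traced junctions.
#'
#' @param graph A [JunctionGraph-class].
#' @param volume the rendered [VolumetricImage-class] providing the
#'   pixel frame.
#' @param path output JSON path.
#' @param azimuthWindow if non-NULL, export only junctions within
#'   this many degrees of tube-top azimuth (the ones measurable on a
#'   projection; side junctions can project to degenerate chords).
#' @return `path`, invisibly.
#' @export
exportJunctionRois <- function(graph, volume, path,
                               azimuthWindow = NULL) {
  idx <- seq_len(nrow(graph@junctions))
  if (!is.null(azimuthWindow)) {
    idx <- idx[visibleJunctions(graph, azimuthWindow)[idx]]
  }
  rois <- lapply(idx, function(i) {
    p3 <- graph@polylines3D[[i]]
    list(id = graph@junctions$id[i], type = "polyline",
         vertices = cbind((p3[, 1] - volume@origin[1]) / volume@voxel[1],
                          (p3[, 2] - volume@origin[2]) / volume@voxel[2]))
  })
  writeRois(rois, path)
}
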