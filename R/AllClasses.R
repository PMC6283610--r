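#' VolumetricImage: calibrated 3D (+time) intensity grid
#'
#' A 3D fluorescence image stack (optionally with a 4th, time axis)
#' together with its physical voxel size. Axis order is (x, y, z[, t])
#' with x conventionally the tube's longitudinal axis in synthetic
#' scenes. `origin` records the physical position (micrometres) of the
#' centre of voxel (0, 0, 0), so scene coordinates map to 0-based voxel
#' coordinates as (p - origin) / voxel.
#'
#' @slot data numeric array, 3D or 4D.
#' @slot voxel numeric(3), voxel edge lengths in micrometres (x, y, z).
#' @slot origin numeric(3), physical position of voxel (0,0,0), um.
#' @aliases VolumetricImage-class
#' @exportClass VolumetricImage
setClass("VolumetricImage",
  slots = c(data = "array", voxel = "numeric", origin = "numeric"),
  prototype = prototype(voxel = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("VolumetricImage", function(object) {
  nd <- length(dim(object@data))
  if (!nd %in% c(3L, 4L)) {
    return("data must be a 3D (x,y,z) or 4D (x,y,z,t) array")
  }
  if (length(object@voxel) != 3L || any(!is.finite(object@voxel)) ||
      any(object@voxel <= 0)) {
    return("voxel must be 3 positive finite edge lengths (um)")
  }
  if (length(object@origin) != 3L || any(!is.finite(object@origin))) {
    return("origin must be 3 finite coordinates (um)")
  }
  TRUE
})

#' Construct a VolumetricImage
#'
#' @param data 3D or 4D numeric array (x, y, z[, t]).
#' @param voxel numeric(3) voxel size in micrometres.
#' @param origin numeric(3) physical position (um) of voxel (0,0,0).
#' @return A [VolumetricImage-class] object.
#' @examples
#' v <- VolumetricImage(array(0, c(4, 4, 2)), voxel = c(0.5, 0.5, 1))
#' voxelSize(v)
#' @export
VolumetricImage <- function(data, voxel = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("VolumetricImage", data = data, voxel = as.numeric(voxel),
      origin = as.numeric(origin))
}

#' TubeSpec: parameters of the synthetic tubular epithelium
#'
#' Describes the geometry, labelling statistics and imaging physics of a
#' synthetic dorsal-trunk-like tube: a cylinder of radius `radius` and
#' length `length` (um) carrying a brick tessellation of `nRings` cell
#' rows by `nAround` cells around the circumference. Junctional signal
#' is laid down with per-unit-length intensity `baseIntensity` at
#' transverse junctions and `enrichment` times that at longitudinal
#' junctions, with per-junction lognormal variability of coefficient of
#' variation `intensityCV`. Rendering convolves with an isotropic
#' Gaussian PSF (`psfSigma`, um) and corrupts with mixed shot
#' (variance = `shotScale` * signal) plus additive Gaussian read noise
#' (`readSD`, counts). `curvature` (1/um) bends the tube along a
#' circular arc in the XY plane; 0 keeps it straight. The same `seed`
#' always reproduces the same tessellation, intensities and noise.
#'
#' @slot radius,length tube radius and length, um.
#' @slot nRings,nAround integer tessellation counts (rows along the
#'   axis; cells around the circumference).
#' @slot vertexJitter fraction of local cell size by which interior
#'   tessellation vertices are displaced.
#' @slot enrichment mean LCJ intensity per unit length divided by mean
#'   TCJ intensity per unit length (1 = orientation-independent).
#' @slot baseIntensity TCJ-class mean intensity, counts per um.
#' @slot intensityCV lognormal coefficient of variation per junction.
#' @slot psfSigma isotropic PSF sigma, um.
#' @slot shotScale,readSD noise model; `readSD = NA` defaults at render
#'   time to 2 percent of the ideal peak line amplitude.
#' @slot voxel numeric(3) voxel size, um.
#' @slot curvature medial-axis curvature, 1/um.
#' @slot seed integer RNG seed.
#' @aliases TubeSpec-class
#' @exportClass TubeSpec
setClass("TubeSpec",
  slots = c(radius = "numeric", length = "numeric", nRings = "integer",
            nAround = "integer", vertexJitter = "numeric",
            enrichment = "numeric", baseIntensity = "numeric",
            intensityCV = "numeric", psfSigma = "numeric",
            shotScale = "numeric", readSD = "numeric", voxel = "numeric",
            curvature = "numeric", seed = "integer"))

setValidity("TubeSpec", function(object) {
  msg <- character(0)
  if (object@radius <= 0 || object@length <= 0) {
    msg <- c(msg, "radius and length must be positive")
  }
  if (object@nRings < 1L) msg <- c(msg, "nRings must be >= 1")
  if (object@nAround < 3L) msg <- c(msg, "nAround must be >= 3")
  if (object@vertexJitter < 0 || object@vertexJitter > 0.25) {
    msg <- c(msg, "vertexJitter must be in [0, 0.25]")
  }
  if (object@enrichment < 0) msg <- c(msg, "enrichment must be >= 0")
  if (object@intensityCV < 0) msg <- c(msg, "intensityCV must be >= 0")
  if (!length(object@psfSigma) %in% c(1L, 3L) || any(object@psfSigma <= 0)) {
    msg <- c(msg, "psfSigma must be 1 (isotropic) or 3 positive sigmas")
  }
  if (length(object@voxel) != 3L || any(object@voxel <= 0)) {
    msg <- c(msg, "voxel must be 3 positive edge lengths")
  }
  if (object@curvature < 0) msg <- c(msg, "curvature must be >= 0")
  if (object@curvature * object@length >= pi) {
    msg <- c(msg, "curvature * length must be < pi (tube stays in frame)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TubeSpec
#'
#' Defaults describe a stage-16 dorsal-trunk-like fragment: radius 6 um,
#' length 35 um, 7 cell rows of 6 cells (cells about 6.3 x 5 um;
#' junction lengths about 3-5 um, as junctions in such tissue measure),
#' wild-type-like longitudinal enrichment 1.5, and high-resolution
#' confocal sampling: a 0.15 um isotropic Gaussian PSF imaged at
#' 0.12 um laterally and 0.125 um axially, so the projection samples
#' the PSF faithfully, with photon-scale intensities (peak junction
#' signal about 150 counts, shot-noise-limited).
#'
#' @param radius,length tube radius and length in um.
#' @param nRings,nAround tessellation counts.
#' @param vertexJitter jitter fraction for interior vertices.
#' @param enrichment LCJ/TCJ mean intensity-density ratio.
#' @param baseIntensity TCJ mean intensity density, counts/um.
#' @param intensityCV per-junction lognormal CV.
#' @param psfSigma PSF sigma, um.
#' @param shotScale,readSD noise parameters (see class docs).
#' @param voxel numeric(3) voxel size, um.
#' @param curvature axis curvature, 1/um.
#' @param seed integer seed.
#' @return A validated [TubeSpec-class].
#' @examples
#' spec <- tubeSpec(enrichment = 1, seed = 7L)
#' @export
tubeSpec <- function(radius = 6, length = 35, nRings = 7L, nAround = 6L,
                     vertexJitter = 0.12, enrichment = 1.5,
                     baseIntensity = 12000, intensityCV = 0.2,
                     psfSigma = 0.15, shotScale = 1, readSD = NA_real_,
                     voxel = c(0.12, 0.12, 0.125), curvature = 0,
                     seed = 1L) {
  new("TubeSpec", radius = radius, length = length,
      nRings = as.integer(nRings), nAround = as.integer(nAround),
      vertexJitter = vertexJitter, enrichment = enrichment,
      baseIntensity = baseIntensity, intensityCV = intensityCV,
      psfSigma = psfSigma, shotScale = shotScale, readSD = readSD,
      voxel = as.numeric(voxel), curvature = curvature,
      seed = as.integer(seed))
}

#' JunctionGraph: tessellated tube surface with ground truth
#'
#' The cell tessellation of a synthetic tube: per-junction polylines in
#' 3D scene coordinates and on the unrolled (circumference x length)
#' plane, true orientation angle, class and intensity density; cell
#' polygons on the unrolled plane with true areas and long-axis angles;
#' and the medial axis. Produced by [tessellateTube()]; intensities are
#' filled in by [assignIntensities()].
#'
#' @slot junctions data.frame with one row per junction: id, class
#'   (LCJ/TCJ/unassigned by the true angle), angleDeg (folded, [0,90]),
#'   lengthUm, density (counts/um; NA until assigned), cellA, cellB
#'   (bounding cell ids; NA for a tube-end junction's missing side).
#' @slot polylines3D list of Nx3 matrices, scene um.
#' @slot polylinesPlane list of Nx2 matrices on the unrolled plane, um
#'   (u unwrapped across the periodic seam).
#' @slot cells list of Mx2 polygon matrices on the unrolled plane, um.
#' @slot cellInfo data.frame: id, areaUm2, phiDeg (true long-axis angle
#'   on the unrolled plane, vertical = longitudinal = 90).
#' @slot medialAxis Nx3 matrix of the tube axis, scene um.
#' @slot spec the generating [TubeSpec-class].
#' @aliases JunctionGraph-class
#' @exportClass JunctionGraph
setClass("JunctionGraph",
  slots = c(junctions = "data.frame", polylines3D = "list",
            polylinesPlane = "list", cells = "list",
            cellInfo = "data.frame", medialAxis = "matrix",
            spec = "TubeSpec"))

setValidity("JunctionGraph", function(object) {
  nj <- nrow(object@junctions)
  if (length(object@polylines3D) != nj ||
      length(object@polylinesPlane) != nj) {
    return("one 3D and one plane polyline required per junction")
  }
  if (any(object@junctions$lengthUm <= 0)) {
    return("degenerate junction polyline (length <= 0)")
  }
  if (nrow(object@medialAxis) < 2L) return("medial axis needs >= 2 points")
  TRUE
})

#' UnrolledImage: circumference-by-length projection of a tube surface
#'
#' Rows run along the straightened longitudinal axis, columns along the
#' circumferential ring; one pixel is `pixelSize` um on both axes. The
#' width before horizontal replication is round(ring perimeter /
#' pixel size); with `replication = 2` the image is duplicated
#' side-by-side so cells crossing the azimuthal seam can be measured in
#' one piece. Pixels that sampled outside the source volume are NA.
#'
#' @slot data numeric matrix (longitudinal x circumferential).
#' @slot pixelSize um per pixel.
#' @slot ringRadius sampling-ring radius, um.
#' @slot baseWidth columns before replication.
#' @slot replication 1 or 2.
#' @aliases UnrolledImage-class
#' @exportClass UnrolledImage
setClass("UnrolledImage",
  slots = c(data = "matrix", pixelSize = "numeric", ringRadius = "numeric",
            baseWidth = "integer", replication = "integer"))

setValidity("UnrolledImage", function(object) {
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  if (!object@replication %in% c(1L, 2L)) return("replication must be 1 or 2")
  if (ncol(object@data) != object@baseWidth * object@replication) {
    return("width must equal baseWidth * replication")
  }
  TRUE
})

#' FrapTrace: a timestamped FRAP intensity trace
#'
#' Uniformly sampled intensities with `nPre` pre-bleach frames; the
#' first post-bleach frame defines t = 0, so pre-bleach times are
#' negative. A trace is `normalized` when intensities are expressed as
#' a fraction of the pre-bleach mean.
#'
#' @slot times numeric, seconds, strictly increasing.
#' @slot intensities numeric, counts or normalized units.
#' @slot nPre integer number of pre-bleach frames.
#' @slot normalized logical.
#' @aliases FrapTrace-class
#' @exportClass FrapTrace
setClass("FrapTrace",
  slots = c(times = "numeric", intensities = "numeric", nPre = "integer",
            normalized = "logical"),
  prototype = prototype(normalized = FALSE))

setValidity("FrapTrace", function(object) {
  if (length(object@times) != length(object@intensities)) {
    return("times and intensities must have equal length")
  }
  if (any(diff(object@times) <= 0)) {
    return("times must be strictly increasing")
  }
  if (object@nPre < 0L || object@nPre >= length(object@times)) {
    return("nPre must leave at least one post-bleach frame")
  }
  TRUE
})

#' Construct a FrapTrace
#' @param times sampling times, s (t = 0 at the first post-bleach frame).
#' @param intensities measured intensities.
#' @param nPre number of pre-bleach frames.
#' @param normalized whether intensities are pre-bleach-normalized.
#' @return A [FrapTrace-class].
#' @export
FrapTrace <- function(times, intensities, nPre, normalized = FALSE) {
  new("FrapTrace", times = as.numeric(times),
      intensities = as.numeric(intensities), nPre = as.integer(nPre),
      normalized = normalized)
}

#' FrapFit: single-exponential FRAP recovery fit
#'
#' Parameters of the least-squares fit F(t) = Finf - (Finf - Fb) *
#' exp(-k t) to the post-bleach samples of a normalized trace, with
#' mobile fraction Mf = (Finf - Fb) / (Fpre - Fb) and half-time
#' tHalf = ln(2) / k.
#'
#' @slot fPre,fB,fInf pre-bleach level, bleach floor, plateau.
#' @slot k recovery rate, 1/s (NA for a flat trace).
#' @slot tHalf half-time, s.
#' @slot mf mobile fraction.
#' @slot rms residual root-mean-square.
#' @slot converged logical.
#' @slot flags character vector of diagnostics ("flat",
#'   "mobile-fraction>1", "nonconvergence", ...).
#' @slot trace the fitted [FrapTrace-class].
#' @aliases FrapFit-class
#' @exportClass FrapFit
setClass("FrapFit",
  slots = c(fPre = "numeric", fB = "numeric", fInf = "numeric",
            k = "numeric", tHalf = "numeric", mf = "numeric",
            rms = "numeric", converged = "logical", flags = "character",
            trace = "FrapTrace"))
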