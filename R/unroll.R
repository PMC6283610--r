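# Tube unrolling: isotropic resampling, two-pass medial-axis
# straightening, ring radial projection, horizontal replication.

#' Resample a stack to isotropic voxels
#'
#' Trilinear resampling onto cubic voxels whose edge is the smallest
#' input voxel edge; the physical extent of the stack is preserved.
#' All unrolling starts here so the projected image has no aspect
#' distortion.
#'
#' @param volume A [VolumetricImage-class].
#' @param method "bilinear" (trilinear intensity interpolation) or
#'   "nearest" (for label volumes).
#' @return An isotropic [VolumetricImage-class].
#' @export
resampleIsotropic <- function(volume, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  vox <- volume@voxel
  px <- min(vox)
  if (all(vox == px)) return(volume)
  d <- dim(volume@data)
  newD <- as.integer(round((d - 1L) * vox / px)) + 1L
  gx <- seq(0, d[1] - 1L, length.out = newD[1])
  gy <- seq(0, d[2] - 1L, length.out = newD[2])
  gz <- seq(0, d[3] - 1L, length.out = newD[3])
  gg <- expand.grid(x = gx, y = gy, z = gz)
  v <- if (method == "bilinear") {
    trilinearSample(volume@data, gg$x, gg$y, gg$z)
  } else {
    nearestSample3(volume@data, gg$x, gg$y, gg$z)
  }
  VolumetricImage(array(v, newD), voxel = rep(px, 3),
                  origin = volume@origin)
}

#' One straightening pass along a hand-drawn medial axis
#'
#' Resamples a 3D stack along a polyline drawn in one view (the "IJ
#' Straighten" operation): for every unit-arclength sample along the
#' (centripetal Catmull-Rom smoothed) polyline, a line perpendicular
#' to the local tangent of length `2 * halfWidth + 1` pixels is
#' extracted, identically in every slice of the orthogonal axis.
#' Applied twice - first in the XY view, then in the XZ view of the
#' first pass's result - it straightens a tube bent in both planes.
#'
#' The output axis 1 is arclength, axis 2 the perpendicular offset
#' (the polyline maps to offset `halfWidth`), axis 3 the untouched
#' orthogonal axis. Samples falling outside the volume are NA
#' (masked).
#'
#' @param volume A [VolumetricImage-class] with isotropic voxels.
#' @param polyline Nx2 matrix, 0-based pixel coordinates in the view
#'   plane (XY: (x, y); XZ: (x, z)).
#' @param halfWidth half-width of the perpendicular line, pixels.
#' @param view "XY" or "XZ".
#' @param method "bilinear" or "nearest".
#' @return A [VolumetricImage-class] (arclength x offset x ortho).
#' @export
straightenPass <- function(volume, polyline, halfWidth,
                           view = c("XY", "XZ"),
                           method = c("bilinear", "nearest")) {
  view <- match.arg(view)
  method <- match.arg(method)
  arr <- volume@data
  if (view == "XZ") arr <- aperm(arr, c(1, 3, 2))
  d <- dim(arr)
  cr <- catmullRomResample(as.matrix(polyline), spacing = 1)
  nS <- nrow(cr$pos)
  offs <- seq(-halfWidth, halfWidth)
  nrm <- cbind(-cr$tangent[, 2], cr$tangent[, 1])
  px <- as.vector(outer(cr$pos[, 1], rep(1, length(offs)))) +
    as.vector(outer(nrm[, 1], offs))
  py <- as.vector(outer(cr$pos[, 2], rep(1, length(offs)))) +
    as.vector(outer(nrm[, 2], offs))
  out <- array(NA_real_, c(nS, length(offs), d[3]))
  for (k in seq_len(d[3])) {
    v <- if (method == "bilinear") {
      bilinearSample(arr[, , k], px, py)
    } else {
      nearestSample2(arr[, , k], px, py)
    }
    out[, , k] <- v
  }
  VolumetricImage(out, voxel = rep(volume@voxel[1], 3),
                  origin = c(0, 0, 0))
}

#' Unroll a straightened tube by ring radial projection
#'
#' For each slice along the straightened axis (axis 1 of a volume that
#' has been through both straightening passes), intensities are
#' sampled bilinearly at 1-pixel arc spacing around a circular ring in
#' the cross-section plane; each ring becomes one row of the output,
#' so the vertical axis of the [UnrolledImage-class] develops along
#' the tube's longitudinal axis and the horizontal axis along the
#' circumference. The image is then replicated horizontally (factor
#' 2) so cells crossing the azimuthal seam can be measured whole.
#'
#' @param volume straightened [VolumetricImage-class] (isotropic).
#' @param ringCenter numeric(2), 0-based (axis2, axis3) pixel
#'   coordinates of the ring centre in the cross-section.
#' @param ringRadius ring radius in um.
#' @param azimuthOffset rotation of the azimuthal origin, degrees.
#' @param replicate logical, apply the horizontal duplication.
#' @param method "bilinear" or "nearest".
#' @return An [UnrolledImage-class].
#' @export
unrollTube <- function(volume, ringCenter, ringRadius,
                       azimuthOffset = 0, replicate = TRUE,
                       method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  arr <- volume@data
  d <- dim(arr)
  px <- volume@voxel[1]
  rpx <- ringRadius / px
  if (ringCenter[1] - rpx < 0 || ringCenter[1] + rpx > d[2] - 1 ||
      ringCenter[2] - rpx < 0 || ringCenter[2] + rpx > d[3] - 1) {
    stop("ring exceeds the cross-section")
  }
  W <- max(4L, round(2 * pi * rpx))
  phi <- (seq_len(W) - 1L) * 2 * pi / W + azimuthOffset * pi / 180
  # azimuth 0 = +axis2 direction (the top of the tube after the two
  # standard passes); increasing phi towards +axis3
  a2 <- ringCenter[1] + rpx * cos(phi)
  a3 <- ringCenter[2] + rpx * sin(phi)
  out <- matrix(NA_real_, d[1], W)
  for (s in seq_len(d[1])) {
    sl <- arr[s, , ]
    out[s, ] <- if (method == "bilinear") {
      bilinearSample(sl, a2, a3)
    } else {
      nearestSample2(sl, a2, a3)
    }
  }
  img <- new("UnrolledImage", data = out, pixelSize = px,
             ringRadius = ringRadius, baseWidth = as.integer(W),
             replication = 1L)
  if (replicate) replicateHorizontal(img) else img
}

#' Duplicate an unrolled image side by side
#'
#' @param img An [UnrolledImage-class] with replication 1.
#' @return The image with replication 2: column c and column
#'   c + baseWidth hold identical values.
#' @export
replicateHorizontal <- function(img) {
  stopifnot(is(img, "UnrolledImage"), img@replication == 1L)
  new("UnrolledImage", data = cbind(img@data, img@data),
      pixelSize = img@pixelSize, ringRadius = img@ringRadius,
      baseWidth = img@baseWidth, replication = 2L)
}

#' Full unrolling chain for a synthetic tube
#'
#' Convenience wrapper running the exact chain used on microscope
#' stacks: isotropic resampling, straightening in the XY view along
#' the medial axis, straightening of the result in the XZ view, then
#' ring radial projection at the cell layer and horizontal
#' replication. The medial axis is taken in scene coordinates (um)
#' and projected into each view; after the two passes the axis lies
#' at the centre of the cross-section, where the ring is placed.
#'
#' @param volume A [VolumetricImage-class] (any voxel anisotropy).
#' @param axis Nx3 matrix, medial-axis polyline in scene um.
#' @param ringRadius ring radius, um (the cell layer; typically the
#'   tube radius).
#' @param halfWidthUm half-width of the straightening window, um;
#'   default covers the ring plus margin.
#' @param azimuthOffset azimuthal origin rotation, degrees.
#' @param method "bilinear" or "nearest".
#' @return list(unrolled = [UnrolledImage-class], straightened =
#'   [VolumetricImage-class], ringCenter).
#' @export
unrollTubePipeline <- function(volume, axis, ringRadius,
                               halfWidthUm = NULL, azimuthOffset = 0,
                               method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  iso <- resampleIsotropic(volume, method = method)
  px <- iso@voxel[1]
  if (is.null(halfWidthUm)) halfWidthUm <- 1.4 * ringRadius
  hw <- ceiling(halfWidthUm / px)
  axPx <- sweep(axis, 2, iso@origin) / px
  # pass 1: XY view; the axis's z profile re-expressed along arclength
  p1 <- straightenPass(iso, axPx[, 1:2], hw, view = "XY", method = method)
  sxy <- c(0, cumsum(segmentLengths(axPx[, 1:2, drop = FALSE])))
  nS <- dim(p1@data)[1]
  zAt <- stats::approx(sxy, axPx[, 3], xout = seq(0, max(sxy),
    length.out = nS), rule = 2)$y
  p2 <- straightenPass(p1, cbind(seq_len(nS) - 1L, zAt), hw,
                       view = "XZ", method = method)
  ringCenter <- c(hw, hw)
  unr <- unrollTube(p2, ringCenter, ringRadius,
                    azimuthOffset = azimuthOffset, method = method)
  list(unrolled = unr, straightened = p2, ringCenter = ringCenter)
}
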