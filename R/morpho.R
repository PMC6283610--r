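# Tube-level morphometrics and subcellular SAR/AFR quantification.

#' Physical length of a traced polyline
#'
#' @param points Nx2 matrix of pixel coordinates (a freehand DT trace,
#'   an embryo-length line, ...).
#' @param pixelSize um per pixel.
#' @param closed logical, close the path back to its first point.
#' @return length in um.
#' @examples
#' polylineLength(rbind(c(0, 0), c(3, 4)))  # 5
#' @export
polylineLength <- function(points, pixelSize = 1, closed = FALSE) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  if (closed) points <- rbind(points, points[1, ])
  polylineArclength(points) * pixelSize
}

#' Dorsal-trunk morphometrics for one embryo
#'
#' Normalizes the traced tube length to the embryo length (the ratio
#' is what makes embryos comparable) and averages exactly three
#' diameter measurements taken along the metamere.
#'
#' @param dtPolyline Nx2 matrix tracing the tube, pixel coords.
#' @param embryoLength embryo length (same pixel units).
#' @param diameters numeric(3) diameter measurements.
#' @param pixelSize um per pixel.
#' @return one-row data.frame: dtLengthUm, embryoLengthUm,
#'   lengthRatio, diameterUm.
#' @examples
#' dtMetrics(rbind(c(0, 0), c(180, 0)), 400, c(4.8, 5.0, 5.2))
#' @export
dtMetrics <- function(dtPolyline, embryoLength, diameters,
                      pixelSize = 1) {
  if (length(diameters) != 3L) {
    stop("diameter is defined as the mean of exactly 3 measurements")
  }
  stopifnot(embryoLength > 0)
  dtLen <- polylineLength(dtPolyline, pixelSize)
  data.frame(dtLengthUm = dtLen,
             embryoLengthUm = embryoLength * pixelSize,
             lengthRatio = dtLen / (embryoLength * pixelSize),
             diameterUm = mean(diameters) * pixelSize)
}

#' Percent change of a condition relative to control
#'
#' @param conditionMean,controlMean group means; control must be
#'   positive.
#' @return 100 * (condition - control) / control (negative =
#'   shrinkage).
#' @examples
#' percentChange(0.67, 1.0)   # -33
#' @export
percentChange <- function(conditionMean, controlMean) {
  stopifnot(controlMean > 0)
  100 * (conditionMean - controlMean) / controlMean
}

#' SAR/AFR subcellular accumulation of one cell
#'
#' On a sum projection, the subapical region (SAR) signal is the mean
#' intensity within a `bandWidth`-pixel band centred on the traced
#' cell contour, and the apical free region (AFR) signal the mean
#' intensity of the cell interior excluding that band (the band's
#' inner edge is not part of the AFR). Means make the ratio
#' comparable across cell sizes and give exactly 1 on a uniform
#' image; `total` (band-integrated SAR plus region-integrated AFR)
#' supports absolute cross-genotype comparisons.
#'
#' @param image numeric matrix (sum projection), (x, y).
#' @param contour Nx2 closed polygon, 0-based pixel coords.
#' @param bandWidth band width in pixels (default 6).
#' @return one-row data.frame: sar, afr, ratio, total, nBandPx,
#'   nInteriorPx.
#' @examples
#' img <- matrix(1, 40, 40)
#' poly <- rbind(c(10, 10), c(30, 10), c(30, 30), c(10, 30))
#' sarAfr(img, poly)$ratio   # 1
#' @export
sarAfr <- function(image, contour, bandWidth = 6L) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3L) stop("contour needs at least 3 vertices")
  nx <- nrow(image); ny <- ncol(image)
  gx <- rep(seq_len(nx) - 1L, times = ny)
  gy <- rep(seq_len(ny) - 1L, each = nx)
  bb <- apply(contour, 2, range)
  near <- gx >= bb[1, 1] - bandWidth & gx <= bb[2, 1] + bandWidth &
    gy >= bb[1, 2] - bandWidth & gy <= bb[2, 2] + bandWidth
  band <- logical(length(gx))
  band[near] <- distToEdges(gx[near], gy[near], contour,
                            closed = TRUE) <= bandWidth / 2
  interior <- logical(length(gx))
  interior[near] <- pointInPolygon(gx[near], gy[near], contour)
  interior <- interior & !band
  if (!any(interior)) {
    stop("band consumes the whole cell: no interior left")
  }
  vals <- as.vector(image)
  sar <- mean(vals[band])
  afr <- mean(vals[interior])
  data.frame(sar = sar, afr = afr, ratio = sar / afr,
             total = sum(vals[band]) + sum(vals[interior]),
             nBandPx = sum(band), nInteriorPx = sum(interior))
}
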