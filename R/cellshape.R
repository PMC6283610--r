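# Apical cell morphometry on the unrolled plane.

#' Area of a traced cell polygon
#'
#' Shoelace area of a simple polygon scaled by the pixel area.
#' Polygons crossing the azimuthal seam are traced in replicated
#' coordinates (columns beyond the base width), which this formula
#' handles without modification.
#'
#' @param polygon Nx2 matrix of vertices (pixel coordinates).
#' @param pixelSize um per pixel.
#' @return area in um^2 (um^2 per px^2 scaling by `pixelSize^2`).
#' @examples
#' polygonArea(rbind(c(0, 0), c(4, 0), c(0, 3)))  # 6
#' @export
polygonArea <- function(polygon, pixelSize = 1) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  if (polygonSelfIntersects(polygon)) {
    stop("polygon is self-intersecting")
  }
  abs(polygonAreaSigned(polygon)) * pixelSize^2
}

#' Long-axis orientation of a cell
#'
#' Fits the second-moment (inertia-equivalent) ellipse of a polygon
#' or binary mask and returns the orientation of its long axis, in
#' degrees within [0, 180), measured from the horizontal
#' (circumferential) axis of the unrolled plane - so 90 degrees means
#' a longitudinally elongated cell. Shapes with eccentricity below
#' 0.1 (near-circular) are flagged orientation-indeterminate.
#'
#' @param shape Nx2 polygon matrix, or a logical/0-1 matrix mask.
#' @return list(phi, eccentricity, indeterminate).
#' @examples
#' rect <- rbind(c(0, 0), c(2, 0), c(2, 10), c(0, 10))
#' fitOrientation(rect)$phi   # 90: elongated vertically
#' @export
fitOrientation <- function(shape) {
  isPolygon <- is.matrix(shape) && !is.logical(shape) &&
    ncol(shape) == 2L && nrow(shape) >= 3L
  if (isPolygon) {
    mom <- polygonMoments(shape)
    if (mom$area <= 0) stop("degenerate polygon (zero area)")
    o <- momentsOrientation(mom$mxx, mom$myy, mom$mxy)
  } else {
    idx <- which(shape > 0, arr.ind = TRUE)
    if (!nrow(idx)) stop("empty mask")
    # mask rows index the vertical (longitudinal) axis: y = row,
    # x = column
    x <- idx[, 2]; y <- idx[, 1]
    o <- momentsOrientation(stats::var(x) * (length(x) - 1) / length(x),
                            stats::var(y) * (length(y) - 1) / length(y),
                            stats::cov(x, y) * (length(x) - 1) / length(x))
  }
  list(phi = o$phi, eccentricity = o$eccentricity,
       indeterminate = o$eccentricity < 0.1)
}

#' Orientation interval (I-VI) of a cell angle
#'
#' Angles of 180 degrees or more are reduced by 180 (a cell oriented
#' at 200 degrees is indistinguishable from one at 20), then binned
#' into six 30-degree intervals: \[0,30) I, \[30,60) II, \[60,90)
#' III, \[90,120) IV, \[120,150) V, \[150,180) VI.
#'
#' @param phi angle(s) in degrees, [0, 360).
#' @return factor with levels I-VI.
#' @examples
#' binOrientation(c(15, 95, 200))
#' @export
binOrientation <- function(phi) {
  phi <- phi %% 180
  lv <- c("I", "II", "III", "IV", "V", "VI")
  factor(lv[pmin(floor(phi / 30), 5) + 1L], levels = lv)
}

#' Frequencies of the six orientation intervals
#'
#' @param phis vector of cell angles, degrees.
#' @return named numeric(6), fractions per interval (the radial-chart
#'   table).
#' @examples
#' orientationHistogram(c(10, 100, 110, 170))
#' @export
orientationHistogram <- function(phis) {
  tab <- table(binOrientation(phis))
  as.numeric(tab) / length(phis) -> fr
  setNames(fr, names(tab))
}

#' Measure cells on an unrolled label image
#'
#' Takes an unrolled image whose pixel values are integer cell labels
#' (see [renderLabelVolume()]) and measures each cell's area,
#' orientation and interval. Measurement uses the replicated image:
#' for each label the largest connected component not touching a
#' vertical image edge is selected, so cells crossing the azimuthal
#' seam are measured in one piece and results do not depend on the
#' azimuthal origin of the ring.
#'
#' @param img An [UnrolledImage-class] with replication 2 and integer
#'   labels (NA pixels are treated as background).
#' @return data.frame: id, areaUm2, phiDeg, eccentricity, interval,
#'   indeterminate.
#' @export
measureUnrolledCells <- function(img) {
  stopifnot(is(img, "UnrolledImage"))
  lab <- img@data
  lab[is.na(lab)] <- 0
  ids <- sort(setdiff(unique(as.vector(lab)), 0))
  rows <- lapply(ids, function(id) {
    cc <- EBImage::bwlabel(lab == id)
    ncc <- max(cc)
    sizes <- tabulate(cc[cc > 0], nbins = ncc)
    touches <- vapply(seq_len(ncc), function(k) {
      any(cc[, 1] == k) || any(cc[, ncol(cc)] == k)
    }, logical(1))
    pick <- if (any(!touches)) {
      which(!touches)[which.max(sizes[!touches])]
    } else {
      which.max(sizes)
    }
    mask <- cc == pick
    fo <- fitOrientation(mask)
    data.frame(id = id, areaUm2 = sizes[pick] * img@pixelSize^2,
               phiDeg = fo$phi, eccentricity = fo$eccentricity,
               interval = as.character(binOrientation(fo$phi)),
               indeterminate = fo$indeterminate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
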