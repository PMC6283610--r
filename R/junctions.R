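# Junction orientation classification and band intensity measurement.

#' Fold an angle into [0, 90] degrees
#'
#' Junction orientation is symmetric under reversal and reflection, so
#' angles are folded as min(theta mod 180, 180 - theta mod 180).
#'
#' @param theta angle(s) in degrees (any real value).
#' @return folded angle(s) in [0, 90].
#' @examples
#' foldAngle(c(15, 172, 270))
#' @export
foldAngle <- function(theta) {
  m <- theta %% 180
  pmin(m, 180 - m)
}

#' Classify folded junction angles into LCJ / TCJ / unassigned
#'
#' Junctions within 30 degrees of the tube's longitudinal axis are
#' longitudinal cell junctions (LCJ), those within 30 degrees of the
#' circumferential direction transverse (TCJ); the band boundaries 30
#' and 60 degrees are inclusive. Oblique junctions in between are
#' unassigned and excluded from the anisotropy ratio.
#'
#' @param thetaF folded angle(s) in [0, 90] (see [foldAngle()]).
#' @return character vector: "LCJ", "TCJ" or "unassigned".
#' @examples
#' classifyAngle(c(15, 30, 45, 60, 90))
#' @export
classifyAngle <- function(thetaF) {
  ifelse(thetaF <= 30, "LCJ", ifelse(thetaF >= 60, "TCJ", "unassigned"))
}

#' Orientation and class of a junction polyline
#'
#' The orientation is taken from the end-to-end chord of the polyline
#' (what a protractor measurement of a short, gently curved junction
#' gives), relative to the longitudinal tube axis.
#'
#' @param polyline Nx2 matrix of (x, y) points, N >= 2.
#' @param axisAngle angle of the tube axis in the image, degrees
#'   (default 0 = axis along +x).
#' @return list(angleDeg = folded angle, class = classification).
#' @examples
#' foldAndClassify(rbind(c(0, 0), c(10, 0)))        # along the axis
#' foldAndClassify(rbind(c(0, 0), c(0, 5)))         # transverse
#' @export
foldAndClassify <- function(polyline, axisAngle = 0) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("polyline needs at least 2 points")
  d <- polyline[nrow(polyline), ] - polyline[1, ]
  if (all(d == 0)) stop("zero-length chord; orientation undefined")
  theta <- atan2(d[2], d[1]) * 180 / pi - axisAngle
  thetaF <- foldAngle(theta)
  list(angleDeg = thetaF, class = classifyAngle(thetaF))
}

#' Integrated intensity over a fixed-width band along a polyline
#'
#' Approximates the "raw integrated density" of a junction traced with
#' a `widthPx`-pixel-wide line: the image is sampled bilinearly at
#' unit-arclength spacing along the polyline and at `widthPx`
#' unit-spaced perpendicular offsets (-2..2 for the default width 5),
#' and the samples are summed scaled by the arclength step. On a
#' constant image the result is value * length * width exactly.
#'
#' @param image numeric matrix (x, y).
#' @param polyline Nx2 matrix of 0-based pixel coordinates.
#' @param widthPx band width in pixels (odd; default 5).
#' @param id junction identifier used in error messages.
#' @return integrated intensity (counts).
#' @examples
#' img <- matrix(7, 20, 20)
#' bandIntegratedDensity(img, rbind(c(5, 10), c(15, 10)))  # 350
#' @export
bandIntegratedDensity <- function(image, polyline, widthPx = 5L,
                                  id = "junction") {
  stopifnot(widthPx >= 1L)
  rs <- resamplePolylineMid(as.matrix(polyline), spacing = 1)
  offs <- seq_len(widthPx) - (widthPx + 1) / 2
  nrm <- cbind(-rs$tangent[, 2], rs$tangent[, 1])
  tot <- 0
  for (o in offs) {
    px <- rs$pos[, 1] + o * nrm[, 1]
    py <- rs$pos[, 2] + o * nrm[, 2]
    v <- bilinearSample(image, px, py)
    if (anyNA(v)) {
      stop(sprintf("band for %s leaves the image bounds", id))
    }
    tot <- tot + sum(v)
  }
  tot * rs$ds
}

#' Measure a set of junction polylines on a projection
#'
#' Applies [foldAndClassify()] and [bandIntegratedDensity()] to each
#' polyline, producing the per-junction table that downstream pooling
#' uses.
#'
#' @param image numeric projection matrix (x, y).
#' @param polylines named list of Nx2 matrices, 0-based pixel coords.
#' @param axisAngle tube-axis angle in the image, degrees.
#' @param widthPx band width in pixels.
#' @param pixelSize um per pixel (for the um arclength column).
#' @return data.frame: id, class, angleDeg, lengthPx, lengthUm,
#'   rawIntegratedDensity.
#' @export
measureJunctions <- function(image, polylines, axisAngle = 0,
                             widthPx = 5L, pixelSize = 1) {
  ids <- names(polylines)
  if (is.null(ids)) ids <- sprintf("j%03d", seq_along(polylines))
  rows <- lapply(seq_along(polylines), function(i) {
    pl <- as.matrix(polylines[[i]])
    fc <- foldAndClassify(pl, axisAngle)
    len <- polylineArclength(pl)
    rid <- bandIntegratedDensity(image, pl, widthPx, id = ids[i])
    data.frame(id = ids[i], class = fc$class, angleDeg = fc$angleDeg,
               lengthPx = len, lengthUm = len * pixelSize,
               rawIntegratedDensity = rid, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-embryo pooled LCJ/TCJ anisotropy statistics
#'
#' Pools all measured junctions of one embryo by class: the class
#' intensity density is the summed raw integrated density divided by
#' the summed junction length (never an average of per-junction
#' densities), the anisotropy ratio R is the LCJ density over the TCJ
#' density, and the percent difference D = 100 * (densityL -
#' densityT) / densityL (so R = 1.5 corresponds to D of about 33
#' percent). Unassigned (oblique) junctions are excluded from R but
#' counted in `fractionAssigned`.
#'
#' @param measurements per-junction data.frame from
#'   [measureJunctions()] (columns class, lengthPx,
#'   rawIntegratedDensity).
#' @return one-row data.frame: iL, iT, lL, lT, densityL, densityT,
#'   ratio, percentDiff, nLCJ, nTCJ, fractionAssigned.
#' @examples
#' m <- data.frame(class = c("LCJ", "LCJ", "TCJ", "TCJ"),
#'   lengthPx = c(10, 10, 10, 10),
#'   rawIntegratedDensity = c(150, 150, 100, 100))
#' embryoAnisotropy(m)$ratio   # 1.5
#' @export
embryoAnisotropy <- function(measurements) {
  l <- measurements$class == "LCJ"
  t <- measurements$class == "TCJ"
  if (!any(l) || !any(t)) {
    stop("ratio undefined: need at least one LCJ and one TCJ")
  }
  iL <- sum(measurements$rawIntegratedDensity[l])
  iT <- sum(measurements$rawIntegratedDensity[t])
  lL <- sum(measurements$lengthPx[l])
  lT <- sum(measurements$lengthPx[t])
  dL <- iL / lL
  dT <- iT / lT
  data.frame(iL = iL, iT = iT, lL = lL, lT = lT,
             densityL = dL, densityT = dT, ratio = dL / dT,
             percentDiff = 100 * (dL - dT) / dL,
             nLCJ = sum(l), nTCJ = sum(t),
             fractionAssigned = (sum(l) + sum(t)) / nrow(measurements))
}

#' Unpaired two-tailed Student's t-test with significance stars
#'
#' Classical equal-variance two-sample t-test, with the star
#' convention * p < 0.05, ** p < 0.01, *** p < 0.001 ("ns"
#' otherwise). Two identical constant groups have zero pooled
#' variance; p = 1 by convention.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @return list(t, df, p, stars).
#' @examples
#' compareConditions(c(1.5, 1.4, 1.6), c(1.0, 1.1, 0.9))
#' @export
compareConditions <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
  if (sd(groupA) == 0 && sd(groupB) == 0) {
    if (mean(groupA) == mean(groupB)) {
      return(list(t = 0, df = length(groupA) + length(groupB) - 2L,
                  p = 1, stars = "ns"))
    }
    return(list(t = Inf, df = length(groupA) + length(groupB) - 2L,
                p = 0, stars = "***"))
  }
  ht <- t.test(groupA, groupB, var.equal = TRUE)
  p <- ht$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = p,
       stars = stars)
}
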