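#' Intensity projections of a stack
#'
#' `maxProject` takes the per-pixel maximum over the selected z
#' slices (the projection used for junction and apical-area
#' measurements); `sumProject` the per-pixel sum (used for total-level
#' and SAR/AFR measurements).
#'
#' @param volume A [VolumetricImage-class] (3D).
#' @param zRange integer vector of 1-based z slice indices (default:
#'   all slices).
#' @return A numeric matrix indexed (x, y).
#' @examples
#' v <- VolumetricImage(array(seq_len(8), c(2, 2, 2)))
#' maxProject(v)
#' sumProject(v)
#' @export
maxProject <- function(volume, zRange = NULL) {
  arr <- if (is(volume, "VolumetricImage")) volume@data else volume
  if (length(dim(arr)) != 3L) stop("maxProject expects a 3D stack")
  zRange <- checkZRange(zRange, dim(arr)[3])
  out <- arr[, , zRange[1]]
  for (k in zRange[-1]) out <- pmax(out, arr[, , k])
  out
}

#' @rdname maxProject
#' @export
sumProject <- function(volume, zRange = NULL) {
  arr <- if (is(volume, "VolumetricImage")) volume@data else volume
  if (length(dim(arr)) != 3L) stop("sumProject expects a 3D stack")
  zRange <- checkZRange(zRange, dim(arr)[3])
  out <- arr[, , zRange[1]]
  for (k in zRange[-1]) out <- out + arr[, , k]
  out
}

#' Average (mean) projection over z, used for FRAP frames
#' @rdname maxProject
#' @export
meanProject <- function(volume, zRange = NULL) {
  arr <- if (is(volume, "VolumetricImage")) volume@data else volume
  zRange <- checkZRange(zRange, dim(arr)[3])
  sumProject(volume, zRange) / length(zRange)
}

checkZRange <- function(zRange, nz) {
  if (is.null(zRange)) zRange <- seq_len(nz)
  zRange <- as.integer(zRange)
  if (!length(zRange)) stop("empty z range")
  if (any(zRange < 1L | zRange > nz)) stop("z range outside the stack")
  zRange
}

#' Subtract the modal background of an image
#'
#' Estimates the background as the mode of a 256-bin intensity
#' histogram and subtracts it, clipping at zero. Used only for
#' absolute cross-condition level comparisons; within-embryo
#' LCJ/TCJ ratios are computed on unsubtracted projections (any
#' uniform offset enters numerator and denominator alike there,
#' whereas absolute levels need the offset removed).
#'
#' @param image numeric matrix.
#' @return matrix of the same shape, background-subtracted.
#' @examples
#' img <- matrix(10, 5, 5); img[3, 3] <- 100
#' backgroundSubtract(img)[3, 3]
#' @export
backgroundSubtract <- function(image) {
  v <- as.vector(image[is.finite(image)])
  if (!length(v)) return(image)
  rg <- range(v)
  if (rg[1] == rg[2]) return(pmax(image - rg[1], 0))
  br <- seq(rg[1], rg[2], length.out = 257L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), 256L)
  mode <- (br[which.max(h)] + br[which.max(h) + 1L]) / 2
  pmax(image - mode, 0)
}
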