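# FRAP trace extraction, normalization, single-exponential fitting,
# average fits, kymographs and translation drift correction.

#' Integer-pixel translation registration of a movie
#'
#' Finds, for each frame, the integer (x, y) translation maximizing
#' the circular cross-correlation with the first frame (computed by
#' FFT), and shifts the frame back with zero fill. This corrects the
#' xy movement of the embryo during acquisition; sub-pixel or rotational
#' registration is out of scope.
#'
#' @param frames 3D array (x, y, t) or list of matrices.
#' @return list(frames = corrected 3D array, shifts = t x 2 matrix of
#'   the detected per-frame shifts).
#' @export
registerTranslation <- function(frames) {
  if (is.list(frames)) frames <- simplify2array(frames)
  d <- dim(frames)
  if (length(d) != 3L || d[3] < 2L) stop("need >= 2 frames")
  ref <- frames[, , 1]
  fRef <- Conj(fft(ref))
  shifts <- matrix(0L, d[3], 2)
  out <- frames
  for (t in 2:d[3]) {
    cc <- Re(fft(fft(frames[, , t]) * fRef, inverse = TRUE))
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    sx <- pk[1] - 1L
    sy <- pk[2] - 1L
    if (sx > d[1] / 2) sx <- sx - d[1]
    if (sy > d[2] / 2) sy <- sy - d[2]
    shifts[t, ] <- c(sx, sy)
    out[, , t] <- shiftZeroFill(frames[, , t], -sx, -sy)
  }
  list(frames = out, shifts = shifts)
}

shiftZeroFill <- function(m, dx, dy) {
  d <- dim(m)
  out <- matrix(0, d[1], d[2])
  sx <- seq_len(d[1]) - dx
  sy <- seq_len(d[2]) - dy
  okx <- sx >= 1 & sx <= d[1]
  oky <- sy >= 1 & sy <= d[2]
  out[okx, oky] <- m[sx[okx], sy[oky]]
  out
}

#' Extract a FRAP trace from a time-lapse stack
#'
#' For each time point the z sections are averaged (the exported
#' average projection) and the mean intensity inside the ROI polygon
#' is recorded.
#'
#' @param stacks 4D [VolumetricImage-class] (x, y, z, t) or 3D array
#'   (x, y, t) of already-projected frames.
#' @param roi Nx2 polygon, 0-based pixel coordinates.
#' @param nPre number of pre-bleach frames.
#' @param dt frame interval, s.
#' @return A raw [FrapTrace-class].
#' @export
extractTrace <- function(stacks, roi, nPre, dt) {
  arr <- if (is(stacks, "VolumetricImage")) stacks@data else stacks
  d <- dim(arr)
  frames <- if (length(d) == 4L) {
    lapply(seq_len(d[4]), function(t) {
      meanProject(VolumetricImage(arr[, , , t, drop = FALSE][, , , 1],
                                  voxel = c(1, 1, 1)))
    })
  } else if (length(d) == 3L) {
    lapply(seq_len(d[3]), function(t) arr[, , t])
  } else {
    stop("stacks must be (x,y,t) or (x,y,z,t)")
  }
  f1 <- frames[[1]]
  gx <- rep(seq_len(nrow(f1)) - 1L, times = ncol(f1))
  gy <- rep(seq_len(ncol(f1)) - 1L, each = nrow(f1))
  roi <- as.matrix(roi)
  inroi <- pointInPolygon(gx, gy, roi)
  if (!any(inroi)) stop("empty ROI: no pixel centres inside polygon")
  vals <- vapply(frames, function(f) mean(f[inroi]), numeric(1))
  nT <- length(vals)
  FrapTrace(times = (seq_len(nT) - 1L - nPre) * dt, intensities = vals,
            nPre = nPre, normalized = FALSE)
}

#' Normalize a FRAP trace to its pre-bleach mean
#'
#' Divides all intensities by the mean of the pre-bleach samples, so
#' the pre-bleach level is 1. No reference-ROI double normalization
#' and no acquisition-bleaching correction are applied.
#'
#' @param trace A [FrapTrace-class].
#' @return The normalized trace.
#' @export
normalizeTrace <- function(trace) {
  stopifnot(is(trace, "FrapTrace"))
  if (trace@nPre < 1L) stop("need at least 1 pre-bleach frame")
  pre <- mean(trace@intensities[seq_len(trace@nPre)])
  if (pre == 0) stop("zero pre-bleach mean")
  FrapTrace(times = trace@times, intensities = trace@intensities / pre,
            nPre = trace@nPre, normalized = TRUE)
}

#' Fit a single-exponential recovery to a normalized trace
#'
#' Least-squares fit of F(t) = Finf - (Finf - Fb) * exp(-k t) to the
#' post-bleach samples. Starting values: Fb at the first post-bleach
#' sample, Finf at the mean of the last 10 percent of samples, k at
#' ln(2) * 4 / T. The mobile fraction is Mf = (Finf - Fb) /
#' (Fpre - Fb) with Fpre = 1, and tHalf = ln(2) / k. A trace whose
#' post-bleach samples are flat returns Mf = 0 with flag "flat";
#' non-convergence and Mf > 1 are flagged; a non-positive fitted rate
#' is rejected.
#'
#' @param trace normalized [FrapTrace-class] with >= 3 pre-bleach and
#'   >= 5 post-bleach frames.
#' @param pinFloor logical; pin Fb to the first post-bleach sample
#'   instead of fitting it (two-parameter variant).
#' @return A [FrapFit-class].
#' @examples
#' tr <- simulateFrapTrace(0.6, 40, 0.2, noiseSD = 0)
#' fit <- fitRecovery(tr)
#' c(fit@mf, fit@tHalf)
#' @export
fitRecovery <- function(trace, pinFloor = FALSE) {
  stopifnot(is(trace, "FrapTrace"))
  if (!trace@normalized) stop("normalize the trace first")
  if (trace@nPre < 3L) stop("need >= 3 pre-bleach frames")
  post <- trace@times >= 0
  t <- trace@times[post]
  y <- trace@intensities[post]
  if (length(t) < 5L) stop("need >= 5 post-bleach frames")

  if (sd(y) < 1e-12) {
    fb <- mean(y)
    return(new("FrapFit", fPre = 1, fB = fb, fInf = fb, k = NA_real_,
               tHalf = NA_real_, mf = 0, rms = sd(y), converged = TRUE,
               flags = "flat", trace = trace))
  }
  fb0 <- y[1]
  finf0 <- mean(y[t >= quantile(t, 0.9)])
  k0 <- log(2) * 4 / max(t)
  fitEnv <- data.frame(t = t, y = y)
  fit <- tryCatch({
    if (pinFloor) {
      minpack.lm::nlsLM(y ~ finf - (finf - fb0) * exp(-k * t),
        data = fitEnv, start = list(finf = finf0, k = k0),
        lower = c(-Inf, 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ finf - (finf - fb) * exp(-k * t),
        data = fitEnv, start = list(finf = finf0, fb = fb0, k = k0),
        lower = c(-Inf, -Inf, 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(new("FrapFit", fPre = 1, fB = fb0, fInf = finf0,
               k = NA_real_, tHalf = NA_real_, mf = NA_real_,
               rms = NA_real_, converged = FALSE,
               flags = "nonconvergence", trace = trace))
  }
  cf <- stats::coef(fit)
  fb <- if (pinFloor) fb0 else unname(cf["fb"])
  finf <- unname(cf["finf"])
  k <- unname(cf["k"])
  flags <- character(0)
  if (k <= 0) flags <- c(flags, "nonpositive-rate")
  mf <- (finf - fb) / (1 - fb)
  if (is.finite(mf) && mf > 1) flags <- c(flags, "mobile-fraction>1")
  if (mf < 0) flags <- c(flags, "negative-mobile-fraction")
  new("FrapFit", fPre = 1, fB = fb, fInf = finf, k = k,
      tHalf = log(2) / k, mf = mf,
      rms = sqrt(mean(stats::resid(fit)^2)),
      converged = !length(flags) || identical(flags, "mobile-fraction>1"),
      flags = flags, trace = trace)
}

#' Evaluate a fitted recovery curve
#' @param fit A [FrapFit-class].
#' @param t times, s (>= 0).
#' @return fitted F(t).
#' @export
predictRecovery <- function(fit, t) {
  if (length(fit@flags) && "flat" %in% fit@flags) {
    return(rep(fit@fB, length(t)))
  }
  fit@fInf - (fit@fInf - fit@fB) * exp(-fit@k * t)
}

#' Average fitted recovery across experiments
#'
#' Evaluates each experiment's fitted curve on a common post-bleach
#' timebase (the overlap of all traces) and returns the pointwise
#' mean and standard deviation - the "average fit" comparison plot.
#'
#' @param fits list of [FrapFit-class] objects (>= 2).
#' @param dt grid spacing, s (default: the first trace's spacing).
#' @return data.frame: time, mean, sd, n.
#' @export
averageFit <- function(fits, dt = NULL) {
  stopifnot(length(fits) >= 2L)
  tmax <- vapply(fits, function(f) max(f@trace@times), numeric(1))
  tEnd <- min(tmax)
  if (tEnd <= 0) stop("disjoint time supports")
  if (is.null(dt)) dt <- mean(diff(fits[[1]]@trace@times))
  tt <- seq(0, tEnd, by = dt)
  curves <- vapply(fits, predictRecovery, numeric(length(tt)), t = tt)
  data.frame(time = tt, mean = rowMeans(curves),
             sd = apply(curves, 1, sd), n = length(fits))
}

#' Kymograph along a line ROI
#'
#' Stacks the bilinear intensity profile along a line, one column per
#' frame, after optional Gaussian denoising of each frame: the
#' horizontal axis is time and the vertical axis distance along the
#' line.
#'
#' @param frames 3D array (x, y, t) or list of matrices.
#' @param lineRoi 2x2 matrix: start and end point, 0-based pixels.
#' @param smoothingSigma Gaussian sigma in pixels (0 = no smoothing).
#' @return matrix (distance x time).
#' @export
kymograph <- function(frames, lineRoi, smoothingSigma = 1) {
  if (is.list(frames)) frames <- simplify2array(frames)
  d <- dim(frames)
  lineRoi <- as.matrix(lineRoi)
  rs <- resamplePolylineMid(lineRoi, spacing = 1)
  out <- matrix(NA_real_, rs$n, d[3])
  for (t in seq_len(d[3])) {
    f <- frames[, , t]
    if (smoothingSigma > 0) f <- gaussBlur(f, smoothingSigma)
    prof <- bilinearSample(f, rs$pos[, 1], rs$pos[, 2])
    if (anyNA(prof)) stop("line ROI leaves the frame")
    out[, t] <- prof
  }
  out
}
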