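#' Simulate a time-lapse stack of an elongating tube
#'
#' Renders one noiseless-geometry frame per time point, stretching the
#' tube length linearly so the final/initial axis-length ratio is `1 +
#' elongation`; an optional rigid per-frame drift (voxels, applied in
#' x and y) emulates embryo movement. Frames share a common canvas so
#' the stack is a single 4D array. The ground truth (per-frame axis
#' length and applied drift) is attached as attribute `groundTruth` of
#' the returned image.
#'
#' @param spec A [TubeSpec-class]; its `length` is the initial length.
#' @param nFrames number of time points.
#' @param elongation total fractional elongation over the movie.
#' @param drift numeric(2) integer-voxel drift per frame (x, y).
#' @param noise logical, add the spec's noise model per frame.
#' @return A 4D [VolumetricImage-class] (x, y, z, t) with attribute
#'   `groundTruth`: data.frame(frame, axisLengthUm, driftX, driftY).
#' @examples
#' ts <- simulateTimeseries(tubeSpec(length = 15, nRings = 3L,
#'   nAround = 4L, seed = 5L), nFrames = 3, elongation = 0.3)
#' attr(ts, "groundTruth")$axisLengthUm
#' @export
simulateTimeseries <- function(spec, nFrames = 5L, elongation = 0,
                               drift = c(0, 0), noise = FALSE) {
  stopifnot(nFrames >= 1L)
  drift <- round(drift)
  lens <- if (nFrames == 1L) spec@length else
    spec@length * (1 + elongation * (seq_len(nFrames) - 1L) / (nFrames - 1L))
  pad <- 4 * spec@psfSigma + 4 * max(spec@voxel)
  maxShift <- abs(drift) * (nFrames - 1L)
  frames <- vector("list", nFrames)
  for (t in seq_len(nFrames)) {
    sp <- spec
    sp@length <- lens[t]
    # same seed for all frames: the same cells (and the same per-
    # junction densities) stretch over time; only the noise varies
    g <- assignIntensities(tessellateTube(sp), sp)
    spNoise <- sp
    spNoise@seed <- sp@seed + 101L * t
    frames[[t]] <- renderVolume(g, spNoise, noise = noise, pad = pad)
  }
  # common canvas sized for the longest frame plus drift travel
  dims <- Reduce(pmax, lapply(frames, function(f) dim(f@data)))
  dims[1] <- dims[1] + maxShift[1]
  dims[2] <- dims[2] + maxShift[2]
  arr <- array(0, c(dims, nFrames))
  gt <- data.frame(frame = seq_len(nFrames), axisLengthUm = lens,
                   driftX = drift[1] * (seq_len(nFrames) - 1L),
                   driftY = drift[2] * (seq_len(nFrames) - 1L))
  for (t in seq_len(nFrames)) {
    d <- dim(frames[[t]]@data)
    ox <- gt$driftX[t] + if (drift[1] < 0) maxShift[1] else 0L
    oy <- gt$driftY[t] + if (drift[2] < 0) maxShift[2] else 0L
    arr[ox + seq_len(d[1]), oy + seq_len(d[2]), seq_len(d[3]), t] <-
      frames[[t]]@data
  }
  out <- VolumetricImage(arr, voxel = spec@voxel,
                         origin = frames[[1]]@origin)
  attr(out, "groundTruth") <- gt
  out
}
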