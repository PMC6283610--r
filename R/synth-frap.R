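#' Simulate a FRAP recovery trace
#'
#' Generates a normalized single-exponential recovery: `nPre`
#' pre-bleach frames at 1, then, with t measured from the first
#' post-bleach frame, F(t) = Fb + Mf * (1 - Fb) * (1 - 2^(-t /
#' tHalf)), plus additive Gaussian noise. The asymptote is Fb + Mf *
#' (1 - Fb) and F(tHalf) sits halfway between floor and asymptote.
#'
#' @param mf mobile fraction in [0, 1].
#' @param tHalf recovery half-time, s.
#' @param bleachFloor normalized intensity immediately after the
#'   bleach, in [0, 1).
#' @param nPre number of pre-bleach frames.
#' @param dt frame interval, s.
#' @param duration post-bleach duration, s.
#' @param noiseSD additive Gaussian noise sd (normalized units).
#' @param seed integer seed.
#' @return A normalized [FrapTrace-class].
#' @examples
#' tr <- simulateFrapTrace(mf = 0.6, tHalf = 40, bleachFloor = 0.2,
#'   noiseSD = 0, seed = 1L)
#' tr@intensities[tr@nPre + 5L]   # F(40 s) = 0.44
#' @export
simulateFrapTrace <- function(mf, tHalf, bleachFloor = 0.2, nPre = 10L,
                              dt = 10, duration = 600, noiseSD = 0.02,
                              seed = 1L) {
  stopifnot(mf >= 0, mf <= 1, tHalf > 0, dt > 0,
            bleachFloor >= 0, bleachFloor < 1)
  nPost <- floor(duration / dt) + 1L
  tPre <- -rev(seq_len(nPre)) * dt
  tPost <- (seq_len(nPost) - 1L) * dt
  f <- c(rep(1, nPre),
         bleachFloor + mf * (1 - bleachFloor) * (1 - 2^(-tPost / tHalf)))
  if (noiseSD > 0) {
    f <- f + withSeed(seed, rnorm(length(f), 0, noiseSD))
  }
  FrapTrace(times = c(tPre, tPost), intensities = f, nPre = nPre,
            normalized = TRUE)
}
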