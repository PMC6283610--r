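test_that("translation registration recovers constructed shifts", {
  withr::with_seed(4, base <- tubeaniso:::gaussBlur(
    matrix(rnorm(64 * 48), 64, 48), 2))
  frames <- array(0, c(64, 48, 3))
  frames[, , 1] <- base
  frames[, , 2] <- tubeaniso:::shiftZeroFill(base, 3, -2)
  frames[, , 3] <- tubeaniso:::shiftZeroFill(base, 6, -4)
  reg <- registerTranslation(frames)
  expect_equal(reg$shifts, rbind(c(0, 0), c(3, -2), c(6, -4)))
  # correction restores the reference in the overlap
  expect_equal(reg$frames[10:50, 10:40, 2], base[10:50, 10:40])
  # identical frames: zero shifts
  same <- array(rep(base, 3), c(64, 48, 3))
  expect_true(all(registerTranslation(same)$shifts == 0))
})

test_that("shift recovery is exact over repeated noisy draws", {
  # SNR >= 5, 50 replicates
  withr::with_seed(11, {
    ok <- vapply(seq_len(50), function(i) {
      base <- tubeaniso:::gaussBlur(matrix(rnorm(48 * 48), 48, 48), 2)
      base <- base / stats::sd(base)
      sh <- c(sample(-5:5, 1), sample(-5:5, 1))
      noisy <- tubeaniso:::shiftZeroFill(base, sh[1], sh[2]) +
        matrix(rnorm(48 * 48, sd = 0.2), 48, 48)
      all(registerTranslation(
        simplify2array(list(base, noisy)))$shifts[2, ] == sh)
    }, logical(1))
    expect_true(all(ok))
  })
})

test_that("trace extraction averages the ROI on mean z-projections", {
  arr <- array(9, c(12, 12, 4, 3))
  roi <- rbind(c(2, 2), c(9, 2), c(9, 9), c(2, 9))
  tr <- extractTrace(arr, roi, nPre = 1L, dt = 10)
  expect_true(all(tr@intensities == 9))
  expect_equal(tr@times, c(-10, 0, 10))
  # two equal slices average to the slice value
  arr2 <- array(0, c(8, 8, 2, 2))
  withr::with_seed(6, sl <- matrix(runif(64), 8, 8))
  arr2[, , 1, ] <- sl
  arr2[, , 2, ] <- sl
  tr2 <- extractTrace(arr2, rbind(c(1, 1), c(6, 1), c(6, 6), c(1, 6)),
                      nPre = 1L, dt = 1)
  inroi <- tubeaniso:::pointInPolygon(rep(0:7, 8), rep(0:7, each = 8),
    rbind(c(1, 1), c(6, 1), c(6, 6), c(1, 6)))
  expect_equal(tr2@intensities[1], mean(sl[matrix(inroi, 8, 8)]))
  expect_error(extractTrace(arr, rbind(c(30, 30), c(31, 30),
    c(31, 31), c(30, 31)), 1L, 1), "empty ROI")
})

test_that("extracted traces follow the generator's recovery", {
  # frames whose bleached disc recovers with known kinetics
  tr0 <- simulateFrapTrace(mf = 0.7, tHalf = 30, bleachFloor = 0.25,
                           nPre = 5L, dt = 5, duration = 300,
                           noiseSD = 0, seed = 2L)
  nT <- length(tr0@times)
  frames <- array(100, c(20, 20, 2, nT))
  for (t in seq_len(nT)) {
    frames[6:14, 6:14, , t] <- 100 * tr0@intensities[t]
  }
  roi <- rbind(c(7, 7), c(13, 7), c(13, 13), c(7, 13))
  tr <- normalizeTrace(extractTrace(frames, roi, nPre = 5L, dt = 5))
  expect_equal(tr@intensities, tr0@intensities, tolerance = 1e-12)
})

test_that("normalization divides by the pre-bleach mean only", {
  tr <- FrapTrace(times = seq(-30, 50, by = 10),
                  intensities = c(200, 210, 190, 40, 60, 80, 90, 100, 110),
                  nPre = 3L)
  nt <- normalizeTrace(tr)
  expect_equal(mean(nt@intensities[1:3]), 1)
  expect_equal(nt@intensities[4], 40 / 200)
  expect_true(nt@normalized)
  # a generator trace is already normalized: unchanged
  sim <- simulateFrapTrace(0.5, 20, noiseSD = 0)
  expect_equal(normalizeTrace(sim)@intensities, sim@intensities)
  bad <- FrapTrace(times = c(-1, 0, 1), intensities = c(0, 1, 1),
                   nPre = 1L)
  expect_error(normalizeTrace(bad), "zero pre-bleach mean")
})

test_that("noiseless fits invert the generator", {
  tr <- simulateFrapTrace(mf = 0.6, tHalf = 40, bleachFloor = 0.2,
                          nPre = 10L, dt = 10, duration = 600,
                          noiseSD = 0)
  fit <- fitRecovery(tr)
  expect_equal(fit@mf, 0.6, tolerance = 1e-6)
  expect_equal(fit@tHalf, 40, tolerance = 1e-6)
  expect_equal(fit@fB, 0.2, tolerance = 1e-6)
  expect_true(fit@converged)
  # pinned-floor variant also inverts a noiseless trace
  fitPin <- fitRecovery(tr, pinFloor = TRUE)
  expect_equal(fitPin@mf, 0.6, tolerance = 1e-6)
  # flat post-bleach trace: immobile
  flat <- simulateFrapTrace(mf = 0, tHalf = 40, bleachFloor = 0.3,
                            noiseSD = 0)
  ffit <- fitRecovery(flat)
  expect_equal(ffit@mf, 0)
  expect_true("flat" %in% ffit@flags)
})

test_that("the mobile fraction is invariant under intensity gain", {
  tr <- simulateFrapTrace(mf = 0.45, tHalf = 25, bleachFloor = 0.15,
                          noiseSD = 0.01, seed = 12L)
  gained <- FrapTrace(times = tr@times,
                      intensities = tr@intensities * 537.2,
                      nPre = tr@nPre)
  f1 <- fitRecovery(normalizeTrace(gained))
  f0 <- fitRecovery(normalizeTrace(
    FrapTrace(tr@times, tr@intensities, tr@nPre)))
  expect_equal(f1@mf, f0@mf, tolerance = 1e-8)
  expect_equal(f1@tHalf, f0@tHalf, tolerance = 1e-8)
})

test_that("parameter recovery is calibrated on noisy traces", {
  withr::with_seed(21, seeds <- sample.int(1e6, 40))
  fits <- lapply(seeds, function(s) {
    fitRecovery(simulateFrapTrace(mf = 0.6, tHalf = 40,
      bleachFloor = 0.2, nPre = 10L, dt = 10, duration = 600,
      noiseSD = 0.02, seed = s))
  })
  mfs <- vapply(fits, function(f) f@mf, numeric(1))
  ths <- vapply(fits, function(f) f@tHalf, numeric(1))
  expect_lt(abs(median(mfs) - 0.6), 0.05)
  expect_lt(abs(median(ths) - 40) / 40, 0.10)
})

test_that("average fits pool fitted curves pointwise", {
  t1 <- simulateFrapTrace(0.4, 30, 0.2, noiseSD = 0)
  t2 <- simulateFrapTrace(0.8, 30, 0.2, noiseSD = 0)
  f1 <- fitRecovery(t1)
  f2 <- fitRecovery(t2)
  # identical fits: zero dispersion
  same <- averageFit(list(f1, f1))
  expect_true(all(same$sd < 1e-10))
  # linearity: the mean asymptote is the midpoint of the asymptotes
  avg <- averageFit(list(f1, f2))
  expect_equal(tail(avg$mean, 1),
               0.2 + 0.6 * 0.8, tolerance = 1e-3)
  expect_equal(avg$time[2] - avg$time[1], 10)
})

test_that("kymographs stack per-frame line profiles over time", {
  withr::with_seed(8, img <- tubeaniso:::gaussBlur(
    matrix(rnorm(40 * 30), 40, 30), 2))
  frames <- array(rep(img, 4), c(40, 30, 4))
  line <- rbind(c(5, 15), c(35, 15))
  ky <- kymograph(frames, line, smoothingSigma = 0)
  expect_equal(ncol(ky), 4L)
  for (t in 2:4) expect_identical(ky[, t], ky[, 1])
  # sigma 0 returns the raw bilinear profile
  rs <- tubeaniso:::resamplePolylineMid(line, 1)
  expect_equal(ky[, 1],
               tubeaniso:::bilinearSample(img, rs$pos[, 1], rs$pos[, 2]))
  # a recovering bleached spot brightens in place: darkest column
  # early, no lateral displacement of the dark band centre
  tr <- simulateFrapTrace(0.8, 20, 0.1, nPre = 2L, dt = 5,
                          duration = 100, noiseSD = 0)
  nT <- length(tr@times)
  fr2 <- array(1, c(40, 30, nT))
  for (t in seq_len(nT)) {
    fr2[16:24, , t] <- tr@intensities[t]
  }
  ky2 <- kymograph(fr2, rbind(c(2, 15), c(37, 15)), smoothingSigma = 1)
  dip <- apply(ky2, 2, which.min)
  # dark band stays within the bleached stripe (no lateral spread);
  # ties on the flat dip floor may move the argmin within it
  expect_true(all(dip[3:nT] >= 13 & dip[3:nT] <= 25))
  expect_true(all(diff(apply(ky2, 2, min))[3:(nT - 1)] > 0))
})
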