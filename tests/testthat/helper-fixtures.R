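# Shared fixtures: small, fast synthetic scenes.

# A coarse, quick-to-render tube for unit tests (not the study
# conditions; those use the tubeSpec() defaults).
smallSpec <- function(...) {
  args <- modifyList(
    list(radius = 3, length = 10, nRings = 2L, nAround = 4L,
         psfSigma = 0.3, baseIntensity = 1000,
         voxel = c(0.25, 0.25, 0.25), seed = 101L),
    list(...))
  do.call(tubeSpec, args)
}

# Smooth random test image: white noise blurred to a given scale.
smoothImage <- function(nx, ny, sigma = 3, seed = 1L, offset = 10) {
  withr::with_seed(seed, {
    img <- matrix(rnorm(nx * ny), nx, ny)
  })
  tubeaniso:::gaussBlur(img, sigma) * 50 + offset
}

# Cylindrical-shell intensity volume built directly from its formula
# (no renderer): value = exp(-(dist_to_axis - r)^2 / (2 s^2)).
shellVolume <- function(r = 4, L = 12, px = 0.25, s = 0.3, pad = 2,
                        marker = NULL) {
  nx <- round(L / px) + 1L
  half <- r + pad
  nyz <- 2L * round(half / px) + 1L
  cy <- (nyz - 1) / 2
  yy <- ((seq_len(nyz) - 1) - cy) * px
  arr <- array(0, c(nx, nyz, nyz))
  cross <- outer(yy, yy, function(y, z) {
    exp(-(sqrt(y^2 + z^2) - r)^2 / (2 * s^2))
  })
  for (i in seq_len(nx)) arr[i, , ] <- cross
  if (!is.null(marker)) {
    # bright blob on the shell at azimuth marker$az (degrees), mid-length
    ang <- marker$az * pi / 180
    my <- r * sin(ang)
    mz <- r * cos(ang)
    bump <- outer(yy, yy, function(y, z) {
      3 * exp(-((y - my)^2 + (z - mz)^2) / (2 * (2 * s)^2))
    })
    mid <- round(nx / 2)
    for (i in (mid - 2):(mid + 2)) arr[i, , ] <- arr[i, , ] + bump
  }
  VolumetricImage(arr, voxel = rep(px, 3),
                  origin = c(0, -half, -half))
}

# Random star-shaped simple polygon around a centre (for area/moment
# oracles).
starPolygon <- function(n = 12, rMin = 3, rMax = 8, seed = 1L,
                        center = c(10, 10)) {
  withr::with_seed(seed, {
    ang <- sort(runif(n, 0, 2 * pi))
    rad <- runif(n, rMin, rMax)
  })
  cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
}
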