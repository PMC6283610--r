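# Rendering of synthetic confocal stacks from a JunctionGraph.
#
# Junction polylines are splatted as line sources at 3x sub-voxel
# supersampling (removing rasterization bias from the flux budget),
# convolved with an isotropic Gaussian PSF, then corrupted with shot
# noise (variance = shotScale * signal) and additive Gaussian read
# noise. Counts are conserved by construction: before noise, the voxel
# sum equals sum(density * length) over junctions up to PSF tails
# clipped at the padded border.

#' Render a synthetic confocal stack of the tube
#'
#' @param graph A [JunctionGraph-class] with densities assigned.
#' @param spec The [TubeSpec-class] controlling voxel size, PSF and
#'   noise (defaults to the one stored in the graph).
#' @param noise logical; set `FALSE` for a noiseless stack (flux
#'   oracle, registration fixtures).
#' @param pad extra physical padding around the geometry, um.
#' @return A [VolumetricImage-class]; intensities are counts per voxel.
#' @examples
#' g <- assignIntensities(tessellateTube(tubeSpec(seed = 2L)))
#' v <- renderVolume(g, noise = FALSE)
#' @export
renderVolume <- function(graph, spec = graph@spec, noise = TRUE,
                         pad = NULL) {
  if (anyNA(graph@junctions$density)) {
    stop("junction densities unset; run assignIntensities() first")
  }
  vox <- spec@voxel
  psf <- rep(spec@psfSigma, length.out = 3)
  if (any(psf < 0.5 * vox)) {
    warning("psfSigma below 0.5 voxel; rendering may alias")
  }
  if (is.null(pad)) pad <- 4 * max(psf) + 4 * max(vox)
  gr <- sceneGrid(graph, vox, pad)
  dims <- gr$dims
  origin <- gr$origin

  arr <- array(0, dims)
  ds <- min(vox) / 3
  # supersampled splat positions and weights for all junctions at once
  pos <- list()
  wts <- list()
  for (i in seq_along(graph@polylines3D)) {
    rs <- resamplePolylineMid(graph@polylines3D[[i]], spacing = ds)
    pos[[i]] <- rs$pos
    wts[[i]] <- rep(graph@junctions$density[i] * rs$ds, rs$n)
  }
  p <- do.call(rbind, pos)
  wt <- unlist(wts)
  cx <- (p[, 1] - origin[1]) / vox[1]
  cy <- (p[, 2] - origin[2]) / vox[2]
  cz <- (p[, 3] - origin[3]) / vox[3]
  x0 <- floor(cx); fx <- cx - x0
  y0 <- floor(cy); fy <- cy - y0
  z0 <- floor(cz); fz <- cz - z0
  flat <- numeric(prod(dims))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wcorner <- wt *
      (if (dx) fx else 1 - fx) *
      (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    idx <- ((z0 + dz) * dims[2] + (y0 + dy)) * dims[1] + (x0 + dx) + 1
    acc <- rowsum(wcorner, idx)
    flat[as.integer(rownames(acc))] <- flat[as.integer(rownames(acc))] +
      acc[, 1]
  }
  arr <- array(flat, dims)

  arr <- gaussBlur(arr, psf / vox)

  if (noise) {
    readSD <- spec@readSD
    if (is.na(readSD)) readSD <- 0.02 * peakLineAmplitude(spec)
    arr <- withSeed(spec@seed + 2L, {
      n <- length(arr)
      shot <- if (spec@shotScale > 0) {
        rnorm(n, 0, sqrt(pmax(arr, 0) * spec@shotScale))
      } else 0
      read <- if (readSD > 0) rnorm(n, 0, readSD) else 0
      arr + shot + read
    })
    arr <- array(arr, dims)
  }
  VolumetricImage(arr, voxel = vox, origin = origin)
}

# Voxel grid covering the scene geometry plus padding. The origin is
# anchored to integer multiples of the voxel size so that scene
# coordinate 0 falls exactly on a voxel centre on every axis (a
# straight tube's axis then samples at voxel centres, which keeps
# nearest-neighbour resampling well-posed).
sceneGrid <- function(graph, vox, pad) {
  allPts <- do.call(rbind, graph@polylines3D)
  lo <- apply(allPts, 2, min)
  hi <- apply(allPts, 2, max)
  origin <- vox * floor((lo - pad) / vox)
  dims <- pmax(2L, as.integer(ceiling((hi + pad - origin) / vox)) + 1L)
  list(origin = origin, dims = dims)
}

# Ideal peak voxel amplitude of an infinite straight line source of
# density baseIntensity blurred by the PSF; the reference for the
# default read-noise level.
peakLineAmplitude <- function(spec) {
  psf <- sort(rep(spec@psfSigma, length.out = 3))
  spec@baseIntensity * prod(spec@voxel) / (2 * pi * psf[1] * psf[2])
}

# Invert the surface embedding: scene points -> (u, v, radial
# distance from the axis). Used to paint label volumes.
surfaceCoords <- function(p, spec) {
  k <- spec@curvature
  r <- spec@radius
  if (k == 0) {
    v <- p[, 1]
    sn <- p[, 2]
    sb <- p[, 3]
  } else {
    Rc <- 1 / k
    alpha <- atan2(p[, 1], Rc - p[, 2])
    v <- alpha / k
    ax <- cbind(sin(alpha) * Rc, (1 - cos(alpha)) * Rc)
    sn <- -sin(alpha) * (p[, 1] - ax[, 1]) + cos(alpha) * (p[, 2] - ax[, 2])
    sb <- p[, 3]
  }
  rloc <- sqrt(sn^2 + sb^2)
  phi <- atan2(sn, sb)
  u <- (phi %% (2 * pi)) * r
  cbind(u = u, v = v, rloc = rloc)
}

#' Render a cell-label volume of the tube surface
#'
#' Paints a thin shell at the cell layer in which every voxel carries
#' the integer id of the cell owning that surface position (0 =
#' background). Pushing this volume through the same resampling,
#' straightening and unrolling chain as the intensity stack (with
#' nearest-neighbour sampling) yields an unrolled label image from
#' which per-cell areas and orientations can be measured against
#' ground truth.
#'
#' @param graph A [JunctionGraph-class].
#' @param spec The [TubeSpec-class] (defaults to the graph's).
#' @param thickness shell thickness, um (default 3 voxel minima).
#' @param pad physical padding, um.
#' @return A [VolumetricImage-class] of integer labels.
#' @export
renderLabelVolume <- function(graph, spec = graph@spec, thickness = NULL,
                              pad = NULL) {
  vox <- spec@voxel
  if (is.null(thickness)) thickness <- 3 * min(vox)
  if (is.null(pad)) {
    pad <- 4 * max(rep(spec@psfSigma, length.out = 3)) + 4 * max(vox)
  }
  gr <- sceneGrid(graph, vox, pad)
  dims <- gr$dims
  origin <- gr$origin

  # rasterize the unrolled-plane tessellation once; voxels then look
  # their cell id up via the inverse embedding
  P <- 2 * pi * spec@radius
  step <- min(P, spec@length) / 400
  gu <- seq(0, P, by = step)
  gv <- seq(0, spec@length, by = step)
  lut <- matrix(0L, length(gu), length(gv))
  gg <- expand.grid(u = gu, v = gv)
  for (i in seq_along(graph@cells)) {
    poly <- graph@cells[[i]]
    for (shift in c(-P, 0, P)) {
      bb <- range(poly[, 1]) + shift
      sel <- which(gg$u >= bb[1] - step & gg$u <= bb[2] + step)
      if (!length(sel)) next
      ins <- pointInPolygon(gg$u[sel] - shift, gg$v[sel], poly)
      lut[sel[ins]] <- graph@cellInfo$id[i]
    }
  }
  # grid points exactly on a shared cell edge can be claimed by
  # neither polygon; every plane point belongs to some cell, so fill
  # the stray zeros from their neighbours
  for (it in seq_len(8L)) {
    z <- which(lut == 0L)
    if (!length(z)) break
    nbr <- cbind(z - 1L, z + 1L, z - nrow(lut), z + nrow(lut))
    nbr[nbr < 1L | nbr > length(lut)] <- NA
    fill <- apply(nbr, 1, function(ix) {
      v <- lut[ix[!is.na(ix)]]
      v <- v[v > 0L]
      if (length(v)) v[1] else 0L
    })
    lut[z] <- fill
  }

  ix <- seq_len(dims[1]) - 1L
  iy <- seq_len(dims[2]) - 1L
  iz <- seq_len(dims[3]) - 1L
  pts <- as.matrix(expand.grid(x = origin[1] + ix * vox[1],
                               y = origin[2] + iy * vox[2],
                               z = origin[3] + iz * vox[3]))
  uvr <- surfaceCoords(pts, spec)
  lab <- integer(nrow(uvr))
  onShell <- abs(uvr[, "rloc"] - spec@radius) <= thickness / 2 &
    uvr[, "v"] >= 0 & uvr[, "v"] <= spec@length
  gi <- pmin(pmax(round(uvr[onShell, "u"] / step), 0), length(gu) - 1L) + 1L
  gj <- pmin(pmax(round(uvr[onShell, "v"] / step), 0), length(gv) - 1L) + 1L
  lab[onShell] <- lut[cbind(gi, gj)]
  VolumetricImage(array(as.numeric(lab), dims), voxel = vox,
                  origin = origin)
}
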