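# End-to-end junction anisotropy pipeline on synthetic embryos:
# tessellate -> assign intensities -> render -> max-project the upper
# half of the stack -> band-measure the visible junctions -> pooled
# per-embryo LCJ/TCJ statistics.

#' Analyze one synthetic embryo end to end
#'
#' Renders the tube described by `spec`, max-projects the upper half
#' of the stack (the hemisphere facing the objective, as when imaging
#' one side of the tube), takes the ground-truth junction traces whose
#' azimuth lies within `azimuthWindow` degrees of the top of the tube
#' (the junctions an analyst can follow on the projection), projects
#' them to pixel coordinates, and measures each with the
#' `widthPx`-pixel band. Classification uses the projected chord
#' angle, exactly as a manual measurement on the projection would.
#'
#' Only the slices covering the measured surface are projected (the
#' substack from the apex down to the depth of the deepest measured
#' junction plus the PSF support), as when an analyst projects the few
#' apical sections of interest; including the tube's side walls would
#' let their steeply foreshortened, piled-up signal bleed into nearby
#' measuring bands.
#'
#' @param spec A [TubeSpec-class] (straight tubes; curvature 0).
#' @param azimuthWindow half-width of the measured azimuth window,
#'   degrees from the tube top.
#' @param widthPx measuring band width, pixels.
#' @param noise logical, render with the spec's noise model.
#' @return list with elements `measurements` (per-junction
#'   data.frame, including the true class in `classTrue`), `summary`
#'   (one-row data.frame from [embryoAnisotropy()]), `projection`,
#'   `graph`, `volume`.
#' @examples
#' res <- analyzeSyntheticEmbryo(tubeSpec(enrichment = 1.5, seed = 11L))
#' res$summary$ratio
#' @export
analyzeSyntheticEmbryo <- function(spec, azimuthWindow = 60,
                                   widthPx = 5L, noise = TRUE) {
  if (spec@curvature != 0) {
    stop("projection-based junction analysis expects a straight tube")
  }
  graph <- assignIntensities(tessellateTube(spec), spec)
  vol <- renderVolume(graph, spec, noise = noise)

  # apical substack: from just above the tube apex down to the
  # deepest measured junction minus the PSF support
  psfZ <- rep(spec@psfSigma, length.out = 3)[3]
  zMin <- spec@radius * cos(azimuthWindow * pi / 180) - 3 * psfZ
  zMax <- spec@radius + 3 * psfZ
  zPos <- (seq_len(dim(vol@data)[3]) - 1L) * vol@voxel[3] + vol@origin[3]
  proj <- maxProject(vol, which(zPos >= zMin & zPos <= zMax))

  sel <- which(visibleJunctions(graph, azimuthWindow))
  # the trace an analyst draws stops short of the tricellular
  # vertices, where the bright blob is overlap of all adjoining
  # junctions rather than the junction's own signal; junctions too
  # short to measure clear of their vertices are skipped
  trimUm <- 2 * rep(spec@psfSigma, length.out = 3)[1] +
    widthPx * vol@voxel[1] / 2
  polys <- list()
  keep <- integer(0)
  for (i in sel) {
    p3 <- graph@polylines3D[[i]]
    p2 <- cbind((p3[, 1] - vol@origin[1]) / vol@voxel[1],
                (p3[, 2] - vol@origin[2]) / vol@voxel[2])
    p2t <- trimPolylineEnds(p2, trimUm / vol@voxel[1])
    if (is.null(p2t)) next
    keep <- c(keep, i)
    polys[[length(polys) + 1L]] <- p2t
  }
  sel <- keep
  names(polys) <- graph@junctions$id[sel]
  meas <- measureJunctions(proj, polys, axisAngle = 0,
                           widthPx = widthPx,
                           pixelSize = vol@voxel[1])
  meas$classTrue <- graph@junctions$class[sel]
  meas$densityTrue <- graph@junctions$density[sel]
  list(measurements = meas, summary = embryoAnisotropy(meas),
       projection = proj, graph = graph, volume = vol)
}

# Indices of junctions whose trace stays within `window` degrees of
# azimuth from the top of the tube (z+), i.e. the junctions visible
# with little foreshortening on an upper-half projection.
visibleJunctions <- function(graph, window = 60) {
  vapply(graph@polylines3D, function(p3) {
    az <- atan2(p3[, 2], p3[, 3]) * 180 / pi
    all(abs(az) <= window)
  }, logical(1))
}

#' Simulate and analyze a cohort of synthetic embryos
#'
#' Runs [analyzeSyntheticEmbryo()] on `nEmbryos` independently seeded
#' tubes sharing the same [TubeSpec-class] parameters and returns the
#' per-embryo pooled anisotropy table. This is the synthetic
#' counterpart of an n-embryo immunostaining experiment: the
#' across-embryo mean of `ratio` estimates the generator's
#' `enrichment`, and the mean of `percentDiff` the corresponding
#' percent difference (about 33 percent at a ratio of 1.5).
#'
#' @param nEmbryos number of embryos.
#' @param seed cohort seed; per-embryo seeds are drawn from it.
#' @param spec template [TubeSpec-class]; its `seed` is replaced
#'   per embryo.
#' @param azimuthWindow,widthPx,noise passed to
#'   [analyzeSyntheticEmbryo()].
#' @return data.frame with one row per embryo (columns of
#'   [embryoAnisotropy()] plus `embryo` and `seed`).
#' @examples
#' \donttest{
#' st <- anisotropyStudy(nEmbryos = 3, seed = 1L,
#'   spec = tubeSpec(enrichment = 1))
#' mean(st$ratio)
#' }
#' @export
anisotropyStudy <- function(nEmbryos = 15, seed = 1L,
                            spec = tubeSpec(), azimuthWindow = 60,
                            widthPx = 5L, noise = TRUE) {
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, nEmbryos))
  rows <- lapply(seq_len(nEmbryos), function(i) {
    sp <- spec
    sp@seed <- seeds[i]
    res <- analyzeSyntheticEmbryo(sp, azimuthWindow, widthPx, noise)
    cbind(data.frame(embryo = i, seed = seeds[i]), res$summary)
  })
  do.call(rbind, rows)
}
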