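# Brick tessellation of a tube surface.
#
# Cells are laid out on the unrolled rectangle [0, 2*pi*r) x [0, L]
# as nRings rows of nAround bricks, alternate rows offset by half a
# cell width, then wrapped onto the cylinder (or bent arc). All
# nominal vertex positions are multiples of w/2 along u, which makes
# the combinatorics exact: interior row boundaries carry 2*nAround
# vertices (both parities), the two tube ends nAround (one parity).

#' Tessellate a synthetic tube surface into cells and junctions
#'
#' Builds the brick tessellation described by a [TubeSpec-class]:
#' junction polylines on the unrolled plane and in 3D scene
#' coordinates, true folded orientation angles and classes, cell
#' polygons with true areas, and the medial axis. Vertex jitter is
#' applied to interior vertices only, so the tessellation always tiles
#' the `2*pi*radius x length` rectangle exactly. Identical seeds give
#' identical tessellations.
#'
#' @param spec A [TubeSpec-class].
#' @return A [JunctionGraph-class] with junction densities unset (NA);
#'   see [assignIntensities()].
#' @examples
#' g <- tessellateTube(tubeSpec(nRings = 2L, nAround = 4L, seed = 3L))
#' table(junctions(g)$class)
#' @export
tessellateTube <- function(spec) {
  validObject(spec)
  r <- spec@radius
  L <- spec@length
  P <- 2 * pi * r
  nA <- spec@nAround
  nR <- spec@nRings
  w <- P / nA
  h <- L / nR
  if (w < 4 * max(spec@voxel) || h < 4 * max(spec@voxel)) {
    stop("cell size below 4 voxels in some direction; ",
         "unresolvable at rendering")
  }

  # vertices per boundary line k = 0..nRings, keyed by half-step index
  # m (u0 = m * w/2). Interior lines hold every m, end lines only the
  # parity of their single adjacent row.
  nM <- 2L * nA
  lineVerts <- withSeed(spec@seed, {
    lapply(0:nR, function(k) {
      if (k == 0L) {
        m <- seq(0L, nM - 2L, by = 2L)            # row 0 parity 0
      } else if (k == nR) {
        m <- seq((nR - 1L) %% 2L, nM - 1L, by = 2L)
      } else {
        m <- 0:(nM - 1L)
      }
      u0 <- m * w / 2
      v0 <- rep(k * h, length(m))
      if (k > 0L && k < nR && spec@vertexJitter > 0) {
        u <- u0 + runif(length(m), -1, 1) * spec@vertexJitter * w
        v <- v0 + runif(length(m), -1, 1) * spec@vertexJitter * h
      } else {
        u <- u0
        v <- v0
      }
      data.frame(m = m, u = u, v = v)
    })
  })
  # lookup of the (possibly wrapped) jittered position of half-step m
  # on line k; m outside [0, nM) wraps with a perimeter shift
  vertexAt <- function(k, m) {
    shift <- floor(m / nM) * P
    mw <- ((m %% nM) + nM) %% nM
    df <- lineVerts[[k + 1L]]
    i <- match(mw, df$m)
    c(df$u[i] + shift, df$v[i])
  }

  ids <- character(0)
  plns <- list()
  cellA <- integer(0)
  cellB <- integer(0)
  cellId <- function(row, i) row * nA + (i %% nA) + 1L

  # longitudinal junctions: one vertical edge per cell column per row
  for (row in 0:(nR - 1L)) {
    p <- row %% 2L
    for (i in 0:(nA - 1L)) {
      m <- p + 2L * i
      pl <- rbind(vertexAt(row, m), vertexAt(row + 1L, m))
      ids <- c(ids, sprintf("L_r%d_i%d", row, i))
      plns <- c(plns, list(pl))
      cellA <- c(cellA, cellId(row, i - 1L))
      cellB <- c(cellB, cellId(row, i))
    }
  }
  # transverse junctions: consecutive vertices along each boundary line
  for (k in 0:nR) {
    ms <- lineVerts[[k + 1L]]$m
    nv <- length(ms)
    for (j in seq_len(nv)) {
      m1 <- ms[j]
      m2 <- if (j < nv) ms[j + 1L] else ms[1L] + nM  # wrap across seam
      pl <- rbind(vertexAt(k, m1), vertexAt(k, m2))
      ids <- c(ids, sprintf("T_k%d_j%d", k, j))
      plns <- c(plns, list(pl))
      mid <- (m1 + m2) / 2
      below <- if (k == 0L) NA_integer_ else
        cellId(k - 1L, floor((mid - (k - 1L) %% 2L) / 2))
      above <- if (k == nR) NA_integer_ else
        cellId(k, floor((mid - k %% 2L) / 2))
      cellA <- c(cellA, below)
      cellB <- c(cellB, above)
    }
  }

  # cell polygons (unrolled plane, unwrapped u for seam cells)
  cells <- list()
  cellRows <- data.frame(id = integer(0), areaUm2 = numeric(0),
                         phiDeg = numeric(0))
  for (row in 0:(nR - 1L)) {
    p <- row %% 2L
    for (i in 0:(nA - 1L)) {
      ml <- p + 2L * i
      mr <- ml + 2L
      bot <- list(vertexAt(row, ml))
      if (row > 0L) bot <- c(bot, list(vertexAt(row, ml + 1L)))
      bot <- c(bot, list(vertexAt(row, mr)))
      top <- list(vertexAt(row + 1L, mr))
      if (row < nR - 1L) top <- c(top, list(vertexAt(row + 1L, ml + 1L)))
      top <- c(top, list(vertexAt(row + 1L, ml)))
      poly <- do.call(rbind, c(bot, top))
      mom <- polygonMoments(poly)
      phi <- momentsOrientation(mom$mxx, mom$myy, mom$mxy)$phi
      cells <- c(cells, list(poly))
      cellRows <- rbind(cellRows, data.frame(id = cellId(row, i),
        areaUm2 = mom$area, phiDeg = phi))
    }
  }

  # angles, classes, 3D embedding
  angle <- vapply(plns, function(pl) {
    d <- pl[nrow(pl), ] - pl[1, ]
    foldAngle(atan2(d[1], d[2]) * 180 / pi)
  }, numeric(1))
  cls <- classifyAngle(angle)
  plns3 <- lapply(plns, function(pl) embedPlanePolyline(pl, spec))
  len3 <- vapply(plns3, polylineArclength, numeric(1))

  axisV <- seq(0, L, length.out = 64L)
  ax <- tubeAxisPoint(axisV, spec)

  jdf <- data.frame(id = ids, class = cls, angleDeg = angle,
                    lengthUm = len3, density = NA_real_,
                    cellA = cellA, cellB = cellB,
                    stringsAsFactors = FALSE)
  new("JunctionGraph", junctions = jdf, polylines3D = plns3,
      polylinesPlane = plns, cells = cells, cellInfo = cellRows,
      medialAxis = ax, spec = spec)
}

# Medial-axis point(s) at arclength v (um). Straight tubes run along
# +x; curvature bends the axis along a circular arc in the XY plane.
tubeAxisPoint <- function(v, spec) {
  k <- spec@curvature
  if (k == 0) {
    cbind(v, 0, 0)
  } else {
    a <- k * v
    cbind(sin(a) / k, (1 - cos(a)) / k, 0)
  }
}

# Map unrolled-plane points (u, v) in um onto the tube surface in 3D
# scene coordinates. u = 0 is the top of the tube (+z); the mapping is
# an isometry for straight tubes.
embedSurfacePoint <- function(u, v, spec) {
  r <- spec@radius
  phi <- u / r
  k <- spec@curvature
  if (k == 0) {
    cbind(v, r * sin(phi), r * cos(phi))
  } else {
    a <- k * v
    ax <- cbind(sin(a) / k, (1 - cos(a)) / k, 0)
    n <- cbind(-sin(a), cos(a), 0)
    ax + r * sin(phi) * n + cbind(0, 0, r * cos(phi))
  }
}

# Embed a plane polyline, subdividing so circumferential segments
# follow the surface arc.
embedPlanePolyline <- function(pl, spec, maxStep = 0.25) {
  out <- list()
  for (i in seq_len(nrow(pl) - 1L)) {
    a <- pl[i, ]
    b <- pl[i + 1L, ]
    nseg <- max(1L, ceiling(sqrt(sum((b - a)^2)) / maxStep))
    tt <- seq(0, 1, length.out = nseg + 1L)
    if (i > 1L) tt <- tt[-1]
    out[[i]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }
  uv <- do.call(rbind, out)
  embedSurfacePoint(uv[, 1], uv[, 2], spec)
}

#' Draw per-junction intensity densities
#'
#' Gives every junction an intensity density (counts per um of
#' junction length) drawn from a lognormal distribution whose mean
#' depends on the junction's true orientation: `baseIntensity *
#' enrichment` for the longitudinal class (folded angle <= 30 degrees),
#' `baseIntensity` for the transverse class (>= 60 degrees), and a
#' linear interpolation in folded angle for oblique junctions in
#' between, which avoids a discontinuity at the class boundaries. The
#' lognormal coefficient of variation is `intensityCV`; with CV = 0
#' every junction receives exactly its class mean.
#'
#' @param graph A [JunctionGraph-class] from [tessellateTube()].
#' @param spec The generating [TubeSpec-class] (defaults to the one
#'   stored in `graph`).
#' @return The graph with the `density` column filled in.
#' @examples
#' g <- tessellateTube(tubeSpec(enrichment = 1.5, intensityCV = 0,
#'   vertexJitter = 0, seed = 1L))
#' g <- assignIntensities(g)
#' tapply(junctions(g)$density, junctions(g)$class, mean)
#' @export
assignIntensities <- function(graph, spec = graph@spec) {
  theta <- graph@junctions$angleDeg
  rho <- spec@enrichment
  base <- spec@baseIntensity
  m <- ifelse(theta <= 30, base * rho,
        ifelse(theta >= 60, base,
               base * (rho - (rho - 1) * (theta - 30) / 30)))
  cv <- spec@intensityCV
  if (cv == 0) {
    dens <- m
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    dens <- withSeed(spec@seed + 1L,
      rlnorm(length(m), meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog))
  }
  graph@junctions$density <- dens
  graph
}
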