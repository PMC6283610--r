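# Internal geometry and interpolation helpers.
#
# Conventions (package-wide): pixel/voxel indices are 0-based in all
# continuous coordinates, with the coordinate value sitting at the pixel
# centre; angles are in degrees.

# Bilinear interpolation on a matrix. `x` indexes rows, `y` columns,
# both 0-based continuous. Points outside [0, n-1] in either axis
# return NA (the mask used by the straightening/unrolling stages).
bilinearSample <- function(img, x, y) {
  nx <- nrow(img)
  ny <- ncol(img)
  inside <- is.finite(x) & is.finite(y) &
    x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1
  xc <- pmin(pmax(x, 0), nx - 1)
  yc <- pmin(pmax(y, 0), ny - 1)
  x0 <- floor(xc)
  y0 <- floor(yc)
  x1 <- pmin(x0 + 1, nx - 1)
  y1 <- pmin(y0 + 1, ny - 1)
  fx <- xc - x0
  fy <- yc - y0
  v <- img[cbind(x0 + 1, y0 + 1)] * (1 - fx) * (1 - fy) +
    img[cbind(x1 + 1, y0 + 1)] * fx * (1 - fy) +
    img[cbind(x0 + 1, y1 + 1)] * (1 - fx) * fy +
    img[cbind(x1 + 1, y1 + 1)] * fx * fy
  v[!inside] <- NA_real_
  v
}

# Nearest-neighbour sampling on a matrix, same conventions as above.
nearestSample2 <- function(img, x, y) {
  nx <- nrow(img)
  ny <- ncol(img)
  xi <- round(x)
  yi <- round(y)
  inside <- is.finite(xi) & is.finite(yi) &
    xi >= 0 & xi <= nx - 1 & yi >= 0 & yi <= ny - 1
  v <- rep(NA_real_, length(x))
  v[inside] <- img[cbind(xi[inside] + 1, yi[inside] + 1)]
  v
}

# Trilinear interpolation on a 3D array, 0-based coords per axis.
trilinearSample <- function(arr, x, y, z) {
  d <- dim(arr)
  inside <- is.finite(x) & is.finite(y) & is.finite(z) &
    x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 & z >= 0 & z <= d[3] - 1
  xc <- pmin(pmax(x, 0), d[1] - 1)
  yc <- pmin(pmax(y, 0), d[2] - 1)
  zc <- pmin(pmax(z, 0), d[3] - 1)
  x0 <- floor(xc); x1 <- pmin(x0 + 1, d[1] - 1); fx <- xc - x0
  y0 <- floor(yc); y1 <- pmin(y0 + 1, d[2] - 1); fy <- yc - y0
  z0 <- floor(zc); z1 <- pmin(z0 + 1, d[3] - 1); fz <- zc - z0
  v <- as.vector(arr)
  lin <- function(ix, iy, iz) v[(iz * d[2] + iy) * d[1] + ix + 1]
  out <- lin(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    lin(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    lin(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
    lin(x1, y1, z0) * fx * fy * (1 - fz) +
    lin(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    lin(x1, y0, z1) * fx * (1 - fy) * fz +
    lin(x0, y1, z1) * (1 - fx) * fy * fz +
    lin(x1, y1, z1) * fx * fy * fz
  out[!inside] <- NA_real_
  out
}

nearestSample3 <- function(arr, x, y, z) {
  d <- dim(arr)
  xi <- round(x); yi <- round(y); zi <- round(z)
  inside <- is.finite(xi) & is.finite(yi) & is.finite(zi) &
    xi >= 0 & xi <= d[1] - 1 & yi >= 0 & yi <= d[2] - 1 &
    zi >= 0 & zi <= d[3] - 1
  v <- rep(NA_real_, length(x))
  v[inside] <- as.vector(arr)[(zi[inside] * d[2] + yi[inside]) * d[1] +
    xi[inside] + 1]
  v
}

# --- separable Gaussian convolution -----------------------------------

gaussKernel1 <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Convolve each column of a matrix with kernel k, zero-padded edges.
convolveCols <- function(m, k) {
  if (length(k) == 1L) return(m * k)
  p <- (length(k) - 1L) / 2L
  n <- nrow(m)
  mp <- rbind(matrix(0, p, ncol(m)), m, matrix(0, p, ncol(m)))
  f <- stats::filter(mp, k, sides = 2)
  matrix(f[(p + 1):(p + n), ], nrow = n)
}

# Separable Gaussian blur of a 2D matrix or 3D array; sigmaVox gives
# the per-axis sigma in voxels (recycled if scalar).
gaussBlur <- function(arr, sigmaVox) {
  d <- dim(arr)
  nd <- length(d)
  sigmaVox <- rep(sigmaVox, length.out = nd)
  for (ax in seq_len(nd)) {
    if (sigmaVox[ax] <= 0) next
    k <- gaussKernel1(sigmaVox[ax])
    perm <- c(ax, setdiff(seq_len(nd), ax))
    a <- aperm(arr, perm)
    dp <- dim(a)
    a <- matrix(a, nrow = dp[1])
    a <- convolveCols(a, k)
    dim(a) <- dp
    arr <- aperm(a, order(perm))
  }
  arr
}

# --- polyline helpers --------------------------------------------------

segmentLengths <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(numeric(0))
  sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
}

polylineArclength <- function(pts) sum(segmentLengths(pts))

# Sample a polyline at arclengths `s` (linear interpolation between
# vertices). Returns positions and unit tangents of the local segment.
polylinePointAt <- function(pts, s) {
  seg <- segmentLengths(pts)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(seg))
  frac <- (s - cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  p0 <- pts[idx, , drop = FALSE]
  p1 <- pts[idx + 1L, , drop = FALSE]
  pos <- p0 + frac * (p1 - p0)
  tang <- (p1 - p0) / pmax(seg[idx], .Machine$double.eps)
  list(pos = pos, tangent = tang)
}

# Midpoint-rule resampling used by the band integral: n = round(L /
# spacing) samples at arclengths (i - 1/2) * L / n.
resamplePolylineMid <- function(pts, spacing = 1) {
  total <- polylineArclength(pts)
  if (total <= 0) stop("polyline has zero length")
  n <- max(1L, round(total / spacing))
  ds <- total / n
  at <- polylinePointAt(pts, (seq_len(n) - 0.5) * ds)
  list(pos = at$pos, tangent = at$tangent, ds = ds, n = n, length = total)
}

# Centripetal Catmull-Rom smoothing of a polyline, resampled at
# (approximately) `spacing` arclength steps. Used to obtain smooth
# tangents for the straightening passes; a 2-point polyline degenerates
# to the straight segment.
catmullRomResample <- function(pts, spacing = 1, densify = 25L) {
  pts <- as.matrix(pts)
  keep <- c(TRUE, segmentLengths(pts) > .Machine$double.eps)
  pts <- pts[keep, , drop = FALSE]
  n <- nrow(pts)
  if (n < 2L) stop("polyline needs at least 2 distinct points")
  if (n == 2L) {
    dense <- pts
  } else {
    ctrl <- rbind(2 * pts[1, ] - pts[2, ], pts,
                  2 * pts[n, ] - pts[n - 1, ])
    dense <- list()
    for (i in seq_len(n - 1L)) {
      P <- ctrl[i:(i + 3L), , drop = FALSE]
      t0 <- 0
      t1 <- t0 + sqrt(sqrt(sum((P[2, ] - P[1, ])^2)))
      t2 <- t1 + sqrt(sqrt(sum((P[3, ] - P[2, ])^2)))
      t3 <- t2 + sqrt(sqrt(sum((P[4, ] - P[3, ])^2)))
      u <- seq(t1, t2, length.out = densify + 1L)
      if (i < n - 1L) u <- u[-length(u)]
      interp <- function(pa, pb, ta, tb, t) {
        w <- (t - ta) / (tb - ta)
        (1 - w) %o% pa + w %o% pb
      }
      A1 <- interp(P[1, ], P[2, ], t0, t1, u)
      A2 <- interp(P[2, ], P[3, ], t1, t2, u)
      A3 <- interp(P[3, ], P[4, ], t2, t3, u)
      B1 <- A1 * ((t2 - u) / (t2 - t0)) + A2 * ((u - t0) / (t2 - t0))
      B2 <- A2 * ((t3 - u) / (t3 - t1)) + A3 * ((u - t1) / (t3 - t1))
      C <- B1 * ((t2 - u) / (t2 - t1)) + B2 * ((u - t1) / (t2 - t1))
      dense[[i]] <- C
    }
    dense <- do.call(rbind, dense)
  }
  total <- polylineArclength(dense)
  s <- seq(0, total, by = spacing)
  if (length(s) < 2L) s <- c(0, total)
  ns <- length(s)
  at <- polylinePointAt(dense, s)
  # smooth tangents by central differences of resampled points
  p <- at$pos
  tg <- rbind(p[2, ] - p[1, ],
              (p[-(1:2), , drop = FALSE] - p[1:(ns - 2), , drop = FALSE]) / 2,
              p[ns, ] - p[ns - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  list(pos = p, tangent = tg, arclength = total, spacing = spacing)
}

# Cut `trim` arclength units off both ends of a polyline; NULL if
# less than 2 * trim (plus a sample) would remain.
trimPolylineEnds <- function(pts, trim) {
  total <- polylineArclength(pts)
  if (total <= 2 * trim + 1e-9) return(NULL)
  seg <- segmentLengths(pts)
  cum <- c(0, cumsum(seg))
  sOut <- c(trim, cum[cum > trim & cum < total - trim], total - trim)
  polylinePointAt(pts, sOut)$pos
}

# --- polygon helpers ---------------------------------------------------

polygonAreaSigned <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygonSelfIntersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(FALSE)
  seg <- cbind(poly, rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE]))
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]
    if (!length(js)) next
    p <- seg[i, 1:2]; r <- seg[i, 3:4] - p
    q1 <- seg[js, 1:2, drop = FALSE]
    s2 <- seg[js, 3:4, drop = FALSE] - q1
    d1 <- cross2(r[1], r[2], q1[, 1] - p[1], q1[, 2] - p[2])
    d2 <- cross2(r[1], r[2], seg[js, 3] - p[1], seg[js, 4] - p[2])
    d3 <- cross2(s2[, 1], s2[, 2], p[1] - q1[, 1], p[2] - q1[, 2])
    d4 <- cross2(s2[, 1], s2[, 2], seg[i, 3] - q1[, 1], seg[i, 4] - q1[, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

# Even-odd (ray casting) point-in-polygon, vectorized over points.
pointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimum distance from points to the edges of a polygon/polyline.
distToEdges <- function(px, py, poly, closed = TRUE) {
  n <- nrow(poly)
  idx <- if (closed) cbind(seq_len(n), c(seq_len(n)[-1], 1L)) else
    cbind(seq_len(n - 1L), seq(2L, n))
  d <- rep(Inf, length(px))
  for (k in seq_len(nrow(idx))) {
    a <- poly[idx[k, 1], ]
    b <- poly[idx[k, 2], ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      dk <- sqrt((px - a[1])^2 + (py - a[2])^2)
    } else {
      t <- pmin(pmax(((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2, 0), 1)
      dk <- sqrt((px - a[1] - t * ab[1])^2 + (py - a[2] - t * ab[2])^2)
    }
    d <- pmin(d, dk)
  }
  d
}

# Area-normalized central second moments of a simple polygon
# (continuous, via Green's theorem). Returns list(area, cx, cy, mxx,
# myy, mxy); area is positive regardless of orientation.
polygonMoments <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  Ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12   # integral of x^2 dA
  Iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12   # integral of y^2 dA
  Ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  list(area = abs(A), cx = cx, cy = cy,
       mxx = Ixx / A - cx^2, myy = Iyy / A - cy^2, mxy = Ixy / A - cx * cy)
}

# Principal-axis orientation in [0, 180) and eccentricity from central
# second moments (mxx = var(x), myy = var(y), mxy = cov).
momentsOrientation <- function(mxx, myy, mxy) {
  phi <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
  phi <- phi %% 180
  common <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- (mxx + myy) / 2 + common
  l2 <- (mxx + myy) / 2 - common
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  list(phi = phi, eccentricity = ecc, lambda1 = l1, lambda2 = l2)
}
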