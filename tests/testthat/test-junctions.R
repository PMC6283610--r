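test_that("chord angles fold and classify per the 30/60 degree bands", {
  expect_equal(foldAngle(c(15, 90, 45, 172, 270, -15)),
               c(15, 90, 45, 8, 90, 15))
  fc <- foldAndClassify(rbind(c(0, 0), c(cos(15 * pi / 180),
                                         sin(15 * pi / 180))))
  expect_equal(fc$angleDeg, 15)
  expect_equal(fc$class, "LCJ")
  expect_equal(foldAndClassify(rbind(c(0, 0), c(0, 5)))$class, "TCJ")
  expect_equal(foldAndClassify(rbind(c(0, 0), c(1, 1)))$class,
               "unassigned")
  fc172 <- foldAndClassify(rbind(c(0, 0),
    c(cos(172 * pi / 180), sin(172 * pi / 180))))
  expect_equal(fc172$angleDeg, 8, tolerance = 1e-9)
  expect_equal(fc172$class, "LCJ")
  # band boundaries are inclusive
  expect_equal(classifyAngle(c(30, 60)), c("LCJ", "TCJ"))
  # a rotated axis shifts the reference
  expect_equal(foldAndClassify(rbind(c(0, 0), c(0, 5)),
                               axisAngle = 90)$class, "LCJ")
  expect_error(foldAndClassify(rbind(c(1, 1), c(1, 1))), "zero-length")
})

test_that("classification is symmetric and partitions the circle", {
  theta <- 0:359
  cls <- classifyAngle(foldAngle(theta))
  expect_identical(cls, classifyAngle(foldAngle(theta + 180)))
  expect_identical(cls, classifyAngle(foldAngle(-theta)))
  expect_true(all(cls %in% c("LCJ", "TCJ", "unassigned")))
  # the three classes partition [0, 90]
  f <- foldAngle(theta)
  expect_true(all((f <= 30) + (f >= 60) + (f > 30 & f < 60) == 1))
})

test_that("the band integral is exact on constant images", {
  img <- matrix(7, 30, 30)
  pl <- rbind(c(5, 15), c(15, 15))
  expect_equal(bandIntegratedDensity(img, pl), 350)   # 10 px * 5 * 7
  expect_equal(bandIntegratedDensity(img, pl) /
                 tubeaniso:::polylineArclength(pl), 35)
  expect_error(bandIntegratedDensity(img, rbind(c(0, 0), c(29, 0))),
               "leaves the image")
})

test_that("the band integral matches a rasterized-mask oracle on an
           oblique segment", {
  img <- smoothImage(80, 80, sigma = 4, seed = 3L, offset = 20)
  a <- c(20, 25)
  b <- a + 30 * c(cos(pi / 6), sin(pi / 6))   # 30 degrees oblique
  got <- bandIntegratedDensity(img, rbind(a, b), widthPx = 5L)
  # oracle: sum pixels whose centre falls in the 5-px rectangle
  # around the segment
  gx <- rep(0:79, times = 80)
  gy <- rep(0:79, each = 80)
  d <- b - a
  L <- sqrt(sum(d^2))
  u <- d / L
  t <- (gx - a[1]) * u[1] + (gy - a[2]) * u[2]
  perp <- abs(-(gx - a[1]) * u[2] + (gy - a[2]) * u[1])
  mask <- t >= 0 & t <= L & perp <= 2.5
  oracle <- sum(img[cbind(gx[mask] + 1, gy[mask] + 1)])
  expect_equal(got, oracle, tolerance = 0.02)
})

test_that("pooled anisotropy statistics follow their definitions", {
  m <- data.frame(
    class = c("LCJ", "LCJ", "TCJ", "TCJ", "unassigned"),
    lengthPx = c(12, 8, 9, 11, 5),
    rawIntegratedDensity = c(180, 120, 100, 100, 40))
  a <- embryoAnisotropy(m)
  expect_equal(a$densityL, 300 / 20)
  expect_equal(a$densityT, 200 / 20)
  expect_equal(a$ratio, 1.5)
  expect_equal(a$percentDiff, 100 * (1 - 1 / 1.5), tolerance = 1e-12)
  expect_equal(a$fractionAssigned, 4 / 5)
  # equal densities: ratio 1, percent difference 0
  m2 <- data.frame(class = c("LCJ", "TCJ"), lengthPx = c(5, 9),
                   rawIntegratedDensity = c(50, 90))
  expect_equal(embryoAnisotropy(m2)$ratio, 1)
  expect_equal(embryoAnisotropy(m2)$percentDiff, 0)
  expect_error(embryoAnisotropy(m[m$class == "LCJ", ]), "undefined")
})

test_that("the anisotropy ratio is scale invariant", {
  m <- data.frame(
    class = rep(c("LCJ", "TCJ"), each = 3),
    lengthPx = c(10, 12, 9, 7, 8, 11),
    rawIntegratedDensity = c(150, 130, 160, 80, 90, 100))
  r0 <- embryoAnisotropy(m)$ratio
  # global intensity gain
  m1 <- m
  m1$rawIntegratedDensity <- m1$rawIntegratedDensity * 17.3
  expect_equal(embryoAnisotropy(m1)$ratio, r0)
  # uniform spatial rescaling of the projection scales lengths and
  # integrals together (integral ~ area ~ s^2, length ~ s)
  s <- 2.6
  m2 <- m
  m2$lengthPx <- m2$lengthPx * s
  m2$rawIntegratedDensity <- m2$rawIntegratedDensity * s^2
  expect_equal(embryoAnisotropy(m2)$ratio, r0)
})

test_that("the t comparison reproduces the closed form and stars", {
  a <- c(1.5, 1.4, 1.6)
  b <- c(1.0, 1.1, 0.9)
  got <- compareConditions(a, b)
  # hand computation: pooled variance, equal n
  sp2 <- (2 * stats::var(a) + 2 * stats::var(b)) / 4
  tOracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$t, tOracle, tolerance = 1e-10)
  expect_equal(got$df, 4)
  expect_identical(compareConditions(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(compareConditions(c(1, 2, 3), c(1, 2, 3))$t, 0)
  # zero pooled variance with equal means: p = 1 by convention
  expect_equal(compareConditions(c(2, 2), c(2, 2))$p, 1)
  # star thresholds
  starFor <- function(p) {
    # build two groups whose t-test lands at the requested p
    n <- 200
    delta <- qt(1 - p / 2, df = 2 * n - 2) * sqrt(2 / n)
    compareConditions(scale(rnorm(n)) + delta, scale(rnorm(n)))$stars
  }
  withr::with_seed(5, {
    expect_identical(starFor(0.03), "*")
    expect_identical(starFor(0.005), "**")
    expect_identical(starFor(1e-4), "***")
    expect_identical(starFor(0.5), "ns")
  })
})
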