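test_that("polyline lengths are Euclidean and calibrated", {
  expect_equal(polylineLength(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(polylineLength(rbind(c(0, 0), c(1, 0), c(1, 1),
                                    c(0, 1)), closed = TRUE), 4)
  th <- seq(0, pi / 2, length.out = 2000)
  quarter <- cbind(10 * cos(th), 10 * sin(th))
  expect_equal(polylineLength(quarter), 10 * pi / 2, tolerance = 1e-3)
  expect_equal(polylineLength(rbind(c(0, 0), c(3, 4)), pixelSize = 2),
               10)
})

test_that("tube morphometrics normalize length and average diameters", {
  m <- dtMetrics(rbind(c(0, 0), c(180, 0)), embryoLength = 400,
                 diameters = c(4.8, 5.0, 5.2))
  expect_equal(m$lengthRatio, 0.45)
  expect_equal(m$diameterUm, 5.0)
  # the ratio cancels pixel size
  m2 <- dtMetrics(rbind(c(0, 0), c(180, 0)), 400, c(4.8, 5, 5.2),
                  pixelSize = 0.31)
  expect_equal(m2$lengthRatio, 0.45)
  # diameter averaging is permutation invariant
  m3 <- dtMetrics(rbind(c(0, 0), c(180, 0)), 400, c(5.2, 4.8, 5.0))
  expect_equal(m3$diameterUm, m$diameterUm)
  expect_error(dtMetrics(rbind(c(0, 0), c(1, 0)), 10, c(1, 2)),
               "exactly 3")
})

test_that("percent change is signed and scale free", {
  expect_equal(percentChange(0.67, 1.0), -33)
  expect_equal(percentChange(1.12, 1.0), 12, tolerance = 1e-9)
  expect_equal(percentChange(3, 3), 0)
  expect_equal(percentChange(0.67 * 5, 1.0 * 5), -33)
})

test_that("SAR/AFR means behave on constructed cells", {
  img <- matrix(1, 40, 40)
  poly <- rbind(c(10, 10), c(30, 10), c(30, 30), c(10, 30))
  u <- sarAfr(img, poly)
  expect_equal(u$ratio, 1)
  # contour band at twice the interior
  img2 <- matrix(0, 40, 40)
  gx <- rep(0:39, 40)
  gy <- rep(0:39, each = 40)
  band <- tubeaniso:::distToEdges(gx, gy, poly) <= 3
  inside <- tubeaniso:::pointInPolygon(gx, gy, poly) & !band
  img2[cbind(gx + 1, gy + 1)] <- ifelse(band, 2, ifelse(inside, 1, 0))
  s2 <- sarAfr(img2, poly, bandWidth = 6L)
  expect_equal(s2$ratio, 2)
  expect_equal(s2$total, 2 * sum(band) + sum(inside))
  # gain invariance of the ratio; totals scale linearly
  s3 <- sarAfr(img2 * 7, poly, bandWidth = 6L)
  expect_equal(s3$ratio, s2$ratio)
  expect_equal(s3$total, 7 * s2$total)
  expect_error(sarAfr(img, rbind(c(10, 10), c(14, 10), c(14, 14),
                                 c(10, 14)), bandWidth = 20L),
               "whole cell")
})

test_that("SAR enrichment is recovered across many synthetic cells", {
  # 50 random cells with a known 1.8x contour-band enrichment,
  # lightly blurred, measured blind
  withr::with_seed(30, {
    ratios <- vapply(seq_len(50), function(i) {
      poly <- starPolygon(n = 8, rMin = 9.5, rMax = 11.5,
                          seed = 1000 + i, center = c(20, 20))
      gx <- rep(0:39, 40)
      gy <- rep(0:39, each = 40)
      # interior level everywhere (neighbouring cells fill the
      # outside), junctional band enriched 1.8-fold on the contour
      band <- tubeaniso:::distToEdges(gx, gy, poly) <= 3
      img <- matrix(50, 40, 40)
      img[cbind(gx + 1, gy + 1)[band, ]] <- 1.8 * 50
      img <- tubeaniso:::gaussBlur(img, 0.4)
      sarAfr(img, poly, bandWidth = 6L)$ratio
    }, numeric(1))
    expect_equal(mean(ratios), 1.8, tolerance = 0.05)
  })
})
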