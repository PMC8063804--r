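# Brute-force oracle: enumerate origin-anchored r x r boxes directly.
box_count_oracle <- function(img, r) {
  n <- 0L
  for (i in seq(1, nrow(img), by = r))
    for (j in seq(1, ncol(img), by = r)) {
      blk <- img[i:min(i + r - 1, nrow(img)), j:min(j + r - 1, ncol(img))]
      if (any(blk > 0)) n <- n + 1L
    }
  n
}

test_that("box counts match brute-force enumeration", {
  expect_equal(box_count(matrix(0L, 8, 8), 3), 0)
  single <- matrix(0L, 9, 9); single[5, 4] <- 1L
  for (r in c(1, 2, 3, 5, 9)) expect_equal(box_count(single, r), 1)
  expect_equal(box_count(matrix(1L, 4, 4), 2), 4)
  set.seed(21)
  for (i in 1:10) {
    img <- matrix(as.integer(runif(30 * 37) > 0.8), 30, 37)
    for (r in c(1, 2, 3, 4, 7, 16))
      expect_equal(box_count(img, r), box_count_oracle(img, r))
  }
  expect_error(box_count(matrix(2, 3, 3), 1), "binary")
})

test_that("N(r) is non-increasing in r and N(1) is the pixel count", {
  set.seed(22)
  for (i in 1:10) {
    img <- matrix(as.integer(runif(40 * 40) > 0.7), 40, 40)
    N <- vapply(1:12, function(r) box_count(img, r), 0)
    expect_equal(N[1], sum(img))
    expect_true(all(diff(N) <= 0))
  }
})

test_that("fractal dimension reproduces closed-form oracles", {
  # line: N(r) = ceil(512 / r); expected Df computed by fitting the
  # closed form over the same scales
  rv <- 2^(0:9)
  oracle_fit <- function(N, r) {
    keep <- N >= 2
    -unname(coef(lm(log(N[keep]) ~ log(r[keep])))[2])
  }
  line <- fractal_fixture("line", 512)
  expect_equal(fractal_dimension(line)$df, oracle_fit(ceiling(512 / rv), rv))
  expect_lt(abs(fractal_dimension(line)$df - 1), 0.05)

  square <- fractal_fixture("filled_square", 512)
  expect_equal(fractal_dimension(square)$df,
               oracle_fit(ceiling(512 / rv)^2, rv))
  expect_lt(abs(fractal_dimension(square)$df - 2), 0.1)

  carpet <- fractal_fixture("sierpinski_carpet", 243)
  expect_equal(sum(carpet), 8^5)
  expect_lt(abs(fractal_dimension(carpet, 3^(0:5))$df - log(8) / log(3)), 0.08)

  koch <- fractal_fixture("koch_curve", 243)
  expect_lt(abs(fractal_dimension(koch, 3^(0:4))$df - log(4) / log(3)), 0.1)
})

test_that("slice fractal dimensions behave like their continuum analogues", {
  disk <- raster_disk(100)
  f <- slice_fractal(disk)
  expect_gte(f$df_perimeter, 0.95)
  expect_lte(f$df_perimeter, 1.1)
  expect_gte(f$df_area, 1.9)
  expect_lte(f$df_area, 2.05)
  expect_gte(f$fit_r2, 0.95)
  # jagged boundary raises the perimeter dimension
  smooth <- raster_wavy_disk(90, 0)
  jag <- raster_wavy_disk(90, 0.08)
  expect_gt(slice_fractal(jag)$df_perimeter,
            slice_fractal(smooth)$df_perimeter)
  # degenerate single pixel: too few usable scales
  single <- matrix(0L, 20, 20); single[3, 3] <- 1L
  expect_error(slice_fractal(single), "fewer than 3")
})

test_that("fractal estimates are stable under translation", {
  set.seed(23)
  base <- raster_wavy_disk(60, 0.05, pad = 30)
  ref <- slice_fractal(base)$df_perimeter
  for (i in 1:5) {
    off <- sample(0:20, 2)
    shifted <- matrix(0L, nrow(base) + 20, ncol(base) + 20)
    shifted[off[1] + seq_len(nrow(base)), off[2] + seq_len(ncol(base))] <- base
    expect_lt(abs(slice_fractal(shifted)$df_perimeter - ref), 0.05)
  }
})

test_that("circularity follows the analytic formula", {
  # ideal continuous disk: Area = pi r^2, Perimeter = 2 pi r -> exactly 1
  expect_identical(circularity(pi * 1^2, 2 * pi * 1), 1)
  for (r in c(10, 137.5))
    expect_equal(circularity(pi * r^2, 2 * pi * r), 1, tolerance = 1e-12)
  # square side a: Area a^2, Perimeter 4a -> pi / 4
  expect_equal(circularity(100^2, 4 * 100), pi / 4)
  expect_error(circularity(10, 0), "positive")
})

test_that("rasterized disk circularity converges to 1 with radius", {
  circ <- vapply(c(25, 50, 100), function(r)
    shape_features(raster_disk(r))$circularity, 0)
  expect_true(all(circ > 0.9 & circ < 1.1))
  expect_true(abs(circ[3] - 1) <= abs(circ[1] - 1) + 0.02)
})

test_that("ellipse moments give the analytic eccentricity and orientation", {
  mk_ellipse <- function(a, b, theta, n = 221) {
    ctr <- (n + 1) / 2
    y <- matrix(seq_len(n) - ctr, n, n)
    x <- t(y)
    xr <- x * cos(theta) + y * sin(theta)
    yr <- -x * sin(theta) + y * cos(theta)
    matrix(as.integer((xr / a)^2 + (yr / b)^2 <= 1), n, n)
  }
  s <- shape_features(mk_ellipse(100, 50, 0))
  expect_equal(s$eccentricity, sqrt(3) / 2, tolerance = 1e-3)
  expect_equal(s$orientation_deg, 0, tolerance = 1)
  # rotated by 30 degrees (y up flips the sign of the image-space angle)
  s30 <- shape_features(mk_ellipse(100, 50, pi / 6))
  expect_equal(abs(s30$orientation_deg), 30, tolerance = 1)
  expect_equal(s30$eccentricity, sqrt(3) / 2, tolerance = 1e-3)
  # circle: eccentricity 0
  expect_lt(shape_features(raster_disk(60))$eccentricity, 0.05)
})

test_that("convex area difference is zero for convex regions and recovers a notch", {
  disk <- raster_disk(100)
  s <- shape_features(disk)
  expect_lte(s$convex_area_diff, 0.01 * sum(disk))
  # remove a full wedge of half-angle h to the center; the hull closes the
  # gap with the chord, so the deficiency is the center triangle r^2 sin h cos h
  r <- 100
  n <- nrow(disk)
  ctr <- (n + 1) / 2
  y <- matrix(seq_len(n) - ctr, n, n)
  x <- t(y)
  phi <- atan2(y, x)
  wedge <- disk
  half <- 0.55
  wedge[abs(phi) < half] <- 0L
  notch_area <- r^2 * sin(half) * cos(half)
  sn <- shape_features(wedge)
  expect_lt(abs(sn$convex_area_diff - notch_area) / notch_area, 0.05)
})
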