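test_that("detrending removes polynomial trends in the per-frame means", {
  # constant movie unchanged
  m0 <- meanScheduleMovie(rep(50, 10))
  expect_equal(movieData(detrendMovie(m0, 1)), movieData(m0), tolerance = 1e-12)
  # linear decay 100 -> 80: all output means equal the grand mean 90
  m1 <- meanScheduleMovie(seq(100, 80, length.out = 100))
  out <- detrendMovie(m1, 1)
  mu <- apply(movieData(out), 1, mean)
  expect_equal(mu, rep(90, 100), tolerance = 1e-9)
  # cubic bleaching trend, order 3: residual linear slope ~ 0
  t <- seq_len(100)
  m3 <- meanScheduleMovie(100 - 0.3 * t + 0.004 * t^2 - 1e-5 * t^3)
  mu3 <- apply(movieData(detrendMovie(m3, 3)), 1, mean)
  expect_lt(abs(stats::coef(stats::lm(mu3 ~ t))[2]), 1e-9)
})

test_that("detrending is idempotent and guards its preconditions", {
  m <- meanScheduleMovie(seq(60, 40, length.out = 20))
  once <- detrendMovie(m, 1)
  twice <- detrendMovie(once, 1)
  expect_equal(movieData(twice), movieData(once), tolerance = 1e-9)
  expect_error(detrendMovie(meanScheduleMovie(c(1, 2, 3)), 3), "too few frames")
})

test_that("spatial bandpass division flattens low frequencies and keeps high", {
  # uniform frame -> exactly 1
  m <- MovieTensor(array(7, c(1, 32, 32)))
  expect_equal(movieData(spatialBandpassDivide(m, 10))[1, , ],
               matrix(1, 32, 32), tolerance = 1e-12)
  # 2-cycle sinusoid (below cutoff) collapses toward 1
  n <- 64
  xg <- matrix(rep(0:(n - 1), each = n), n, n)
  low <- 100 + 20 * sin(2 * pi * 2 * xg / n)
  mL <- MovieTensor(array(low, c(1, n, n)))
  outL <- movieData(spatialBandpassDivide(mL, 10))[1, , ]
  expect_lt(max(outL) - min(outL), 0.05)
  # 20-cycle grating (above cutoff) keeps its relative contrast within 10%
  hig <- 100 + 20 * sin(2 * pi * 20 * xg / n)
  mH <- MovieTensor(array(hig, c(1, n, n)))
  outH <- movieData(spatialBandpassDivide(mH, 10))[1, , ]
  inContrast <- (max(hig) - min(hig)) / mean(hig)
  outContrast <- (max(outH) - min(outH)) / mean(outH)
  expect_lt(abs(outContrast - inContrast) / inContrast, 0.1)
})

test_that("bandpass division matches an independent FFT-mask oracle", {
  set.seed(3)
  fr <- smoothImage(48, 48, sigma = 1.5, seed = 3)
  m <- MovieTensor(array(fr, c(1, 48, 48)))
  got <- movieData(spatialBandpassDivide(m, 10))[1, , ]
  want <- fr / fftLowpassOracle(fr, 10)
  expect_lt(max(abs(got - want) / abs(want)), 1e-6)
})

test_that("registration normalization follows the pillbox chain", {
  # constant frame -> constant output
  cst <- matrix(5, 32, 32)
  out <- normalizeFrameForRegistration(cst)
  expect_equal(max(out) - min(out), 0, tolerance = 1e-12)
  # pillbox radius is one tenth of the smaller dimension: 200x300 -> 20
  fr <- matrix(rnorm(200 * 300), 200, 300)
  expect_equal(floor(min(dim(fr)) * 0.1), 20)
  # dark 3-px line on a bright field becomes the global maximum ridge
  ph <- matrix(100, 64, 64)
  ph[31:33, ] <- 40
  outp <- normalizeFrameForRegistration(ph, complement = TRUE)
  peak <- which(outp == max(outp), arr.ind = TRUE)
  expect_true(all(peak[, 1] %in% 31:33))
  expect_error(normalizeFrameForRegistration(matrix(0, 5, 5)), "too small")
})

test_that("dF/F follows its closed forms", {
  # constant movie -> all zeros
  m <- MovieTensor(array(80, c(5, 6, 6)))
  expect_equal(movieData(computeDFF(m, "mean")), array(0, c(5, 6, 6)),
               tolerance = 1e-12)
  # F = 2 F0 at one frame -> 1.0 there (mean mode needs a matched schedule)
  data <- array(100, c(4, 4, 4)); data[2, , ] <- 200  # mean F0 = 125
  dff <- computeDFF(MovieTensor(data), "mean")
  expect_equal(movieData(dff)[2, 1, 1], (200 - 125) / 125)
  # soft-min mode: value 75 with pixelwise 0.1th percentile 50 -> 0.5
  d2 <- array(75, c(1000, 2, 2)); d2[1, , ] <- 50  # bottom of the pixel's history
  sm <- computeDFF(MovieTensor(d2), "soft_min", softMinPercentile = 0.1)
  f0 <- as.double(stats::quantile(d2[, 1, 1], 0.001))
  expect_equal(movieData(sm)[2, 1, 1], (75 - f0) / f0, tolerance = 1e-9)
  expect_error(computeDFF(MovieTensor(array(0, c(2, 4, 4)))), "all-zero")
})

test_that("dF/F inverts its own construction", {
  set.seed(4)
  f0 <- matrix(runif(36, 50, 150), 6, 6)
  D <- array(rnorm(10 * 36, 0, 0.2), c(10, 6, 6))
  data <- array(NA_real_, c(10, 6, 6))
  for (t in 1:10) data[t, , ] <- f0 * (1 + D[t, , ])
  # remove per-pixel mean of D so that mean-image F0 equals f0 exactly
  Dc <- sweep(D, c(2, 3), apply(D, c(2, 3), mean))
  for (t in 1:10) data[t, , ] <- f0 * (1 + Dc[t, , ])
  got <- movieData(computeDFF(MovieTensor(data), "mean"))
  expect_equal(got, Dc, tolerance = 1e-9)
})

test_that("downsampling preserves means and endpoints", {
  m <- MovieTensor(array(runif(4 * 8 * 8), c(4, 8, 8)))
  expect_identical(movieData(downsampleMovie(m, 1, 1)), movieData(m))
  # 2x2 on a checkerboard of 0/100 -> uniform 50
  cb <- outer(0:7, 0:7, function(a, b) ((a + b) %% 2) * 100)
  mc <- MovieTensor(array(rep(cb, 2), c(2, 8, 8)))
  mc@data[1, , ] <- cb; mc@data[2, , ] <- cb
  ds <- downsampleMovie(mc, 2, 1)
  expect_equal(movieData(ds)[1, , ], matrix(50, 4, 4))
  # temporal downsampling of a linear ramp keeps the endpoints
  T <- 40
  ramp <- array(rep(seq(0, 39), 4), c(T, 2, 2))
  for (t in 1:T) ramp[t, , ] <- t - 1
  dt <- downsampleMovie(MovieTensor(ramp), 1, 4)
  expect_equal(movieData(dt)[1, 1, 1], 0)
  expect_equal(movieData(dt)[nFrames(dt), 1, 1], T - 1)
  expect_error(downsampleMovie(MovieTensor(array(0, c(2, 2, 2))), 4), "smaller")
})

test_that("uint8 conversion clips, rescales and lifts dark values", {
  set.seed(5)
  m <- MovieTensor(array(runif(4 * 16 * 16), c(4, 16, 16)))
  out <- movieData(convertToUint8(m))
  expect_true(all(out >= round(0.01 * 255)))
  expect_true(all(out <= 255))
  expect_gte(min(out), 2)
  # a value at the midpoint of the clipped range maps near mid-scale
  q <- stats::quantile(movieData(m), c(0.01, 0.9999))
  mid <- (q[1] + q[2]) / 2
  expMid <- round(255 * (0.01 + 0.99 * 0.5))
  idx <- which.min(abs(movieData(m) - mid))
  expect_lt(abs(out[idx] - expMid), 3)
  expect_error(convertToUint8(MovieTensor(array(1, c(2, 4, 4)))), "constant")
})

test_that("border padding follows the min(motion, cap) rule", {
  m <- MovieTensor(array(1, c(2, 40, 40)))
  b14 <- movieData(padBorder(m, 30, cap = 14))
  expect_true(all(is.na(b14[, 1:14, ])))
  expect_false(anyNA(b14[, 15:26, 15:26]))
  b5 <- movieData(padBorder(m, 5))
  expect_true(all(is.na(b5[, 1:5, ])))
  expect_false(anyNA(b5[, 6:35, 6:35]))
  expect_identical(movieData(padBorder(m, 0)), movieData(m))
})

test_that("missing values propagate, never silently filled", {
  data <- array(runif(3 * 16 * 16, 10, 20), c(3, 16, 16))
  data[2, 5, 5] <- NA
  m <- MovieTensor(data)
  expect_true(is.na(movieData(detrendMovie(m, 1))[2, 5, 5]))
  expect_true(is.na(movieData(spatialBandpassDivide(m, 5))[2, 5, 5]))
  expect_true(is.na(movieData(computeDFF(m, "mean"))[2, 5, 5]))
})
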