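test_that("the wheel conversion factor matches the printed value", {
  tr <- makeEncoderTrace(rep(0, 10))
  sp <- encoderSpeed(tr)
  expect_equal(sp$cmPerPulse, 0.0691144, tolerance = 1e-4)
  expect_true(all(sp$speed == 0))
})

test_that("encoder decoding recovers synthetic quadrature pulses exactly", {
  # one full revolution at constant speed in 1 s: 600 pulses, ~41.47 cm/s
  v <- 2 * pi * 6.6  # cm/s for one rev/s
  tr <- makeEncoderTrace(rep(v, 2000), sampleRate = 2000)
  sp <- encoderSpeed(tr)
  expect_equal(sum(sp$pulses), 600, tolerance = 1)
  expect_equal(mean(sp$speed), v, tolerance = v * 0.01)
  # direction flip mid-trace: CW pulses then CCW pulses
  prof <- c(rep(20, 800), rep(-20, 800))
  tr2 <- makeEncoderTrace(prof, sampleRate = 2000)
  sp2 <- encoderSpeed(tr2)
  expect_gt(sum(sp2$pulses[1:800]), 0)
  expect_lt(sum(sp2$pulses[801:1600]), 0)
  # reversing the channel roles swaps CW and CCW
  sp3 <- encoderSpeed(list(A = tr$B, B = tr$A, frameRate = 2000))
  expect_equal(sum(sp3$pulses), -sum(sp$pulses))
  expect_error(encoderSpeed(list(A = c(0, 2), B = c(0, 0))), "non-binary")
  expect_error(encoderSpeed(list(A = 1, B = 1)), ">= 2 samples")
})

test_that("body-part speed follows the frame-difference formula", {
  # stationary point: all zeros
  trk <- data.frame(x = rep(5, 10), y = rep(3, 10), likelihood = 1)
  expect_true(all(bodypartSpeed(trk, fps = 20, pxPerCm = 5) == 0))
  # 10 px/frame at 20 fps and 5 px/cm -> 40 cm/s
  trk2 <- data.frame(x = seq(0, 90, by = 10), y = 0, likelihood = 1)
  v <- bodypartSpeed(trk2, fps = 20, pxPerCm = 5)
  expect_equal(v[-1], rep(40, 9))
  expect_equal(v[1], 0)
  # likelihood gate excludes frames; elapsed time bridges the gap
  trk3 <- trk2; trk3$likelihood[5] <- 0.05
  v3 <- bodypartSpeed(trk3, fps = 20, pxPerCm = 5, minLikelihood = 0.1)
  expect_true(is.na(v3[5]))
  expect_equal(v3[6], 40)  # 20 px over 2 frames
  expect_error(bodypartSpeed(data.frame(x = 1, y = 1, likelihood = 1), 20, 5),
               "fewer than 2")
})

test_that("moving-mean smoothing spreads a spike while preserving its area", {
  n <- 400
  trk <- data.frame(x = c(rep(0, 200), 100, rep(100, n - 201)), y = 0,
                    likelihood = 1)
  fps <- 20
  raw <- bodypartSpeed(trk, fps, pxPerCm = 1)
  sm <- bodypartSpeed(trk, fps, pxPerCm = 1, smoothWindowS = 5)
  win <- 5 * fps
  expect_equal(sum(sm, na.rm = TRUE), sum(raw, na.rm = TRUE), tolerance = 1e-6)
  expect_gt(sum(sm > 0), win - 2)
  expect_lt(max(sm), max(raw))
})

test_that("SUDO thresholds evaluate the printed formula", {
  expect_equal(sudoThreshold(5, responded = TRUE), 10^(-0.46), tolerance = 1e-12)
  expect_equal(sudoThreshold(5, responded = FALSE), 10^(0.24 * 5.5 - 1.54))
  # strictly monotone in the filament index
  for (s in c(TRUE, FALSE)) {
    v <- sudoThreshold(1:9, responded = s)
    expect_true(all(diff(v) > 0))
  }
  # response vs no response differ by exactly 10^0.24
  expect_equal(sudoThreshold(4, FALSE) / sudoThreshold(4, TRUE), 10^0.24)
  expect_error(sudoThreshold(10, TRUE), "out of range")
})

test_that("Chaplan up-down thresholds evaluate the printed formula", {
  expect_equal(chaplanUpdown(2, 0, 0.3), 2)
  expect_equal(chaplanUpdown(1, 1, 0.3), 10^0.3)
  # k moves the threshold monotonically around F
  ks <- seq(-2, 2, by = 0.5)
  v <- vapply(ks, function(k) chaplanUpdown(0.6, k, 0.25), 0)
  expect_true(all(diff(v) > 0))
  expect_error(chaplanUpdown(-1, 0, 0.3), "positive")
})

test_that("microglia asymmetry ratio is bounded, antisymmetric and normalizable", {
  expect_equal(microgliaRatio(3, 3)$ratio, 0)
  expect_equal(microgliaRatio(3, 1)$ratio, 0.5)
  set.seed(71)
  ipsi <- runif(1e4, 0.1, 10); contra <- runif(1e4, 0.1, 10)
  r <- microgliaRatio(ipsi, contra)$ratio
  expect_true(all(r >= -1 & r <= 1))
  expect_equal(microgliaRatio(contra, ipsi)$ratio, -r)
  # baseline normalization subtracts the baseline-session mean
  rr <- microgliaRatio(c(2, 2, 4), c(1, 1, 1), baselineIdx = 1:2)
  expect_equal(mean(rr$normalized[1:2]), 0)
  expect_error(microgliaRatio(1, -1), "zero or non-finite")
})

test_that("stimulus response maps localize activations and find outer contours", {
  # zero-activity movie: all-zero map, no contours
  z <- MovieTensor(array(0, c(20, 32, 32)), frameRate = 10)
  r0 <- stimulusResponseMap(z, stimFrames = c(3, 10), windowFrames = 5,
                            contourThresholds = 0.5)
  expect_true(all(r0$map == 0))
  expect_equal(length(r0$outermost), 0)
  # Gaussian activation at (y0, x0): map peak within 2 px
  ny <- 48
  yg <- matrix(rep(0:(ny - 1), ny), ny, ny)
  xg <- matrix(rep(0:(ny - 1), each = ny), ny, ny)
  blob <- exp(-((yg - 30)^2 + (xg - 17)^2) / 18)
  data <- array(0, c(30, ny, ny))
  for (t in c(6:9, 16:19)) data[t, , ] <- blob
  m <- MovieTensor(data, frameRate = 10)
  r1 <- stimulusResponseMap(m, stimFrames = c(6, 16), windowFrames = 4,
                            medianFilter = TRUE, contourThresholds = 0.3)
  pk <- which(r1$map == max(r1$map), arr.ind = TRUE)[1, ]
  expect_lt(abs(pk[1] - 31), 2 + 1e-9)
  expect_lt(abs(pk[2] - 18), 2 + 1e-9)
  # two disjoint activation zones give two outermost contours
  data2 <- data
  blob2 <- exp(-((yg - 10)^2 + (xg - 38)^2) / 10)
  for (t in c(6:9, 16:19)) data2[t, , ] <- blob + blob2
  r2 <- stimulusResponseMap(MovieTensor(data2, frameRate = 10),
                            stimFrames = c(6, 16), windowFrames = 4,
                            contourThresholds = 0.3)
  expect_equal(length(r2$outermost), 2)
  # linearity in the input
  r3 <- stimulusResponseMap(setMovieData(m, movieData(m) * 2.5),
                            stimFrames = c(6, 16), windowFrames = 4,
                            medianFilter = FALSE)
  r1n <- stimulusResponseMap(m, stimFrames = c(6, 16), windowFrames = 4,
                             medianFilter = FALSE)
  expect_equal(r3$map, 2.5 * r1n$map, tolerance = 1e-12)
  expect_error(stimulusResponseMap(m, stimFrames = 99), "outside")
})

test_that("bead profiles normalize to [0, 1] with affine invariance", {
  expect_equal(beadProfileNormalize(c(2, 4, 6)), c(0, 0.5, 1))
  p <- c(0, 0.25, 1)
  expect_equal(beadProfileNormalize(p), p)
  set.seed(72)
  prof <- runif(50)
  expect_equal(beadProfileNormalize(3.2 * prof - 7), beadProfileNormalize(prof),
               tolerance = 1e-12)
  expect_error(beadProfileNormalize(rep(2, 5)), "constant")
})

test_that("per-camera intensity normalization equalizes gains", {
  x <- c(10, 12, 11)
  expect_equal(crossCameraIntensityNormalize(x, rep("a", 3)), x / mean(x))
  # two cameras with a 10x gain difference on the same true signal coincide
  truth <- c(1, 1.2, 0.9, 1.1)
  obs <- c(truth * 5, truth * 50)
  cams <- rep(c("ccd", "scmos"), each = 4)
  norm <- crossCameraIntensityNormalize(obs, cams)
  expect_equal(norm[1:4], norm[5:8], tolerance = 1e-12)
  for (cam in unique(cams)) expect_equal(mean(norm[cams == cam]), 1)
  expect_error(crossCameraIntensityNormalize(c(0, 0), c("a", "a")), "zero mean")
})
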