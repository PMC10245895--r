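test_that("likelihood gating drops records per frame, not per feature", {
  tab <- data.frame(feature = c("a", "a", "b", "b"), frame = c(1, 2, 1, 2),
                    x = 1:4, y = 1:4, likelihood = c(0.5, 0.995, 0.995, 0.5))
  out <- filterByLikelihood(tab, 0.99)
  expect_equal(nrow(out), 2)
  expect_equal(out$feature, c("a", "b"))
  expect_equal(out$frame, c(2, 1))
  # threshold 0 keeps everything
  expect_equal(nrow(filterByLikelihood(tab, 0)), 4)
  # a frame losing every feature is flagged uncorrectable
  tab2 <- tab; tab2$likelihood <- c(0.5, 0.995, 0.6, 0.995)
  expect_equal(attr(filterByLikelihood(tab2, 0.99), "uncorrectable"), 1)
})

test_that("feature QC drops decorrelated features", {
  T <- 60
  set.seed(21)
  drive <- cumsum(rnorm(T))
  mk <- function(id, y) data.frame(feature = id, frame = seq_len(T),
                                   x = 50, y = y, likelihood = 1)
  # four co-moving features: all pairwise correlations 1, none dropped
  tab <- rbind(mk("a", drive), mk("b", drive + 5), mk("c", drive - 3),
               mk("d", drive * 1 + 10))
  res <- qcFeatures(tab, minMeanCorrelation = 0.5)
  expect_equal(sort(res$report$kept), c("a", "b", "c", "d"))
  expect_true(all(abs(res$report$correlation - 1) < 1e-12))
  # an anti-phase feature has mean correlation ~ -1 and is dropped at 0
  tabA <- rbind(tab, mk("e", -drive))
  resA <- qcFeatures(tabA, minMeanCorrelation = 0)
  expect_true("e" %in% resA$report$dropped)
  # an independent random walk decorrelates and is dropped at 0.5
  tabR <- rbind(tab, mk("f", cumsum(rnorm(T))))
  resR <- qcFeatures(tabR, minMeanCorrelation = 0.5)
  expect_true("f" %in% resR$report$dropped)
  expect_false("a" %in% resR$report$dropped)
  expect_error(qcFeatures(tab[tab$frame == 1, ]), "fewer than 2 frames")
})

test_that("NCC tracking locates static, shifted and occluded features", {
  sim <- makeMovie(simConfig(shape = c(64, 64), T = 4, nCells = 0, seed = 22))
  m <- sim$movie
  pts <- rbind(c(31, 20), c(31, 44))
  rownames(pts) <- c("f1", "f2")
  # static movie: constant tracks, likelihood ~ 1
  tr <- trackFeaturesNCC(m, pts, searchRadius = 10)
  expect_true(all(tr$likelihood > 0.99))
  expect_equal(sd(tr$x[tr$feature == "f1"]), 0)
  # globally shifted frames are tracked at the shifted position
  d <- movieData(m)
  for (t in 2:4) d[t, , ] <- rbind(d[1, 13:64, ], d[1, 1:12, ])  # shift +12 rows
  m2 <- setMovieData(m, d)
  tr2 <- trackFeaturesNCC(m2, pts, searchRadius = 16)
  dy <- tr2$y[tr2$feature == "f1" & tr2$frame == 2] -
        tr2$y[tr2$feature == "f1" & tr2$frame == 1]
  expect_equal(dy, -12, tolerance = 0.5)
  # an occluding bright blob drops the likelihood
  d3 <- movieData(m)
  d3[3, 15:26, 26:37] <- max(d3) * 1.5
  tr3 <- trackFeaturesNCC(setMovieData(m, d3), pts[1, , drop = FALSE],
                          searchRadius = 10)
  expect_lt(tr3$likelihood[tr3$frame == 3], 0.99)
  expect_error(trackFeaturesNCC(m, pts, templateRadius = 40), "template larger")
})

test_that("LD-MCM leaves a motion-free movie untouched", {
  sim <- makeMovie(simConfig(shape = c(64, 64), T = 6, nCells = 0, seed = 23))
  tab <- makeFeatureTable(sim$truth)
  res <- runLDMCM(sim$movie, tab, residualPass = FALSE, refinementRounds = 0)
  for (t in 1:6) {
    M <- asMatrix(res$transforms[[t]])
    expect_lt(max(abs(M - cbind(diag(2), c(0, 0)))), 1e-6)
  }
  expect_equal(movieData(res$movie), movieData(sim$movie), tolerance = 1e-9)
})

test_that("LD-MCM collapses tracked feature point clouds on a moving movie", {
  sim <- makeMovie(simConfig(shape = c(96, 96), T = 25, rcShiftMax = 30,
                             jitterSdPx = 0.5, nCells = 0, seed = 24))
  tab <- makeFeatureTable(sim$truth, jitterSd = 0.2, seed = 25)
  res <- runLDMCM(sim$movie, tab, seed = 0)
  clean <- makeFeatureTable(sim$truth)
  raw <- featureResidual(clean)
  cor <- featureResidual(clean, res$transforms)
  expect_gt(raw, 5)
  expect_lt(cor, 0.5)
  expect_lt(cor, raw)
  # determinism: identical transforms for the same seed
  res2 <- runLDMCM(sim$movie, tab, seed = 0)
  expect_identical(lapply(res$transforms, asMatrix),
                   lapply(res2$transforms, asMatrix))
})

test_that("LD-MCM tolerates outlier features through the consensus fit", {
  sim <- makeMovie(simConfig(shape = c(96, 96), T = 20, rcShiftMax = 25,
                             nCells = 0, seed = 26))
  clean <- makeFeatureTable(sim$truth)
  resC <- runLDMCM(sim$movie, clean, seed = 0, residualPass = FALSE)
  noisy <- makeFeatureTable(sim$truth, jitterSd = 0.2, outlierFraction = 0.3,
                            seed = 27)
  resN <- runLDMCM(sim$movie, noisy, seed = 0, residualPass = FALSE)
  rC <- featureResidual(clean, resC$transforms)
  rN <- featureResidual(clean, resN$transforms)
  expect_lt(abs(rN - rC), 0.5)
})

test_that("frames with too few features inherit a neighbour transform and flag", {
  sim <- makeMovie(simConfig(shape = c(64, 64), T = 5, rcShiftMax = 6,
                             nCells = 0, seed = 28))
  tab <- makeFeatureTable(sim$truth)
  tab$likelihood[tab$frame == 3] <- 0.5  # frame 3 loses all features
  res <- runLDMCM(sim$movie, tab, seed = 0, residualPass = FALSE,
                  refinementRounds = 0)
  expect_true(3 %in% res$flaggedFrames)
  expect_true("interpolated" %in% res$transforms[[3]]@flags)
})

test_that("hemicords can be corrected separately and recombined", {
  sim <- makeMovie(simConfig(shape = c(96, 96), T = 10, rcShiftMax = 15,
                             nCells = 0, seed = 29))
  tab <- makeFeatureTable(sim$truth)
  res <- runLDMCMHemicords(sim$movie, tab, seed = 0, residualPass = FALSE)
  expect_equal(frameDim(res$movie), c(96, 96))
  clean <- makeFeatureTable(sim$truth)
  # per-side transforms both track the global rigid motion
  s <- sim$truth$shifts; trueDy <- s[, "rc"] - s[1, "rc"]
  for (side in c("left", "right")) {
    recDy <- vapply(res[[side]]$transforms, function(tf) asMatrix(tf)[2, 3], 0)
    expect_lt(max(abs(recDy - trueDy)), 1)
  }
  # recombined movie aligns to the reference frame better than raw
  c0 <- mean(frameTemplateCorrelation(sim$movie, 1), na.rm = TRUE)
  c1 <- mean(frameTemplateCorrelation(res$movie, getFrame(res$movie, 1)), na.rm = TRUE)
  expect_gt(c1, c0)
})
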