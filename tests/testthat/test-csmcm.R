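sessionBase <- function(seed = 41, shape = c(160, 160)) {
  sim <- makeMovie(simConfig(shape = shape, T = 3, nCells = 0, seed = seed))
  spinalmcm:::meanFrame(sim$movie)
}

test_that("session sets pad to a common shape with missing pixels", {
  a <- matrix(1, 20, 30); b <- matrix(2, 25, 10)
  ss <- sessionSet(list(s1 = a, s2 = b))
  expect_equal(dim(ss$frames[[1]]), c(25, 30))
  expect_true(all(is.na(ss$frames[[1]]
[21:25, ])))
  expect_true(all(is.na(ss$frames[[2]][, 11:30])))
})

test_that("a session aligns to itself with identity and correlation 1", {
  base <- sessionBase()
  res <- alignSessions(sessionSet(list(ref = base, ref2 = base)))
  expect_equal(unname(res$correlations["ref"]), 1)
  expect_gt(res$correlations["ref2"], 0.999)
  M <- asMatrix(res$transforms[[2]])
  expect_lt(max(abs(M - cbind(diag(2), c(0, 0)))), 0.2)
})

test_that("a shifted and rotated session copy is recovered within 1 px / 0.3 deg", {
  base <- sessionBase(42)
  # large shifts run along the cord (rostrocaudal), as they do in vivo
  tfT <- rigidTransform(-15, 80, 2 * pi / 180)
  mov <- warpImage(base, tfT)
  res <- alignSessions(sessionSet(list(ref = base, shifted = mov)),
                       init = list(NULL, c(18, -78)))
  M <- asMatrix(res$transforms[[2]])
  want <- asMatrix(invertTransform(tfT))
  theta <- atan2(M[2, 1], M[1, 1]) * 180 / pi
  expect_lt(abs(theta - (-2)), 0.3)
  expect_lt(max(abs(M[, 3] - want[, 3])), 1)
  expect_gt(res$correlations[2], 0.95)
})

test_that("alignment does not depend on session order", {
  base <- sessionBase(43)
  m2 <- warpImage(base, rigidTransform(25, 10, 0.01))
  m3 <- warpImage(base, rigidTransform(-18, 30, -0.015))
  r1 <- alignSessions(sessionSet(list(a = base, b = m2, c = m3)))
  r2 <- alignSessions(sessionSet(list(a = base, c = m3, b = m2)))
  expect_equal(asMatrix(r1$transforms[[2]]), asMatrix(r2$transforms[[3]]),
               tolerance = 0.05)
  expect_equal(asMatrix(r1$transforms[[3]]), asMatrix(r2$transforms[[2]]),
               tolerance = 0.05)
})

test_that("concatenated refinement removes residual inter-session jitter", {
  sim <- makeMovie(simConfig(shape = c(64, 64), T = 4, nCells = 0, seed = 44))
  m <- sim$movie
  # a single pre-aligned session passes through within interpolation error
  ref <- refineConcatenated(list(m))
  ok <- is.finite(movieData(ref))
  expect_lt(max(abs(movieData(ref)[ok] - movieData(m)[ok])), 0.25)
  # inject +-2 px jitter on the second copy
  d <- movieData(m)
  jit <- m
  for (t in 1:4) d[t, , ] <- warpImage(getFrame(m, t),
                                       translationTransform(2 * (-1)^t, -2))
  jit <- setMovieData(m, d)
  refJ <- refineConcatenated(list(m, jit))
  corPre <- frameTemplateCorrelation(jit, getFrame(m, 1))
  corPost <- frameTemplateCorrelation(refJ, 1)[5:8]
  expect_gt(mean(corPost, na.rm = TRUE), mean(corPre, na.rm = TRUE))
  expect_error(refineConcatenated(list(m), referenceFrame = 99), "out of range")
  expect_error(refineConcatenated(list(m, m), maxFrames = 5), "streaming")
})

test_that("session quality reports Pearson and Spearman, with vessel enhancement", {
  base <- sessionBase(45, shape = c(96, 96))
  q <- sessionQuality(list(self = base), base)
  expect_equal(q$pearson, 1)
  expect_equal(q$spearman, 1)
  # additive noise at SNR ~ sqrt(10) attenuates like the closed form
  set.seed(46)
  sdS <- sd(base)
  noisy <- base + rnorm(length(base), 0, sdS / sqrt(10))
  qn <- sessionQuality(list(n = noisy), base)
  expect_equal(qn$pearson, 1 / sqrt(1 + 1 / 10), tolerance = 0.02)
  # a brightness rescale leaves raw correlation unchanged and vessel-enhanced
  # correlation near 1
  qr <- sessionQuality(list(r = base * 3 + 40), base)
  expect_equal(qr$pearson, 1, tolerance = 1e-9)
  qv <- sessionQuality(list(r = base * 3 + 40), base, vesselEnhance = TRUE)
  expect_gt(qv$pearson, 0.98)
  # constant frames report missing
  qc <- sessionQuality(list(flat = matrix(1, 96, 96)), base)
  expect_true(is.na(qc$pearson))
})

test_that("cell matching honors the centroid and shape gates", {
  cen <- separatedCentroids(12, seed = 47)
  mapA <- makeCellMap(cen, seed = 5)
  # identical duplicate: every cell matches itself with shape correlation 1
  mId <- matchCellsAcrossSessions(list(mapA, mapA), centroidMaxPx = 5)
  expect_equal(sum(table(mId$global_id) == 2), 12)
  expect_true(all(mId$shape_corr[!is.na(mId$shape_corr)] > 0.999))
  # 3 px shift within the 5 px gate: full matching
  mapB <- makeCellMap(cen + matrix(c(2.1, -2.1), 12, 2, byrow = TRUE), seed = 5)
  m3 <- matchCellsAcrossSessions(list(mapA, mapB), centroidMaxPx = 5,
                                 minShapeCorr = 0.6)
  expect_equal(sum(table(m3$global_id) == 2), 12)
  # 20 px shift against a 15 px gate: nothing matches (cells separated by
  # more than shift + gate, so no wrong pairing is geometrically possible)
  set.seed(50)
  cenW <- cbind(c(18, 18, 74, 74), c(18, 74, 18, 74)) + matrix(runif(8, -3, 3), 4, 2)
  wideA <- makeCellMap(cenW, seed = 6)
  wideC <- makeCellMap(cenW + matrix(c(14.2, -14.2), 4, 2, byrow = TRUE), seed = 6)
  m20 <- matchCellsAcrossSessions(list(wideA, wideC), centroidMaxPx = 15,
                                  minShapeCorr = 0.6)
  expect_equal(sum(table(m20$global_id) == 2), 0)
})

test_that("the nearer centroid wins and matching is symmetric", {
  # two candidate cells 4 px apart versus one target
  mkOne <- function(cen) makeCellMap(cen, seed = 9)
  A <- mkOne(rbind(c(40, 40), c(40, 44)))
  B <- mkOne(rbind(c(40, 41)))
  m <- matchCellsAcrossSessions(list(A, B), centroidMaxPx = 5, minShapeCorr = 0)
  grp <- m$global_id[m$session == 2]
  partner <- m[m$session == 1 & m$global_id == grp, ]
  expect_equal(partner$centroid_y, 40)  # 1 px beats 3 px
  # symmetry: A->B equals B->A as a set of pairs
  cen <- separatedCentroids(8, seed = 48)
  X <- makeCellMap(cen, seed = 11)
  Y <- makeCellMap(cen + 1.5, seed = 11)
  ab <- matchCellsAcrossSessions(list(X, Y), centroidMaxPx = 5)
  ba <- matchCellsAcrossSessions(list(Y, X), centroidMaxPx = 5)
  pairsOf <- function(m, sesLabel) {
    g <- split(paste0(sesLabel[m$session], ":", m$cell), m$global_id)
    g <- g[lengths(g) == 2]
    sort(unname(vapply(g, function(p) paste(sort(p), collapse = "|"), "")))
  }
  expect_equal(pairsOf(ab, c("X", "Y")), pairsOf(ba, c("Y", "X")))
  # empty sessions are allowed
  m0 <- matchCellsAcrossSessions(list(A, list()), centroidMaxPx = 5)
  expect_equal(sum(m0$session == 2), 0)
})

test_that("session transforms map footprints before matching", {
  set.seed(49)
  cen <- cbind(rep(c(22, 50, 78), 2), rep(c(30, 66), each = 3)) +
         matrix(runif(12, -3, 3), 6, 2)
  A <- makeCellMap(cen, seed = 13)
  B <- makeCellMap(cen + matrix(c(12, -9), 6, 2, byrow = TRUE), seed = 13)
  # without the transform nothing matches at the 5 px gate...
  m0 <- matchCellsAcrossSessions(list(A, B), centroidMaxPx = 5)
  expect_equal(sum(table(m0$global_id) == 2), 0)
  # ...with the session transform everything does
  tfs <- list(NULL, translationTransform(-12, 9))
  m1 <- matchCellsAcrossSessions(list(A, B), sessionTransforms = tfs,
                                 centroidMaxPx = 5)
  expect_equal(sum(table(m1$global_id) == 2), 6)
})
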