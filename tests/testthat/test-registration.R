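test_that("Transform2D forms a group under composition", {
  a <- rigidTransform(3, -2, 0.2)
  b <- rigidTransform(-1, 5, -0.05)
  c <- affineTransform(matrix(c(1.02, 0.01, -0.01, 0.98, 2, 1), 2, 3))
  # associativity
  m1 <- asMatrix(composeTransform(composeTransform(a, b), c))
  m2 <- asMatrix(composeTransform(a, composeTransform(b, c)))
  expect_equal(m1, m2, tolerance = 1e-12)
  # inverse: invert(compose(a,b)) == compose(invert(b), invert(a))
  i1 <- asMatrix(invertTransform(composeTransform(a, b)))
  i2 <- asMatrix(composeTransform(invertTransform(b), invertTransform(a)))
  expect_equal(i1, i2, tolerance = 1e-12)
  # identity round trip on points
  pts <- cbind(runif(5, 0, 100), runif(5, 0, 100))
  back <- applyTransform(invertTransform(a), applyTransform(a, pts))
  expect_equal(unname(back), unname(pts), tolerance = 1e-10)
})

test_that("rigid transforms keep an orthonormal linear part", {
  tf <- rigidTransform(1, 2, 0.3)
  L <- asMatrix(tf)[, 1:2]
  expect_equal(crossprod(L), diag(2), tolerance = 1e-12)
  expect_equal(det(L), 1, tolerance = 1e-12)
  expect_error(new("Transform2D", kind = "rigid",
                   matrix = matrix(c(2, 0, 0, 1, 0, 0), 2, 3)),
               "orthonormal")
})

test_that("warping honors identity, inversion and the missing-border contract", {
  img <- smoothImage(48, 48, seed = 11)
  expect_identical(warpImage(img, translationTransform(0, 0)), img)
  w <- warpImage(img, translationTransform(5, 0))
  expect_true(all(is.na(w[, 1:5])))
  back <- warpImage(w, translationTransform(-5, 0))
  ok <- is.finite(back)
  expect_lt(max(abs(back[ok] - img[ok])), 1e-6)
})

test_that("phase correlation recovers integer and subpixel translations", {
  img <- smoothImage(96, 96, sigma = 2, seed = 12)
  expect_equal(unname(asMatrix(estimateTranslation(img, img))[, 3]), c(0, 0),
               tolerance = 0.01)
  # fixed is the moving image shifted by (12, -7) (circular wrap)
  fixed <- circShift(img, 12, -7)
  d <- asMatrix(estimateTranslation(img, fixed))[, 3]
  expect_equal(unname(d), c(12, -7), tolerance = 0.1)
  # subpixel: band-limited fixed image shifted by (3.4, 0)
  fixed2 <- warpImage(img, translationTransform(3.4, 0))
  fixed2[!is.finite(fixed2)] <- mean(img)
  d2 <- asMatrix(estimateTranslation(img, fixed2))[, 3]
  expect_equal(unname(d2), c(3.4, 0), tolerance = 0.25)
  expect_error(estimateTranslation(matrix(1, 10, 10), matrix(1, 10, 10)),
               "degenerate")
})

test_that("constrained affine estimation recovers constructed warps", {
  img <- smoothImage(128, 128, sigma = 3, seed = 13)
  # identity pair
  e0 <- asMatrix(estimateAffine(img, img))
  expect_equal(unname(e0), unname(cbind(diag(2), c(0, 0))), tolerance = 0.02)
  # 2 deg rotation + (10, 5) shift
  tfT <- rigidTransform(10, 5, 2 * pi / 180)
  mov <- warpImage(img, tfT)
  est <- estimateAffine(mov, img, allowRotation = TRUE)
  M <- asMatrix(est)
  theta <- atan2(M[2, 1], M[1, 1]) * 180 / pi
  want <- asMatrix(invertTransform(tfT))
  expect_lt(abs(theta - (-2)), 0.2)
  expect_lt(max(abs(M[, 3] - want[, 3])), 0.5)
  # with skew disallowed the estimated linear part carries no skew at all:
  # R(theta)^T L is exactly diagonal by construction
  shear <- affineTransform(matrix(c(1, 0, 0.08, 1, 0, 0), 2, 3))
  ms <- warpImage(img, shear)
  es <- asMatrix(estimateAffine(ms, img, allowRotation = TRUE, allowSkew = FALSE))
  th <- atan2(es[2, 1], es[1, 1])
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  D <- t(R) %*% es[, 1:2]
  expect_equal(unname(D[1, 2]), 0, tolerance = 1e-9)
})

test_that("consensus rigid estimation resists outliers and recovers rotations", {
  set.seed(14)
  pts <- cbind(runif(10, 0, 200), runif(10, 0, 200))
  # pure translation, no outliers: closed form
  tf <- estimateRigidFromPoints(pts + matrix(c(30, 0), 10, 2, byrow = TRUE), pts,
                                trials = 200, seed = 0)
  M <- asMatrix(tf)
  expect_equal(M[, 3], c(30, 0), tolerance = 1e-6)
  expect_equal(atan2(M[2, 1], M[1, 1]), 0, tolerance = 1e-6)
  # 3 of 10 points replaced by distant outliers
  theta <- 5 * pi / 180
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  ref <- t(R %*% t(pts)) + matrix(c(12, -8), 10, 2, byrow = TRUE)
  mov <- pts
  mov[1:3, ] <- mov[1:3, ] + matrix(runif(6, 100, 200), 3, 2)
  tfo <- estimateRigidFromPoints(ref, mov, trials = 1000, inlierPx = 20, seed = 0)
  expect_equal(sum(attr(tfo, "inliers")), 7)
  Mo <- asMatrix(tfo)
  expect_equal(atan2(Mo[2, 1], Mo[1, 1]) * 180 / pi, 5, tolerance = 0.01)
  expect_equal(Mo[, 3], c(12, -8), tolerance = 0.1)
  # rotation about the centroid: Procrustes-exact
  cen <- colMeans(pts)
  refR <- t(R %*% t(sweep(pts, 2, cen))) + matrix(cen, 10, 2, byrow = TRUE)
  tfr <- estimateRigidFromPoints(refR, pts, seed = 0)
  expect_equal(atan2(asMatrix(tfr)[2, 1], asMatrix(tfr)[1, 1]) * 180 / pi, 5,
               tolerance = 0.01)
})

test_that("consensus estimator handles degenerate inputs and is deterministic", {
  expect_error(estimateRigidFromPoints(cbind(1, 1), cbind(1, 1)[0, , drop = FALSE]),
               "at least 2")
  # coincident points: translation-only fallback
  mv <- matrix(5, 4, 2)
  rf <- matrix(8, 4, 2)
  tfd <- estimateRigidFromPoints(rf, mv)
  expect_equal(transformKind(tfd), "translation")
  expect_equal(asMatrix(tfd)[, 3], c(3, 3))
  # same seed, same answer
  set.seed(15)
  pts <- cbind(runif(8, 0, 100), runif(8, 0, 100))
  ref <- pts + matrix(c(4, 9), 8, 2, byrow = TRUE)
  ref[1:3, ] <- ref[1:3, ] + 300
  a <- estimateRigidFromPoints(ref, pts, seed = 7)
  b <- estimateRigidFromPoints(ref, pts, seed = 7)
  expect_identical(asMatrix(a), asMatrix(b))
})

test_that("point-based and intensity-based translation agree on pure shifts", {
  img <- smoothImage(96, 96, sigma = 2.5, seed = 16)
  fixed <- circShift(img, 9, -4)
  dI <- asMatrix(estimateTranslation(img, fixed))[, 3]
  set.seed(16)
  pts <- cbind(runif(12, 20, 76), runif(12, 20, 76))
  dP <- asMatrix(estimateRigidFromPoints(pts + matrix(c(9, -4), 12, 2, byrow = TRUE),
                                         pts, seed = 0))[, 3]
  expect_lt(max(abs(dI - dP)), 0.25)
})

test_that("consensus recovery survives 50% inlier fractions (mini Monte Carlo)", {
  # small-scale version of the breakdown property: full-scale run lives in
  # the acceptance suite
  ok <- 0
  for (rep in 1:25) {
    set.seed(100 + rep)
    pts <- cbind(runif(10, 0, 150), runif(10, 0, 150))
    ref <- pts + matrix(c(20, -30), 10, 2, byrow = TRUE)
    out <- sample(10, 5)
    mv <- pts
    mv[out, ] <- mv[out, ] + matrix(runif(10, 80, 300) * sample(c(-1, 1), 10, TRUE), 5, 2)
    tf <- estimateRigidFromPoints(ref, mv, trials = 1000, inlierPx = 20, seed = rep)
    err <- max(abs(asMatrix(tf)[, 3] - c(20, -30)))
    if (err < 1) ok <- ok + 1
  }
  expect_equal(ok, 25)
})
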