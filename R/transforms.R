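#' Compose two transforms
#'
#' `composeTransform(a, b)` returns the transform applying `b` first and then
#' `a` (matrix product `A %*% [B; 0 0 1]`).
#'
#' @param a,b [Transform2D-class] objects.
#' @return a [Transform2D-class].
#' @export
composeTransform <- function(a, b) {
  A <- rbind(a@matrix, c(0, 0, 1))
  B <- rbind(b@matrix, c(0, 0, 1))
  M <- (A %*% B)[1:2, , drop = FALSE]
  kind <- if (a@kind == "affine" || b@kind == "affine") "affine"
          else if (a@kind == "rigid" || b@kind == "rigid") "rigid"
          else "translation"
  new("Transform2D", kind = kind, matrix = M,
      frameIndex = b@frameIndex, flags = union(a@flags, b@flags))
}

#' Invert a transform
#' @param x a [Transform2D-class].
#' @return the inverse [Transform2D-class].
#' @export
invertTransform <- function(x) {
  M <- solve(rbind(x@matrix, c(0, 0, 1)))[1:2, , drop = FALSE]
  new("Transform2D", kind = x@kind, matrix = M, frameIndex = x@frameIndex,
      flags = x@flags)
}

#' Apply a transform to point coordinates
#'
#' @param x a [Transform2D-class].
#' @param pts n x 2 matrix of (x, y) pixel coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
applyTransform <- function(x, pts) {
  pts <- as.matrix(pts)[, 1:2, drop = FALSE]
  out <- cbind(pts, 1) %*% t(x@matrix)
  colnames(out) <- c("x", "y")
  out
}

#' Warp a frame or movie by a transform or displacement field
#'
#' Resamples with bilinear interpolation so the output is aligned with the
#' fixed/reference frame. For a [Transform2D-class] `tf` (moving coordinates
#' to fixed coordinates) the output is `out(p) = frame(tf^{-1} p)`. For a
#' [DisplacementField-class] `u` the output is `out(p) = frame(p + u(p))`.
#' Pixels sampling outside the input support become missing, never
#' extrapolated.
#'
#' @param x a Y x X matrix or a [MovieTensor-class].
#' @param transform a [Transform2D-class], a [DisplacementField-class], or a
#'   list of either with one element per frame (movies only).
#' @return the warped object of the same type.
#' @export
warpImage <- function(x, transform) {
  if (is(x, "MovieTensor")) {
    d <- dim(x@data)
    tfs <- if (is.list(transform)) transform else rep(list(transform), d[1])
    stopifnot(length(tfs) == d[1])
    out <- x@data
    for (t in seq_len(d[1]))
      out[t, , ] <- warpImage(matrix(x@data[t, , ], d[2], d[3]), tfs[[t]])
    return(setMovieData(x, out))
  }
  if (is(x, "matrix")) {
    if (is(transform, "Transform2D")) {
      Binv <- invertTransform(transform)@matrix
      return(cpp_warp_affine(x, Binv))
    }
    if (is(transform, "DisplacementField")) {
      if (transform@rcAxis == "y")
        return(cpp_warp_field(x, transform@uML, transform@uRC))
      return(cpp_warp_field(x, transform@uRC, transform@uML))
    }
  }
  stop("unsupported combination of image and transform types")
}

#' Estimate a subpixel translation between two frames
#'
#' Phase cross-correlation with local quadratic subpixel refinement. Returns
#' a translation transform `tf` such that `warpImage(moving, tf)` aligns with
#' `fixed`. Both frames should have been normalized with
#' [normalizeFrameForRegistration] when they come from raw movies.
#'
#' @param moving,fixed Y x X matrices of identical shape.
#' @param window apply a Hann window before the FFT (default TRUE).
#' @return a [Transform2D-class] of kind `"translation"`.
#' @export
estimateTranslation <- function(moving, fixed, window = TRUE) {
  stopifnot(all(dim(moving) == dim(fixed)))
  prep <- function(f) {
    na <- !is.finite(f)
    if (all(na)) stop("degenerate (all-missing) frame")
    if (any(na)) f[na] <- mean(f[!na])
    if (stats::sd(f) == 0) stop("degenerate (constant) frame")
    f - mean(f)
  }
  f <- prep(fixed); m <- prep(moving)
  ny <- nrow(f); nx <- ncol(f)
  if (window) {
    wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 1) / (ny - 1))
    wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / (nx - 1))
    W <- outer(wy, wx)
    f <- f * W; m <- m * W
  }
  Ff <- stats::fft(f); Fm <- stats::fft(m)
  cross <- Ff * Conj(Fm)
  mag <- Mod(cross)
  cross <- cross / pmax(mag, 1e-12)
  corr <- Re(stats::fft(cross, inverse = TRUE))
  peak <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  # quadratic subpixel refinement around the peak (wrapped neighbours)
  sub <- function(idx, n, get) {
    c0 <- get(idx); cm <- get((idx - 2) %% n + 1); cp <- get(idx %% n + 1)
    den <- cm - 2 * c0 + cp
    off <- if (abs(den) > 1e-12) 0.5 * (cm - cp) / den else 0
    off <- max(min(off, 0.5), -0.5)
    shift <- (idx - 1) + off
    if (shift > n / 2) shift <- shift - n
    shift
  }
  dy <- sub(peak[1], ny, function(i) corr[i, peak[2]])
  dx <- sub(peak[2], nx, function(i) corr[peak[1], i])
  translationTransform(dx, dy)
}

# parameter vector (tx, ty, sx, sy, theta, k) -> 2 x 3 matrix acting about a
# center c: x' = L (x - c) + c + t
affineFromParams <- function(p, center, allowRotation, allowSkew) {
  theta <- if (allowRotation) p[5] else 0
  k <- if (allowSkew) p[6] else 0
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  L <- R %*% matrix(c(p[3], 0, k, p[4]), 2, 2)
  cbind(L, p[1:2] + center - as.double(L %*% center))
}

#' Estimate a constrained affine transform between two frames
#'
#' Multi-resolution (coarse-to-fine) least-squares intensity registration.
#' With `allowRotation = FALSE` and `allowSkew = FALSE` the linear part is
#' diagonal (per-axis scale plus translation); adding rotation gives a
#' similarity-like transform without skew. Images are smoothed at each
#' pyramid level (`smoothingPx` scales down with the level). Returns the
#' transform mapping `moving` into `fixed` coordinates; if the optimizer does
#' not converge the best transform so far is returned with a
#' `"not_converged"` flag.
#'
#' @param moving,fixed Y x X matrices of identical shape.
#' @param allowRotation,allowSkew free the rotation / skew parameters.
#' @param pyramidLevels number of pyramid levels (default 6, capped so the
#'   coarsest level keeps at least 16 px on each side).
#' @param smoothingPx nominal smoothing in px (default 30); converted to a
#'   per-level Gaussian sigma (halved per level and capped at 2.5 px, since
#'   pyramid levels are already band-limited and heavy blur biases the fit
#'   across missing-data borders).
#' @param maxIter Gauss-Newton iterations per level.
#' @param init optional initial [Transform2D-class] (e.g. a translation from
#'   feature matching).
#' @param scaleBounds allowed per-axis scale range (default `c(0.8, 1.25)`).
#'   Imaging sessions share their optics, so the field-of-view scale cannot
#'   drift far; the bound also removes a texture-aliasing attractor where a
#'   large stretch of blurred texture accidentally matches.
#' @param translationOnly freeze the scales at 1 (pure translation estimate).
#' @return a [Transform2D-class] of kind `"affine"` (or `"translation"`).
#' @export
estimateAffine <- function(moving, fixed, allowRotation = FALSE, allowSkew = FALSE,
                           pyramidLevels = 6, smoothingPx = 30, maxIter = 50,
                           init = NULL, scaleBounds = c(0.8, 1.25),
                           translationOnly = FALSE) {
  stopifnot(all(dim(moving) == dim(fixed)))
  # missing pixels stay missing through the pyramid so padded / out-of-FOV
  # regions never pull the optimum; residuals use the valid overlap only
  naDown <- function(fr) {
    ny <- floor(nrow(fr) / 2) * 2; nx <- floor(ncol(fr) / 2) * 2
    fr <- fr[seq_len(ny), seq_len(nx), drop = FALSE]
    a <- array(fr, c(2, ny / 2, 2, nx / 2))
    out <- apply(a, c(2, 4), function(v) {
      v <- v[is.finite(v)]
      if (length(v)) mean(v) else NA_real_
    })
    matrix(out, ny / 2, nx / 2)
  }
  # Gaussian smoothing by normalized convolution (NA-aware)
  ncSmooth <- function(fr, sigma) {
    ok <- is.finite(fr)
    v <- ifelse(ok, fr, 0)
    num <- cpp_gauss_smooth(v, sigma)
    den <- cpp_gauss_smooth(matrix(as.double(ok), nrow(fr), ncol(fr)), sigma)
    out <- num / pmax(den, 1e-9)
    out[den < 0.8] <- NA_real_   # erode rather than extrapolate at borders
    out
  }
  maxLev <- max(1, floor(log2(min(dim(fixed)) / 16)) + 1)
  L <- min(pyramidLevels, maxLev)
  pyr <- list(list(m = moving, f = fixed))
  for (l in seq_len(L - 1))
    pyr[[l + 1]] <- list(m = naDown(pyr[[l]]$m), f = naDown(pyr[[l]]$f))
  # shape parameters (scale-free): sx, sy, theta, k; translation carried as
  # the full-resolution matrix column and re-derived per level
  shape <- c(1, 1, 0, 0)
  Lpart <- diag(2)
  tFull <- c(0, 0)
  if (!is.null(init)) {
    M <- init@matrix
    shape[3] <- atan2(M[2, 1], M[1, 1])
    shape[1] <- sqrt(M[1, 1]^2 + M[2, 1]^2)
    shape[2] <- sqrt(M[1, 2]^2 + M[2, 2]^2)
    Lpart <- M[, 1:2]
    tFull <- M[, 3]
  }
  nPar <- if (translationOnly) 2L else if (allowSkew) 6L else if (allowRotation) 5L else 4L
  converged <- FALSE
  for (l in L:1) {
    sc <- 2^(l - 1)
    # pyramid levels are already low-passed; cap the extra per-level blur, as
    # heavy blur extrapolates across missing-data borders and biases the fit
    sig <- min(max(0.6, smoothingPx / sc / 2), 2.5)
    f <- ncSmooth(pyr[[l]]$f, sig)
    m <- ncSmooth(pyr[[l]]$m, sig)
    ny <- nrow(f); nx <- ncol(f)
    xg0 <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
    yg0 <- matrix(rep(0:(ny - 1), nx), ny, nx)
    # level-coordinate matrix: x_l' = L x_l + t / sc
    Ml <- cbind(Lpart, tFull / sc)
    # anchor the scale / rotation center on the centroid of the current valid
    # overlap (the overlap can sit far off the image center after large
    # inter-session shifts, and a distant center couples scale to translation)
    Binv0 <- solve(rbind(Ml, c(0, 0, 1)))[1:2, ]
    w0 <- cpp_warp_affine(m, Binv0)
    ok0 <- is.finite(w0) & is.finite(f)
    cen <- if (sum(ok0) >= 32) c(mean(xg0[ok0]), mean(yg0[ok0]))
           else c((nx - 1) / 2, (ny - 1) / 2)
    xg <- xg0 - cen[1]
    yg <- yg0 - cen[2]
    pl <- c(as.double(Ml[, 3] - cen + Ml[, 1:2] %*% cen), shape)
    # guard against the overlap-shrink degeneracy: a scale or shift that
    # drives the valid overlap down can reach a tiny, accidentally matching
    # sliver; track the best parameters by overlap-penalized mean residual
    n0 <- max(sum(ok0), 32)
    bestPl <- pl; bestScore <- Inf
    for (it in seq_len(maxIter)) {
      A <- affineFromParams(pl, cen, allowRotation, allowSkew)
      Binv <- solve(rbind(A, c(0, 0, 1)))[1:2, ]
      w <- cpp_warp_affine(m, Binv)
      gx <- w; gy <- w
      gx[] <- 0; gy[] <- 0
      gx[, 2:(nx - 1)] <- (w[, 3:nx] - w[, 1:(nx - 2)]) / 2
      gy[2:(ny - 1), ] <- (w[3:ny, ] - w[1:(ny - 2), ]) / 2
      r <- w - f
      ok <- is.finite(r) & is.finite(gx) & is.finite(gy)
      if (sum(ok) < max(32, 0.4 * n0)) break
      score <- mean(r[ok]^2) * (n0 / sum(ok))^2
      if (score < bestScore) { bestScore <- score; bestPl <- pl }
      # output-coordinate (overlap-centered) perturbation columns:
      # translation, per-axis scale, rotation, skew
      cols <- list(gx[ok], gy[ok])
      if (!translationOnly) {
        cols <- c(cols, list((gx * xg)[ok], (gy * yg)[ok]))
        if (allowRotation) cols <- c(cols, list((-gx * yg + gy * xg)[ok]))
        if (allowSkew) cols <- c(cols, list((gx * yg)[ok]))
      }
      J <- do.call(cbind, cols)
      H <- crossprod(J)
      step <- tryCatch(solve(H + 1e-8 * diag(nPar), crossprod(J, r[ok])),
                       error = function(e) NULL)
      if (is.null(step)) break
      dp <- as.double(step)
      # per-parameter damping: translations up to 8 px per iteration, scale /
      # rotation / skew increments kept small so coarse levels cannot diverge
      dp[1:2] <- pmax(pmin(dp[1:2], 8), -8)
      if (!translationOnly) {
        dp[-(1:2)] <- pmax(pmin(dp[-(1:2)], 0.05), -0.05)
        pl[3] <- min(max(pl[3] * (1 + dp[3]), scaleBounds[1]), scaleBounds[2])
        pl[4] <- min(max(pl[4] * (1 + dp[4]), scaleBounds[1]), scaleBounds[2])
        if (allowRotation) pl[5] <- pl[5] + dp[5]
        if (allowSkew) pl[6] <- pl[6] + dp[6]
      }
      pl[1] <- pl[1] + dp[1]; pl[2] <- pl[2] + dp[2]
      if (max(abs(dp[1:2])) < 1e-3 &&
          (translationOnly || max(abs(dp[-(1:2)])) < 1e-5)) { converged <- TRUE; break }
    }
    Ml <- affineFromParams(bestPl, cen, allowRotation, allowSkew)
    Lpart <- Ml[, 1:2, drop = FALSE]
    tFull <- Ml[, 3] * sc
    shape <- bestPl[3:6]
  }
  M <- cbind(Lpart, tFull)
  kind <- if (translationOnly) "translation" else "affine"
  tf <- new("Transform2D", kind = kind,
            matrix = if (translationOnly) cbind(diag(2), M[, 3]) else M,
            flags = if (converged) character() else "not_converged")
  tf
}

#' Robust rigid transform from corresponding control points
#'
#' Random-sample-consensus estimation of a rigid (rotation + translation, no
#' scaling) transform mapping `movPts` onto `refPts`. Candidate transforms
#' from random point pairs are scored by their inlier count (pairs within
#' `inlierPx` after applying the candidate); the best candidate is refit on
#' its inliers by 2-D Procrustes without scaling. Ties are broken by minimum
#' inlier RMS error. Fully reproducible given `seed`.
#'
#' @param refPts,movPts n x 2 matrices of (x, y) coordinates (n >= 2).
#' @param trials number of random trials (default 1000).
#' @param inlierPx inlier distance gate in px (default 20).
#' @param maxRotationDeg candidate rotations beyond this magnitude are
#'   rejected (default 30). Field-of-view motion cannot flip or spin the
#'   cord, so large-rotation candidates are always outlier artifacts.
#' @param seed RNG seed (default 0).
#' @return a [Transform2D-class] of kind `"rigid"` (or `"translation"` for
#'   degenerate point sets), with attribute `inliers` (logical vector).
#' @export
estimateRigidFromPoints <- function(refPts, movPts, trials = 1000, inlierPx = 20,
                                    maxRotationDeg = 30, seed = 0) {
  refPts <- as.matrix(refPts); movPts <- as.matrix(movPts)
  n <- nrow(refPts)
  if (n < 2 || nrow(movPts) != n) stop("need at least 2 corresponding point pairs")
  # degenerate: all points coincident -> translation-only
  spread <- max(dist(movPts))
  if (!is.finite(spread) || spread < 1e-9) {
    d <- colMeans(refPts) - colMeans(movPts)
    tf <- translationTransform(d[1], d[2])
    attr(tf, "inliers") <- rep(TRUE, n)
    return(tf)
  }
  idx <- withSeed(seed, {
    i1 <- sample.int(n, trials, replace = TRUE)
    i2 <- sample.int(n - 1, trials, replace = TRUE)
    i2 <- ifelse(i2 >= i1, i2 + 1L, i2)  # distinct second index
    cbind(i1, i2)
  })
  # vectorized candidate transforms from each sampled pair
  mv1 <- movPts[idx[, 1], , drop = FALSE]; mv2 <- movPts[idx[, 2], , drop = FALSE]
  rf1 <- refPts[idx[, 1], , drop = FALSE]; rf2 <- refPts[idx[, 2], , drop = FALSE]
  angM <- atan2(mv2[, 2] - mv1[, 2], mv2[, 1] - mv1[, 1])
  angR <- atan2(rf2[, 2] - rf1[, 2], rf2[, 1] - rf1[, 1])
  theta <- angR - angM
  ct <- cos(theta); st <- sin(theta)
  txv <- rf1[, 1] - (ct * mv1[, 1] - st * mv1[, 2])
  tyv <- rf1[, 2] - (st * mv1[, 1] + ct * mv1[, 2])
  # residuals: trials x n
  px <- outer(ct, movPts[, 1]) - outer(st, movPts[, 2]) + txv
  py <- outer(st, movPts[, 1]) + outer(ct, movPts[, 2]) + tyv
  d2 <- (px - matrix(refPts[, 1], trials, n, byrow = TRUE))^2 +
        (py - matrix(refPts[, 2], trials, n, byrow = TRUE))^2
  inl <- d2 <= inlierPx^2
  counts <- rowSums(inl)
  tooRotated <- abs(((theta + pi) %% (2 * pi)) - pi) > maxRotationDeg * pi / 180
  counts[tooRotated] <- -1L
  if (max(counts) < 0) {
    # every candidate over-rotated: translation-only consensus fallback
    d <- refPts - movPts
    tf <- translationTransform(stats::median(d[, 1]), stats::median(d[, 2]))
    attr(tf, "inliers") <- sqrt(rowSums((movPts + matrix(asMatrix(tf)[, 3], n, 2,
      byrow = TRUE) - refPts)^2)) <= inlierPx
    return(tf)
  }
  best <- which(counts == max(counts))
  if (length(best) > 1) {
    rms <- vapply(best, function(i) sqrt(mean(d2[i, inl[i, ]])), 0)
    best <- best[which.min(rms)]
  } else best <- best[1]
  inliers <- inl[best, ]
  if (sum(inliers) < 2) inliers <- rep(TRUE, n)
  tf <- procrustesRigid(refPts[inliers, , drop = FALSE], movPts[inliers, , drop = FALSE])
  attr(tf, "inliers") <- inliers
  tf
}

# least-squares rigid fit (rotation + translation, no scaling)
procrustesRigid <- function(refPts, movPts) {
  cr <- colMeans(refPts); cm <- colMeans(movPts)
  A <- crossprod(sweep(movPts, 2, cm), sweep(refPts, 2, cr))
  if (max(abs(A)) < 1e-12) {
    d <- cr - cm
    return(translationTransform(d[1], d[2]))
  }
  sv <- svd(A)
  R <- sv$v %*% diag(c(1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
  t <- cr - as.double(R %*% cm)
  theta <- atan2(R[2, 1], R[1, 1])
  rigidTransform(t[1], t[2], theta)
}

#' Pyramid least-squares translation registration
#'
#' The in-house intensity-based rigid engine's translation mode, implemented
#' in compiled code for per-frame use on whole movies: coarse-to-fine
#' Gauss-Newton on the sum of squared differences. This is the conventional
#' gradient-descent translation registration; unlike feature-based
#' correction it has a limited capture range and fails on displacements
#' beyond its coarsest pyramid basin.
#'
#' @param moving,fixed Y x X matrices of identical shape (missing pixels are
#'   treated as zero weight).
#' @param pyramidLevels pyramid depth (default 4).
#' @param smoothingPx Gaussian smoothing sigma per level (default 1.5).
#' @param maxIter iterations per level (default 50).
#' @return a [Transform2D-class] of kind `"translation"` mapping `moving`
#'   onto `fixed`.
#' @export
estimateTranslationLK <- function(moving, fixed, pyramidLevels = 4,
                                  smoothingPx = 1.5, maxIter = 50) {
  stopifnot(all(dim(moving) == dim(fixed)))
  d <- cpp_lk_translation(fixed, moving, as.integer(pyramidLevels),
                          smoothingPx, as.integer(maxIter))
  translationTransform(d[1], d[2])
}
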