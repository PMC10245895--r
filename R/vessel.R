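#' Frangi vesselness filter configuration
#'
#' Defaults match the vessel-diameter pipeline: Hessian scales 1 to 20 px in
#' steps of 2, blobness correction beta1 = 0.5, structureness correction
#' beta2 = 15, detecting dark ridges (vessels darker than tissue).
#'
#' @param sigmaMin,sigmaMax,sigmaStep Hessian scale range and step (px).
#' @param beta1 blobness (eccentricity) correction constant.
#' @param beta2 structureness (second-order energy) correction constant.
#' @param darkRidges detect dark ridges on a bright background (default TRUE);
#'   set FALSE for bright ridges.
#' @return a list of class `"FrangiConfig"`.
#' @export
frangiConfig <- function(sigmaMin = 1, sigmaMax = 20, sigmaStep = 2,
                         beta1 = 0.5, beta2 = 15, darkRidges = TRUE) {
  stopifnot(sigmaMin <= sigmaMax, sigmaMin > 0, sigmaStep > 0,
            beta1 > 0, beta2 > 0)
  structure(list(sigmas = seq(sigmaMin, sigmaMax, by = sigmaStep),
                 beta1 = beta1, beta2 = beta2, darkRidges = isTRUE(darkRidges)),
            class = "FrangiConfig")
}

#' Min-max normalize a frame and match its histogram to a reference
#'
#' Per-frame vessel-measurement normalization: rescale the frame to [0, 1]
#' by its min and max, match its histogram to the (equally normalized)
#' reference frame by quantile mapping, and multiply by 150 so downstream
#' thresholds operate on a consistent scale across frames.
#'
#' @param frame non-constant Y x X matrix.
#' @param reference reference Y x X matrix (non-constant).
#' @param scale final multiplicative scale (default 150).
#' @return normalized, histogram-matched frame.
#' @export
normalizeAndMatch <- function(frame, reference, scale = 150) {
  mm <- function(f) {
    v <- f[is.finite(f)]
    if (!length(v) || max(v) == min(v)) stop("constant frame: cannot normalize")
    (f - min(v)) / (max(v) - min(v))
  }
  f <- mm(frame); r <- mm(reference)
  fv <- f[is.finite(f)]; rv <- r[is.finite(r)]
  # quantile mapping via mid-rank probabilities and the inverse empirical
  # CDF (type 1): exact identity when frame and reference share a
  # distribution, including heavily tied (discrete) histograms
  p <- (rank(fv, ties.method = "average") - 0.5) / length(fv)
  mapped <- stats::quantile(rv, p, names = FALSE, type = 1)
  out <- f
  out[is.finite(f)] <- mapped
  out * scale
}

#' Multiscale Frangi vesselness of a frame
#'
#' Hessian-eigenvalue ridge filter: at each scale sigma the frame is
#' Gaussian-smoothed, the gamma-normalized Hessian (multiplied by sigma^2)
#' gives eigenvalues |l1| <= |l2|, and the vesselness is
#' `exp(-Rb^2 / (2 b1^2)) * (1 - exp(-S^2 / (2 b2^2)))` with blobness
#' Rb = l1/l2 and structureness S the Frobenius norm, zeroed where the ridge
#' polarity is wrong (l2 < 0 for dark ridges). The response is the maximum
#' over scales and lies in [0, 1]: elongated ridges score high, blobs and
#' flat regions low.
#'
#' @param frame Y x X matrix (finite values).
#' @param config a [frangiConfig].
#' @return vesselness map in [0, 1].
#' @export
frangiVesselness <- function(frame, config = frangiConfig()) {
  if (min(dim(frame)) <= 4 * max(config$sigmas) / 2 && min(dim(frame)) < 16)
    stop("frame smaller than the largest Hessian scale support")
  na <- !is.finite(frame)
  if (any(na)) frame[na] <- mean(frame[!na])
  best <- matrix(0, nrow(frame), ncol(frame))
  ny <- nrow(frame); nx <- ncol(frame)
  for (s in config$sigmas) {
    g <- cpp_gauss_smooth(frame, s)
    # second differences, gamma-normalized by s^2
    dxx <- matrix(0, ny, nx); dyy <- dxx; dxy <- dxx
    dxx[, 2:(nx - 1)] <- g[, 3:nx] - 2 * g[, 2:(nx - 1)] + g[, 1:(nx - 2)]
    dyy[2:(ny - 1), ] <- g[3:ny, ] - 2 * g[2:(ny - 1), ] + g[1:(ny - 2), ]
    gx <- matrix(0, ny, nx)
    gx[, 2:(nx - 1)] <- (g[, 3:nx] - g[, 1:(nx - 2)]) / 2
    dxy[2:(ny - 1), ] <- (gx[3:ny, ] - gx[1:(ny - 2), ]) / 2
    dxx <- dxx * s^2; dyy <- dyy * s^2; dxy <- dxy * s^2
    # eigenvalues of [[dxx, dxy], [dxy, dyy]]
    tr2 <- (dxx + dyy) / 2
    rad <- sqrt(((dxx - dyy) / 2)^2 + dxy^2)
    e1 <- tr2 + rad; e2 <- tr2 - rad
    # order by magnitude: l1 smaller, l2 larger
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1); l2 <- ifelse(swap, e1, e2)
    S2 <- l1^2 + l2^2
    Rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-Rb2 / (2 * config$beta1^2)) * (1 - exp(-S2 / (2 * config$beta2^2)))
    # polarity: dark ridges have l2 > 0, bright ridges l2 < 0
    v[if (config$darkRidges) l2 < 0 else l2 > 0] <- 0
    best <- pmax(best, v)
  }
  best[na] <- 0
  best
}

#' Local thickness of a binary mask
#'
#' For every foreground pixel p, the diameter of the largest disk that lies
#' fully inside the mask and contains p; zero on background. Pixels are
#' treated as unit squares, so a full-width strip of height h has thickness h
#' on its interior. Computed per frame independently for movies (time must
#' never be treated as a spatial axis). Implemented by exact Euclidean
#' distance transform plus disk painting.
#'
#' @param mask Y x X logical or 0/1 matrix.
#' @return Y x X thickness map in px.
#' @export
localThickness <- function(mask) {
  m <- matrix(as.double(mask > 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(matrix(0, nrow(m), ncol(m)))
  cpp_local_thickness(m)
}

#' Per-frame vessel diameter series for a region of interest
#'
#' The full diameter chain, run per frame: min-max normalization and
#' histogram matching to a reference frame ([normalizeAndMatch]), Frangi
#' vesselness ([frangiVesselness]), thresholding the vesselness at
#' `maskThresh`, local thickness ([localThickness]), and the mean thickness
#' over the ROI's foreground pixels. Optionally the series is normalized to
#' the mean over a declared baseline epoch. Frames where the ROI is empty
#' after thresholding give a missing value.
#'
#' @param movie a [MovieTensor-class].
#' @param roi list(y = rows, x = cols) ROI (1-based index vectors), or a
#'   logical Y x X matrix.
#' @param referenceFrame histogram-matching reference (default 1).
#' @param frangi a [frangiConfig].
#' @param maskThresh vesselness threshold (default 0.03).
#' @param ltThresh gray-value threshold (default 40, alternative 80) on the
#'   complemented matched frame (0-150 scale) defining the vessel boundary.
#' @param medianPrefilter apply a small median prefilter to each frame first.
#' @param baselineFrames optional frame indices of the baseline epoch; when
#'   given, `normalized` divides by the baseline mean.
#' @return data.frame with columns `frame`, `thickness_px`, `thickness_um`
#'   (NA when pixel size unknown) and, when `baselineFrames` is given,
#'   `normalized`.
#' @export
roiDiameterSeries <- function(movie, roi, referenceFrame = 1,
                              frangi = frangiConfig(), maskThresh = 0.03,
                              ltThresh = 40, medianPrefilter = FALSE,
                              baselineFrames = NULL) {
  d <- frameDim(movie)
  roiMask <- if (is.matrix(roi)) roi > 0 else {
    stopifnot(max(roi$y) <= d[1], max(roi$x) <= d[2], min(roi$y) >= 1, min(roi$x) >= 1)
    m <- matrix(FALSE, d[1], d[2]); m[roi$y, roi$x] <- TRUE; m
  }
  ref <- getFrame(movie, referenceFrame)
  th <- rep(NA_real_, nFrames(movie))
  for (t in seq_len(nFrames(movie))) {
    fr <- getFrame(movie, t)
    if (medianPrefilter) fr <- medianFilter3(fr)
    nm <- normalizeAndMatch(fr, ref)
    vs <- frangiVesselness(nm, frangi)
    cmpl <- 150 - nm   # complement: vessels bright on the 0-150 scale
    mask <- vs >= maskThresh & cmpl >= ltThresh
    if (!any(mask & roiMask)) next
    lt <- localThickness(mask)
    sel <- mask & roiMask
    th[t] <- mean(lt[sel])
  }
  out <- data.frame(frame = seq_len(nFrames(movie)), thickness_px = th,
                    thickness_um = if (is.na(movie@pixelSize)) NA_real_
                                   else th * movie@pixelSize)
  if (!is.null(baselineFrames)) {
    base <- mean(th[baselineFrames], na.rm = TRUE)
    out$normalized <- th / base
  }
  out
}

# 3x3 median filter (replicate border) used as an optional prefilter
medianFilter3 <- function(fr) {
  ny <- nrow(fr); nx <- ncol(fr)
  idx <- function(v, n) pmin(pmax(v, 1), n)
  stack <- array(NA_real_, c(ny, nx, 9))
  k <- 0
  for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1
    stack[, , k] <- fr[idx(1:ny + dy, ny), idx(1:nx + dx, nx)]
  }
  apply(stack, c(1, 2), stats::median, na.rm = TRUE)
}

#' Epoch-wise correlation of vessel diameter and fluorescence
#'
#' Ordinary least-squares line per epoch between the diameter series and the
#' paired whole-frame fluorescence, reporting slope, intercept and R^2 (in
#' [0, 1]) for each epoch.
#'
#' @param series numeric vessel diameter series.
#' @param fluorescence numeric series of equal length.
#' @param epochs named list of frame-index vectors partitioning the frames
#'   (default: one epoch covering everything).
#' @return data.frame with columns `epoch, n, slope, intercept, r_squared`.
#' @export
correlateDiameterFluorescence <- function(series, fluorescence, epochs = NULL) {
  stopifnot(length(series) == length(fluorescence))
  if (is.null(epochs)) epochs <- list(all = seq_along(series))
  if (is.null(names(epochs))) names(epochs) <- paste0("epoch", seq_along(epochs))
  out <- lapply(names(epochs), function(nm) {
    i <- epochs[[nm]]
    x <- series[i]; y <- fluorescence[i]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) stop("epoch '", nm, "' has fewer than 3 usable frames")
    fit <- stats::lm(y[ok] ~ x[ok])
    data.frame(epoch = nm, n = sum(ok),
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = summary(fit)$r.squared)
  })
  do.call(rbind, out)
}
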