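#' Remove a photobleaching trend from a movie
#'
#' Fits a polynomial (order 1 or 3) to the temporally ordered per-frame mean
#' intensities, subtracts the fitted value from every pixel of each frame and
#' adds back the grand mean, so the output sits in the same intensity range as
#' the input and develops no negative offset. After detrending, the per-frame
#' means carry no residual polynomial trend up to the chosen order.
#'
#' @param movie a [MovieTensor-class].
#' @param order polynomial order, 1 or 3. Requires `nFrames(movie) > order`.
#' @return a detrended [MovieTensor-class] of the same shape.
#' @export
detrendMovie <- function(movie, order = 1) {
  stopifnot(order %in% c(1, 3))
  T <- nFrames(movie)
  if (T <= order) stop("too few frames (T <= order) to fit the trend")
  mu <- apply(movie@data, 1, function(fr) mean(fr, na.rm = TRUE))
  t <- seq_len(T)
  fit <- stats::lm(mu ~ stats::poly(t, order))
  fitted <- as.double(stats::fitted(fit))
  grand <- mean(mu)
  out <- movie@data
  for (i in t) out[i, , ] <- movie@data[i, , ] - fitted[i] + grand
  setMovieData(movie, out)
}

# radially symmetric low-pass FFT mask: unity out to `cutoff` cycles per FOV,
# raised-cosine rolloff over the next `edge` cycles
lowpassMask <- function(ny, nx, cutoff, edge = 2) {
  fy <- c(0:(floor(ny / 2)), -((ceiling(ny / 2) - 1):1))
  if (ny %% 2 == 0) fy <- c(0:(ny / 2 - 1), -(ny / 2):-1)
  fx <- if (nx %% 2 == 0) c(0:(nx / 2 - 1), -(nx / 2):-1) else c(0:floor(nx / 2), -(floor(nx / 2):1))
  r <- sqrt(outer(fy^2, fx^2, "+"))
  m <- matrix(0, ny, nx)
  m[r <= cutoff] <- 1
  band <- r > cutoff & r < cutoff + edge
  m[band] <- 0.5 * (1 + cos(pi * (r[band] - cutoff) / edge))
  m
}

#' Divide each frame by its spatial low-pass version
#'
#' Flattens slow background fluctuations (neuropil, uneven illumination) by
#' dividing every frame by a low-pass-filtered copy of itself that keeps only
#' 0 to `cutoffCycles` cycles across the field of view. A spatially uniform
#' frame maps to 1 everywhere; structure finer than the cutoff keeps its
#' relative contrast. The low-pass uses a radially symmetric FFT mask with a
#' raised-cosine edge of 2 cycles to suppress ringing. Denominator magnitudes
#' below 1e-12 yield missing values.
#'
#' @param movie a [MovieTensor-class] with strictly positive frames (shift the
#'   input first if needed).
#' @param cutoffCycles low-pass cutoff in cycles per field of view (>= 1).
#' @return a [MovieTensor-class] of dimensionless ratios.
#' @export
spatialBandpassDivide <- function(movie, cutoffCycles = 10) {
  stopifnot(cutoffCycles >= 1)
  d <- frameDim(movie)
  mask <- lowpassMask(d[1], d[2], cutoffCycles)
  n <- prod(d)
  mapFrames(movie, function(fr) {
    na <- !is.finite(fr)
    if (all(na)) return(fr)
    if (any(na)) fr[na] <- mean(fr[!na])
    lp <- Re(stats::fft(stats::fft(fr) * mask, inverse = TRUE)) / n
    if (all(abs(lp) < 1e-12)) stop("all-zero low-pass frame: cannot divide")
    out <- fr / lp
    out[abs(lp) < 1e-12] <- NA_real_
    out[na] <- NA_real_
    out
  })
}

#' Normalize a frame for intensity-based registration
#'
#' The registration normalization chain: subtract the frame mean; subtract a
#' pillbox-filtered (circular averaging, radius one tenth of the smaller frame
#' dimension by default) copy to remove slowly varying background; smooth with
#' a disk of radius 3 px; and optionally complement the image (subtract each
#' pixel from the frame maximum) so that dark vasculature becomes the
#' brightest structure.
#'
#' @param frame Y x X matrix, at least 10 x 10.
#' @param pillboxFraction pillbox radius as a fraction of the smaller frame
#'   dimension (default 0.1). Overridden by `pillboxRadius`.
#' @param pillboxRadius explicit pillbox radius in px (optional).
#' @param blurDiskRadius radius of the final smoothing disk (default 3 px).
#' @param complement invert the result so vessels are bright (default TRUE).
#' @return normalized Y x X matrix.
#' @export
normalizeFrameForRegistration <- function(frame, pillboxFraction = 0.1,
                                          pillboxRadius = NULL,
                                          blurDiskRadius = 3, complement = TRUE) {
  if (nrow(frame) < 10 || ncol(frame) < 10) stop("frame too small (needs >= 10 x 10)")
  r <- if (is.null(pillboxRadius)) floor(min(dim(frame)) * pillboxFraction) else pillboxRadius
  if (r < 1) stop("frame too small for a pillbox radius of at least 1 px")
  na <- !is.finite(frame)
  if (any(na)) frame[na] <- mean(frame[!na])
  f <- frame - mean(frame)
  f <- f - diskFilter(f, r)
  f <- diskFilter(f, blurDiskRadius)
  if (complement) f <- max(f) - f
  f[na] <- NA_real_
  f
}

#' Relative fluorescence change (delta F over F)
#'
#' Computes (F - F0) / F0 per pixel. The baseline F0 is either the pixelwise
#' temporal mean of the whole movie (`"mean"`) or a pixelwise soft minimum,
#' the temporal quantile at `softMinPercentile` percent (`"soft_min"`,
#' default bottom 0.1 percent). Pixels whose baseline is not strictly
#' positive become missing.
#'
#' @param movie a [MovieTensor-class].
#' @param f0Mode `"mean"` or `"soft_min"`.
#' @param softMinPercentile percentile (in percent) for the soft minimum.
#' @return a dimensionless [MovieTensor-class].
#' @export
computeDFF <- function(movie, f0Mode = c("mean", "soft_min"), softMinPercentile = 0.1) {
  f0Mode <- match.arg(f0Mode)
  if (all(movie@data == 0, na.rm = TRUE)) stop("all-zero movie: baseline undefined")
  d <- dim(movie@data)
  f0 <- apply(movie@data, c(2, 3), function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    if (f0Mode == "mean") mean(v)
    else stats::quantile(v, softMinPercentile / 100, names = FALSE, type = 7)
  })
  f0[!is.finite(f0) | f0 <= 0] <- NA_real_
  out <- movie@data
  for (t in seq_len(d[1])) out[t, , ] <- (movie@data[t, , ] - f0) / f0
  setMovieData(movie, out)
}

# block-mean downsampling of one frame by an integer factor
blockDown <- function(fr, f) {
  ny <- floor(nrow(fr) / f) * f; nx <- floor(ncol(fr) / f) * f
  fr <- fr[seq_len(ny), seq_len(nx), drop = FALSE]
  a <- array(fr, c(f, ny / f, f, nx / f))
  apply(a, c(2, 4), mean)
}

#' Downsample a movie spatially and/or temporally
#'
#' Spatial downsampling averages `factor x factor` pixel blocks (bilinear
#' interpolation at the aligned half-integer grid). Temporal downsampling
#' linearly interpolates each pixel's time series onto an evenly spaced grid
#' that preserves the first and last time points.
#'
#' @param movie a [MovieTensor-class].
#' @param spatialFactor 1, 2 or 4.
#' @param temporalFactor 1 or 4 (any integer >= 1 accepted).
#' @return a [MovieTensor-class]; `frameRate` and `pixelSize` are rescaled.
#' @export
downsampleMovie <- function(movie, spatialFactor = 1, temporalFactor = 1) {
  stopifnot(spatialFactor %in% c(1, 2, 4), temporalFactor >= 1)
  d <- dim(movie@data)
  if (spatialFactor > min(d[2], d[3])) stop("spatial dimension smaller than factor")
  if (temporalFactor > d[1]) stop("temporal dimension smaller than factor")
  data <- movie@data
  if (spatialFactor > 1) {
    ny <- floor(d[2] / spatialFactor); nx <- floor(d[3] / spatialFactor)
    out <- array(NA_real_, c(d[1], ny, nx))
    for (t in seq_len(d[1]))
      out[t, , ] <- blockDown(matrix(data[t, , ], d[2], d[3]), spatialFactor)
    data <- out
    d <- dim(data)
  }
  newRate <- movie@frameRate
  if (temporalFactor > 1) {
    Tn <- max(2L, round(d[1] / temporalFactor))
    tOld <- seq_len(d[1])
    tNew <- seq(1, d[1], length.out = Tn)
    out <- array(NA_real_, c(Tn, d[2], d[3]))
    flat <- matrix(data, d[1], d[2] * d[3])
    res <- apply(flat, 2, function(v) stats::approx(tOld, v, xout = tNew)$y)
    out[] <- array(res, c(Tn, d[2], d[3]))
    data <- out
    newRate <- movie@frameRate * (Tn - 1) / (length(tOld) - 1)
  }
  new("MovieTensor", data = data, frameRate = newRate,
      pixelSize = movie@pixelSize * spatialFactor, rcAxis = movie@rcAxis)
}

#' Convert a movie to 8-bit with percentile clipping
#'
#' Computes a soft maximum and minimum as the `clipPercentiles` (default
#' 99.99th and 1st) percentiles of all pixel intensities, normalizes to
#' M1 = (M - min) / (max - min) clipped to 0..1, then rescales as
#' Mf = round(255 * (0.01 + 0.99 * M1)), which shifts all values upward so no
#' pixel is fully dark (the darkest output value is 3).
#'
#' @param movie a [MovieTensor-class]; must not be constant after clipping.
#' @param clipPercentiles length-2 vector, lower and upper percentile in
#'   percent (default `c(1, 99.99)`).
#' @return a [MovieTensor-class] holding integers in 0..255.
#' @export
convertToUint8 <- function(movie, clipPercentiles = c(1, 99.99)) {
  v <- movie@data[is.finite(movie@data)]
  q <- stats::quantile(v, clipPercentiles / 100, names = FALSE)
  if (q[2] <= q[1]) stop("constant movie: cannot rescale to 8-bit")
  m1 <- pmin(pmax((movie@data - q[1]) / (q[2] - q[1]), 0), 1)
  setMovieData(movie, round(255 * (0.01 + 0.99 * m1)))
}

#' Mark a fixed missing-value border on every frame
#'
#' Registration leaves variable invalid borders across frames; this applies a
#' single fixed border of width `min(ceiling(perFrameMaxMotion), cap)` pixels
#' (default cap 14) by setting border pixels to missing on every frame.
#'
#' @param movie a [MovieTensor-class].
#' @param perFrameMaxMotion the maximum per-frame motion in pixels.
#' @param cap maximum border width (default 14 px).
#' @return a [MovieTensor-class] with border pixels set to `NA`.
#' @export
padBorder <- function(movie, perFrameMaxMotion, cap = 14) {
  stopifnot(cap >= 0)
  b <- min(ceiling(perFrameMaxMotion), cap)
  if (b <= 0) return(movie)
  d <- frameDim(movie)
  out <- movie@data
  idxY <- c(seq_len(min(b, d[1])), d[1] - seq_len(min(b, d[1])) + 1)
  idxX <- c(seq_len(min(b, d[2])), d[2] - seq_len(min(b, d[2])) + 1)
  out[, idxY, ] <- NA_real_
  out[, , idxX] <- NA_real_
  setMovieData(movie, out)
}
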