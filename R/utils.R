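# Internal helpers shared across modules.

# run code with a temporarily fixed RNG state, restoring whatever was there
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# normalized disk ("pillbox") kernel of the given radius
diskKernel <- function(radius) {
  r <- floor(radius)
  stopifnot(r >= 1)
  g <- expand.grid(y = -r:r, x = -r:r)
  k <- matrix(as.double(g$y^2 + g$x^2 <= radius^2), 2 * r + 1, 2 * r + 1)
  k / sum(k)
}

# disk-kernel convolution with replicate border (EBImage filter2)
diskFilter <- function(frame, radius) {
  EBImage::filter2(frame, diskKernel(radius), boundary = "replicate")
}

# per-frame apply returning a movie array
mapFrames <- function(movie, f, ...) {
  d <- dim(movie@data)
  out <- movie@data
  for (t in seq_len(d[1])) {
    out[t, , ] <- f(matrix(movie@data[t, , ], d[2], d[3]), ...)
  }
  setMovieData(movie, out)
}

# Pearson correlation over jointly finite pixels; NA if degenerate
frameCor <- function(a, b, method = "pearson") {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) return(NA_real_)
  va <- a[ok]; vb <- b[ok]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb, method = method)
}

# mean frame (pixelwise, NA-aware) of a MovieTensor
meanFrame <- function(movie) {
  d <- dim(movie@data)
  m <- apply(movie@data, c(2, 3), function(v) {
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  })
  matrix(m, d[2], d[3])
}

# moving mean with NA-awareness, centered window
movingMean <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  out <- numeric(n)
  half <- floor(window / 2)
  xs <- ifelse(is.finite(x), x, 0)
  ws <- as.double(is.finite(x))
  cx <- cumsum(c(0, xs)); cw <- cumsum(c(0, ws))
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, lo + window - 1); lo <- max(1, hi - window + 1)
    w <- cw[hi + 1] - cw[lo]
    out[i] <- if (w > 0) (cx[hi + 1] - cx[lo]) / w else NA_real_
  }
  out
}
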