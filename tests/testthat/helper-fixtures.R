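# Shared fixtures: small deterministic images/movies built in code.

# band-limited random image (smooth enough for subpixel registration checks)
smoothImage <- function(ny = 64, nx = ny, sigma = 2, seed = 1, offset = 100,
                        amplitude = 20) {
  set.seed(seed)
  f <- spinalmcm:::cpp_gauss_smooth(matrix(rnorm(ny * nx), ny, nx), sigma)
  offset + amplitude * f / stats::sd(f)
}

# movie whose per-frame means follow `means`, with fixed spatial pattern
meanScheduleMovie <- function(means, ny = 8, nx = 8) {
  T <- length(means)
  pat <- matrix(seq(-1, 1, length.out = ny * nx), ny, nx)
  data <- array(0, c(T, ny, nx))
  for (t in seq_len(T)) data[t, , ] <- means[t] + pat - mean(pat)
  MovieTensor(data, frameRate = 20)
}

# integer-shift copy with circular wrap (keeps phase correlation exact)
circShift <- function(img, dx, dy) {
  ny <- nrow(img); nx <- ncol(img)
  img[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
}

# independent FFT low-pass oracle matching the package's mask definition
fftLowpassOracle <- function(frame, cutoff, edge = 2) {
  ny <- nrow(frame); nx <- ncol(frame)
  fy <- if (ny %% 2 == 0) c(0:(ny / 2 - 1), -(ny / 2):-1) else c(0:floor(ny / 2), -(floor(ny / 2):1))
  fx <- if (nx %% 2 == 0) c(0:(nx / 2 - 1), -(nx / 2):-1) else c(0:floor(nx / 2), -(floor(nx / 2):1))
  r <- sqrt(outer(fy^2, fx^2, "+"))
  m <- ifelse(r <= cutoff, 1, ifelse(r >= cutoff + edge, 0,
                                     0.5 * (1 + cos(pi * (r - cutoff) / edge))))
  Re(stats::fft(stats::fft(frame) * m, inverse = TRUE)) / (ny * nx)
}

# brute-force local thickness oracle: for each foreground pixel the largest
# 2 * (dist-to-background - 0.5) over centers whose open disk covers it,
# with the distance map computed by exhaustive search
bruteLocalThickness <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  fg <- which(mask > 0, arr.ind = TRUE)
  bg <- which(mask <= 0, arr.ind = TRUE)
  th <- matrix(0, ny, nx)
  if (!nrow(fg)) return(th)
  dt <- rep(Inf, nrow(fg))
  if (nrow(bg)) {
    for (i in seq_len(nrow(fg)))
      dt[i] <- sqrt(min((fg[i, 1] - bg[, 1])^2 + (fg[i, 2] - bg[, 2])^2))
  }
  r <- dt - 0.5
  for (i in seq_len(nrow(fg))) {
    if (r[i] < 0) next
    covered <- (fg[, 1] - fg[i, 1])^2 + (fg[, 2] - fg[i, 2])^2 <= r[i]^2
    t2 <- 2 * r[i]
    sel <- covered & th[fg] < t2
    th[fg[sel, , drop = FALSE]] <- t2
  }
  th
}

# cell centroids with a minimum separation (cell bodies do not overlap)
separatedCentroids <- function(n, lo = 12, hi = 84, minSep = 12, seed = 1) {
  set.seed(seed)
  out <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(out) < n) {
    tries <- tries + 1
    if (tries > 20000) stop("cannot place ", n, " cells at separation ", minSep)
    p <- runif(2, lo, hi)
    if (!nrow(out) || min(sqrt(rowSums(sweep(out, 2, p)^2))) >= minSep)
      out <- rbind(out, p)
  }
  out
}

# cell map fixture: anisotropic Gaussian cells with per-cell shape, so shape
# correlation is informative
makeCellMap <- function(centroids, ny = 96, nx = 96, seed = 1) {
  set.seed(seed)
  xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  ys <- matrix(rep(0:(ny - 1), nx), ny, nx)
  lapply(seq_len(nrow(centroids)), function(i) {
    cx <- centroids[i, 1]; cy <- centroids[i, 2]
    sx <- runif(1, 1.5, 3.5); sy <- runif(1, 1.5, 3.5)
    th <- runif(1, 0, pi)
    dx <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    dy <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    fp <- exp(-(dx^2 / (2 * sx^2) + dy^2 / (2 * sy^2)))
    fp[fp < 0.05] <- 0
    list(footprint = fp, centroid = c(cx, cy))
  })
}

# odd-width dark horizontal bar phantom, centered on a pixel row
barMovie <- function(w, ny = 80, contrast = 0.5, T = 1) {
  yg <- matrix(rep(0:(ny - 1), ny), ny, ny)
  fr <- 100 * (1 - contrast * ((abs(yg - ny / 2) <= (w - 1) / 2) * 1))
  data <- array(NA_real_, c(T, ny, ny))
  for (t in seq_len(T)) data[t, , ] <- fr
  MovieTensor(data)
}

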