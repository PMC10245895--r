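#' Locomotor speed from a quadrature rotary encoder
#'
#' Decodes the two binary channels A and B with the elementwise rules
#' `CW = (A > B) > diff(A)` and `CCW = -((B > A) > diff(B))`, combines them
#' as `v(t) = |CW(t) + CCW(t)|` (pulses per sample) and converts to cm/s with
#' the wheel conversion factor `Cp = 2 * pi * r / pulsesPerRev` cm per pulse
#' (0.0691144 cm/pulse at r = 6.6 cm and 600 pulses per revolution). The
#' first sample's speed is defined as 0.
#'
#' @param trace list or data.frame with binary vectors `A` and `B`, sample
#'   rate `frameRate` (Hz), `wheelRadiusCm` (default 6.6) and `pulsesPerRev`
#'   (default 600); missing fields take the defaults.
#' @return list with `speed` (cm/s per sample), `pulses` (signed pulses per
#'   sample, CW positive) and `cmPerPulse`.
#' @export
encoderSpeed <- function(trace) {
  A <- as.double(trace$A); B <- as.double(trace$B)
  if (length(A) < 2 || length(B) != length(A)) stop("need >= 2 samples on both channels")
  if (!all(A %in% c(0, 1)) || !all(B %in% c(0, 1))) stop("non-binary channels")
  fr <- if (!is.null(trace$frameRate)) trace$frameRate else 20
  r <- if (!is.null(trace$wheelRadiusCm)) trace$wheelRadiusCm else 6.6
  ppr <- if (!is.null(trace$pulsesPerRev)) trace$pulsesPerRev else 600
  stopifnot(r > 0, ppr > 0)
  cp <- 2 * pi * r / ppr
  n <- length(A)
  dA <- c(A[-1] - A[-n], 0)
  dB <- c(B[-1] - B[-n], 0)
  cw <- as.double((A > B) > dA)
  ccw <- -as.double((B > A) > dB)
  v <- abs(cw + ccw)
  v[1] <- 0
  list(speed = v * cp * fr, pulses = cw + ccw, cmPerPulse = cp)
}

#' Body-part speed from pose-estimation tracks
#'
#' Speed between successive tracked positions,
#' `v(t) = sqrt(dx^2 + dy^2) / (pxPerCm * dt)`, using only frames whose
#' tracking likelihood exceeds `minLikelihood` (default 0.1); gaps use the
#' actual elapsed time between retained frames. The first frame's speed is 0.
#' Optionally smoothed with a moving mean over `smoothWindowS` seconds
#' (5 s, i.e. 100 frames at 20 Hz, in the stimulus-response analyses).
#'
#' @param track data.frame with columns `x, y, likelihood` (one row per
#'   frame, in order) for a single body part.
#' @param fps frames per second.
#' @param pxPerCm pixels per cm conversion factor (> 0).
#' @param minLikelihood likelihood gate (default 0.1).
#' @param smoothWindowS moving-mean window in seconds (0 = no smoothing).
#' @return numeric speed series (cm/s), NA on frames excluded by the gate.
#' @export
bodypartSpeed <- function(track, fps, pxPerCm, minLikelihood = 0.1,
                          smoothWindowS = 0) {
  stopifnot(pxPerCm > 0, fps > 0)
  ok <- which(track$likelihood > minLikelihood)
  if (length(ok) < 2) stop("fewer than 2 frames pass the likelihood gate")
  n <- nrow(track)
  v <- rep(NA_real_, n)
  x <- track$x[ok]; y <- track$y[ok]
  dt <- diff(ok) / fps
  dist <- sqrt(diff(x)^2 + diff(y)^2) / pxPerCm
  v[ok[-1]] <- dist / dt
  v[ok[1]] <- 0
  if (smoothWindowS > 0) v <- movingMean(v, round(smoothWindowS * fps))
  v
}

#' SUDO up-down 50 percent withdrawal threshold
#'
#' Simplified up-down estimator from the final filament number:
#' `PWT = 10^(x * (F +- 0.5) + B)` gram-force, with slope x = 0.24 and
#' intercept B = -1.54; the adjustment is +0.5 when the animal did NOT
#' respond to the final filament and -0.5 when it did.
#'
#' @param finalFilament final filament number, 1 to 9 (the standard series
#'   0.04, 0.07, 0.16, 0.4, 0.6, 1, 1.4, 2, 4 gf).
#' @param responded logical: did the animal respond to the final filament?
#' @param slope,intercept formula constants (defaults 0.24 and -1.54).
#' @return threshold in gram-force.
#' @export
sudoThreshold <- function(finalFilament, responded, slope = 0.24, intercept = -1.54) {
  if (any(finalFilament < 1 | finalFilament > 9)) stop("filament index out of range 1-9")
  adj <- ifelse(responded, -0.5, 0.5)
  10^(slope * (finalFilament + adj) + intercept)
}

#' Chaplan up-down 50 percent withdrawal threshold
#'
#' `T50 = 10^(log10(F) + k * D)` gram-force, where F is the force of the
#' final filament, k the tabulated lookup value for the observed response
#' sequence and D the mean log10 gram-force difference between adjacent
#' filaments. The k table is not shipped with the package: supply the value
#' for your response sequence from the published up-down tables (they are
#' user data here, as lookup conventions vary between labs).
#'
#' @param finalForceGf force of the final filament in gram-force (> 0).
#' @param k lookup value for the response sequence.
#' @param D mean log-force step between adjacent filaments (> 0).
#' @return threshold in gram-force.
#' @export
chaplanUpdown <- function(finalForceGf, k, D) {
  if (any(finalForceGf <= 0)) stop("final filament force must be positive")
  stopifnot(D > 0)
  10^(log10(finalForceGf) + k * D)
}

#' Ipsilateral/contralateral fluorescence asymmetry ratio
#'
#' `R(t) = (F_ipsi - F_contra) / (F_ipsi + F_contra)`, bounded in [-1, 1]
#' for non-negative inputs and antisymmetric under side exchange. When
#' baseline sessions are declared the ratio series is additionally
#' normalized by subtracting the mean over all baseline sessions.
#'
#' @param ipsi,contra per-frame (or per-session) mean fluorescence of the
#'   two rectangular side ROIs; sums must be positive.
#' @param baselineIdx optional indices of baseline entries.
#' @return list with `ratio` and (when `baselineIdx` given) `normalized`.
#' @export
microgliaRatio <- function(ipsi, contra, baselineIdx = NULL) {
  stopifnot(length(ipsi) == length(contra))
  tot <- ipsi + contra
  if (any(!is.finite(tot)) || any(tot == 0)) stop("zero or non-finite total fluorescence")
  r <- (ipsi - contra) / tot
  out <- list(ratio = r)
  if (!is.null(baselineIdx)) out$normalized <- r - mean(r[baselineIdx])
  out
}

#' Post-stimulus response map with outermost activity contours
#'
#' Somatotopy analysis: averages the dF/F movie over the post-stimulus
#' window after each stimulus, median-filters the mean projection, and
#' extracts iso-level contour polylines at the requested thresholds. The
#' "outermost" contours are those not nested inside any other contour at the
#' same level (the outer edge of the bulk activity); two disjoint activation
#' zones therefore yield two outermost contours.
#'
#' @param dffMovie a [MovieTensor-class] of dF/F values.
#' @param stimFrames stimulus onset frame indices.
#' @param windowFrames frames averaged after each onset (default 3 s worth).
#' @param medianFilter median-filter the projection (default TRUE).
#' @param contourThresholds iso-levels for contour extraction.
#' @return list with `map` (Y x X projection), `contours` (all polylines from
#'   [grDevices::contourLines], x/y in 0-based px), and `outermost` (the
#'   non-nested subset).
#' @export
stimulusResponseMap <- function(dffMovie, stimFrames,
                                windowFrames = NULL, medianFilter = TRUE,
                                contourThresholds = NULL) {
  T <- nFrames(dffMovie)
  if (is.null(windowFrames)) windowFrames <- max(1L, round(3 * frameRate(dffMovie)))
  stopifnot(windowFrames >= 1)
  if (any(stimFrames < 1 | stimFrames > T)) stop("stimulus frame outside the movie")
  d <- frameDim(dffMovie)
  acc <- matrix(0, d[1], d[2]); n <- 0L
  for (s in stimFrames) {
    idx <- s:min(T, s + windowFrames - 1L)
    acc <- acc + apply(dffMovie@data[idx, , , drop = FALSE], c(2, 3), mean)
    n <- n + 1L
  }
  map <- acc / n
  if (medianFilter) map <- medianFilter3(map)
  contours <- list(); outer <- list()
  if (!is.null(contourThresholds) && any(map > min(contourThresholds), na.rm = TRUE)) {
    # contourLines works on x = rows -> transpose so x follows image columns
    cl <- grDevices::contourLines(x = 0:(d[2] - 1), y = 0:(d[1] - 1), z = t(map),
                                  levels = contourThresholds)
    contours <- cl
    if (length(cl)) {
      nested <- vapply(seq_along(cl), function(i) {
        any(vapply(seq_along(cl), function(j) {
          if (i == j || cl[[j]]$level != cl[[i]]$level) return(FALSE)
          pointInPolygon(cl[[i]]$x[1], cl[[i]]$y[1], cl[[j]]$x, cl[[j]]$y)
        }, TRUE))
      }, TRUE)
      outer <- cl[!nested]
    }
  }
  list(map = map, contours = contours, outermost = outer)
}

# even-odd ray-casting point-in-polygon test
pointInPolygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py) &&
        px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      inside <- !inside
    j <- i
  }
  inside
}

#' Min-max normalize a microsphere intensity profile
#'
#' `(I - min) / (max - min)`: output spans exactly [0, 1] and is invariant
#' under affine transformations of the input.
#'
#' @param profile non-constant numeric vector.
#' @return normalized profile.
#' @export
beadProfileNormalize <- function(profile) {
  v <- profile[is.finite(profile)]
  if (!length(v) || max(v) == min(v)) stop("constant profile: cannot normalize")
  (profile - min(v)) / (max(v) - min(v))
}

#' Normalize session intensities per acquisition camera
#'
#' Cameras differ in gain, so each session intensity is divided by the mean
#' intensity over all sessions acquired with the same camera; every camera's
#' normalized values then average exactly 1.
#'
#' @param intensities per-session intensity values.
#' @param cameraIds per-session camera labels (same length).
#' @return normalized intensity series.
#' @export
crossCameraIntensityNormalize <- function(intensities, cameraIds) {
  stopifnot(length(intensities) == length(cameraIds))
  out <- numeric(length(intensities))
  for (cam in unique(cameraIds)) {
    i <- cameraIds == cam
    m <- mean(intensities[i])
    if (!is.finite(m) || m == 0) stop("camera '", cam, "' has zero mean intensity")
    out[i] <- intensities[i] / m
  }
  out
}
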