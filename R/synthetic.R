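#' Synthetic spinal-cord movie configuration
#'
#' Study conditions for the ground-truth generator: a bright tissue field
#' crossed by a dark dorsal vein with ascending venule branches, two lateral
#' strips of Gaussian-blob neurons with exponential-decay calcium
#' transients, large predominantly rostrocaudal rigid shifts, smooth
#' rostrocaudal non-rigid deformation, an independently moving bright
#' occluding layer, exponential photobleaching, and Poisson plus read noise.
#' All amplitudes are in pixels / intensity units; a fixed `seed` makes every
#' output bitwise reproducible.
#'
#' @param shape frame shape `c(Y, X)`.
#' @param T number of frames.
#' @param frameRate Hz.
#' @param pixelSizeUm microns per pixel (2.5 um/px, a one-photon macroscope
#'   scale at which a 650 um shift is 260 px).
#' @param dorsalVeinWidth vein width in px.
#' @param venuleWidths widths of the ascending venule branches (px).
#' @param vesselContrast multiplicative intensity of vessel interiors
#'   (0.55: vessels are dark on bright tissue).
#' @param nCells neurons per movie, split between two lateral strips.
#' @param cellRadius Gaussian footprint sigma (px).
#' @param transientRateHz Poisson event rate per cell.
#' @param decayS single-exponential transient decay constant (1.5 s,
#'   GCaMP6s-like).
#' @param transientAmplitude peak dF/F-like amplitude relative to baseline.
#' @param rcShiftMax maximum absolute rostrocaudal rigid shift (px); the
#'   shift schedule is smooth bouts rescaled so its maximum is exactly this.
#' @param mlShiftSd mediolateral rigid shift SD (px, small).
#' @param jitterSdPx additional per-frame rostrocaudal jitter SD (px).
#' @param nrAmplitudePx smooth non-rigid rostrocaudal field amplitude (px).
#' @param nrWavelengthPx spatial wavelength of the non-rigid field (px).
#'   The default (256) is field-of-view-scale: the cord bends smoothly along
#'   its length rather than rippling at vessel scale.
#' @param nExtraVenules number of additional small vessels scattered over
#'   the scene (default 8), giving the vessel network density a real cord
#'   field of view carries.
#' @param occluderFraction field-of-view fraction covered by the occluding
#'   layer (0 disables it).
#' @param occluderOpacity alpha of the occluding layer.
#' @param occluderSpeedPx per-frame random-walk step of the occluder (px).
#' @param bleachFraction total fractional intensity decline over the movie
#'   (exponential trend).
#' @param photonsPerUnit Poisson photon scale (0 disables shot noise).
#' @param readNoiseSd Gaussian read noise SD (intensity units).
#' @param nFeatures number of trackable vessel landmarks, spread along
#'   the whole cord so several remain in view at any shift.
#' @param vesselWidthSchedule optional per-frame vein width (px) overriding
#'   `dorsalVeinWidth`, for vasodilation simulations.
#' @param seed RNG seed.
#' @return a list of class `"SimConfig"`.
#' @export
simConfig <- function(shape = c(128, 128), T = 100, frameRate = 20,
                      pixelSizeUm = 2.5,
                      dorsalVeinWidth = 9, venuleWidths = c(4, 5, 6),
                      vesselContrast = 0.55,
                      nCells = 20, cellRadius = 2.5, transientRateHz = 0.08,
                      decayS = 1.5, transientAmplitude = 0.6,
                      rcShiftMax = 0, mlShiftSd = 0, jitterSdPx = 0,
                      nrAmplitudePx = 0, nrWavelengthPx = 256,
                      occluderFraction = 0, occluderOpacity = 0.8,
                      occluderSpeedPx = 2, nExtraVenules = 8,
                      bleachFraction = 0, photonsPerUnit = 0, readNoiseSd = 0,
                      nFeatures = 16, vesselWidthSchedule = NULL, seed = 0) {
  stopifnot(length(shape) == 2, shape >= 16, T >= 1, frameRate > 0,
            rcShiftMax >= 0, nrAmplitudePx >= 0, occluderFraction >= 0,
            occluderFraction < 1, bleachFraction >= 0, bleachFraction < 1,
            photonsPerUnit >= 0, readNoiseSd >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "SimConfig"
  cfg
}

# smooth bout-like schedule of length T, rescaled to max |x| == amp exactly
boutSchedule <- function(T, amp) {
  if (amp == 0 || T < 2) return(numeric(T))
  raw <- cumsum(stats::rnorm(T))
  k <- max(3, round(T / 20))
  sm <- movingMean(raw, k)
  sm <- sm - sm[1]
  m <- max(abs(sm))
  if (m < 1e-12) return(numeric(T))
  sm / m * amp
}

#' Generate a synthetic spinal-cord movie with exact ground truth
#'
#' Renders the scene configured by [simConfig] and returns both the movie
#' and a ground-truth record holding the true per-frame rigid shifts, the
#' non-rigid field parameters, the true feature positions in every frame,
#' per-cell transient traces, the vein width per frame and the bleaching
#' trend. The movie is `warp(scene + transients, true motion) * bleach`,
#' alpha-composited with the occluder, plus Poisson and read noise.
#'
#' @param config a [simConfig].
#' @return list with `movie` (a [MovieTensor-class]) and `truth` (class
#'   `"GroundTruth"`: `shifts` (T x 2, columns rc/ml), `nonrigid`
#'   (per-frame amplitude/phase + wavelength), `featureFrame` (T x K x 2
#'   array of true (x, y) per frame, NA when outside the FOV),
#'   `featureScene`, `cellTraces`, `cellPositions`, `vesselWidth`,
#'   `bleach`).
#' @export
makeMovie <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  c_ <- config
  withSeed(c_$seed, {
    ny <- c_$shape[1]; nx <- c_$shape[2]; T <- c_$T
    pad <- ceiling(c_$rcShiftMax + 4 * (c_$mlShiftSd + c_$jitterSdPx) +
                   c_$nrAmplitudePx + 8)
    sy <- ny + 2 * pad; sx <- nx + 2 * pad

    # --- static tissue with smooth + fine texture ---
    smoothNoise <- function(sigma, amp) {
      f <- cpp_gauss_smooth(matrix(stats::rnorm(sy * sx), sy, sx), sigma)
      f / stats::sd(f) * amp
    }
    tissue <- matrix(100, sy, sx) + smoothNoise(8, 4) + smoothNoise(1.5, 3)

    # --- vessels: distance maps to the vein axis and venule segments ---
    ygrid <- matrix(rep(0:(sy - 1), sx), sy, sx)
    xgrid <- matrix(rep(0:(sx - 1), each = sy), sy, sx)
    veinX <- (sx - 1) / 2 + 6 * sin(2 * pi * (0:(sy - 1)) / (1.5 * sy))
    veinDist <- abs(xgrid - matrix(veinX[ygrid + 1], sy, sx))
    nVen <- length(c_$venuleWidths)
    branchY <- round(seq(0.2, 0.8, length.out = max(nVen, 2)) * (sy - 1))[seq_len(nVen)]
    smoothstep <- function(d) pmin(pmax(0.5 - d, 0), 1)  # 1 inside, 0 outside, 1-px edge
    venIn <- matrix(0, sy, sx)
    branchPts <- NULL
    for (i in seq_len(nVen)) {
      y0 <- branchY[i]; x0 <- veinX[y0 + 1]
      sgn <- if (i %% 2 == 0) 1 else -1
      len <- stats::runif(1, 0.25, 0.45) * sx
      ex <- x0 + sgn * len
      ey <- y0 + stats::runif(1, -0.2, 0.2) * len
      # point-to-segment distance, minus the half-width -> inside when < 0
      vx <- ex - x0; vy <- ey - y0
      tt <- pmin(pmax(((xgrid - x0) * vx + (ygrid - y0) * vy) / (vx^2 + vy^2), 0), 1)
      dd <- sqrt((xgrid - (x0 + tt * vx))^2 + (ygrid - (y0 + tt * vy))^2)
      venIn <- pmax(venIn, smoothstep(dd - c_$venuleWidths[i] / 2))
      branchPts <- rbind(branchPts, c(x0, y0), c((x0 + ex) / 2, (y0 + ey) / 2))
    }
    for (i in seq_len(c_$nExtraVenules)) {
      y0 <- stats::runif(1, 0, sy - 1); x0 <- stats::runif(1, 0, sx - 1)
      ang <- stats::runif(1, 0, pi)
      len <- stats::runif(1, 0.2, 0.5) * min(sy, sx)
      w <- stats::runif(1, 2, 5)
      ex <- x0 + len * cos(ang); ey <- y0 + len * sin(ang)
      vx <- ex - x0; vy <- ey - y0
      tt <- pmin(pmax(((xgrid - x0) * vx + (ygrid - y0) * vy) / (vx^2 + vy^2), 0), 1)
      dd <- sqrt((xgrid - (x0 + tt * vx))^2 + (ygrid - (y0 + tt * vy))^2)
      venIn <- pmax(venIn, smoothstep(dd - w / 2))
    }
    widths <- if (is.null(c_$vesselWidthSchedule)) rep(c_$dorsalVeinWidth, T)
              else rep_len(c_$vesselWidthSchedule, T)
    staticWidth <- length(unique(widths)) == 1L
    veinIn0 <- smoothstep(veinDist - widths[1] / 2)
    vesselMult <- function(w) {
      veinIn <- if (staticWidth) veinIn0 else smoothstep(veinDist - w / 2)
      1 - (1 - c_$vesselContrast) * pmax(veinIn, venIn)
    }
    baseMult <- vesselMult(widths[1])

    # --- feature landmarks: vein-axis points and branch midpoints ---
    K <- c_$nFeatures
    featY <- round(seq(0.08, 0.92, length.out = K) * (sy - 1))
    featureScene <- cbind(x = veinX[featY + 1], y = featY)
    if (!is.null(branchPts) && nrow(branchPts) >= 2) {
      nb <- min(nrow(branchPts), floor(K / 3))
      featureScene[seq_len(nb), ] <- branchPts[seq_len(nb), ]
    }

    # --- cells: two lateral strips of Gaussian blobs ---
    nC <- c_$nCells
    cellPositions <- NULL
    cellTraces <- NULL
    if (nC > 0) {
      side <- rep(c(-1, 1), length.out = nC)
      off <- stats::runif(nC, 0.12, 0.3) * sx
      cellPositions <- cbind(x = (sx - 1) / 2 + side * off,
                             y = stats::runif(nC, pad, sy - 1 - pad))
      dt <- 1 / c_$frameRate
      decay <- exp(-dt / c_$decayS)
      cellTraces <- matrix(0, nC, T)
      for (i in seq_len(nC)) {
        ev <- stats::rbinom(T, 1, min(1, c_$transientRateHz * dt))
        tr <- numeric(T)
        for (t in seq_len(T)) tr[t] <- (if (t > 1) tr[t - 1] * decay else 0) +
          ev[t] * c_$transientAmplitude
        cellTraces[i, ] <- tr
      }
    }

    # --- motion schedules ---
    rc <- boutSchedule(T, c_$rcShiftMax) +
          (if (c_$jitterSdPx > 0) stats::rnorm(T, 0, c_$jitterSdPx) else 0)
    if (c_$rcShiftMax > 0) {
      # re-pin the exact configured maximum after jitter
      rc <- rc / max(abs(rc)) * c_$rcShiftMax
    }
    ml <- if (c_$mlShiftSd > 0) stats::rnorm(T, 0, c_$mlShiftSd) else numeric(T)
    shifts <- cbind(rc = rc, ml = ml)
    nrAmp <- if (c_$nrAmplitudePx > 0)
      c_$nrAmplitudePx * (0.5 + 0.5 * sin(2 * pi * seq_len(T) / max(8, T / 3)))
      else numeric(T)
    nrPhase <- if (c_$nrAmplitudePx > 0) cumsum(stats::rnorm(T, 0, 4)) else numeric(T)

    # --- occluder layer (frame coordinates, own canvas and random walk) ---
    occ <- NULL; occPath <- NULL
    if (c_$occluderFraction > 0) {
      oc <- cpp_gauss_smooth(matrix(stats::rnorm((ny + 80) * (nx + 80)), ny + 80, nx + 80), 10)
      oc <- oc / stats::sd(oc)
      thr <- stats::quantile(oc, 1 - c_$occluderFraction)
      occ <- pmin(pmax((oc - thr) * 2, 0), 1)  # soft edge ~ 0.5 sd wide
      occPath <- cbind(cumsum(stats::rnorm(T, 0, c_$occluderSpeedPx)),
                       cumsum(stats::rnorm(T, 0, c_$occluderSpeedPx)))
    }

    bleach <- if (c_$bleachFraction > 0)
      exp(log(1 - c_$bleachFraction) * (seq_len(T) - 1) / max(1, T - 1))
      else rep(1, T)

    # --- render frames ---
    yg <- matrix(rep(0:(ny - 1), nx), ny, nx)
    xg <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
    data <- array(NA_real_, c(T, ny, nx))
    featureFrame <- array(NA_real_, c(T, K, 2))
    lam <- 2 * pi / c_$nrWavelengthPx
    for (t in seq_len(T)) {
      sceneT <- tissue
      if (nC > 0 && any(cellTraces[, t] > 1e-4)) {
        for (i in which(cellTraces[, t] > 1e-4)) {
          cxp <- cellPositions[i, 1]; cyp <- cellPositions[i, 2]
          r <- ceiling(3 * c_$cellRadius)
          ys <- max(0, round(cyp) - r):min(sy - 1, round(cyp) + r)
          xs <- max(0, round(cxp) - r):min(sx - 1, round(cxp) + r)
          blob <- exp(-((outer(ys, xs * 0, "+") - cyp)^2 +
                        (outer(ys * 0, xs, "+") - cxp)^2) / (2 * c_$cellRadius^2))
          sceneT[ys + 1, xs + 1] <- sceneT[ys + 1, xs + 1] *
            (1 + cellTraces[i, t] * blob)
        }
      }
      mult <- if (staticWidth) baseMult else vesselMult(widths[t])
      sceneT <- sceneT * mult
      uRC <- if (c_$nrAmplitudePx > 0)
        nrAmp[t] * sin(lam * (yg + nrPhase[t])) else matrix(0, ny, nx)
      # sample position in scene coords (rc axis = y)
      SX <- xg + pad + ml[t]
      SY <- yg + pad + rc[t] + uRC
      fr <- cpp_sample(sceneT, SX, SY)
      fr <- fr * bleach[t]
      if (!is.null(occ)) {
        OX <- xg + 40 - occPath[t, 1]
        OY <- yg + 40 - occPath[t, 2]
        a <- cpp_sample(occ, OX, OY)
        a[!is.finite(a)] <- 0
        a <- a * c_$occluderOpacity
        fr <- (1 - a) * fr + a * 160
      }
      if (c_$photonsPerUnit > 0) {
        v <- pmax(fr, 0) * c_$photonsPerUnit
        okv <- is.finite(v)
        fr[okv] <- stats::rpois(sum(okv), v[okv]) / c_$photonsPerUnit
      }
      if (c_$readNoiseSd > 0) fr <- fr + stats::rnorm(length(fr), 0, c_$readNoiseSd)
      data[t, , ] <- fr
      # true feature positions: solve p = q - pad - s_t - u_t(p) (fixed point)
      for (kf in seq_len(K)) {
        qx <- featureScene[kf, 1]; qy <- featureScene[kf, 2]
        px <- qx - pad - ml[t]
        py <- qy - pad - rc[t]
        if (c_$nrAmplitudePx > 0) {
          for (it in 1:4) py <- qy - pad - rc[t] - nrAmp[t] * sin(lam * (py + nrPhase[t]))
        }
        if (px >= 0 && px <= nx - 1 && py >= 0 && py <= ny - 1)
          featureFrame[t, kf, ] <- c(px, py)
      }
    }
    movie <- MovieTensor(data, frameRate = c_$frameRate,
                         pixelSize = c_$pixelSizeUm, rcAxis = "y")
    truth <- structure(list(
      shifts = shifts,
      nonrigid = list(amplitude = nrAmp, phase = nrPhase,
                      wavelength = c_$nrWavelengthPx),
      featureScene = featureScene, featureFrame = featureFrame,
      cellTraces = cellTraces, cellPositions = cellPositions,
      vesselWidth = widths, bleach = bleach, pad = pad), class = "GroundTruth")
    list(movie = movie, truth = truth)
  })
}

#' True displacement field of a simulated frame
#'
#' Reconstructs, from a ground-truth record, the field `u` such that
#' `frame_t(p + u(p)) = template(p)` maps frame `t` back onto the template
#' frame (rigid shift difference plus the non-rigid component difference).
#'
#' @param truth a `"GroundTruth"` record from [makeMovie].
#' @param t frame index.
#' @param templateFrame template frame index.
#' @param shape frame shape `c(Y, X)`.
#' @return a [DisplacementField-class].
#' @export
truthDisplacementField <- function(truth, t, templateFrame, shape) {
  ny <- shape[1]; nx <- shape[2]
  yg <- matrix(rep(0:(ny - 1), nx), ny, nx)
  lam <- 2 * pi / truth$nonrigid$wavelength
  uT <- function(i, py) {
    if (!length(truth$nonrigid$amplitude)) return(0)
    truth$nonrigid$amplitude[i] * sin(lam * (py + truth$nonrigid$phase[i]))
  }
  # scene position sampled by the template at p: q(p) = p + s_tmpl + u_tmpl(p)
  # field must make frame t sample the same scene position:
  # p + u + s_t + u_t(p + u) = q(p); solve by fixed point on u (u smooth)
  uRC <- matrix(0, ny, nx)
  q <- yg + truth$shifts[templateFrame, "rc"] + uT(templateFrame, yg)
  for (it in 1:6) uRC <- q - yg - truth$shifts[t, "rc"] - uT(t, yg + uRC)
  uML <- matrix(truth$shifts[templateFrame, "ml"] - truth$shifts[t, "ml"], ny, nx)
  DisplacementField(uRC = uRC, uML = uML, rcAxis = "y", frameIndex = t)
}

#' Simulated feature track table from ground truth
#'
#' Converts the true per-frame feature positions into a pose-estimation
#' style track table, adding Gaussian tracking jitter, a fraction of
#' low-likelihood dropouts (mistracked, likelihood below the 0.99
#' registration gate) and optionally a fraction of confident outliers
#' (grossly wrong position, high likelihood) to exercise the consensus fit.
#' Features outside the field of view get likelihood 0.
#'
#' @param truth a `"GroundTruth"` record from [makeMovie].
#' @param jitterSd tracking jitter SD in px (0 = exact positions,
#'   likelihood 1).
#' @param dropout probability a record is a low-likelihood mistrack.
#' @param outlierFraction probability a record is a high-likelihood outlier
#'   displaced by 100-200 px.
#' @param seed RNG seed.
#' @return a feature track table (see [readFeatureTable]).
#' @export
makeFeatureTable <- function(truth, jitterSd = 0, dropout = 0,
                             outlierFraction = 0, seed = 0) {
  dims <- dim(truth$featureFrame)
  T <- dims[1]; K <- dims[2]
  withSeed(seed, {
    out <- vector("list", K)
    for (kf in seq_len(K)) {
      x <- truth$featureFrame[, kf, 1]
      y <- truth$featureFrame[, kf, 2]
      lik <- rep(1, T)
      if (jitterSd > 0 || dropout > 0 || outlierFraction > 0) {
        lik <- 0.995 + stats::runif(T, 0, 0.005)
        if (jitterSd > 0) {
          x <- x + stats::rnorm(T, 0, jitterSd)
          y <- y + stats::rnorm(T, 0, jitterSd)
        }
        isOut <- stats::runif(T) < outlierFraction
        if (any(isOut)) {
          off <- stats::runif(sum(isOut), 100, 200) *
                 sign(stats::runif(sum(isOut)) - 0.5)
          y[isOut] <- y[isOut] + off
          x[isOut] <- x[isOut] + stats::runif(sum(isOut), -30, 30)
        }
        isDrop <- stats::runif(T) < dropout
        if (any(isDrop)) {
          lik[isDrop] <- stats::runif(sum(isDrop), 0.2, 0.9)
          x[isDrop] <- x[isDrop] + stats::rnorm(sum(isDrop), 0, 30)
          y[isDrop] <- y[isDrop] + stats::rnorm(sum(isDrop), 0, 30)
        }
      }
      bad <- !is.finite(x) | !is.finite(y)
      lik[bad] <- 0
      x[bad] <- 0; y[bad] <- 0
      out[[kf]] <- data.frame(feature = sprintf("vessel%02d", kf),
                              frame = seq_len(T), x = x, y = y,
                              likelihood = lik, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Synthetic quadrature encoder trace from a speed profile
#'
#' Emits two binary channels whose pulse pattern decodes (via
#' [encoderSpeed]) back to the input profile within one-pulse quantization:
#' wheel phase is accumulated as `v * dt / Cp` and each whole pulse emits a
#' one-sample (A=1, B=0) state for clockwise or (A=0, B=1) for
#' counter-clockwise motion.
#'
#' @param speedProfileCmS signed speed in cm/s, one value per sample.
#' @param sampleRate samples per second (default 2000; must exceed the pulse
#'   rate implied by the fastest speed).
#' @param wheelRadiusCm,pulsesPerRev wheel geometry (defaults 6.6 cm, 600).
#' @return an encoder trace list (`A`, `B`, `frameRate`, `wheelRadiusCm`,
#'   `pulsesPerRev`) consumable by [encoderSpeed].
#' @export
makeEncoderTrace <- function(speedProfileCmS, sampleRate = 2000,
                             wheelRadiusCm = 6.6, pulsesPerRev = 600) {
  cp <- 2 * pi * wheelRadiusCm / pulsesPerRev
  n <- length(speedProfileCmS)
  maxPulses <- max(abs(speedProfileCmS)) / sampleRate / cp
  if (maxPulses > 1)
    stop("sample rate too low for the requested speed (", round(maxPulses, 2),
         " pulses per sample)")
  A <- integer(n); B <- integer(n)
  phase <- 0
  for (i in seq_len(n)) {
    phase <- phase + speedProfileCmS[i] / sampleRate / cp
    if (phase >= 1) { A[i] <- 1L; phase <- phase - 1 }
    else if (phase <= -1) { B[i] <- 1L; phase <- phase + 1 }
  }
  list(A = A, B = B, frameRate = sampleRate, wheelRadiusCm = wheelRadiusCm,
       pulsesPerRev = pulsesPerRev)
}
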