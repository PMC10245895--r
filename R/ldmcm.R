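#' Read a pose-estimation feature track CSV
#'
#' Parses the three-header-row CSV dialect emitted by markerless pose
#' trackers (rows: scorer, bodyparts, coords; then per-feature x, y,
#' likelihood columns). Frame indices come from row order (first data row is
#' frame 1).
#'
#' @param path CSV file.
#' @return a feature track table: `data.frame` with columns
#'   `feature, frame, x, y, likelihood`.
#' @examples
#' # synthetic example table shipped with the package
#' p <- system.file("extdata", "example_tracks.csv", package = "spinalmcm")
#' head(readFeatureTable(p))
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3, stringsAsFactors = FALSE)
  if (nrow(hdr) < 3 || !any(grepl("bodyparts", hdr[, 1], ignore.case = TRUE)) ||
      !any(grepl("coords", hdr[, 1], ignore.case = TRUE)))
    stop("malformed header: expected scorer / bodyparts / coords rows")
  bodyRow <- which(grepl("bodyparts", hdr[, 1], ignore.case = TRUE))[1]
  coordRow <- which(grepl("coords", hdr[, 1], ignore.case = TRUE))[1]
  parts <- as.character(unlist(hdr[bodyRow, -1]))
  coords <- tolower(as.character(unlist(hdr[coordRow, -1])))
  dat <- utils::read.csv(path, header = FALSE, skip = 3, stringsAsFactors = FALSE)
  features <- unique(parts)
  out <- list()
  for (ft in features) {
    ix <- which(parts == ft & coords == "x") + 1L
    iy <- which(parts == ft & coords == "y") + 1L
    il <- which(parts == ft & coords == "likelihood") + 1L
    if (!length(ix) || !length(iy)) stop("malformed header: feature ", ft, " lacks x/y")
    if (!length(il)) stop("missing likelihood column for feature ", ft)
    x <- suppressWarnings(as.numeric(dat[[ix[1]]]))
    y <- suppressWarnings(as.numeric(dat[[iy[1]]]))
    l <- suppressWarnings(as.numeric(dat[[il[1]]]))
    if (anyNA(x) || anyNA(y)) stop("non-numeric coordinates for feature ", ft)
    out[[ft]] <- data.frame(feature = ft, frame = seq_along(x), x = x, y = y,
                            likelihood = l, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a feature track table in the pose-estimation CSV dialect
#'
#' @param table feature track table (see [readFeatureTable]).
#' @param path output CSV path.
#' @param scorer scorer name written into the first header row.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(table, path, scorer = "spinalmcm") {
  features <- unique(table$feature)
  frames <- sort(unique(table$frame))
  cols <- list(frames - 1L)
  hdr1 <- "scorer"; hdr2 <- "bodyparts"; hdr3 <- "coords"
  for (ft in features) {
    sub <- table[table$feature == ft, ]
    sub <- sub[match(frames, sub$frame), ]
    cols <- c(cols, list(sub$x, sub$y, sub$likelihood))
    hdr1 <- c(hdr1, rep(scorer, 3))
    hdr2 <- c(hdr2, rep(ft, 3))
    hdr3 <- c(hdr3, c("x", "y", "likelihood"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr1, collapse = ","), con)
  writeLines(paste(hdr2, collapse = ","), con)
  writeLines(paste(hdr3, collapse = ","), con)
  body <- do.call(cbind, cols)
  utils::write.table(body, con, sep = ",", col.names = FALSE, row.names = FALSE)
  invisible(path)
}

#' Track features by normalized cross-correlation
#'
#' Template-matching substitute for a learned feature tracker: each feature is
#' a small template cut from a reference frame at an annotated point, located
#' in every frame at the peak of normalized cross-correlation within
#' `searchRadius` of the reference position. The reported likelihood is the
#' NCC peak clipped to [0, 1], so occluded or deformed features score low.
#'
#' @param movie a [MovieTensor-class].
#' @param points n x 2 matrix of (x, y) feature positions on the reference
#'   frame (0-based pixel coordinates), row names used as feature ids.
#' @param referenceFrame frame the templates are cut from (default 1).
#' @param templateRadius half-size of the square template (default 7 px).
#' @param searchRadius search window half-size around the reference position
#'   (default 30 px).
#' @return a feature track table (see [readFeatureTable]).
#' @export
trackFeaturesNCC <- function(movie, points, referenceFrame = 1,
                             templateRadius = 7, searchRadius = 30) {
  d <- frameDim(movie)
  if (2 * templateRadius + 1 > min(d)) stop("template larger than frame")
  points <- as.matrix(points)
  ids <- rownames(points)
  if (is.null(ids)) ids <- paste0("feature", seq_len(nrow(points)))
  ref <- getFrame(movie, referenceFrame)
  tr <- templateRadius
  out <- list()
  for (i in seq_len(nrow(points))) {
    # template around the annotated point (0-based coords -> 1-based indices)
    cx <- round(points[i, 1]) + 1L; cy <- round(points[i, 2]) + 1L
    ys <- max(1, cy - tr):min(d[1], cy + tr)
    xs <- max(1, cx - tr):min(d[2], cx + tr)
    tmpl <- ref[ys, xs]
    tv <- as.double(tmpl) - mean(tmpl)
    tn <- sqrt(sum(tv^2))
    rows <- vector("list", nFrames(movie))
    for (t in seq_len(nFrames(movie))) {
      fr <- getFrame(movie, t)
      y0 <- max(1, cy - tr - searchRadius); y1 <- min(d[1], cy + tr + searchRadius)
      x0 <- max(1, cx - tr - searchRadius); x1 <- min(d[2], cx + tr + searchRadius)
      win <- fr[y0:y1, x0:x1]
      win[!is.finite(win)] <- mean(win[is.finite(win)])
      sc <- nccMap(win, tmpl, tv, tn)
      pk <- which(sc == max(sc, na.rm = TRUE), arr.ind = TRUE)[1, ]
      rows[[t]] <- data.frame(
        feature = ids[i], frame = t,
        x = (x0 - 1) + (pk[2] - 1) + (cx - min(xs)),
        y = (y0 - 1) + (pk[1] - 1) + (cy - min(ys)),
        likelihood = min(max(sc[pk[1], pk[2]], 0), 1), stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# normalized cross-correlation of template over all valid positions of win
nccMap <- function(win, tmpl, tv, tn) {
  th <- nrow(tmpl); tw <- ncol(tmpl)
  oy <- nrow(win) - th + 1; ox <- ncol(win) - tw + 1
  if (oy < 1 || ox < 1) stop("search window smaller than template")
  sc <- matrix(NA_real_, oy, ox)
  for (xx in seq_len(ox)) {
    for (yy in seq_len(oy)) {
      patch <- win[yy:(yy + th - 1), xx:(xx + tw - 1)]
      pv <- as.double(patch) - mean(patch)
      pn <- sqrt(sum(pv^2))
      sc[yy, xx] <- if (pn > 1e-12 && tn > 1e-12) sum(pv * tv) / (pn * tn) else 0
    }
  }
  sc
}

#' Gate feature tracks by likelihood
#'
#' Removes records (per frame, not per feature) whose tracking likelihood is
#' at or below `minLikelihood`. Frames losing every feature are reported in
#' the `"uncorrectable"` attribute.
#'
#' @param table feature track table.
#' @param minLikelihood threshold in [0, 1]; registration uses 0.99,
#'   behavior analyses 0.1.
#' @return the filtered table, with attribute `uncorrectable` (frame indices
#'   that retained no features).
#' @export
filterByLikelihood <- function(table, minLikelihood = 0.99) {
  stopifnot(minLikelihood >= 0, minLikelihood <= 1)
  keep <- table$likelihood > minLikelihood | minLikelihood == 0
  out <- table[keep, , drop = FALSE]
  lost <- setdiff(unique(table$frame), unique(out$frame))
  attr(out, "uncorrectable") <- sort(lost)
  out
}

#' Quality-control features by displacement correlation
#'
#' Rigid field-of-view motion moves all well-tracked features together, so a
#' feature whose frame-to-frame rostrocaudal displacement decorrelates from
#' the others indicates unstable tracking and degrades the consensus rigid
#' fit. This computes the Spearman correlation matrix between the features'
#' per-frame displacement series and drops features whose mean correlation
#' with all others falls below `minMeanCorrelation` (or that appear on
#' `dropList`).
#'
#' @param table feature track table (>= 3 features, >= 2 frames).
#' @param minMeanCorrelation drop threshold on the per-feature mean
#'   correlation (default 0.5).
#' @param dropList feature ids to drop unconditionally.
#' @param axis `"rc"` (rostrocaudal displacement, default) or `"2d"`
#'   (displacement magnitude).
#' @param rcAxis which image axis is rostrocaudal (default `"y"`).
#' @return list with `table` (filtered) and `report` (correlation matrix,
#'   per-feature mean correlation, kept/dropped ids, per-frame feature counts).
#' @export
qcFeatures <- function(table, minMeanCorrelation = 0.5, dropList = character(),
                       axis = c("rc", "2d"), rcAxis = "y") {
  axis <- match.arg(axis)
  features <- unique(table$feature)
  frames <- sort(unique(table$frame))
  if (length(frames) < 2) stop("fewer than 2 frames: displacement undefined")
  if (length(features) < 3) stop("need at least 3 features for correlation QC")
  rcCol <- if (rcAxis == "y") "y" else "x"
  mlCol <- if (rcAxis == "y") "x" else "y"
  disp <- sapply(features, function(ft) {
    sub <- table[table$feature == ft, ]
    v <- sub[match(frames, sub$frame), ]
    if (axis == "rc") diff(v[[rcCol]])
    else sqrt(diff(v[[rcCol]])^2 + diff(v[[mlCol]])^2)
  })
  cm <- suppressWarnings(stats::cor(disp, method = "spearman",
                                    use = "pairwise.complete.obs"))
  diag(cm) <- 1
  meanCor <- vapply(seq_along(features),
                    function(i) mean(cm[i, -i], na.rm = TRUE), 0)
  names(meanCor) <- features
  drop <- features[meanCor < minMeanCorrelation]
  drop <- union(drop, dropList)
  keep <- setdiff(features, drop)
  counts <- table(factor(table$frame[table$feature %in% keep], levels = frames))
  list(table = table[table$feature %in% keep, , drop = FALSE],
       report = list(correlation = cm, meanCorrelation = meanCor,
                     kept = keep, dropped = drop,
                     perFrameFeatureCount = as.integer(counts)))
}

#' Large-displacement motion correction from tracked control points (LD-MCM)
#'
#' Per frame, fits a robust rigid transform (random-sample consensus, 1000
#' trials, 20 px inlier gate by default) from the frame's tracked features to
#' the reference frame's features, warps the movie with linear interpolation,
#' and then removes residual frame-to-frame jitter with a translation pass on
#' a stable subregion. Frames with fewer than `minInliers` usable features
#' inherit the nearest corrected frame's transform and are flagged.
#'
#' @param movie a [MovieTensor-class] (detrended / filtered beforehand).
#' @param table feature track table in the movie's pixel coordinates.
#' @param referenceFrame frame index the movie is registered to.
#' @param minLikelihood per-record likelihood gate (default 0.99).
#' @param trials,inlierPx consensus parameters (defaults 1000 and 20).
#' @param seed RNG seed for the consensus sampler.
#' @param qc run [qcFeatures] first (default FALSE; requires >= 3 features).
#' @param minMeanCorrelation QC threshold when `qc = TRUE`.
#' @param residualPass run the residual translation pass (default TRUE).
#' @param residualRegion list(y = range, x = range) subregion for the residual
#'   pass; auto-selected (highest contrast, temporally stable) when NULL.
#' @param residualMaxPx residual translations larger than this are treated as
#'   failed estimates and skipped (default 5 px; the residual pass corrects
#'   subpixel feature-localization jitter, not gross motion).
#' @param minInliers minimum consensus inliers for a frame to count as
#'   corrected (default 2).
#' @param refinementRounds robust reference refinement rounds (default 2):
#'   after the per-frame fits, each feature's reference position is
#'   re-estimated as the per-component median of its transformed positions
#'   over all frames, and the fits are repeated against this consensus
#'   reference. This suppresses outlier records on the reference frame
#'   itself and gives every feature a usable reference position even when it
#'   is out of view on the reference frame (essential under shifts larger
#'   than the field of view overlap). Set 0 to register strictly against the
#'   reference frame's own records.
#' @return list with `movie` (corrected), `transforms` (list of
#'   [Transform2D-class], one per frame, moving -> reference), `qcReport`,
#'   and `flaggedFrames` (frames whose transform was inherited).
#' @export
runLDMCM <- function(movie, table, referenceFrame = 1, minLikelihood = 0.99,
                     trials = 1000, inlierPx = 20, seed = 0, qc = FALSE,
                     minMeanCorrelation = 0.5, residualPass = TRUE,
                     residualRegion = NULL, residualMaxPx = 5, minInliers = 2,
                     refinementRounds = 2) {
  qcReport <- NULL
  if (qc) {
    res <- qcFeatures(table, minMeanCorrelation, rcAxis = movie@rcAxis)
    table <- res$table
    qcReport <- res$report
  }
  table <- filterByLikelihood(table, minLikelihood)
  refTab <- table[table$frame == referenceFrame, ]
  if (nrow(refTab) < 2) stop("reference frame has too few features passing QC")
  T <- nFrames(movie)
  refPts <- as.matrix(refTab[, c("x", "y")])
  rownames(refPts) <- refTab$feature
  # index records once per frame
  byFrame <- split(table, table$frame)
  fitAll <- function(refPts) {
    transforms <- vector("list", T)
    flagged <- integer()
    for (t in seq_len(T)) {
      sub <- byFrame[[as.character(t)]]
      common <- if (is.null(sub)) character() else
        intersect(sub$feature, rownames(refPts))
      if (length(common) >= 2) {
        mov <- as.matrix(sub[match(common, sub$feature), c("x", "y")])
        ref <- refPts[common, , drop = FALSE]
        tf <- estimateRigidFromPoints(ref, mov, trials = trials,
                                      inlierPx = inlierPx, seed = seed + t)
        if (sum(attr(tf, "inliers")) < minInliers) tf <- NULL
      } else tf <- NULL
      if (is.null(tf)) flagged <- c(flagged, t)
      transforms[[t]] <- tf
    }
    list(transforms = transforms, flagged = flagged)
  }
  fit <- fitAll(refPts)
  if (!any(!vapply(fit$transforms, is.null, TRUE)))
    stop("no frame could be corrected from the tracked features")
  for (round in seq_len(refinementRounds)) {
    # consensus reference: per-feature median of transformed positions
    feats <- unique(table$feature)
    pos <- matrix(NA_real_, length(feats), 2, dimnames = list(feats, c("x", "y")))
    acc <- lapply(feats, function(f) NULL)
    names(acc) <- feats
    for (t in seq_len(T)) {
      tf <- fit$transforms[[t]]
      if (is.null(tf)) next
      sub <- byFrame[[as.character(t)]]
      if (is.null(sub)) next
      pts <- applyTransform(tf, as.matrix(sub[, c("x", "y")]))
      for (i in seq_len(nrow(sub)))
        acc[[sub$feature[i]]] <- rbind(acc[[sub$feature[i]]], pts[i, ])
    }
    for (f in feats) {
      if (!is.null(acc[[f]]) && nrow(acc[[f]]) >= 3)
        pos[f, ] <- apply(acc[[f]], 2, stats::median)
    }
    pos <- pos[rowSums(is.finite(pos)) == 2, , drop = FALSE]
    if (nrow(pos) < 2) break
    fit <- fitAll(pos)
  }
  transforms <- fit$transforms
  flagged <- fit$flagged
  # temporal-consistency guard: cord motion is continuous, so a fitted shift
  # that leaps far from the running median of its neighbours is an outlier
  # consensus (e.g. a chance cluster of wrong tracks) and is discarded
  good <- which(!vapply(transforms, is.null, TRUE))
  if (length(good) >= 5) {
    dx <- vapply(good, function(t) asMatrix(transforms[[t]])[1, 3], 0)
    dy <- vapply(good, function(t) asMatrix(transforms[[t]])[2, 3], 0)
    mx <- stats::runmed(dx, 5); my <- stats::runmed(dy, 5)
    bad <- good[sqrt((dx - mx)^2 + (dy - my)^2) > 2 * inlierPx]
    for (t in bad) transforms[t] <- list(NULL)
    flagged <- sort(union(flagged, bad))
  }
  # frames without a usable fit inherit the nearest corrected frame's transform
  good <- which(!vapply(transforms, is.null, TRUE))
  if (!length(good)) stop("no frame could be corrected from the tracked features")
  for (t in flagged) {
    nearest <- good[which.min(abs(good - t))]
    tf <- transforms[[nearest]]
    tf@flags <- union(tf@flags, "interpolated")
    transforms[[t]] <- tf
  }
  for (t in seq_len(T)) transforms[[t]]@frameIndex <- t
  corrected <- warpImage(movie, transforms)
  if (residualPass) {
    reg <- if (is.null(residualRegion)) autoRegion(corrected) else residualRegion
    ref <- getFrame(corrected, referenceFrame)[reg$y, reg$x]
    refN <- normalizeFrameForRegistration(ref, complement = TRUE)
    for (t in seq_len(T)) {
      fr <- getFrame(corrected, t)[reg$y, reg$x]
      if (all(!is.finite(fr))) next
      tf2 <- tryCatch(
        estimateTranslation(normalizeFrameForRegistration(fr, complement = TRUE), refN),
        error = function(e) NULL)
      if (is.null(tf2)) next
      if (max(abs(asMatrix(tf2)[, 3])) > residualMaxPx) next
      # accept only when it actually improves alignment to the reference
      if (frameCor(warpImage(fr, tf2), ref) <= frameCor(fr, ref)) next
      tf2@frameIndex <- t
      transforms[[t]] <- composeTransform(tf2, transforms[[t]])
    }
    corrected <- warpImage(movie, transforms)
  }
  list(movie = corrected, transforms = transforms, qcReport = qcReport,
       flaggedFrames = flagged)
}

# pick a subregion (about a quarter of the FOV) that is high-contrast in the
# mean frame but temporally stable (low temporal variance: avoids occluders
# and tracked-feature neighbourhoods) with few missing pixels
autoRegion <- function(movie) {
  d <- frameDim(movie)
  hy <- max(16, floor(d[1] / 2)); hx <- max(16, floor(d[2] / 2))
  mf <- meanFrame(movie)
  tsd <- apply(movie@data, c(2, 3), function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) stats::sd(v) else NA_real_
  })
  naFrac <- apply(movie@data, c(2, 3), function(v) mean(!is.finite(v)))
  best <- NULL; bestScore <- -Inf
  for (oy in unique(c(1, floor(d[1] / 4), d[1] - hy + 1))) {
    for (ox in unique(c(1, floor(d[2] / 4), d[2] - hx + 1))) {
      if (oy < 1 || ox < 1 || oy + hy - 1 > d[1] || ox + hx - 1 > d[2]) next
      ys <- oy:(oy + hy - 1); xs <- ox:(ox + hx - 1)
      v <- mf[ys, xs]
      instab <- mean(tsd[ys, xs], na.rm = TRUE)
      score <- stats::sd(v[is.finite(v)]) / (1 + instab) *
               (1 - mean(naFrac[ys, xs]))
      if (is.finite(score) && score > bestScore) { bestScore <- score; best <- list(y = ys, x = xs) }
    }
  }
  best
}

#' Mean absolute residual displacement of tracked features
#'
#' Applies per-frame transforms to the tracked feature positions and reports
#' each feature's absolute deviation from its reference position, the
#' collapse-of-point-clouds metric used to evaluate motion correction.
#'
#' @param table feature track table.
#' @param transforms per-frame transforms (list, `NULL` entries skipped), or
#'   `NULL` to evaluate the raw tracks.
#' @param referenceFrame frame whose feature positions are the target.
#' @return mean absolute residual distance in px.
#' @export
featureResidual <- function(table, transforms = NULL, referenceFrame = 1) {
  table <- table[table$likelihood > 0, , drop = FALSE]
  refTab <- table[table$frame == referenceFrame, ]
  tot <- 0; n <- 0
  for (t in unique(table$frame)) {
    sub <- table[table$frame == t, ]
    common <- intersect(sub$feature, refTab$feature)
    if (!length(common)) next
    pts <- as.matrix(sub[match(common, sub$feature), c("x", "y")])
    if (!is.null(transforms)) {
      tf <- transforms[[t]]
      if (is.null(tf)) next
      pts <- applyTransform(tf, pts)
    }
    ref <- as.matrix(refTab[match(common, refTab$feature), c("x", "y")])
    ok <- rowSums(is.finite(pts)) == 2 & rowSums(is.finite(ref)) == 2
    if (!any(ok)) next
    tot <- tot + sum(sqrt(rowSums((pts[ok, , drop = FALSE] - ref[ok, , drop = FALSE])^2)))
    n <- n + sum(ok)
  }
  tot / n
}

#' LD-MCM with the two hemicords corrected separately
#'
#' The left and right sides of the cord can drift apart over long-term
#' imaging; correcting each hemicord with its own features and recombining
#' at a seam column improves alignment in that regime. The movie is split
#' at `seamX` (columns at or left of the seam form the left hemicord),
#' features are assigned to sides by their reference-frame position, each
#' side runs [runLDMCM] independently, and the corrected halves are
#' recombined.
#'
#' @param movie a [MovieTensor-class].
#' @param table feature track table covering both hemicords.
#' @param seamX seam column (1-based; default: middle of the frame).
#' @param referenceFrame reference frame index.
#' @param ... further arguments passed to [runLDMCM].
#' @return list with `movie` (recombined), `left` and `right` (each the
#'   corresponding [runLDMCM] result).
#' @export
runLDMCMHemicords <- function(movie, table, seamX = NULL, referenceFrame = 1,
                              ...) {
  d <- frameDim(movie)
  if (is.null(seamX)) seamX <- floor(d[2] / 2)
  stopifnot(seamX >= 2, seamX <= d[2] - 1)
  refTab <- table[table$frame == referenceFrame, ]
  sideOf <- refTab$feature[refTab$x < seamX]      # 0-based coords vs 1-based seam
  leftTab <- table[table$feature %in% sideOf, , drop = FALSE]
  rightTab <- table[!table$feature %in% sideOf, , drop = FALSE]
  rightTab$x <- rightTab$x - seamX
  splitMovie <- function(cols) setMovieData(movie, movie@data[, , cols, drop = FALSE])
  left <- runLDMCM(splitMovie(seq_len(seamX)), leftTab,
                   referenceFrame = referenceFrame, ...)
  right <- runLDMCM(splitMovie((seamX + 1):d[2]), rightTab,
                    referenceFrame = referenceFrame, ...)
  out <- movie@data
  out[, , seq_len(seamX)] <- left$movie@data
  out[, , (seamX + 1):d[2]] <- right$movie@data
  list(movie = setMovieData(movie, out), left = left, right = right)
}
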