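#' Assemble a cross-session set
#'
#' Bundles per-session movies or mean frames with their declared camera
#' orientation corrections. Declared rotations/flips are applied immediately
#' (sessions acquired on different cameras arrive rotated or mirrored), and
#' all frames are padded to a common shape with missing-value pixels so
#' correlations ignore the pads.
#'
#' @param frames named list of Y x X mean frames or [MovieTensor-class]
#'   objects (a movie contributes its temporal mean frame).
#' @param referenceSession name or index of the reference session (default 1).
#' @param rotations per-session clockwise rotation in degrees (0, 90, 180,
#'   270), recycled.
#' @param flips per-session logical: mirror about the vertical axis, recycled.
#' @param cameraIds optional per-session camera labels.
#' @return a list of class `"SessionSet"` with padded mean frames.
#' @export
sessionSet <- function(frames, referenceSession = 1, rotations = 0,
                       flips = FALSE, cameraIds = NULL) {
  n <- length(frames)
  ids <- names(frames)
  if (is.null(ids)) ids <- paste0("session", seq_len(n))
  rotations <- rep_len(rotations, n)
  flips <- rep_len(flips, n)
  mats <- lapply(seq_len(n), function(i) {
    f <- frames[[i]]
    if (is(f, "MovieTensor")) f <- meanFrame(f)
    if (rotations[i] %% 360 != 0) {
      k <- (rotations[i] %/% 90) %% 4
      for (j in seq_len(k)) f <- t(f[nrow(f):1, , drop = FALSE])
    }
    if (flips[i]) f <- f[, ncol(f):1, drop = FALSE]
    f
  })
  ny <- max(vapply(mats, nrow, 0L)); nx <- max(vapply(mats, ncol, 0L))
  mats <- lapply(mats, function(f) {
    out <- matrix(NA_real_, ny, nx)
    out[seq_len(nrow(f)), seq_len(ncol(f))] <- f
    out
  })
  if (is.character(referenceSession)) referenceSession <- match(referenceSession, ids)
  structure(list(frames = mats, ids = ids,
                 reference = as.integer(referenceSession),
                 cameraIds = if (is.null(cameraIds)) ids else cameraIds),
            class = "SessionSet")
}

#' Align imaging sessions onto a reference session (CS-MCM)
#'
#' Cross-session alignment of per-session mean frames: an initial
#' large-shift correction (user-supplied integer offsets or feature tables
#' matched by robust rigid fitting), then affine registration without
#' rotation or skew, then a second affine registration with rotation and no
#' skew. Returns the composed transform for every session mapping it onto the
#' reference session's coordinates.
#'
#' @param sessions a [sessionSet].
#' @param init optional initialization: a list (one element per session) of
#'   either `c(dx, dy)` integer offsets or feature track tables (matched
#'   against the reference session's table by feature id, frame 1 used).
#' @param smoothingPx,pyramidLevels passed to [estimateAffine] (defaults 30
#'   and 6).
#' @return list with `transforms` (per-session [Transform2D-class]),
#'   `aligned` (list of warped mean frames), `correlations` (to the
#'   reference, post-alignment), and `flagged` (sessions with no overlap).
#' @export
alignSessions <- function(sessions, init = NULL, smoothingPx = 30,
                          pyramidLevels = 6) {
  stopifnot(inherits(sessions, "SessionSet"))
  n <- length(sessions$frames)
  refIdx <- sessions$reference
  ref <- sessions$frames[[refIdx]]
  transforms <- vector("list", n)
  aligned <- vector("list", n)
  flagged <- character()
  for (i in seq_len(n)) {
    mov <- sessions$frames[[i]]
    if (i == refIdx) {
      transforms[[i]] <- translationTransform(0, 0)
      aligned[[i]] <- mov
      next
    }
    tf0 <- NULL
    if (!is.null(init) && !is.null(init[[i]])) {
      ini <- init[[i]]
      if (is.numeric(ini)) tf0 <- translationTransform(ini[1], ini[2])
      else {
        refTab <- init[[refIdx]]
        common <- intersect(ini$feature, refTab$feature)
        if (length(common) >= 2) {
          mv <- as.matrix(ini[match(common, ini$feature), c("x", "y")])
          rf <- as.matrix(refTab[match(common, refTab$feature), c("x", "y")])
          tf0 <- estimateRigidFromPoints(rf, mv)
        }
      }
    }
    tf1 <- estimateAffine(mov, ref, allowRotation = FALSE, allowSkew = FALSE,
                          pyramidLevels = pyramidLevels, smoothingPx = smoothingPx,
                          init = tf0)
    tf2 <- estimateAffine(mov, ref, allowRotation = TRUE, allowSkew = FALSE,
                          pyramidLevels = pyramidLevels, smoothingPx = smoothingPx,
                          init = tf1)
    transforms[[i]] <- tf2
    aligned[[i]] <- warpImage(mov, tf2)
    if (all(!is.finite(aligned[[i]]))) flagged <- c(flagged, sessions$ids[i])
  }
  cors <- vapply(aligned, function(a) frameCor(a, ref), 0)
  names(cors) <- sessions$ids
  list(transforms = transforms, aligned = aligned, correlations = cors,
       flagged = flagged)
}

#' Refine alignment on the concatenated movie
#'
#' Concatenates pre-aligned per-session movies into one T*N-frame tensor and
#' registers every frame (translation, phase correlation on normalized
#' frames) to a single reference frame, removing residual inter-session
#' jitter. For large inputs pass movies one at a time and reuse
#' `referenceFrame` (streaming mode): above `maxFrames` frames the
#' concatenation is refused.
#'
#' @param alignedMovies list of [MovieTensor-class] objects with identical
#'   frame sizes, already aligned by [alignSessions].
#' @param referenceFrame index into the concatenated tensor (default 1).
#' @param maxFrames memory guard (default 5000 frames).
#' @return the refined concatenated [MovieTensor-class].
#' @export
refineConcatenated <- function(alignedMovies, referenceFrame = 1, maxFrames = 5000) {
  if (is(alignedMovies, "MovieTensor")) alignedMovies <- list(alignedMovies)
  d <- frameDim(alignedMovies[[1]])
  Ts <- vapply(alignedMovies, nFrames, 0L)
  total <- sum(Ts)
  if (total > maxFrames)
    stop("concatenation of ", total, " frames exceeds maxFrames = ", maxFrames,
         "; process sessions in batches (streaming mode)")
  if (referenceFrame < 1 || referenceFrame > total)
    stop("reference frame index out of range")
  data <- array(NA_real_, c(total, d[1], d[2]))
  off <- 0L
  for (m in alignedMovies) {
    stopifnot(all(frameDim(m) == d))
    data[off + seq_len(nFrames(m)), , ] <- m@data
    off <- off + nFrames(m)
  }
  cat0 <- setMovieData(alignedMovies[[1]], data)
  refN <- normalizeFrameForRegistration(getFrame(cat0, referenceFrame),
                                        complement = TRUE)
  for (t in seq_len(total)) {
    fr <- getFrame(cat0, t)
    tf <- tryCatch(
      estimateTranslation(normalizeFrameForRegistration(fr, complement = TRUE), refN),
      error = function(e) translationTransform(0, 0))
    data[t, , ] <- warpImage(fr, tf)
  }
  setMovieData(cat0, data)
}

#' Per-session correlation to a reference frame
#'
#' Pearson and Spearman correlation of each aligned session frame to the
#' reference, optionally on vessel-enhanced (Frangi-filtered)
#' representations, which are less sensitive to baseline fluorescence
#' changes across sessions.
#'
#' @param alignedFrames list of aligned Y x X frames.
#' @param reference reference Y x X frame.
#' @param vesselEnhance apply [frangiVesselness] to both sides first.
#' @param frangi a [frangiConfig] used when `vesselEnhance = TRUE`.
#' @return data.frame with columns `session, pearson, spearman` (NA when a
#'   frame is constant over the overlap).
#' @export
sessionQuality <- function(alignedFrames, reference, vesselEnhance = FALSE,
                           frangi = frangiConfig()) {
  prep <- function(f) {
    if (!vesselEnhance) return(f)
    g <- f
    g[!is.finite(g)] <- mean(g[is.finite(g)])
    # min-max normalize to the 0-150 working scale first, so the enhanced
    # representation is invariant to brightness/gain changes across sessions
    if (max(g) > min(g)) g <- (g - min(g)) / (max(g) - min(g)) * 150
    frangiVesselness(g, frangi)
  }
  refP <- prep(reference)
  out <- lapply(seq_along(alignedFrames), function(i) {
    fp <- prep(alignedFrames[[i]])
    data.frame(session = if (!is.null(names(alignedFrames))) names(alignedFrames)[i] else i,
               pearson = frameCor(fp, refP, "pearson"),
               spearman = frameCor(fp, refP, "spearman"))
  })
  do.call(rbind, out)
}

#' Match cells across sessions into global identities
#'
#' Cell footprints from each session are mapped into reference coordinates
#' with the session transforms, then matched across sessions by centroid
#' distance with a shape-correlation gate: candidate pairs are ordered
#' globally by centroid distance and accepted greedily when both cells are
#' still unmatched, the distance is within `centroidMaxPx` and the
#' footprint image correlation exceeds `minShapeCorr`. The global ordering
#' makes two-session matching symmetric. Additional `rounds` re-estimate a
#' residual per-session centroid shift from the current matches and rematch.
#' Unmatched cells keep singleton global IDs.
#'
#' @param cellMaps list (one per session) of lists with elements `footprint`
#'   (Y x X non-negative matrix) and `centroid` (`c(x, y)`, 0-based px);
#'   alternatively each session may be a 3-D array cells x Y x X.
#' @param sessionTransforms per-session [Transform2D-class] into reference
#'   coordinates (NULL for identity).
#' @param centroidMaxPx centroid gate in px per round (default 5; 15 is the
#'   permissive setting), recycled to `rounds`.
#' @param minShapeCorr footprint correlation gate (default 0.6).
#' @param rounds matching rounds (default 1; 5 is the thorough setting).
#' @return data.frame with columns `global_id, session, cell, centroid_x,
#'   centroid_y, shape_corr` (shape_corr NA for singletons).
#' @export
matchCellsAcrossSessions <- function(cellMaps, sessionTransforms = NULL,
                                     centroidMaxPx = 5, minShapeCorr = 0.6,
                                     rounds = 1) {
  nS <- length(cellMaps)
  gates <- rep_len(centroidMaxPx, rounds)
  cells <- list()   # flat list of cells across sessions
  for (s in seq_len(nS)) {
    cm <- cellMaps[[s]]
    if (is.array(cm) && length(dim(cm)) == 3) {
      cm <- lapply(seq_len(dim(cm)[1]), function(i) {
        fp <- matrix(cm[i, , ], dim(cm)[2], dim(cm)[3])
        list(footprint = fp, centroid = footprintCentroid(fp))
      })
    }
    tf <- if (!is.null(sessionTransforms)) sessionTransforms[[s]] else NULL
    for (i in seq_along(cm)) {
      cen <- cm[[i]]$centroid
      fp <- cm[[i]]$footprint
      if (!is.null(tf)) {
        cen <- as.double(applyTransform(tf, matrix(cen, 1)))
        fp <- warpImage(fp, tf)
        fp[!is.finite(fp)] <- 0
      }
      cells[[length(cells) + 1]] <- list(session = s, cell = i,
                                         centroid = cen, footprint = fp)
    }
  }
  if (!length(cells))
    return(data.frame(global_id = integer(), session = integer(), cell = integer(),
                      centroid_x = double(), centroid_y = double(),
                      shape_corr = double()))
  shift <- matrix(0, nS, 2)  # per-session residual centroid shift
  for (round in seq_len(rounds)) {
    cen <- t(vapply(cells, function(c)
      c$centroid + shift[c$session, ], c(0, 0)))
    ses <- vapply(cells, function(c) c$session, 0L)
    # candidate cross-session pairs within the gate, ordered by distance
    pairs <- NULL
    nC <- length(cells)
    dmat <- as.matrix(dist(cen))
    cand <- which(upper.tri(dmat) & dmat <= gates[round] &
                  outer(ses, ses, "!="), arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dmat[cand])
      cand <- cand[ord, , drop = FALSE]
    }
    parent <- seq_len(nC)            # union-find over cells
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    groupSessions <- lapply(seq_len(nC), function(i) ses[i])
    corrs <- rep(NA_real_, nC)
    for (k in seq_len(nrow(cand))) {
      a <- find(cand[k, 1]); b <- find(cand[k, 2])
      if (a == b) next
      # a global ID may hold at most one cell per session
      if (length(intersect(groupSessions[[a]], groupSessions[[b]]))) next
      sc <- shapeCorrelation(cells[[cand[k, 1]]]$footprint,
                             cells[[cand[k, 2]]]$footprint,
                             cells[[cand[k, 1]]]$centroid,
                             cells[[cand[k, 2]]]$centroid)
      if (!is.finite(sc) || sc <= minShapeCorr) next
      parent[b] <- a
      groupSessions[[a]] <- c(groupSessions[[a]], groupSessions[[b]])
      corrs[cand[k, 1]] <- max(corrs[cand[k, 1]], sc, na.rm = TRUE)
      corrs[cand[k, 2]] <- max(corrs[cand[k, 2]], sc, na.rm = TRUE)
    }
    roots <- vapply(seq_len(nC), find, 0L)
    if (round < rounds) {
      # per-session residual shift: mean offset of matched cells to their
      # group's mean centroid
      for (s in seq_len(nS)) {
        inGrp <- which(ses == s & roots %in% roots[duplicated(roots) | rev(duplicated(rev(roots)))])
        if (!length(inGrp)) next
        offs <- t(vapply(inGrp, function(i) {
          grp <- which(roots == roots[i])
          colMeans(cen[grp, , drop = FALSE]) - cen[i, ]
        }, c(0, 0)))
        shift[s, ] <- shift[s, ] + colMeans(offs)
      }
    }
  }
  gid <- match(roots, unique(roots))
  data.frame(global_id = gid,
             session = ses,
             cell = vapply(cells, function(c) c$cell, 0L),
             centroid_x = cen[, 1], centroid_y = cen[, 2],
             shape_corr = corrs)
}

footprintCentroid <- function(fp) {
  fp[!is.finite(fp)] <- 0
  tot <- sum(fp)
  if (tot <= 0) return(c(NA_real_, NA_real_))
  xs <- matrix(rep(0:(ncol(fp) - 1), each = nrow(fp)), nrow(fp), ncol(fp))
  ys <- matrix(rep(0:(nrow(fp) - 1), ncol(fp)), nrow(fp), ncol(fp))
  c(sum(fp * xs) / tot, sum(fp * ys) / tot)
}

# image correlation of two footprints, compared as SHAPES: each footprint is
# cropped in a window centered on its own centroid (so residual centroid
# offsets within the distance gate do not masquerade as shape differences)
shapeCorrelation <- function(a, b, ca = NULL, cb = NULL, radius = 12) {
  if (is.null(ca)) ca <- footprintCentroid(a)
  if (is.null(cb)) cb <- footprintCentroid(b)
  crop <- function(fp, cen) {
    ny <- nrow(fp); nx <- ncol(fp)
    cx <- round(cen[1]); cy <- round(cen[2])
    out <- matrix(0, 2 * radius + 1, 2 * radius + 1)
    xs <- (cx - radius):(cx + radius); ys <- (cy - radius):(cy + radius)
    okx <- xs >= 0 & xs <= nx - 1; oky <- ys >= 0 & ys <= ny - 1
    sub <- fp[ys[oky] + 1, xs[okx] + 1, drop = FALSE]
    sub[!is.finite(sub)] <- 0
    out[which(oky), which(okx)] <- sub
    out
  }
  va <- crop(a, ca); vb <- crop(b, cb)
  sup <- (va > 0) | (vb > 0)
  if (sum(sup) < 3) return(NA_real_)
  if (stats::sd(va[sup]) == 0 || stats::sd(vb[sup]) == 0) return(NA_real_)
  stats::cor(va[sup], vb[sup])
}

#' Write a cross-session cell match table as TSV
#' @param matches output of [matchCellsAcrossSessions].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeMatchTable <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
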