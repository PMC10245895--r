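#' Demons registration configuration
#'
#' Defaults follow the parameterization used throughout: 3 pyramid levels
#' with 2000, 400 and 100 iterations (coarsest first) and Gaussian smoothing
#' of the accumulated field with sigma 1.5 px, with the mediolateral
#' component of every emitted field constrained to zero.
#'
#' @param pyramidLevels number of pyramid levels.
#' @param iterations iterations per level, coarsest first; length must equal
#'   `pyramidLevels`.
#' @param fieldSmoothingSigma Gaussian sigma (px) applied to the accumulated
#'   field at every iteration.
#' @param constrainToRC zero the mediolateral component (default TRUE).
#' @param stopTol early-exit tolerance: a level stops before its iteration
#'   budget once the mean per-pixel field update falls below this (px).
#'   Set to 0 to always run the full budget.
#' @return a list of class `"DemonsConfig"`.
#' @export
demonsConfig <- function(pyramidLevels = 3, iterations = c(2000, 400, 100),
                         fieldSmoothingSigma = 1.5, constrainToRC = TRUE,
                         stopTol = 1e-3) {
  stopifnot(pyramidLevels == length(iterations), fieldSmoothingSigma > 0,
            all(iterations >= 1), stopTol >= 0)
  structure(list(pyramidLevels = pyramidLevels, iterations = as.integer(iterations),
                 fieldSmoothingSigma = fieldSmoothingSigma,
                 constrainToRC = isTRUE(constrainToRC), stopTol = stopTol),
            class = "DemonsConfig")
}

#' Estimate a non-rigid displacement field (diffeomorphic demons)
#'
#' Multi-resolution demons registration between two frames that were
#' normalized with [normalizeFrameForRegistration]. The returned field `u`
#' maps reference pixels onto moving-frame sample positions
#' (`corrected(p) = moving(p + u(p))`); identical inputs give a field whose
#' magnitude is below 0.01 px everywhere.
#'
#' @param moving,fixed Y x X matrices of identical shape, finite everywhere.
#' @param config a [demonsConfig]. When `constrainToRC` is set the
#'   mediolateral component is held at zero throughout the iterations, so the
#'   solver optimizes within the constrained space (spinal cord motion is
#'   rostrocaudal-dominant, and an unconstrained field can drift sideways
#'   along the vessel axis where the image gives no lateral evidence).
#' @param rcAxis which image axis is rostrocaudal.
#' @return a [DisplacementField-class]; with `constrainToRC` the emitted
#'   `uML` is exactly zero (see also [constrainFieldAxis]).
#' @export
estimateDisplacementField <- function(moving, fixed, config = demonsConfig(),
                                      rcAxis = "y") {
  stopifnot(all(dim(moving) == dim(fixed)))
  if (any(!is.finite(moving)) || any(!is.finite(fixed)))
    stop("non-finite frames: normalize/fill before demons estimation")
  constrain <- if (!isTRUE(config$constrainToRC)) 0L
               else if (rcAxis == "y") 1L else 2L
  res <- cpp_demons(fixed, moving, config$iterations, config$fieldSmoothingSigma,
                    config$stopTol, constrain)
  if (rcAxis == "y") DisplacementField(uRC = res$uy, uML = res$ux, rcAxis = "y")
  else DisplacementField(uRC = res$ux, uML = res$uy, rcAxis = "x")
}

#' Zero the mediolateral component of a displacement field
#'
#' Spinal cord motion is predominantly rostrocaudal; zeroing the mediolateral
#' displacement before warping prevents spurious lateral shifts (at the
#' documented cost that genuine mediolateral deformation is left uncorrected).
#' Idempotent; the rostrocaudal component is untouched.
#'
#' @param field a [DisplacementField-class].
#' @param rcAxis optionally re-declare the rostrocaudal axis.
#' @return the constrained [DisplacementField-class] with `uML` identically 0.
#' @export
constrainFieldAxis <- function(field, rcAxis = NULL) {
  if (!is.null(rcAxis)) field@rcAxis <- rcAxis
  field@uML <- matrix(0, nrow(field@uML), ncol(field@uML))
  field
}

#' Non-rigid motion correction with constrained demons fields (NR-MCM)
#'
#' Two-track flow: displacement fields are estimated per frame on the
#' normalization-chain representation ([normalizeFrameForRegistration]) of
#' the movie against a fixed template frame, the mediolateral component is
#' zeroed, and the fields are then applied with linear interpolation to the
#' analysis movie (typically the bandpass-divided movie; pass `applyTo`).
#' Residual frame-to-frame jitter is removed afterwards by a rigid
#' (translation) pass.
#'
#' @param movie a [MovieTensor-class] used for field ESTIMATION (raw or
#'   detrended; frames are normalized internally).
#' @param templateFrame index of the template frame (default 1).
#' @param config a [demonsConfig].
#' @param applyTo optional [MovieTensor-class] the fields are applied to
#'   (default: `movie` itself).
#' @param residualPass run the residual translation pass (default TRUE).
#' @return list with `movie` (corrected), `fields` (list of constrained
#'   [DisplacementField-class]), and `residualTransforms` (per-frame
#'   translation transforms, or NULL).
#' @export
runNRMCM <- function(movie, templateFrame = 1, config = demonsConfig(),
                     applyTo = NULL, residualPass = TRUE) {
  target <- if (is.null(applyTo)) movie else applyTo
  stopifnot(all(frameDim(target) == frameDim(movie)),
            nFrames(target) == nFrames(movie))
  T <- nFrames(movie)
  norm <- mapFrames(movie, normalizeFrameForRegistration, complement = TRUE)
  # demons needs finite frames; fill registration borders with the frame mean
  # (the warp applied to `target` still propagates its own missing pixels)
  fillNA <- function(f) { na <- !is.finite(f); if (any(na)) f[na] <- mean(f[!na]); f }
  norm <- mapFrames(norm, fillNA)
  tmplN <- getFrame(norm, templateFrame)
  fields <- vector("list", T)
  out <- target@data
  d <- frameDim(movie)
  for (t in seq_len(T)) {
    fld <- estimateDisplacementField(getFrame(norm, t), tmplN, config,
                                     rcAxis = movie@rcAxis)
    if (config$constrainToRC) fld <- constrainFieldAxis(fld)  # exact zeros
    fld@frameIndex <- t
    fields[[t]] <- fld
    out[t, , ] <- warpImage(matrix(target@data[t, , ], d[1], d[2]), fld)
  }
  corrected <- setMovieData(target, out)
  residual <- NULL
  if (residualPass) {
    residual <- vector("list", T)
    tmplC <- getFrame(corrected, templateFrame)
    refN <- normalizeFrameForRegistration(tmplC, complement = TRUE)
    for (t in seq_len(T)) {
      fr <- getFrame(corrected, t)
      tf <- tryCatch(
        estimateTranslation(normalizeFrameForRegistration(fr, complement = TRUE), refN),
        error = function(e) translationTransform(0, 0))
      # keep the rigid touch-up only when it actually improves alignment
      wfr <- warpImage(fr, tf)
      if (!is.finite(frameCor(wfr, tmplC)) ||
          frameCor(wfr, tmplC) <= frameCor(fr, tmplC)) {
        tf <- translationTransform(0, 0)
        wfr <- fr
      }
      tf@frameIndex <- t
      residual[[t]] <- tf
      out[t, , ] <- wfr
    }
    corrected <- setMovieData(target, out)
  }
  list(movie = corrected, fields = fields, residualTransforms = residual)
}

#' Per-frame correlation of a movie to a template frame
#'
#' The motion-correction quality metric: Pearson correlation of every frame
#' with the template frame over jointly valid pixels.
#'
#' @param movie a [MovieTensor-class].
#' @param templateFrame index of the template frame, or a Y x X matrix.
#' @return numeric vector of per-frame correlations.
#' @export
frameTemplateCorrelation <- function(movie, templateFrame = 1) {
  tmpl <- if (is.matrix(templateFrame)) templateFrame else getFrame(movie, templateFrame)
  vapply(seq_len(nFrames(movie)),
         function(t) frameCor(getFrame(movie, t), tmpl), 0)
}

#' Save displacement fields as an HDF5 tensor
#'
#' Stores a list of per-frame fields as a T x Y x X x 2 dataset (components
#' ordered rostrocaudal, mediolateral) with the rostrocaudal axis recorded
#' as an attribute.
#'
#' @param fields list of [DisplacementField-class] objects of equal shape.
#' @param path output HDF5 file.
#' @param dataset dataset name (default `"/fields"`).
#' @return `path`, invisibly.
#' @export
saveDisplacementFields <- function(fields, path, dataset = "/fields") {
  stopifnot(length(fields) >= 1)
  d <- dim(fields[[1]]@uRC)
  arr <- array(NA_real_, c(length(fields), d[1], d[2], 2))
  for (t in seq_along(fields)) {
    arr[t, , , 1] <- fields[[t]]@uRC
    arr[t, , , 2] <- fields[[t]]@uML
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  name <- sub("^/", "", dataset)
  rhdf5::h5write(arr, path, name)
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, name)
  rhdf5::h5writeAttribute(fields[[1]]@rcAxis, did, "rcAxis")
  rhdf5::H5Dclose(did); rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read displacement fields written by [saveDisplacementFields]
#' @param path HDF5 file.
#' @param dataset dataset name (default `"/fields"`).
#' @return list of [DisplacementField-class] objects.
#' @export
readDisplacementFields <- function(path, dataset = "/fields") {
  arr <- rhdf5::h5read(path, dataset)
  ax <- tryCatch(as.character(rhdf5::h5readAttributes(path, sub("^/", "", dataset))$rcAxis),
                 error = function(e) "y")
  if (!length(ax)) ax <- "y"
  lapply(seq_len(dim(arr)[1]), function(t)
    DisplacementField(uRC = matrix(arr[t, , , 1], dim(arr)[2], dim(arr)[3]),
                      uML = matrix(arr[t, , , 2], dim(arr)[2], dim(arr)[3]),
                      rcAxis = ax, frameIndex = t))
}
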