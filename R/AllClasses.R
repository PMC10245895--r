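#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib spinalmcm, .registration = TRUE
NULL

#' MovieTensor: a fluorescence movie with acquisition metadata
#'
#' Container for a T x Y x X fluorescence stack. Intensities are stored as
#' doubles; invalid pixels (e.g. outside the support of a warp) are `NA`,
#' never extrapolated. The rostrocaudal anatomical axis maps onto one image
#' axis (`"y"`, rows, by default); several operations (field constraint,
#' motion simulation) interpret displacements relative to this axis.
#'
#' @slot data numeric array, T x Y x X.
#' @slot frameRate frames per second (> 0).
#' @slot pixelSize microns per pixel, or `NA` when unknown.
#' @slot rcAxis `"y"` or `"x"`: which image axis is rostrocaudal.
#'
#' @aliases MovieTensor-class
#' @exportClass MovieTensor
setClass("MovieTensor",
  representation(data = "array", frameRate = "numeric",
                 pixelSize = "numeric", rcAxis = "character"),
  prototype(frameRate = 20, pixelSize = NA_real_, rcAxis = "y"))

setValidity("MovieTensor", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-D array (T x Y x X)")
  if (d[1] < 1L) return("movie must contain at least one frame")
  if (d[2] < 2L || d[3] < 2L) return("frames must be at least 2 x 2")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0) return("frameRate must be a positive scalar")
  if (!object@rcAxis %in% c("y", "x")) return("rcAxis must be 'y' or 'x'")
  TRUE
})

#' Construct a MovieTensor
#'
#' @param data 3-D numeric array, T x Y x X.
#' @param frameRate frames per second.
#' @param pixelSize microns per pixel (optional).
#' @param rcAxis which image axis is rostrocaudal, `"y"` (default) or `"x"`.
#' @return A [MovieTensor-class] object.
#' @examples
#' m <- MovieTensor(array(rnorm(4 * 8 * 8), c(4, 8, 8)), frameRate = 20)
#' nFrames(m)
#' @export
MovieTensor <- function(data, frameRate = 20, pixelSize = NA_real_, rcAxis = "y") {
  if (is.matrix(data)) stop("non-3-D array: got a 2-D matrix; a movie needs T x Y x X")
  if (length(dim(data)) != 3L) stop("non-3-D array")
  new("MovieTensor", data = array(as.double(data), dim(data)),
      frameRate = as.double(frameRate), pixelSize = as.double(pixelSize),
      rcAxis = rcAxis)
}

#' @describeIn MovieTensor number of frames T
#' @param x,object a `MovieTensor`.
#' @export
nFrames <- function(x) dim(x@data)[1]

#' @describeIn MovieTensor frame dimensions c(Y, X)
#' @export
frameDim <- function(x) dim(x@data)[2:3]

#' @describeIn MovieTensor the raw T x Y x X array
#' @export
movieData <- function(x) x@data

#' @describeIn MovieTensor acquisition rate in Hz
#' @export
frameRate <- function(x) x@frameRate

#' @describeIn MovieTensor microns per pixel (NA if unknown)
#' @export
pixelSize <- function(x) x@pixelSize

#' @describeIn MovieTensor rostrocaudal image axis ("y" or "x")
#' @export
rcAxis <- function(x) x@rcAxis

#' Extract one frame as a Y x X matrix
#' @param x a `MovieTensor`.
#' @param t frame index (1-based).
#' @return Y x X numeric matrix.
#' @export
getFrame <- function(x, t) {
  stopifnot(t >= 1, t <= nFrames(x))
  matrix(x@data[t, , ], frameDim(x)[1], frameDim(x)[2])
}

#' Replace the data array of a movie, keeping metadata
#' @param x a `MovieTensor`.
#' @param data new T x Y x X array.
#' @return a `MovieTensor`.
#' @export
setMovieData <- function(x, data) {
  new("MovieTensor", data = data, frameRate = x@frameRate,
      pixelSize = x@pixelSize, rcAxis = x@rcAxis)
}

setMethod("show", "MovieTensor", function(object) {
  d <- dim(object@data)
  cat(sprintf("MovieTensor: %d frames of %d x %d px @ %.4g Hz\n",
              d[1], d[2], d[3], object@frameRate))
  cat(sprintf("  pixel size: %s; rostrocaudal axis: %s; %.3g%% missing\n",
              if (is.na(object@pixelSize)) "unknown"
              else sprintf("%.3g um/px", object@pixelSize),
              object@rcAxis, 100 * mean(is.na(object@data))))
})

#' Transform2D: a per-frame 2-D geometric transform
#'
#' Rigid, translation or affine map of image coordinates, stored as a 2 x 3
#' matrix acting on homogeneous (x, y, 1) pixel coordinates (0-based pixel
#' centers). The transform maps points in the MOVING frame into the FIXED
#' (reference) frame. Rigid transforms keep an orthonormal linear part with
#' determinant +1.
#'
#' @slot kind `"translation"`, `"rigid"` or `"affine"`.
#' @slot matrix 2 x 3 transform matrix.
#' @slot frameIndex the movie frame this transform belongs to (NA if free).
#' @slot flags character vector of advisory flags (e.g. `"interpolated"`,
#'   `"not_converged"`).
#'
#' @aliases Transform2D-class
#' @exportClass Transform2D
setClass("Transform2D",
  representation(kind = "character", matrix = "matrix",
                 frameIndex = "numeric", flags = "character"),
  prototype(kind = "translation", frameIndex = NA_real_, flags = character()))

setValidity("Transform2D", function(object) {
  if (!object@kind %in% c("translation", "rigid", "affine"))
    return("kind must be translation, rigid or affine")
  if (!all(dim(object@matrix) == c(2L, 3L))) return("matrix must be 2 x 3")
  if (any(!is.finite(object@matrix))) return("non-finite transform")
  if (object@kind %in% c("translation", "rigid")) {
    L <- object@matrix[, 1:2]
    if (max(abs(crossprod(L) - diag(2))) > 1e-6 || det(L) < 0)
      return("rigid transform's linear part must be orthonormal with det +1")
  }
  TRUE
})

#' Build a translation transform
#' @param dx,dy translation in pixels (x = columns, y = rows).
#' @param frameIndex optional frame index.
#' @return a [Transform2D-class].
#' @export
translationTransform <- function(dx, dy, frameIndex = NA_real_) {
  new("Transform2D", kind = "translation",
      matrix = cbind(diag(2), c(dx, dy)), frameIndex = as.double(frameIndex))
}

#' Build a rigid (rotation + translation) transform
#' @param dx,dy translation in pixels.
#' @param theta rotation in radians (counter-clockwise in pixel coordinates).
#' @param frameIndex optional frame index.
#' @return a [Transform2D-class].
#' @export
rigidTransform <- function(dx, dy, theta = 0, frameIndex = NA_real_) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  new("Transform2D", kind = if (abs(theta) < 1e-15) "translation" else "rigid",
      matrix = cbind(R, c(dx, dy)), frameIndex = as.double(frameIndex))
}

#' Build an affine transform from a 2 x 3 matrix
#' @param m 2 x 3 matrix acting on (x, y, 1).
#' @param frameIndex optional frame index.
#' @return a [Transform2D-class].
#' @export
affineTransform <- function(m, frameIndex = NA_real_) {
  new("Transform2D", kind = "affine", matrix = m, frameIndex = as.double(frameIndex))
}

#' @describeIn Transform2D the 2 x 3 matrix
#' @param x a `Transform2D`.
#' @export
asMatrix <- function(x) x@matrix

#' @describeIn Transform2D the transform kind
#' @export
transformKind <- function(x) x@kind

setMethod("show", "Transform2D", function(object) {
  m <- object@matrix
  theta <- atan2(m[2, 1], m[1, 1])
  cat(sprintf("Transform2D <%s>: dx=%.4g dy=%.4g theta=%.4g deg%s\n",
              object@kind, m[1, 3], m[2, 3], theta * 180 / pi,
              if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ","), "]")
              else ""))
})

#' DisplacementField: a per-frame non-rigid displacement field
#'
#' Two-component per-pixel field from demons registration. Components are
#' stored anatomically: `uRC` along the rostrocaudal axis, `uML` along the
#' mediolateral axis (see [rcAxis]). Warping samples the moving image at
#' p + u(p), so the field maps reference-frame pixels onto moving-frame
#' positions.
#'
#' @slot uRC Y x X rostrocaudal displacement (px).
#' @slot uML Y x X mediolateral displacement (px).
#' @slot rcAxis which image axis is rostrocaudal.
#' @slot frameIndex frame the field belongs to.
#'
#' @aliases DisplacementField-class
#' @exportClass DisplacementField
setClass("DisplacementField",
  representation(uRC = "matrix", uML = "matrix", rcAxis = "character",
                 frameIndex = "numeric"),
  prototype(rcAxis = "y", frameIndex = NA_real_))

setValidity("DisplacementField", function(object) {
  if (!all(dim(object@uRC) == dim(object@uML)))
    return("uRC and uML must have identical dimensions")
  if (any(!is.finite(object@uRC)) || any(!is.finite(object@uML)))
    return("displacement field must be finite everywhere")
  if (!object@rcAxis %in% c("y", "x")) return("rcAxis must be 'y' or 'x'")
  TRUE
})

#' Construct a DisplacementField
#' @param uRC,uML Y x X matrices of rostrocaudal / mediolateral displacement (px).
#' @param rcAxis which image axis is rostrocaudal.
#' @param frameIndex optional frame index.
#' @return a [DisplacementField-class].
#' @export
DisplacementField <- function(uRC, uML, rcAxis = "y", frameIndex = NA_real_) {
  new("DisplacementField", uRC = uRC, uML = uML, rcAxis = rcAxis,
      frameIndex = as.double(frameIndex))
}

#' @describeIn DisplacementField rostrocaudal component (px)
#' @param x a `DisplacementField`.
#' @export
fieldRC <- function(x) x@uRC

#' @describeIn DisplacementField mediolateral component (px)
#' @export
fieldML <- function(x) x@uML

setMethod("show", "DisplacementField", function(object) {
  cat(sprintf("DisplacementField %d x %d (rc axis %s): max|uRC|=%.3g px, max|uML|=%.3g px\n",
              nrow(object@uRC), ncol(object@uRC), object@rcAxis,
              max(abs(object@uRC)), max(abs(object@uML))))
})
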