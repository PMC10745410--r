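#' @include methods-accessors.R
NULL

#' Create a parallel-beam scan geometry
#'
#' View angles are equally spaced on `[0, angularSpanDeg)`:
#' `k * angularSpanDeg / nViews` for `k = 0, ..., nViews - 1`.  The detector
#' is a linear array perpendicular to the ray direction, centred on the
#' rotation centre (= image centre).  By default its extent is resolved when
#' a system matrix is built: the bins span the image diagonal
#' (`sqrt(2) * nCols` pixels), so every pixel is covered at every angle.
#'
#' @param nViews number of projection views (>= 1).
#' @param nDetectors number of detector bins (>= 1).
#' @param angularSpanDeg angular span in degrees, in (0, 360]; 180 is the
#'   standard parallel-beam span.
#' @param detectorSpacing bin spacing in pixel-size units, or `NA` (default)
#'   for the diagonal-spanning automatic spacing.
#' @param detectorOffset lateral shift of the detector centre in pixel-size
#'   units (default 0).
#' @return A [ScanGeometry-class].
#' @examples
#' g <- makeParallelGeometry(30, 512)
#' viewAngles(g)[1:5]   # 0, 6, 12, 18, 24 degrees
#' @export
makeParallelGeometry <- function(nViews, nDetectors, angularSpanDeg = 180,
                                 detectorSpacing = NA_real_,
                                 detectorOffset = 0) {
  if (length(nViews) != 1L || !is.finite(nViews) || nViews < 1)
    stop("nViews must be a positive integer")
  if (length(nDetectors) != 1L || !is.finite(nDetectors) || nDetectors < 1)
    stop("nDetectors must be a positive integer")
  if (!(angularSpanDeg > 0 && angularSpanDeg <= 360))
    stop("angularSpanDeg must lie in (0, 360]")
  nViews <- as.integer(nViews)
  angles <- (seq_len(nViews) - 1) * angularSpanDeg / nViews
  new("ScanGeometry",
      nViews = nViews, nDetectors = as.integer(nDetectors),
      angularSpan = as.numeric(angularSpanDeg), angles = angles,
      detectorSpacing = as.numeric(detectorSpacing),
      detectorOffset = as.numeric(detectorOffset))
}

# signed detector-bin centre positions along the detector axis, in physical
# units, for a grid with nCols columns
.detectorOffsets <- function(geometry, nCols, pixelSize) {
  nd <- geometry@nDetectors
  spacing <- if (is.na(geometry@detectorSpacing))
    sqrt(2) * nCols * pixelSize / nd
  else geometry@detectorSpacing * pixelSize
  (seq_len(nd) - 1 - (nd - 1) / 2) * spacing +
    geometry@detectorOffset * pixelSize
}

#' Trace a single ray through a pixel grid
#'
#' Incremental Siddon-style grid traversal of a zero-width ray through the
#' centre of one detector bin.  Angle 0 sends rays along the +x (column)
#' direction; the grid centre is the rotation centre.  Segment lengths are
#' in physical units and sum to the chord length of the ray through the grid
#' bounding box; zero-length corner grazings are dropped.
#'
#' @param geometry a [ScanGeometry-class].
#' @param gridShape integer `c(nRows, nCols)`.
#' @param pixelSize pixel edge length (default 1).
#' @param viewIndex view number, 1-based.
#' @param detectorIndex detector bin number, 1-based.
#' @return A `data.frame` with columns `pixel` (column-major linear index,
#'   1-based), `row`, `col`, and `length`; one row per crossed pixel.
#' @export
traceRay <- function(geometry, gridShape, pixelSize = 1,
                     viewIndex, detectorIndex) {
  stopifnot(is(geometry, "ScanGeometry"))
  if (viewIndex < 1 || viewIndex > geometry@nViews)
    stop("viewIndex out of range")
  if (detectorIndex < 1 || detectorIndex > geometry@nDetectors)
    stop("detectorIndex out of range")
  nr <- as.integer(gridShape[1]); nc <- as.integer(gridShape[2])
  th <- geometry@angles[viewIndex] * pi / 180
  t <- .detectorOffsets(geometry, nc, pixelSize)[detectorIndex]
  hit <- .cpp_trace_ray(-t * sin(th), t * cos(th), cos(th), sin(th),
                        nr, nc, pixelSize)
  idx <- hit$index + 1L
  data.frame(pixel = idx,
             row = ((idx - 1L) %% nr) + 1L,
             col = ((idx - 1L) %/% nr) + 1L,
             length = hit$length)
}

#' Build the sparse system matrix for a geometry/grid pair
#'
#' Traces every ray of the geometry through the grid and assembles the
#' M x N matrix W of ray--pixel intersection lengths (M = nViews *
#' nDetectors rays in view-major order, N pixels in column-major order).
#' Rays that miss the grid produce empty rows; they are recorded in the
#' `zeroRows` slot and skipped by SART updates.
#'
#' @param geometry a [ScanGeometry-class].
#' @param grid a [CTImage-class] (only its dimensions and pixel size are
#'   used).
#' @return A [SystemMatrix-class].
#' @examples
#' g <- makeParallelGeometry(10, 64)
#' A <- buildSystemMatrix(g, sheppLogan(64))
#' dim(A)   # 640 rays x 4096 pixels
#' @export
buildSystemMatrix <- function(geometry, grid) {
  stopifnot(is(geometry, "ScanGeometry"), is(grid, "CTImage"))
  nr <- nrow(grid@values); nc <- ncol(grid@values)
  px <- grid@pixelSize
  off <- .detectorOffsets(geometry, nc, px)
  trip <- .cpp_trace_all(geometry@angles * pi / 180, off, nr, nc, px)
  M <- geometry@nViews * geometry@nDetectors
  N <- nr * nc
  wT <- Matrix::sparseMatrix(i = trip$pixel + 1L, j = trip$ray + 1L,
                             x = trip$value, dims = c(N, M))
  new("SystemMatrix",
      weightsT = wT, geometry = geometry,
      imageDim = c(nr, nc), pixelSize = px,
      rowSums = trip$row_sums,
      zeroRows = which(trip$row_sums == 0))
}

.imageVector <- function(image, A = NULL) {
  v <- if (is(image, "CTImage")) image@values else as.matrix(image)
  if (!is.null(A) && !identical(dim(v), as.integer(A@imageDim)) &&
      !identical(as.integer(dim(v)), A@imageDim))
    stop("image dimensions do not match the system matrix grid")
  as.vector(v)
}

# length-M view-major ray vector of a sinogram
.sinoVector <- function(s) {
  if (is(s, "Sinogram")) as.vector(t(s@values)) else as.numeric(s)
}

#' @rdname forwardProject
setMethod("forwardProject", "SystemMatrix", function(object, image) {
  f <- .imageVector(image, object)
  if (any(is.na(f))) stop("image contains NA values")
  p <- as.numeric(Matrix::crossprod(object@weightsT, f))
  sinogram(p, object@geometry)
})

#' @rdname backProject
setMethod("backProject", "SystemMatrix", function(object, sinogram) {
  p <- .sinoVector(sinogram)
  if (length(p) != dim(object)[1])
    stop("sinogram length does not match the system matrix")
  b <- as.numeric(object@weightsT %*% p)
  ctImage(matrix(b, nrow = object@imageDim[1]), object@pixelSize)
})
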