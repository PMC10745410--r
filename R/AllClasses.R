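#' @include fdtvct-package.R
NULL

#' Parallel-beam scan geometry
#'
#' Describes a 2-D parallel-beam acquisition: the ordered set of view angles
#' (equally spaced over the angular span) and a linear detector array that is
#' perpendicular to the ray direction and centred on the rotation centre.
#'
#' @slot nViews number of projection views.
#' @slot nDetectors number of detector bins per view.
#' @slot angularSpan angular span in degrees (180 for standard parallel-beam
#'   sampling).
#' @slot angles view angles in degrees, `k * angularSpan / nViews` for
#'   `k = 0, ..., nViews - 1`.
#' @slot detectorSpacing detector bin spacing in pixel-size units; `NA` means
#'   "auto": the detector row spans the image diagonal, so every pixel is
#'   covered at every angle.
#' @slot detectorOffset lateral shift of the detector centre, in pixel-size
#'   units.
#' @seealso [makeParallelGeometry()]
#' @exportClass ScanGeometry
setClass("ScanGeometry",
  representation(
    nViews = "integer",
    nDetectors = "integer",
    angularSpan = "numeric",
    angles = "numeric",
    detectorSpacing = "numeric",
    detectorOffset = "numeric"
  )
)

setValidity("ScanGeometry", function(object) {
  msg <- character()
  if (length(object@nViews) != 1L || object@nViews < 1L)
    msg <- c(msg, "nViews must be a single positive integer")
  if (length(object@nDetectors) != 1L || object@nDetectors < 1L)
    msg <- c(msg, "nDetectors must be a single positive integer")
  if (!(object@angularSpan > 0 && object@angularSpan <= 360))
    msg <- c(msg, "angularSpan must lie in (0, 360]")
  a <- object@angles
  if (length(a) != object@nViews) {
    msg <- c(msg, "angles must have length nViews")
  } else {
    if (any(a < 0 | a >= object@angularSpan))
      msg <- c(msg, "angles must lie in [0, angularSpan)")
    if (length(a) > 1) {
      d <- diff(a)
      if (any(d <= 0) || max(abs(d - d[1])) > 1e-9)
        msg <- c(msg, "angles must be strictly increasing and equally spaced")
    }
  }
  if (length(msg)) msg else TRUE
})

#' 2-D attenuation image
#'
#' The reconstruction unknown: an `nRows x nCols` matrix of attenuation
#' values on a square pixel grid with spacing `pixelSize` (same in x and y).
#'
#' @slot values numeric matrix of pixel values (finite).
#' @slot pixelSize pixel edge length in physical units.
#' @seealso [ctImage()], [sheppLogan()]
#' @exportClass CTImage
setClass("CTImage",
  representation(values = "matrix", pixelSize = "numeric")
)

setValidity("CTImage", function(object) {
  msg <- character()
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be numeric")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(object@pixelSize) != 1L || !(object@pixelSize > 0))
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Sparse ray--pixel system matrix
#'
#' Holds the M x N projection matrix W of ray--pixel intersection lengths
#' for a geometry/grid pair.  Rays are ordered view-major (all detectors of
#' view 1, then view 2, ...), so view `v` owns rows
#' `((v-1) * nDetectors + 1) : (v * nDetectors)`.  W is stored once, as the
#' `dgCMatrix` of its transpose: the CSC slots of t(W) are exactly the CSR
#' layout of W that the SART sweep kernel consumes.
#'
#' @slot weightsT `Matrix::dgCMatrix` of dimension N x M holding t(W).
#' @slot geometry the [ScanGeometry-class] the matrix was built from.
#' @slot imageDim integer `c(nRows, nCols)` of the target grid.
#' @slot pixelSize pixel size of the target grid.
#' @slot rowSums length-M vector of per-ray weight sums (chord lengths).
#' @slot zeroRows indices of rays that miss the grid entirely (skipped by
#'   SART updates).
#' @seealso [buildSystemMatrix()], [forwardProject()]
#' @exportClass SystemMatrix
setClass("SystemMatrix",
  representation(
    weightsT = "dgCMatrix",
    geometry = "ScanGeometry",
    imageDim = "integer",
    pixelSize = "numeric",
    rowSums = "numeric",
    zeroRows = "integer"
  )
)

setValidity("SystemMatrix", function(object) {
  msg <- character()
  M <- object@geometry@nViews * object@geometry@nDetectors
  N <- prod(object@imageDim)
  if (!identical(dim(object@weightsT), c(as.integer(N), as.integer(M))))
    msg <- c(msg, "weightsT must be N x M for the geometry/grid pair")
  if (length(object@rowSums) != M)
    msg <- c(msg, "rowSums must have length M")
  x <- object@weightsT@x
  if (length(x) && (any(x <= 0) ||
                    max(x) > sqrt(2) * object@pixelSize * (1 + 1e-9)))
    msg <- c(msg,
      "stored weights must be positive and at most sqrt(2) * pixelSize")
  if (length(msg)) msg else TRUE
})

#' Projection data for one acquisition
#'
#' Measured or simulated line integrals, as an `nViews x nDetectors` matrix
#' (one row per view angle) together with the geometry that produced them.
#'
#' @slot values numeric `nViews x nDetectors` matrix of projection values.
#' @slot geometry the associated [ScanGeometry-class].
#' @seealso [forwardProject()], [sinogram()]
#' @exportClass Sinogram
setClass("Sinogram",
  representation(values = "matrix", geometry = "ScanGeometry")
)

setValidity("Sinogram", function(object) {
  msg <- character()
  g <- object@geometry
  if (!identical(dim(object@values),
                 c(as.integer(g@nViews), as.integer(g@nDetectors))))
    msg <- c(msg, "values must be an nViews x nDetectors matrix")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' Total-variation configuration
#'
#' @slot epsilon small positive constant added under the square root of the
#'   per-pixel gradient magnitude so the steepest-descent direction never
#'   divides by zero.
#' @slot delta sampling interval (pixel spacing) used to scale the squared
#'   differences.
#' @slot boundary boundary rule; `"replicate"` treats out-of-range neighbour
#'   differences as zero.
#' @seealso [tvConfig()], [fdtvValue()]
#' @exportClass TVConfig
setClass("TVConfig",
  representation(epsilon = "numeric", delta = "numeric",
                 boundary = "character")
)

setValidity("TVConfig", function(object) {
  msg <- character()
  if (!(object@epsilon > 0)) msg <- c(msg, "epsilon must be > 0")
  if (!(object@delta > 0)) msg <- c(msg, "delta must be > 0")
  if (!identical(object@boundary, "replicate"))
    msg <- c(msg, "only boundary = 'replicate' is supported")
  if (length(msg)) msg else TRUE
})

#' Reconstruction configuration
#'
#' Bundle of solver controls for [reconstruct()].  The constructor
#' [reconConfig()] fills algorithm-appropriate defaults.
#'
#' @slot algorithm one of `"SART"`, `"SART_TV"`, `"SART_FDTV"`,
#'   `"ADAPTIVE_FDTV"`, `"ASD_POCS"`.
#' @slot kIter maximum number of outer iterations.
#' @slot nTV number of inner TV steepest-descent steps per outer iteration.
#' @slot lambdaMode `"fixed"` or `"adaptive"` SART relaxation.
#' @slot lambdaFixed fixed relaxation value (used when `lambdaMode` is
#'   `"fixed"`).
#' @slot stepMode `"fixed"` or `"adaptive"` TV step size.
#' @slot stepFixed fixed TV step value.
#' @slot resTol stopping tolerance on the per-pixel iterate change.
#' @slot tvKind `"four_direction"` or `"two_direction"`.
#' @slot tv the [TVConfig-class] used by the TV stage.
#' @slot nonneg where the non-negativity projection is applied: `"sweep"`
#'   (after each full pass over the views) or `"view"` (after every view).
#' @slot gradientForm `"analytic"` (exact gradient of the four-direction
#'   functional) or `"printed"` (literal horizontal/vertical stencil).
#' @slot asd named list of ASD-POCS controls (`beta`, `betaRed`, `ng`,
#'   `alpha`, `alphaRed`, `rMax`).
#' @exportClass ReconConfig
setClass("ReconConfig",
  representation(
    algorithm = "character",
    kIter = "integer",
    nTV = "integer",
    lambdaMode = "character",
    lambdaFixed = "numeric",
    stepMode = "character",
    stepFixed = "numeric",
    resTol = "numeric",
    tvKind = "character",
    tv = "TVConfig",
    nonneg = "character",
    gradientForm = "character",
    asd = "list"
  )
)

setValidity("ReconConfig", function(object) {
  msg <- character()
  if (!object@algorithm %in%
      c("SART", "SART_TV", "SART_FDTV", "ADAPTIVE_FDTV", "ASD_POCS"))
    msg <- c(msg, "unknown algorithm")
  if (object@kIter < 1L) msg <- c(msg, "kIter must be >= 1")
  if (object@nTV < 0L) msg <- c(msg, "nTV must be >= 0")
  if (!(object@lambdaFixed > 0)) msg <- c(msg, "lambdaFixed must be > 0")
  if (!(object@resTol > 0)) msg <- c(msg, "resTol must be > 0")
  if (!object@lambdaMode %in% c("fixed", "adaptive"))
    msg <- c(msg, "lambdaMode must be 'fixed' or 'adaptive'")
  if (!object@stepMode %in% c("fixed", "adaptive"))
    msg <- c(msg, "stepMode must be 'fixed' or 'adaptive'")
  if (!object@tvKind %in% c("two_direction", "four_direction"))
    msg <- c(msg, "tvKind must be 'two_direction' or 'four_direction'")
  if (!object@nonneg %in% c("sweep", "view", "none"))
    msg <- c(msg, "nonneg must be 'sweep', 'view' or 'none'")
  if (!object@gradientForm %in% c("analytic", "printed"))
    msg <- c(msg, "gradientForm must be 'analytic' or 'printed'")
  if (length(msg)) msg else TRUE
})

#' Reconstruction result
#'
#' Returned by [reconstruct()] and [asdPocs()]: the final image, the
#' per-iteration trace (columns `k`, `delta_d`, `eta`, `res`, and
#' `psnr`/`ssim`/`rmse` when a reference image was supplied), and the
#' per-view relaxation parameters that were used.
#'
#' @slot image the reconstructed [CTImage-class].
#' @slot trace per-iteration `data.frame`.
#' @slot lambdaPerView numeric vector of per-view relaxation parameters
#'   (constant vector for fixed-relaxation runs).
#' @slot config the [ReconConfig-class] that produced the result.
#' @exportClass ReconResult
setClass("ReconResult",
  representation(
    image = "CTImage",
    trace = "data.frame",
    lambdaPerView = "numeric",
    config = "ReconConfig"
  )
)

#' Image-quality report
#'
#' @slot psnr peak signal-to-noise ratio in dB.
#' @slot ssim structural similarity index.
#' @slot rmse root-mean-square error.
#' @slot c1,c2 SSIM stabilisation constants that were used.
#' @slot refStats named vector with mean and standard deviation of the
#'   reference image.
#' @slot testStats named vector with mean and standard deviation of the
#'   test image.
#' @seealso [qualityReport()]
#' @exportClass QualityReport
setClass("QualityReport",
  representation(
    psnr = "numeric", ssim = "numeric", rmse = "numeric",
    c1 = "numeric", c2 = "numeric",
    refStats = "numeric", testStats = "numeric"
  )
)

# ---- constructors ---------------------------------------------------------

#' Create a CT image
#'
#' @param values numeric matrix (or object coercible to one) of pixel values.
#' @param pixelSize pixel edge length, default 1 (pixel units).
#' @return A [CTImage-class].
#' @examples
#' img <- ctImage(matrix(0, 8, 8))
#' dim(img)
#' @export
ctImage <- function(values, pixelSize = 1) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("CTImage", values = values, pixelSize = as.numeric(pixelSize))
}

#' Create a sinogram from a matrix of projection values
#'
#' @param values `nViews x nDetectors` matrix (or vector of length
#'   `nViews * nDetectors` in view-major ray order).
#' @param geometry the [ScanGeometry-class] the data belong to.
#' @return A [Sinogram-class].
#' @export
sinogram <- function(values, geometry) {
  if (is.null(dim(values))) {
    stopifnot(length(values) == geometry@nViews * geometry@nDetectors)
    values <- matrix(as.numeric(values), nrow = geometry@nViews,
                     ncol = geometry@nDetectors, byrow = TRUE)
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("Sinogram", values = values, geometry = geometry)
}

#' Total-variation settings
#'
#' @param epsilon positive constant guarding the gradient-magnitude
#'   denominators (default `1e-8`).
#' @param delta sampling interval, default 1 (pixel units).
#' @param boundary boundary rule; only `"replicate"` (out-of-range neighbour
#'   differences are zero) is supported.
#' @return A [TVConfig-class].
#' @export
tvConfig <- function(epsilon = 1e-8, delta = 1, boundary = "replicate") {
  new("TVConfig", epsilon = as.numeric(epsilon), delta = as.numeric(delta),
      boundary = boundary)
}

#' Solver configuration
#'
#' Builds a [ReconConfig-class] with defaults appropriate for the chosen
#' algorithm:
#' \describe{
#'   \item{`SART`}{plain SART with fixed relaxation, no TV stage.}
#'   \item{`SART_TV`}{fixed relaxation + fixed-step descent on the
#'     conventional two-direction TV.}
#'   \item{`SART_FDTV`}{fixed relaxation + fixed-step descent on the
#'     four-direction TV.}
#'   \item{`ADAPTIVE_FDTV`}{the adaptive method: per-view relaxation from the
#'     projection-mass share of each view, four-direction TV, and a descent
#'     step tied to the image change of the POCS stage.}
#'   \item{`ASD_POCS`}{classical adaptive-steepest-descent POCS baseline.}
#' }
#'
#' @param algorithm algorithm name, see above.
#' @param kIter maximum outer iterations (default 200).
#' @param nTV inner TV descent steps per outer iteration (default 20).
#' @param lambdaMode,lambdaFixed SART relaxation control; `NULL` mode picks
#'   the algorithm default (`"adaptive"` for `ADAPTIVE_FDTV`, else
#'   `"fixed"`); fixed value defaults to 0.5.
#' @param stepMode,stepFixed TV step control; `NULL` mode picks the algorithm
#'   default (`"adaptive"` for `ADAPTIVE_FDTV`, else `"fixed"`); fixed value
#'   defaults to 0.3.
#' @param resTol stopping tolerance on `res` (default `1e-12`).
#' @param tvKind `NULL` picks the algorithm default (`"two_direction"` for
#'   `SART_TV` and `ASD_POCS`, else `"four_direction"`).
#' @param epsilon,delta forwarded to [tvConfig()].
#' @param nonneg `"sweep"` (default), `"view"` or `"none"`.
#' @param gradientForm `"analytic"` (default) or `"printed"`.
#' @param asd named list overriding ASD-POCS controls; defaults
#'   `list(beta = 1, betaRed = 0.995, ng = 20, alpha = 0.2,
#'   alphaRed = 0.95, rMax = 0.95)`.
#' @return A validated [ReconConfig-class].
#' @export
reconConfig <- function(algorithm = c("ADAPTIVE_FDTV", "SART", "SART_TV",
                                      "SART_FDTV", "ASD_POCS"),
                        kIter = 200L, nTV = 20L,
                        lambdaMode = NULL, lambdaFixed = 0.5,
                        stepMode = NULL, stepFixed = 0.3,
                        resTol = 1e-12, tvKind = NULL,
                        epsilon = 1e-8, delta = 1,
                        nonneg = "sweep", gradientForm = "analytic",
                        asd = list()) {
  algorithm <- match.arg(algorithm)
  if (is.null(lambdaMode))
    lambdaMode <- if (algorithm == "ADAPTIVE_FDTV") "adaptive" else "fixed"
  if (is.null(stepMode))
    stepMode <- if (algorithm == "ADAPTIVE_FDTV") "adaptive" else "fixed"
  if (is.null(tvKind))
    tvKind <- if (algorithm %in% c("SART_TV", "ASD_POCS"))
      "two_direction" else "four_direction"
  asdDefaults <- list(beta = 1.0, betaRed = 0.995, ng = 20L,
                      alpha = 0.2, alphaRed = 0.95, rMax = 0.95)
  asd <- modifyList(asdDefaults, asd)
  new("ReconConfig",
      algorithm = algorithm, kIter = as.integer(kIter), nTV = as.integer(nTV),
      lambdaMode = lambdaMode, lambdaFixed = as.numeric(lambdaFixed),
      stepMode = stepMode, stepFixed = as.numeric(stepFixed),
      resTol = as.numeric(resTol), tvKind = tvKind,
      tv = tvConfig(epsilon = epsilon, delta = delta),
      nonneg = nonneg, gradientForm = gradientForm, asd = asd)
}
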