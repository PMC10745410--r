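#' @include AllClasses.R
NULL

#' Forward projection P = W F
#'
#' @param object a [SystemMatrix-class].
#' @param image a [CTImage-class] (or plain matrix) with `prod(imageDim)`
#'   pixels.
#' @return A [Sinogram-class] with one row per view.
#' @seealso [backProject()]
#' @export
setGeneric("forwardProject", function(object, image)
  standardGeneric("forwardProject"))

#' Unfiltered back projection t(W) P
#'
#' @param object a [SystemMatrix-class].
#' @param sinogram a [Sinogram-class] (or a length-M vector in view-major
#'   ray order).
#' @return A [CTImage-class].
#' @export
setGeneric("backProject", function(object, sinogram)
  standardGeneric("backProject"))

#' Iterative reconstruction from a sinogram
#'
#' Runs the solver selected by `config@algorithm` (see [reconConfig()]) from
#' a zero initial image: alternating SART sweeps with non-negativity
#' projection and TV steepest-descent steps, stopping when the per-pixel
#' iterate change falls below `config@resTol` or `config@kIter` outer
#' iterations have run.
#'
#' @param sinogram a [Sinogram-class].
#' @param matrix the [SystemMatrix-class] for the target grid.
#' @param config a [ReconConfig-class]; default `reconConfig()` (the
#'   adaptive four-direction method).
#' @param reference optional ground-truth [CTImage-class]; when given,
#'   per-iteration PSNR/SSIM/RMSE are recorded in the trace.
#' @param verbose print per-iteration progress.
#' @return A [ReconResult-class].
#' @export
setGeneric("reconstruct",
  function(sinogram, matrix, config = reconConfig(), reference = NULL,
           verbose = FALSE)
    standardGeneric("reconstruct"))

#' @rdname accessors
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("nViews", function(x) standardGeneric("nViews"))

#' @rdname accessors
#' @export
setGeneric("nDetectors", function(x) standardGeneric("nDetectors"))

#' @rdname accessors
#' @export
setGeneric("viewAngles", function(x) standardGeneric("viewAngles"))

#' @rdname accessors
#' @export
setGeneric("sinoValues", function(x) standardGeneric("sinoValues"))

#' @rdname accessors
#' @export
setGeneric("sysWeights", function(x) standardGeneric("sysWeights"))

#' @rdname accessors
#' @export
setGeneric("rayRowSums", function(x) standardGeneric("rayRowSums"))

#' @rdname accessors
#' @export
setGeneric("rowGroups", function(x) standardGeneric("rowGroups"))

#' @rdname accessors
#' @export
setGeneric("zeroRays", function(x) standardGeneric("zeroRays"))

#' @rdname accessors
#' @export
setGeneric("reconImage", function(x) standardGeneric("reconImage"))

#' @rdname accessors
#' @export
setGeneric("iterationTrace", function(x) standardGeneric("iterationTrace"))

#' @rdname accessors
#' @export
setGeneric("lambdaPerView", function(x) standardGeneric("lambdaPerView"))
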