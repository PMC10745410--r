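#' @include AllGenerics.R
NULL

#' Accessors for the core classes
#'
#' Small accessor functions for [CTImage-class], [ScanGeometry-class],
#' [SystemMatrix-class], [Sinogram-class] and [ReconResult-class] objects;
#' prefer these over direct slot access.
#'
#' @param x an object of the matching class.
#' @return `imageValues`: the pixel matrix; `pixelSize`: the pixel edge
#'   length; `nViews`/`nDetectors`/`viewAngles`: geometry fields;
#'   `sinoValues`: the `nViews x nDetectors` projection matrix;
#'   `sysWeights`: the M x N sparse weight matrix W; `rayRowSums`: per-ray
#'   weight sums; `rowGroups`: a two-column matrix with the first and last
#'   ray index of each view; `zeroRays`: indices of rays that miss the grid;
#'   `reconImage`/`iterationTrace`/`lambdaPerView`: components of a
#'   reconstruction result.
#' @name accessors
NULL

#' @rdname accessors
setMethod("imageValues", "CTImage", function(x) x@values)

#' @rdname accessors
setMethod("pixelSize", "CTImage", function(x) x@pixelSize)

#' @rdname accessors
setMethod("pixelSize", "SystemMatrix", function(x) x@pixelSize)

#' @rdname accessors
setMethod("nViews", "ScanGeometry", function(x) x@nViews)

#' @rdname accessors
setMethod("nViews", "Sinogram", function(x) x@geometry@nViews)

#' @rdname accessors
setMethod("nViews", "SystemMatrix", function(x) x@geometry@nViews)

#' @rdname accessors
setMethod("nDetectors", "ScanGeometry", function(x) x@nDetectors)

#' @rdname accessors
setMethod("nDetectors", "Sinogram", function(x) x@geometry@nDetectors)

#' @rdname accessors
setMethod("nDetectors", "SystemMatrix", function(x) x@geometry@nDetectors)

#' @rdname accessors
setMethod("viewAngles", "ScanGeometry", function(x) x@angles)

#' @rdname accessors
setMethod("viewAngles", "Sinogram", function(x) x@geometry@angles)

#' @rdname accessors
setMethod("sinoValues", "Sinogram", function(x) x@values)

#' @rdname accessors
setMethod("sysWeights", "SystemMatrix", function(x) Matrix::t(x@weightsT))

#' @rdname accessors
setMethod("rayRowSums", "SystemMatrix", function(x) x@rowSums)

#' @rdname accessors
setMethod("rowGroups", "SystemMatrix", function(x) {
  nd <- x@geometry@nDetectors
  v <- seq_len(x@geometry@nViews)
  cbind(first = (v - 1L) * nd + 1L, last = v * nd)
})

#' @rdname accessors
setMethod("zeroRays", "SystemMatrix", function(x) x@zeroRows)

#' @rdname accessors
setMethod("reconImage", "ReconResult", function(x) x@image)

#' @rdname accessors
setMethod("iterationTrace", "ReconResult", function(x) x@trace)

#' @rdname accessors
setMethod("lambdaPerView", "ReconResult", function(x) x@lambdaPerView)

#' @describeIn accessors image dimensions `c(nRows, nCols)`.
setMethod("dim", "CTImage", function(x) dim(x@values))

#' @describeIn accessors sinogram dimensions `c(nViews, nDetectors)`.
setMethod("dim", "Sinogram", function(x) dim(x@values))

#' @describeIn accessors system-matrix dimensions `c(M, N)`.
setMethod("dim", "SystemMatrix", function(x) rev(dim(x@weightsT)))

# ---- show methods ---------------------------------------------------------

setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf(
    "ScanGeometry: %d views over %g deg (step %g deg), %d detectors\n",
    object@nViews, object@angularSpan,
    if (object@nViews > 1) object@angles[2] - object@angles[1]
    else object@angularSpan,
    object@nDetectors))
  sp <- if (is.na(object@detectorSpacing)) "auto (image diagonal)"
        else sprintf("%g px", object@detectorSpacing)
  cat(sprintf("  detector spacing: %s, centre offset: %g px\n",
              sp, object@detectorOffset))
})

setMethod("show", "CTImage", function(object) {
  v <- object@values
  cat(sprintf("CTImage: %d x %d, pixel size %g, range [%.4g, %.4g]\n",
              nrow(v), ncol(v), object@pixelSize, min(v), max(v)))
})

setMethod("show", "SystemMatrix", function(object) {
  d <- dim(object)
  cat(sprintf(
    "SystemMatrix: %d rays x %d pixels, %d stored weights (%.2f%% dense)\n",
    d[1], d[2], length(object@weightsT@x),
    100 * length(object@weightsT@x) / prod(as.double(d))))
  if (length(object@zeroRows))
    cat(sprintf("  %d rays miss the grid\n", length(object@zeroRows)))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d views x %d detectors, range [%.4g, %.4g]\n",
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "ReconConfig", function(object) {
  cat(sprintf("ReconConfig: %s (kIter=%d, nTV=%d)\n",
              object@algorithm, object@kIter, object@nTV))
  cat(sprintf("  lambda: %s (fixed %g); step: %s (fixed %g); TV: %s\n",
              object@lambdaMode, object@lambdaFixed,
              object@stepMode, object@stepFixed, object@tvKind))
})

setMethod("show", "ReconResult", function(object) {
  k <- nrow(object@trace)
  cat(sprintf("ReconResult: %s, %d iteration(s), final res %.3e\n",
              object@config@algorithm, k,
              if (k) object@trace$res[k] else NA_real_))
  show(object@image)
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport: PSNR %.4f dB, SSIM %.4f, RMSE %.4g\n",
              object@psnr, object@ssim, object@rmse))
})
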