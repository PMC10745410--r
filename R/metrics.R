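#' @include regularizers.R
NULL

.metricPair <- function(reference, test) {
  r <- if (is(reference, "CTImage")) reference@values else as.matrix(reference)
  t <- if (is(test, "CTImage")) test@values else as.matrix(test)
  if (!identical(dim(r), dim(t)))
    stop("reference and test images must have the same dimensions")
  list(r = r, t = t)
}

#' Peak signal-to-noise ratio
#'
#' \deqn{PSNR = 10 \log_{10}\left(\frac{\mathrm{peak}^2}{MSE}\right)} in dB,
#' with the mean squared error taken over all pixels.  By default the peak
#' is the maximum of the reference image (standard practice); `peak =
#' "test"` uses the reconstructed image's maximum instead.  Identical
#' images give `Inf` (zero MSE).
#'
#' @param reference ground-truth image ([CTImage-class] or matrix).
#' @param test reconstructed image, same shape.
#' @param peak `"reference"` (default) or `"test"`.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(reference, test, peak = c("reference", "test")) {
  peak <- match.arg(peak)
  im <- .metricPair(reference, test)
  pk <- if (peak == "reference") max(im$r) else max(im$t)
  if (!(pk > 0)) stop("peak value must be positive")
  mse <- mean((im$r - im$t)^2)
  if (mse == 0) return(Inf)
  10 * log10(pk^2 / mse)
}

#' Root-mean-square error
#'
#' @inheritParams psnr
#' @return `sqrt(mean((reference - test)^2))`.
#' @export
rmse <- function(reference, test) {
  im <- .metricPair(reference, test)
  sqrt(mean((im$r - im$t)^2))
}

# truncated, normalised 1-D Gaussian (11 taps for sigma 1.5), the standard
# SSIM window
.ssimKernel <- function(sigma = 1.5, radius = 5L) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Structural similarity index
#'
#' Two modes are provided.  `"windowed"` (default) is the standard local
#' SSIM: means, variances and the cross-covariance are computed under an
#' 11 x 11 Gaussian window (sigma 1.5) with replicate edge padding,
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, and the per-pixel map is averaged.
#' `"global"` evaluates a single global index from whole-image means and
#' standard deviations,
#' \deqn{\frac{(2\mu_O\mu_R + C_1)(2\sigma_O\sigma_R + C_2)}
#'   {(\mu_O^2 + \mu_R^2 + C_1)(\sigma_O^2 + \sigma_R^2 + C_2)},}
#' which omits the cross-covariance (it cannot detect sign-flipped
#' structure) and is kept for comparison.
#'
#' @inheritParams psnr
#' @param mode `"windowed"` (default) or `"global"`.
#' @param dataRange dynamic range L; default `max(reference) -
#'   min(reference)` (1 if the reference is constant).
#' @param crop drop a filter-radius (5 pixel) border of the SSIM map before
#'   averaging, as scikit-image does; the default `FALSE` averages the full
#'   map (the MATLAB convention).
#' @return SSIM value in [-1, 1]; 1 for identical images.
#' @export
ssim <- function(reference, test, mode = c("windowed", "global"),
                 dataRange = NULL, crop = FALSE) {
  mode <- match.arg(mode)
  im <- .metricPair(reference, test)
  if (is.null(dataRange)) {
    dataRange <- max(im$r) - min(im$r)
    if (dataRange == 0) dataRange <- 1
  }
  c1 <- (0.01 * dataRange)^2
  c2 <- (0.03 * dataRange)^2
  if (mode == "global") {
    muO <- mean(im$r); muR <- mean(im$t)
    sdO <- sqrt(mean((im$r - muO)^2)); sdR <- sqrt(mean((im$t - muR)^2))
    return(((2 * muO * muR + c1) * (2 * sdO * sdR + c2)) /
             ((muO^2 + muR^2 + c1) * (sdO^2 + sdR^2 + c2)))
  }
  k <- .ssimKernel()
  muO <- .cpp_sepconv_replicate(im$r, k)
  muR <- .cpp_sepconv_replicate(im$t, k)
  sOO <- .cpp_sepconv_replicate(im$r * im$r, k) - muO^2
  sRR <- .cpp_sepconv_replicate(im$t * im$t, k) - muR^2
  sOR <- .cpp_sepconv_replicate(im$r * im$t, k) - muO * muR
  map <- ((2 * muO * muR + c1) * (2 * sOR + c2)) /
         ((muO^2 + muR^2 + c1) * (sOO + sRR + c2))
  if (crop) {
    rad <- (length(k) - 1L) %/% 2L
    map <- map[(rad + 1L):(nrow(map) - rad), (rad + 1L):(ncol(map) - rad),
               drop = FALSE]
  }
  mean(map)
}

#' Full image-quality report
#'
#' Computes PSNR, windowed SSIM and RMSE between a reference and a test
#' image and records the SSIM constants and whole-image statistics used.
#'
#' @inheritParams psnr
#' @param dataRange forwarded to [ssim()].
#' @return A [QualityReport-class].
#' @export
qualityReport <- function(reference, test, dataRange = NULL) {
  im <- .metricPair(reference, test)
  dr <- if (is.null(dataRange)) {
    d <- max(im$r) - min(im$r); if (d == 0) 1 else d
  } else dataRange
  new("QualityReport",
      psnr = psnr(reference, test),
      ssim = ssim(reference, test, dataRange = dr),
      rmse = rmse(reference, test),
      c1 = (0.01 * dr)^2, c2 = (0.03 * dr)^2,
      refStats = c(mean = mean(im$r), sd = stats::sd(as.vector(im$r))),
      testStats = c(mean = mean(im$t), sd = stats::sd(as.vector(im$t))))
}
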