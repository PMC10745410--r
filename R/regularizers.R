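#' @include io.R
NULL

.tvMatrix <- function(image) {
  v <- if (is(image, "CTImage")) image@values else as.matrix(image)
  if (nrow(v) < 2 || ncol(v) < 2)
    stop("TV functionals need an image of at least 2 x 2 pixels")
  storage.mode(v) <- "double"
  v
}

#' Four-direction total variation
#'
#' `fdtvValue()` evaluates the four-direction TV functional
#' \deqn{\|F\|_{TV} = \sum_{i,j} \mu_{i,j}, \quad
#'   \mu_{i,j} = \sqrt{\frac{d_v^2 + d_h^2 + d_{d1}^2 + d_{d2}^2}
#'   {2\Delta^2} + \varepsilon^2}}
#' where \eqn{d_v, d_h} are the backward vertical/horizontal differences and
#' \eqn{d_{d1}, d_{d2}} the two backward diagonal differences of pixel
#' (i, j); out-of-range neighbours contribute a zero difference.
#' `fdtvGradient()` returns its gradient field.  The default `"analytic"`
#' form differentiates the functional exactly (including the diagonal
#' terms), so it matches central finite differences of `fdtvValue()`; the
#' `"printed"` form is a literal horizontal/vertical five-point stencil
#' divided by the four-direction magnitudes, kept for comparison runs.
#'
#' @param image a [CTImage-class] or numeric matrix, at least 2 x 2.
#' @param config a [TVConfig-class]; default `tvConfig()`
#'   (\eqn{\varepsilon = 10^{-8}}, \eqn{\Delta = 1}).
#' @param form `"analytic"` (default) or `"printed"`.
#' @return `fdtvValue`: a scalar; `fdtvGradient`: a matrix the shape of the
#'   image.
#' @examples
#' f <- imageValues(makeFixture("disk", 16))
#' fdtvValue(f)
#' range(fdtvGradient(f))
#' @export
fdtvValue <- function(image, config = tvConfig()) {
  .cpp_tv_value(.tvMatrix(image), config@epsilon, config@delta, TRUE)
}

#' @rdname fdtvValue
#' @export
fdtvGradient <- function(image, config = tvConfig(),
                         form = c("analytic", "printed")) {
  form <- match.arg(form)
  v <- .tvMatrix(image)
  if (form == "analytic")
    .cpp_tv_gradient(v, config@epsilon, config@delta, TRUE)
  else
    .cpp_tv_gradient_printed(v, config@epsilon, config@delta)
}

#' Conventional two-direction total variation
#'
#' Baseline TV with per-pixel magnitude built from the backward vertical and
#' horizontal differences only, under the same \eqn{1/(2\Delta^2)}
#' normalisation and \eqn{\varepsilon} guard as [fdtvValue()] (so the
#' four-direction functional dominates it by construction).
#'
#' @inheritParams fdtvValue
#' @return `tv2Value`: a scalar; `tv2Gradient`: a gradient matrix matching
#'   finite differences of `tv2Value`.
#' @export
tv2Value <- function(image, config = tvConfig()) {
  .cpp_tv_value(.tvMatrix(image), config@epsilon, config@delta, FALSE)
}

#' @rdname tv2Value
#' @export
tv2Gradient <- function(image, config = tvConfig()) {
  .cpp_tv_gradient(.tvMatrix(image), config@epsilon, config@delta, FALSE)
}
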