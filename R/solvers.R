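#' @include metrics.R
NULL

#' Data-driven per-view SART relaxation
#'
#' Sets one relaxation parameter per view from the share of the total
#' projection mass that the view carries:
#' \deqn{\lambda_\phi = \exp\left(-\sum_{p_i \in P_\phi} p_i \Big/
#'   \sum_{i=1}^{M} p_i\right),}
#' so every \eqn{\lambda_\phi \in (0, 1]}, and sparser samplings (each view
#' carrying a larger share) get smaller relaxation.  Negative projection
#' values are clipped to zero with a warning before the sums are formed.
#'
#' @param sino a [Sinogram-class].
#' @return Numeric vector of length `nViews(sino)` with values in (0, 1].
#' @examples
#' g <- makeParallelGeometry(30, 8)
#' s <- sinogram(matrix(1, 30, 8), g)
#' adaptiveRelaxation(s)[1]   # exp(-1/30)
#' @export
adaptiveRelaxation <- function(sino) {
  stopifnot(is(sino, "Sinogram"))
  v <- sino@values
  if (any(v < 0)) {
    warning("negative projection values clipped to zero")
    v[v < 0] <- 0
  }
  total <- sum(v)
  if (!(total > 0))
    stop("adaptive relaxation is undefined for an all-zero sinogram")
  exp(-rowSums(v) / total)
}

.lambdaVector <- function(config, sino) {
  if (config@lambdaMode == "adaptive") {
    # an all-zero sinogram leaves the zero image fixed for any relaxation;
    # use 1 so the run degenerates gracefully instead of erroring
    if (sum(pmax(sino@values, 0)) == 0) rep(1, sino@geometry@nViews)
    else adaptiveRelaxation(sino)
  } else rep(config@lambdaFixed, sino@geometry@nViews)
}

#' One SART sweep over all views
#'
#' Performs one full pass over the views in ascending angle order.  For view
#' \eqn{\phi} every pixel j is updated simultaneously by
#' \deqn{f_j \leftarrow f_j + \lambda_\phi
#'   \frac{\sum_{p_i \in P_\phi} \frac{p_i - \sum_n w_{in} f_n}
#'   {\sum_n w_{in}} w_{ij}}{\sum_{p_i \in P_\phi} w_{ij}}.}
#' Rays with zero row sum (missing the grid) are skipped and pixels with a
#' zero per-view column sum are untouched for that view.  Negative pixels
#' are set to zero after the full pass (`nonneg = "sweep"`, the default) or
#' after every view (`"view"`).
#'
#' @param image current estimate ([CTImage-class] or matrix).
#' @param matrix the [SystemMatrix-class].
#' @param sino the measured [Sinogram-class].
#' @param lambdas per-view relaxation parameters (length `nViews`), or a
#'   single value recycled to all views.
#' @param nonneg `"sweep"` (default), `"view"` or `"none"`.
#' @return The updated [CTImage-class].
#' @export
sartSweep <- function(image, matrix, sino, lambdas,
                      nonneg = c("sweep", "view", "none")) {
  nonneg <- match.arg(nonneg)
  stopifnot(is(matrix, "SystemMatrix"))
  f <- .imageVector(image, matrix)
  p <- .sinoVector(sino)
  if (any(is.na(f)) || any(is.na(p)))
    stop("NaN/NA in image or sinogram")
  g <- matrix@geometry
  if (length(lambdas) == 1L) lambdas <- rep(lambdas, g@nViews)
  stopifnot(length(lambdas) == g@nViews)
  st <- .csrState(matrix)
  f1 <- .cpp_sart_sweep(st$rowPtr, st$colInd, st$vals, f, p,
                        matrix@rowSums, as.numeric(lambdas), st$viewColSums,
                        g@nDetectors, g@nViews,
                        nonneg == "view", nonneg == "sweep")
  ctImage(base::matrix(f1, nrow = matrix@imageDim[1]), matrix@pixelSize)
}

#' Adaptive TV descent step
#'
#' The steepest-descent step for iteration k is tied to the image change
#' produced by the POCS stage:
#' \deqn{\eta_k = \Delta d(1) \frac{\Delta d(k)}{\sum_{j=1}^{k} \Delta d(j)}}
#' so the schedule starts at \eqn{\Delta d(1)}, never exceeds it, and decays
#' towards zero as the POCS updates shrink.
#'
#' @param deltaHistory numeric vector `Delta d(1..k)` of POCS image changes
#'   up to the current iteration (non-negative, first entry positive).
#' @return The step \eqn{\eta_k} (0 when the cumulative sum is zero).
#' @examples
#' adaptiveStep(5)            # 5: first iteration returns Delta d(1)
#' adaptiveStep(c(2, 1))      # 2 * 1 / 3
#' @export
adaptiveStep <- function(deltaHistory) {
  if (length(deltaHistory) == 0L) stop("empty step history")
  if (any(deltaHistory < 0)) stop("step history must be non-negative")
  if (!(deltaHistory[1] > 0)) stop("Delta d(1) must be positive")
  s <- sum(deltaHistory)
  if (s == 0) return(0)
  deltaHistory[1] * deltaHistory[length(deltaHistory)] / s
}

#' TV steepest-descent steps
#'
#' Performs `nSteps` normalised steepest-descent updates
#' \eqn{F \leftarrow F - \eta\, G / \|G\|} on the chosen TV functional,
#' where \eqn{G} is the TV gradient and \eqn{\|G\|} its L2 (Frobenius) norm
#' over all pixels.  Steps with \eqn{\|G\| < 10^{-15}} are skipped.
#'
#' @param image starting image ([CTImage-class] or matrix).
#' @param eta step size (>= 0).
#' @param nSteps number of descent steps (>= 0).
#' @param tvKind `"four_direction"` (default) or `"two_direction"`.
#' @param config a [TVConfig-class].
#' @param form gradient form, see [fdtvGradient()].
#' @return The descended [CTImage-class] (or matrix, matching the input).
#' @export
tvDescent <- function(image, eta, nSteps,
                      tvKind = c("four_direction", "two_direction"),
                      config = tvConfig(), form = c("analytic", "printed")) {
  tvKind <- match.arg(tvKind)
  form <- match.arg(form)
  stopifnot(eta >= 0, nSteps >= 0)
  isCT <- is(image, "CTImage")
  v <- if (isCT) image@values else as.matrix(image)
  four <- tvKind == "four_direction"
  for (n in seq_len(nSteps)) {
    g <- if (form == "printed" && four)
      .cpp_tv_gradient_printed(v, config@epsilon, config@delta)
    else
      .cpp_tv_gradient(v, config@epsilon, config@delta, four)
    nrm <- sqrt(sum(g * g))
    if (nrm < 1e-15) next
    v <- v - (eta / nrm) * g
  }
  if (isCT) ctImage(v, image@pixelSize) else v
}

#' Per-pixel iterate change (stopping criterion)
#'
#' \deqn{res = \frac{1}{N} \|F^{(k)} - F^{(k-1)}\|_2} with N the pixel
#' count; the main loop stops when this falls below the configured
#' tolerance.
#'
#' @param imageK,imageKm1 images of identical shape.
#' @return Non-negative scalar.
#' @export
residualNorm <- function(imageK, imageKm1) {
  a <- if (is(imageK, "CTImage")) imageK@values else as.matrix(imageK)
  b <- if (is(imageKm1, "CTImage")) imageKm1@values else as.matrix(imageKm1)
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  sqrt(sum((a - b)^2)) / length(a)
}

# ---- main loop ------------------------------------------------------------

.traceRow <- function(k, deltaD, eta, res, f, refValues, dataRange) {
  row <- data.frame(k = k, delta_d = deltaD, eta = eta, res = res)
  if (!is.null(refValues)) {
    row$psnr <- psnr(refValues, f)
    row$ssim <- ssim(refValues, f, dataRange = dataRange)
    row$rmse <- rmse(refValues, f)
  }
  row
}

#' @rdname reconstruct
setMethod("reconstruct", "Sinogram",
  function(sinogram, matrix, config = reconConfig(), reference = NULL,
           verbose = FALSE) {
    stopifnot(is(matrix, "SystemMatrix"), is(config, "ReconConfig"))
    validObject(config)
    if (config@algorithm == "ASD_POCS")
      return(asdPocs(sinogram, matrix, config, reference, verbose))

    g <- matrix@geometry
    refValues <- if (is.null(reference)) NULL
      else .metricPair(reference, base::matrix(0, matrix@imageDim[1],
                                               matrix@imageDim[2]))$r
    dataRange <- if (is.null(refValues)) NULL else {
      d <- max(refValues) - min(refValues); if (d == 0) 1 else d
    }
    lambdas <- .lambdaVector(config, sinogram)
    p <- .sinoVector(sinogram)
    st <- .csrState(matrix)
    N <- prod(matrix@imageDim)
    fPrev <- numeric(N)
    deltaD <- numeric(0)
    rows <- vector("list", config@kIter)
    runTV <- config@algorithm != "SART" && config@nTV > 0L

    for (k in seq_len(config@kIter)) {
      fSart <- .cpp_sart_sweep(st$rowPtr, st$colInd, st$vals, fPrev, p,
                               matrix@rowSums, lambdas, st$viewColSums,
                               g@nDetectors, g@nViews,
                               config@nonneg == "view",
                               config@nonneg == "sweep")
      deltaD[k] <- sqrt(sum((fSart - fPrev)^2))
      if (runTV) {
        eta <- if (config@stepMode == "adaptive") {
          # a fixed point of the POCS stage (e.g. zero data) needs no TV step
          if (deltaD[1] == 0) 0 else adaptiveStep(deltaD)
        } else config@stepFixed
        fK <- tvDescent(base::matrix(fSart, nrow = matrix@imageDim[1]),
                        eta, config@nTV, config@tvKind, config@tv,
                        config@gradientForm)
        fK <- as.vector(fK)
      } else {
        eta <- NA_real_
        fK <- fSart
      }
      res <- sqrt(sum((fK - fPrev)^2)) / N
      fImg <- base::matrix(fK, nrow = matrix@imageDim[1])
      rows[[k]] <- .traceRow(k, deltaD[k], eta, res, fImg,
                             refValues, dataRange)
      if (verbose)
        message(sprintf("iter %3d: delta_d %.4e eta %.4e res %.4e",
                        k, deltaD[k], eta, res))
      fPrev <- fK
      if (res < config@resTol) break
    }
    trace <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    # final projection onto the non-negativity constraint set: the TV stage
    # runs after the in-loop positivity step and may leave tiny negative
    # excursions
    new("ReconResult",
        image = ctImage(base::matrix(pmax(fPrev, 0),
                                     nrow = matrix@imageDim[1]),
                        matrix@pixelSize),
        trace = trace, lambdaPerView = lambdas, config = config)
  })

#' Classical ASD-POCS baseline
#'
#' Adaptive-steepest-descent POCS with the published control scheme: the
#' POCS stage is a SART sweep with relaxation `beta` reduced by `betaRed`
#' every iteration; the TV stage runs `ng` normalised descent steps with a
#' step `dtvg` initialised to `alpha * dp` on the first iteration (dp is the
#' POCS-induced image change) and multiplied by `alphaRed` whenever the TV
#' change exceeds `rMax * dp`.  The step sequence is non-increasing by
#' construction.  This method is external to the adaptive FDTV scheme and is
#' included as a comparison baseline; its TV kind follows
#' `config@tvKind` (two-direction by default for `ASD_POCS`).
#'
#' @inheritParams reconstruct
#' @return A [ReconResult-class] (same contract as [reconstruct()]).
#' @export
asdPocs <- function(sinogram, matrix, config = reconConfig("ASD_POCS"),
                    reference = NULL, verbose = FALSE) {
  stopifnot(is(sinogram, "Sinogram"), is(matrix, "SystemMatrix"))
  g <- matrix@geometry
  a <- config@asd
  refValues <- if (is.null(reference)) NULL
    else .metricPair(reference, base::matrix(0, matrix@imageDim[1],
                                             matrix@imageDim[2]))$r
  dataRange <- if (is.null(refValues)) NULL else {
    d <- max(refValues) - min(refValues); if (d == 0) 1 else d
  }
  p <- .sinoVector(sinogram)
  st <- .csrState(matrix)
  N <- prod(matrix@imageDim)
  beta <- a$beta
  dtvg <- NA_real_
  fPrev <- numeric(N)
  rows <- vector("list", config@kIter)
  for (k in seq_len(config@kIter)) {
    fPocs <- .cpp_sart_sweep(st$rowPtr, st$colInd, st$vals, fPrev, p,
                             matrix@rowSums, rep(beta, g@nViews),
                             st$viewColSums, g@nDetectors, g@nViews,
                             FALSE, TRUE)
    dp <- sqrt(sum((fPocs - fPrev)^2))
    if (k == 1L) dtvg <- a$alpha * dp
    fTv <- as.vector(tvDescent(base::matrix(fPocs,
                                            nrow = matrix@imageDim[1]),
                               dtvg, a$ng, config@tvKind, config@tv))
    dg <- sqrt(sum((fTv - fPocs)^2))
    if (dg > a$rMax * dp && dp > 1e-15) dtvg <- dtvg * a$alphaRed
    res <- sqrt(sum((fTv - fPrev)^2)) / N
    fImg <- base::matrix(fTv, nrow = matrix@imageDim[1])
    rows[[k]] <- .traceRow(k, dp, dtvg, res, fImg, refValues, dataRange)
    if (verbose)
      message(sprintf("iter %3d: dp %.4e dtvg %.4e res %.4e",
                      k, dp, dtvg, res))
    fPrev <- fTv
    beta <- beta * a$betaRed
    if (res < config@resTol) break
  }
  trace <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  new("ReconResult",
      image = ctImage(base::matrix(pmax(fPrev, 0),
                                   nrow = matrix@imageDim[1]),
                      matrix@pixelSize),
      trace = trace, lambdaPerView = rep(a$beta, g@nViews), config = config)
}

# CSR arrays of W (the CSC slots of t(W)) and dense per-view column sums
.csrState <- function(A) {
  g <- A@geometry
  list(rowPtr = A@weightsT@p, colInd = A@weightsT@i, vals = A@weightsT@x,
       viewColSums = .cpp_view_col_sums(A@weightsT@p, A@weightsT@i,
                                        A@weightsT@x, prod(A@imageDim),
                                        g@nDetectors, g@nViews))
}
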