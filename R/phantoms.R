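#' @include geometry.R
NULL

# Standard Shepp-Logan ellipse tables: columns intensity A, semi-axes a, b,
# centre (x0, y0) in [-1, 1]^2, rotation phi in degrees (counter-clockwise).
# "modified" is the widely used contrast-enhanced variant (max intensity 1);
# "original" keeps the historical low-contrast intensities.
.sheppLoganTable <- function(variant = c("modified", "original")) {
  variant <- match.arg(variant)
  geom <- matrix(c(
    0.6900, 0.9200,  0.00,  0.0000,   0,
    0.6624, 0.8740,  0.00, -0.0184,   0,
    0.1100, 0.3100,  0.22,  0.0000, -18,
    0.1600, 0.4100, -0.22,  0.0000,  18,
    0.2100, 0.2500,  0.00,  0.3500,   0,
    0.0460, 0.0460,  0.00,  0.1000,   0,
    0.0460, 0.0460,  0.00, -0.1000,   0,
    0.0460, 0.0230, -0.08, -0.6050,   0,
    0.0230, 0.0230,  0.00, -0.6060,   0,
    0.0230, 0.0460,  0.06, -0.6050,   0), ncol = 5, byrow = TRUE)
  A <- if (variant == "modified")
    c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  else
    c(2, -0.98, -0.02, -0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01)
  data.frame(A = A, a = geom[, 1], b = geom[, 2],
             x0 = geom[, 3], y0 = geom[, 4], phi = geom[, 5])
}

# additive intensity of the ellipse composite at points (x, y)
.ellipseSum <- function(x, y, table) {
  v <- numeric(length(x))
  for (e in seq_len(nrow(table))) {
    ph <- table$phi[e] * pi / 180
    dx <- x - table$x0[e]; dy <- y - table$y0[e]
    xr <- dx * cos(ph) + dy * sin(ph)
    yr <- -dx * sin(ph) + dy * cos(ph)
    inside <- (xr / table$a[e])^2 + (yr / table$b[e])^2 <= 1
    v[inside] <- v[inside] + table$A[e]
  }
  v
}

#' Shepp-Logan head phantom
#'
#' Analytic n x n rasterization of the standard 10-ellipse Shepp-Logan
#' phantom: each pixel takes the sum of the intensities of the ellipses
#' covering its centre (no anti-aliasing), clipped to be non-negative.
#' The default `"modified"` variant uses the widely published
#' contrast-enhanced intensities with maximum 1; `"original"` uses the
#' historical low-contrast values (maximum 2).
#'
#' @param n image side length (>= 8).
#' @param variant `"modified"` (default) or `"original"`.
#' @param pixelSize pixel edge length of the returned image (default 1).
#' @return A [CTImage-class], deterministic and non-negative.
#' @examples
#' ph <- sheppLogan(64)
#' range(imageValues(ph))
#' @export
sheppLogan <- function(n, variant = c("modified", "original"),
                       pixelSize = 1) {
  if (length(n) != 1L || !is.finite(n) || n < 8)
    stop("n must be a single integer >= 8")
  n <- as.integer(n)
  variant <- match.arg(variant)
  tab <- .sheppLoganTable(variant)
  # pixel centres: x along columns (left to right), y up; row 1 is the top
  xs <- (seq_len(n) - (n + 1) / 2) * (2 / n)
  ys <- ((n + 1) / 2 - seq_len(n)) * (2 / n)
  x <- rep(xs, each = n)       # column-major: row index varies fastest
  y <- rep(ys, times = n)
  v <- matrix(pmax(.ellipseSum(x, y, tab), 0), nrow = n)
  ctImage(v, pixelSize)
}

#' Analytic sinogram of the Shepp-Logan phantom
#'
#' Exact, noise-free parallel-beam projection data of the ellipse composite:
#' the line integral of a (rotated) ellipse with intensity A and semi-axes
#' (a, b) along a ray with signed perpendicular offset s from its centre is
#' \deqn{\frac{2ab}{\alpha^2}\sqrt{\alpha^2 - s^2}, \qquad
#'   \alpha^2 = a^2\sin^2\gamma + b^2\cos^2\gamma,}
#' (zero when \eqn{|s| \ge \alpha}), with \eqn{\gamma} the ray angle in the
#' ellipse frame; the sinogram is the sum over the ten ellipses.
#'
#' Simulating the data analytically, rather than multiplying the rasterized
#' phantom by the reconstruction system matrix, keeps the measurements
#' independent of the discrete image model (no "inverse crime"): the
#' residual inconsistency between exact line integrals and the pixel-grid
#' projector then plays the role that measurement imperfections play in real
#' scans, which is what makes the sparse-view comparison of regularizers
#' meaningful.  The benchmark protocol therefore uses this simulator;
#' [forwardProject()] gives the matrix-consistent alternative.
#'
#' @param geometry a [ScanGeometry-class].
#' @param n side length of the target reconstruction grid (defines the
#'   physical scale: the phantom's unit square spans the grid).
#' @param variant ellipse table variant, see [sheppLogan()].
#' @param pixelSize pixel edge length of the target grid (default 1).
#' @return A [Sinogram-class] with exact ellipse line integrals.
#' @examples
#' g <- makeParallelGeometry(30, 128)
#' s <- phantomSinogram(g, 64)
#' dim(s)
#' @export
phantomSinogram <- function(geometry, n, variant = c("modified", "original"),
                            pixelSize = 1) {
  stopifnot(is(geometry, "ScanGeometry"))
  variant <- match.arg(variant)
  tab <- .sheppLoganTable(variant)
  half <- n * pixelSize / 2
  off <- .detectorOffsets(geometry, n, pixelSize)
  vals <- matrix(0, geometry@nViews, geometry@nDetectors)
  for (v in seq_len(geometry@nViews)) {
    th <- geometry@angles[v] * pi / 180
    nx <- -sin(th); ny <- cos(th)
    for (e in seq_len(nrow(tab))) {
      a <- tab$a[e] * half; b <- tab$b[e] * half
      # phantom frame has y up, projector world has y down: flip centre y
      # and rotation sense
      cx <- tab$x0[e] * half; cy <- -tab$y0[e] * half
      phi <- -tab$phi[e] * pi / 180
      gamma <- th - phi
      al2 <- a^2 * sin(gamma)^2 + b^2 * cos(gamma)^2
      s <- off - (cx * nx + cy * ny)
      inside <- s^2 < al2
      vals[v, inside] <- vals[v, inside] +
        tab$A[e] * 2 * a * b * sqrt(al2 - s[inside]^2) / al2
    }
  }
  sinogram(vals, geometry)
}

#' Deterministic synthetic test images
#'
#' Small reproducible fixtures for unit tests and demonstrations:
#' `"disk"` is a binary disk of radius n/4 centred on the grid, `"squares"`
#' a set of nested squares with increasing intensity, and `"gradient"` a
#' smooth ramp strictly increasing along columns.  Optional i.i.d. Gaussian
#' noise (standard deviation `noise`) is seeded with `seed`; the global RNG
#' state is left untouched.
#'
#' @param kind `"disk"`, `"squares"` or `"gradient"`.
#' @param n image side length (>= 8).
#' @param seed integer seed for the optional noise.
#' @param noise standard deviation of added Gaussian noise (default 0:
#'   noiseless, fully deterministic pattern).
#' @param pixelSize pixel edge length (default 1).
#' @return A [CTImage-class]; identical arguments give bit-identical images.
#' @export
makeFixture <- function(kind = c("disk", "squares", "gradient"), n, seed = 0,
                        noise = 0, pixelSize = 1) {
  kind <- match.arg(kind)
  if (length(n) != 1L || !is.finite(n) || n < 8)
    stop("n must be a single integer >= 8")
  n <- as.integer(n)
  ctr <- (n + 1) / 2
  v <- switch(kind,
    disk = {
      d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
      matrix(as.numeric(d2 <= (n / 4)^2), n)
    },
    squares = {
      m <- matrix(0, n, n)
      for (w in c(0.45, 0.30, 0.15)) {
        half <- round(w * n / 2)
        i <- max(1, round(ctr - half)):min(n, round(ctr + half))
        m[i, i] <- m[i, i] + 0.3
      }
      m
    },
    gradient = matrix(rep(seq(0, 1, length.out = n), each = n), n)
  )
  if (noise > 0) {
    state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(state))
      assign(".Random.seed", state, envir = globalenv()))
    set.seed(as.integer(seed))
    v <- v + matrix(stats::rnorm(n * n, sd = noise), n)
  }
  ctImage(v, pixelSize)
}
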