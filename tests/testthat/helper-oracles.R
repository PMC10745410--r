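# Independent oracles used across the suite.  These deliberately avoid the
# package's computational paths: closed forms, dense linear algebra and
# literal per-pixel loops.

# chord length of the line o + t*d (|d| = 1) through the axis-aligned box
# [-w/2, w/2] x [-h/2, h/2], by Liang-Barsky slab clipping
chordLengthBox <- function(ox, oy, dx, dy, w, h) {
  t0 <- -Inf; t1 <- Inf
  for (s in list(c(ox, dx, w / 2), c(oy, dy, h / 2))) {
    o <- s[1]; d <- s[2]; half <- s[3]
    if (abs(d) < 1e-15) {
      if (o <= -half || o >= half) return(0)
    } else {
      ta <- (-half - o) / d; tb <- (half - o) / d
      lo <- min(ta, tb); hi <- max(ta, tb)
      t0 <- max(t0, lo); t1 <- min(t1, hi)
    }
  }
  max(t1 - t0, 0)
}

# literal per-pixel evaluation of the four-direction magnitude sum
fdtvByHand <- function(m, eps = 1e-8, delta = 1) {
  nr <- nrow(m); nc <- ncol(m)
  total <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    if (i > 1) s <- s + (m[i, j] - m[i - 1, j])^2
    if (j > 1) s <- s + (m[i, j] - m[i, j - 1])^2
    if (i > 1 && j > 1) s <- s + (m[i, j] - m[i - 1, j - 1])^2
    if (i > 1 && j < nc) s <- s + (m[i, j] - m[i - 1, j + 1])^2
    total <- total + sqrt(s / (2 * delta^2) + eps^2)
  }
  total
}

# literal dense-matrix SART sweep: sequential views, simultaneous pixel
# update per view, non-negativity after the full pass
denseSartSweep <- function(W, f, p, lambdas, nDet, nViews) {
  for (v in seq_len(nViews)) {
    rows <- ((v - 1) * nDet + 1):(v * nDet)
    num <- numeric(length(f))
    colSum <- colSums(W[rows, , drop = FALSE])
    for (r in rows) {
      w <- W[r, ]
      rs <- sum(w)
      if (rs <= 0) next
      c <- (p[r] - sum(w * f)) / rs
      num <- num + c * w
    }
    upd <- colSum > 0
    f[upd] <- f[upd] + lambdas[v] * num[upd] / colSum[upd]
  }
  pmax(f, 0)
}

# analytic ellipse-composite value at a single point, straight off the table
ellipseSumAt <- function(x, y, table) {
  v <- 0
  for (e in seq_len(nrow(table))) {
    ph <- table$phi[e] * pi / 180
    dx <- x - table$x0[e]; dy <- y - table$y0[e]
    xr <- dx * cos(ph) + dy * sin(ph)
    yr <- -dx * sin(ph) + dy * cos(ph)
    if ((xr / table$a[e])^2 + (yr / table$b[e])^2 <= 1) v <- v + table$A[e]
  }
  v
}

# small consistent test problem shared by solver tests
makeTestProblem <- function(n = 64, views = 30, dets = 128) {
  ph <- sheppLogan(n)
  g <- makeParallelGeometry(views, dets)
  A <- buildSystemMatrix(g, ph)
  list(phantom = ph, geometry = g, matrix = A,
       sino = forwardProject(A, ph))
}
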