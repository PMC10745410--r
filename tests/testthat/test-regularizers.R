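test_that("TV functionals hit their closed forms on simple images", {
  eps <- 1e-8
  # constant image: every per-pixel magnitude collapses to epsilon
  for (dims in list(c(2, 2), c(5, 9))) {
    cst <- matrix(3.7, dims[1], dims[2])
    expect_equal(fdtvValue(cst), prod(dims) * eps, tolerance = 1e-15)
    expect_equal(tv2Value(cst), prod(dims) * eps, tolerance = 1e-15)
    expect_equal(fdtvGradient(cst), matrix(0, dims[1], dims[2]))
    expect_equal(tv2Gradient(cst), matrix(0, dims[1], dims[2]))
  }

  # 2x2 step image, evaluated per pixel by hand
  m <- matrix(c(0, 0, 1, 1), 2, 2)  # [[0,1],[0,1]]
  expected <- eps +                  # (1,1): no in-range differences
    sqrt(1 / 2 + eps^2) +            # (1,2): horizontal step
    sqrt(1 / 2 + eps^2) +            # (2,1): anti-diagonal step to (1,2)
    sqrt((1 + 1) / 2 + eps^2)        # (2,2): horizontal + diagonal steps
  expect_equal(fdtvValue(m), expected, tolerance = 1e-14)
  expect_equal(fdtvValue(m), fdtvByHand(m), tolerance = 1e-14)

  # positive homogeneity in the vanishing-epsilon limit
  set.seed(5)
  f <- matrix(runif(100), 10)
  cfg0 <- tvConfig(epsilon = 1e-15)
  expect_equal(fdtvValue(2 * f, cfg0) / fdtvValue(f, cfg0), 2,
               tolerance = 1e-9)

  expect_error(fdtvValue(matrix(1, 1, 5)), "2 x 2")
})

test_that("analytic gradients match central finite differences", {
  set.seed(7)
  f <- matrix(runif(64), 8, 8)
  h <- 1e-6
  for (eps in c(1e-2, 1e-8)) {
    cfg <- tvConfig(epsilon = eps)
    for (kind in c("fdtv", "tv2")) {
      val <- switch(kind, fdtv = function(x) fdtvValue(x, cfg),
                    tv2 = function(x) tv2Value(x, cfg))
      g <- switch(kind, fdtv = fdtvGradient(f, cfg),
                  tv2 = tv2Gradient(f, cfg))
      for (idx in list(c(1, 1), c(1, 8), c(8, 1), c(4, 5), c(8, 8),
                       c(2, 7), c(5, 2))) {
        i <- idx[1]; j <- idx[2]
        fp <- f; fp[i, j] <- fp[i, j] + h
        fm <- f; fm[i, j] <- fm[i, j] - h
        fd <- (val(fp) - val(fm)) / (2 * h)
        expect_equal(g[i, j], fd, tolerance = 1e-5)
      }
    }
  }
})

test_that("TV invariants hold across random images", {
  set.seed(21)
  cfgTiny <- tvConfig(epsilon = 1e-15)
  for (rep in 1:100) {
    f <- matrix(rnorm(64), 8)
    # the four-direction functional dominates the two-direction one
    expect_gte(fdtvValue(f, cfgTiny), tv2Value(f, cfgTiny))
  }
  f <- matrix(rnorm(144), 12)
  # translation invariance is exact
  expect_identical(fdtvValue(f + 5), fdtvValue(f))
  expect_identical(tv2Value(f - 2), tv2Value(f))
  # hence the gradient components sum to zero
  expect_equal(sum(fdtvGradient(f)), 0, tolerance = 1e-10)
  expect_equal(sum(tv2Gradient(f)), 0, tolerance = 1e-10)
  # lower bound n*m*epsilon
  expect_gte(fdtvValue(f), 144 * 1e-8)
})

test_that("the literal printed gradient stencil is available and distinct", {
  set.seed(3)
  f <- matrix(runif(64), 8)
  gA <- fdtvGradient(f)
  gP <- fdtvGradient(f, form = "printed")
  expect_equal(dim(gP), dim(f))
  expect_true(all(is.finite(gP)))
  expect_gt(max(abs(gA - gP)), 1e-3)  # genuinely different stencils
  # both vanish on constants
  expect_equal(fdtvGradient(matrix(1, 6, 6), form = "printed"),
               matrix(0, 6, 6))
})
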