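test_that("adaptive relaxation evaluates the projection-mass closed forms", {
  g30 <- makeParallelGeometry(30, 8)
  lam <- adaptiveRelaxation(sinogram(matrix(1, 30, 8), g30))
  expect_equal(lam, rep(exp(-1 / 30), 30), tolerance = 1e-12)

  g1 <- makeParallelGeometry(1, 8)
  expect_equal(adaptiveRelaxation(sinogram(matrix(2, 1, 8), g1)), exp(-1),
               tolerance = 1e-12)

  g2 <- makeParallelGeometry(2, 4)
  s2 <- sinogram(rbind(rep(0.25, 4), rep(0.75, 4)), g2)  # view sums 1, 3
  expect_equal(adaptiveRelaxation(s2), c(exp(-0.25), exp(-0.75)),
               tolerance = 1e-12)

  # always in (0, 1]
  s <- phantomSinogram(makeParallelGeometry(13, 64), 32)
  lamP <- adaptiveRelaxation(s)
  expect_true(all(lamP > 0 & lamP <= 1))

  neg <- sinogram(matrix(c(-1, rep(1, 7)), 2, 4), g2)
  expect_warning(adaptiveRelaxation(neg), "clipped")
  expect_error(adaptiveRelaxation(sinogram(matrix(0, 2, 4), g2)),
               "all-zero")
})

test_that("fewer views mean smaller relaxation parameters", {
  lam30 <- adaptiveRelaxation(phantomSinogram(makeParallelGeometry(30, 128), 64))
  lam90 <- adaptiveRelaxation(phantomSinogram(makeParallelGeometry(90, 128), 64))
  expect_lt(mean(lam30), mean(lam90))
})

test_that("a SART sweep solves the one-ray problem and matches the dense oracle", {
  # single ray through a single unit pixel: w = 1
  g <- makeParallelGeometry(1, 1, 180)
  A <- buildSystemMatrix(g, ctImage(matrix(0, 1, 1)))
  s <- sinogram(matrix(2, 1, 1), g)
  expect_equal(imageValues(sartSweep(matrix(0, 1, 1), A, s, 1))[1, 1], 2)
  expect_equal(imageValues(sartSweep(matrix(0, 1, 1), A, s, 0.5))[1, 1], 1)

  # 16x16 grid, 6 views: sweep equals the literal dense implementation
  prob <- makeTestProblem(n = 16, views = 6, dets = 24)
  set.seed(31)
  f0 <- matrix(runif(256), 16)
  lam <- runif(6, 0.3, 1)
  mine <- imageValues(sartSweep(f0, prob$matrix, prob$sino, lam))
  W <- as.matrix(sysWeights(prob$matrix))
  oracle <- denseSartSweep(W, as.vector(f0), as.vector(t(sinoValues(prob$sino))),
                           lam, 24, 6)
  expect_equal(as.vector(mine), oracle, tolerance = 1e-10)

  bad <- matrix(NaN, 16, 16)
  expect_error(sartSweep(bad, prob$matrix, prob$sino, 0.5), "NaN")
})

test_that("SART sweeps monotonically reduce the data residual on consistent data", {
  prob <- makeTestProblem(n = 64, views = 60, dets = 128)
  p <- sinoValues(prob$sino)
  f <- matrix(0, 64, 64)
  resid <- numeric(20)
  for (k in 1:20) {
    f <- imageValues(sartSweep(f, prob$matrix, prob$sino, 0.5))
    resid[k] <- sqrt(sum((sinoValues(forwardProject(prob$matrix, f)) - p)^2))
  }
  expect_true(all(diff(resid) < 0))
})

test_that("the adaptive step follows its closed forms", {
  expect_equal(adaptiveStep(5), 5)
  expect_equal(adaptiveStep(c(2, 1)), 2 / 3)
  for (k in c(2, 5, 17)) {
    expect_equal(adaptiveStep(rep(3, k)), 3 / k, tolerance = 1e-14)
  }
  # monotone in k for constant history
  etas <- vapply(1:10, function(k) adaptiveStep(rep(2, k)), numeric(1))
  expect_true(all(diff(etas) < 0))

  expect_error(adaptiveStep(numeric(0)), "empty")
  expect_error(adaptiveStep(c(-1, 2)), "non-negative")
  expect_error(adaptiveStep(c(0, 1)), "positive")
})

test_that("TV descent reduces the functional and respects degenerate inputs", {
  noisy <- imageValues(makeFixture("disk", 32, seed = 1, noise = 0.1))
  expect_identical(tvDescent(noisy, 0, 10), noisy)
  cst <- matrix(2, 16, 16)
  expect_equal(tvDescent(cst, 0.5, 10), cst)

  vals <- numeric(21)
  vals[1] <- fdtvValue(noisy)
  f <- noisy
  for (n in 1:20) {
    f <- tvDescent(f, 0.3, 1)
    vals[n + 1] <- fdtvValue(f)
  }
  expect_true(all(diff(vals) < 0))

  # the CTImage path preserves class and pixel size
  img <- makeFixture("disk", 16, seed = 2, noise = 0.05, pixelSize = 2)
  out <- tvDescent(img, 0.1, 3, tvKind = "two_direction")
  expect_s4_class(out, "CTImage")
  expect_equal(pixelSize(out), 2)
})

test_that("the stopping residual is the per-pixel L2 change", {
  a <- matrix(0, 16, 16)
  expect_equal(residualNorm(a, a), 0)
  expect_equal(residualNorm(a + 1, a), 1 / sqrt(256))
  b <- matrix(0, 256, 256)
  d <- b; d[100, 100] <- 1e-6
  expect_equal(residualNorm(d, b), 1e-6 / 65536, tolerance = 1e-20)
  expect_error(residualNorm(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("reconstruction on a zero sinogram stops immediately at zero", {
  prob <- makeTestProblem(n = 16, views = 4, dets = 24)
  z <- sinogram(matrix(0, 4, 24), prob$geometry)
  for (alg in c("SART", "ADAPTIVE_FDTV", "ASD_POCS")) {
    r <- reconstruct(z, prob$matrix, reconConfig(alg, kIter = 10))
    expect_equal(max(abs(imageValues(reconImage(r)))), 0)
    expect_equal(nrow(iterationTrace(r)), 1L)
    expect_equal(iterationTrace(r)$res[1], 0)
  }
})

test_that("noise-free SART converges on the scaled-down phantom", {
  prob <- makeTestProblem(n = 64, views = 90, dets = 128)
  r <- reconstruct(prob$sino, prob$matrix,
                   reconConfig("SART", kIter = 200), reference = prob$phantom)
  expect_lt(rmse(prob$phantom, reconImage(r)), 0.05)
  tr <- iterationTrace(r)
  expect_true(all(c("psnr", "ssim", "rmse") %in% names(tr)))
  # early iterations steadily reduce the error on consistent data
  expect_true(all(diff(tr$rmse[1:50]) < 0))
})

test_that("reconstructions are non-negative, deterministic and properly traced", {
  prob <- makeTestProblem(n = 32, views = 10, dets = 48)
  s <- phantomSinogram(prob$geometry, 32)
  for (alg in c("SART", "SART_TV", "SART_FDTV", "ADAPTIVE_FDTV", "ASD_POCS")) {
    r <- reconstruct(s, prob$matrix, reconConfig(alg, kIter = 15))
    expect_gte(min(imageValues(reconImage(r))), 0)
    expect_equal(nrow(iterationTrace(r)), 15L)
    r2 <- reconstruct(s, prob$matrix, reconConfig(alg, kIter = 15))
    expect_identical(imageValues(reconImage(r)), imageValues(reconImage(r2)))
    expect_identical(iterationTrace(r), iterationTrace(r2))
  }
})

test_that("the adaptive schedule starts at Delta d(1) and never exceeds it", {
  prob <- makeTestProblem(n = 32, views = 12, dets = 48)
  s <- phantomSinogram(prob$geometry, 32)
  r <- reconstruct(s, prob$matrix, reconConfig("ADAPTIVE_FDTV", kIter = 40))
  tr <- iterationTrace(r)
  expect_equal(tr$eta[1], tr$delta_d[1])
  expect_true(all(tr$eta <= tr$delta_d[1] + 1e-12))
  expect_equal(lambdaPerView(r),
               adaptiveRelaxation(s), tolerance = 1e-15)
})

test_that("ASD-POCS keeps a non-increasing TV step", {
  prob <- makeTestProblem(n = 32, views = 10, dets = 48)
  s <- phantomSinogram(prob$geometry, 32)
  r <- asdPocs(s, prob$matrix, reconConfig("ASD_POCS", kIter = 30))
  steps <- iterationTrace(r)$eta
  expect_true(all(diff(steps) <= 0))
  expect_gte(min(imageValues(reconImage(r))), 0)
})
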