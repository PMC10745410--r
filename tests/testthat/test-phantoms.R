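test_that("Shepp-Logan rasterization is deterministic, bounded and exact at pixel centres", {
  ph <- sheppLogan(256)
  v <- imageValues(ph)
  expect_equal(dim(v), c(256L, 256L))
  expect_gte(min(v), 0)
  expect_lte(max(v), 1)
  expect_identical(v, imageValues(sheppLogan(256)))

  # pixel values equal the analytic ellipse sum at the pixel centre
  tab <- fdtvct:::.sheppLoganTable("modified")
  v64 <- imageValues(sheppLogan(64))
  for (ij in list(c(33, 33), c(32, 32), c(10, 40), c(50, 20))) {
    i <- ij[1]; j <- ij[2]
    x <- (j - 65 / 2) * (2 / 64)
    y <- (65 / 2 - i) * (2 / 64)
    expect_equal(v64[i, j], max(ellipseSumAt(x, y, tab), 0),
                 tolerance = 1e-12)
  }

  # original variant keeps the historical intensities: skull 2, interior
  # brain 2 - 0.98 = 1.02
  orig <- imageValues(sheppLogan(64, variant = "original"))
  expect_equal(max(orig), 2)
  expect_equal(orig[33, 33], 1.02, tolerance = 1e-12)

  expect_error(sheppLogan(4), ">= 8")
})

test_that("fixtures are reproducible and have the advertised structure", {
  disk <- imageValues(makeFixture("disk", 32, 0))
  expect_setequal(unique(as.vector(disk)), c(0, 1))
  ctr <- (32 + 1) / 2
  d2 <- outer((seq_len(32) - ctr)^2, (seq_len(32) - ctr)^2, "+")
  expect_identical(disk, matrix(as.numeric(d2 <= 8^2), 32))

  grad <- imageValues(makeFixture("gradient", 16, 0))
  expect_true(all(diff(grad[8, ]) > 0))       # increasing along columns
  expect_true(all(grad[, 5] == grad[1, 5]))   # constant along rows

  expect_identical(imageValues(makeFixture("squares", 64, 1)),
                   imageValues(makeFixture("squares", 64, 1)))

  # seeded noise is reproducible and does not disturb the global RNG
  set.seed(99); before <- .Random.seed
  n1 <- imageValues(makeFixture("disk", 16, seed = 7, noise = 0.1))
  expect_identical(.Random.seed, before)
  n2 <- imageValues(makeFixture("disk", 16, seed = 7, noise = 0.1))
  expect_identical(n1, n2)

  expect_error(makeFixture("blob", 32, 0))
})

test_that("analytic phantom sinogram matches closed-form ellipse integrals", {
  g <- makeParallelGeometry(12, 256)
  s <- phantomSinogram(g, 64)
  expect_equal(dim(s), c(12L, 256L))
  v <- sinoValues(s)
  expect_gte(min(v), 0)

  # per-view mass: sum over detector bins x spacing approximates the
  # phantom's total integral sum_e A_e * pi * a_e * b_e (scaled), equally
  # for every view
  tab <- fdtvct:::.sheppLoganTable("modified")
  half <- 32
  mass <- sum(tab$A * pi * (tab$a * half) * (tab$b * half))
  spacing <- sqrt(2) * 64 / 256
  viewMass <- rowSums(v) * spacing
  expect_equal(viewMass, rep(mass, 12), tolerance = 1e-3)

  # stays close to the discrete projection of the rasterized phantom
  # (the gap is pure discretization error of the 64x64 grid)
  A <- buildSystemMatrix(g, sheppLogan(64))
  d <- sinoValues(forwardProject(A, sheppLogan(64)))
  expect_lt(sqrt(sum((v - d)^2) / sum(d^2)), 0.10)
})

test_that("image files round-trip", {
  m <- matrix(runif(64 * 64), 64)
  p <- tempfile(fileext = ".npy")
  writeNpy(m, p)
  expect_identical(readNpy(p), m)
  img <- loadImage(p, pixelSize = 1.1667)
  expect_identical(imageValues(img), m)
  expect_equal(pixelSize(img), 1.1667)
  unlink(p)

  # 8-bit PNG of constant full intensity loads as constant 1.0
  p2 <- tempfile(fileext = ".png")
  png::writePNG(matrix(1, 16, 16), p2)
  expect_equal(imageValues(loadImage(p2)), matrix(1, 16, 16))
  unlink(p2)

  # a hand-built fortran-order NPY reads back correctly
  p3 <- tempfile(fileext = ".npy")
  con <- file(p3, "wb")
  header <- "{'descr': '<f8', 'fortran_order': True, 'shape': (3, 2), }"
  pad <- 64 - ((10 + nchar(header) + 1) %% 64)
  header <- paste0(header, strrep(" ", pad %% 64), "\n")
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(nchar(header), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  mm <- matrix(as.numeric(1:6), 3, 2)
  writeBin(as.vector(mm), con, size = 8, endian = "little")
  close(con)
  expect_identical(readNpy(p3), mm)
  unlink(p3)

  expect_error(loadImage(tempfile(fileext = ".npy")), "cannot read")
  expect_error(readNpy(tempfile()), "cannot read")
})
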