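#' @include phantoms.R
NULL

# ---- minimal NPY v1.0 support for 2-D double arrays -----------------------
# Layout follows the NPY format description: magic, version 1.0, little-
# endian uint16 header length, python-dict header padded to a multiple of
# 64 bytes, then raw data.  Only what the package needs: <f8/<f4 2-D arrays,
# C or Fortran order on read; C order, <f8 on write (bit-exact round trips).

#' Read / write NPY arrays
#'
#' Minimal NPY (version 1.0) support for 2-D numeric arrays: `writeNpy()`
#' stores a double matrix in C (row-major) order, `readNpy()` reads
#' `<f8`/`<f4` arrays in either storage order.  A write/read round trip is
#' bit-exact for double matrices.
#'
#' @param path file path.
#' @param x numeric matrix.
#' @return `readNpy()`: a numeric matrix; `writeNpy()`: `path`, invisibly.
#' @export
readNpy <- function(path) {
  if (!file.exists(path)) stop("cannot read NPY file: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file: ", path)
  ver <- readBin(con, "raw", 2)
  hlen <- if (ver[1] == as.raw(1)) {
    readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  } else {
    readBin(con, "integer", 1, size = 4, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- regmatches(header,
    regexpr("'descr':\\s*'[^']+'", header))
  descr <- sub(".*'([^']+)'$", "\\1", descr)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shp <- regmatches(header, regexpr("'shape':\\s*\\(([^)]*)\\)", header))
  dims <- as.integer(strsplit(gsub("[^0-9,]", "", shp), ",")[[1]])
  if (length(dims) == 1L) dims <- c(dims, 1L)
  if (length(dims) != 2L)
    stop("only 1-D/2-D NPY arrays are supported: ", path)
  size <- switch(descr, "<f8" = 8L, "<f4" = 4L,
                 stop("unsupported NPY dtype '", descr, "' in ", path))
  n <- prod(dims)
  vals <- readBin(con, "numeric", n, size = size, endian = "little")
  if (fortran) matrix(vals, nrow = dims[1])
  else t(matrix(vals, nrow = dims[2]))
}

#' @rdname readNpy
#' @export
writeNpy <- function(x, path) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(x), ncol(x))
  # total header block (magic 6 + version 2 + len 2 + dict + newline) must be
  # a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(nchar(header), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.vector(t(x)), con, size = 8, endian = "little")
  invisible(path)
}

# ---- raster image I/O -----------------------------------------------------

#' Load a grayscale raster image as a CT image
#'
#' Reads PNG, TIFF or NPY files.  PNG/TIFF values arrive scaled to [0, 1]
#' (multi-channel images are averaged to grayscale); NPY arrays are read
#' verbatim.  With `raw = FALSE` (default) PNG/TIFF data are kept on the
#' [0, 1] scale; NPY data are never rescaled, so NPY round trips are
#' bit-exact.
#'
#' @param path file path; format is chosen by extension
#'   (`.png`, `.tif`/`.tiff`, `.npy`).
#' @param pixelSize pixel edge length to attach (default 1).
#' @param raw logical; reserved to skip any rescaling (PNG/TIFF readers
#'   already deliver [0, 1]).
#' @return A [CTImage-class].
#' @export
loadImage <- function(path, pixelSize = 1, raw = FALSE) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  v <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    npy = readNpy(path),
    stop("unsupported image format '", ext, "': ", path))
  if (length(dim(v)) == 3L) v <- apply(v, c(1, 2), mean)
  if (length(dim(v)) != 2L) stop("not a 2-D grayscale image: ", path)
  ctImage(v, pixelSize)
}

#' Save a CT image
#'
#' `.npy` stores the raw double values (bit-exact); `.png`/`.tif` write an
#' 8-/16-bit preview with values clipped to [0, 1].
#'
#' @param image a [CTImage-class] or numeric matrix.
#' @param path destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
saveImage <- function(image, path) {
  v <- if (is(image, "CTImage")) image@values else as.matrix(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    npy = writeNpy(v, path),
    png = png::writePNG(pmin(pmax(v, 0), 1), path),
    tif = ,
    tiff = tiff::writeTIFF(pmin(pmax(v, 0), 1), path, bits.per.sample = 16L),
    stop("unsupported image format '", ext, "': ", path))
  invisible(path)
}

# ---- sinogram container ---------------------------------------------------

#' Serialize a sinogram with its geometry
#'
#' Writes the projection values as an NPY `nViews x nDetectors` array plus a
#' JSON sidecar (`<path>.json`) carrying the scan-geometry fields; the pair
#' round-trips bit-exactly through [readSinogram()].
#'
#' @param sino a [Sinogram-class].
#' @param path destination `.npy` path.
#' @return `path`, invisibly.
#' @export
writeSinogram <- function(sino, path) {
  stopifnot(is(sino, "Sinogram"))
  writeNpy(sino@values, path)
  g <- sino@geometry
  meta <- list(n_views = g@nViews, n_detectors = g@nDetectors,
               angular_span_deg = g@angularSpan, angles_deg = g@angles,
               detector_spacing = g@detectorSpacing,
               detector_center_offset = g@detectorOffset)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spacing <- meta$detector_spacing
  if (is.null(spacing)) spacing <- NA_real_
  g <- makeParallelGeometry(meta$n_views, meta$n_detectors,
                            meta$angular_span_deg,
                            detectorSpacing = as.numeric(spacing),
                            detectorOffset = meta$detector_center_offset)
  sinogram(readNpy(path), g)
}
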