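# Image stack input/output and the maximum projection feeding the 2D
# analyses.
#
# TIFF support is deliberately minimal: uncompressed baseline grayscale,
# single- or multi-page, 8- or 16-bit unsigned, either byte order on read,
# little-endian single-strip pages on write. That covers the bright-field /
# fluorescence exports this package consumes; nothing else is attempted.
# Spacing is supplied by the caller, never parsed from TIFF tags (resolution
# tags are unreliable across acquisition software).

#' Construct a VoxelGrid
#'
#' @param data 3D numeric array, dim `(nz, ny, nx)`; z is the vertical
#'   (optical) axis with the plate bottom at low z.
#' @param spacing numeric(3), micrometers per voxel `(sz, sy, sx)`.
#'   Default `c(2.0, 1.3, 1.3)`, the light-sheet acquisition settings
#'   (2 um z-step, 1.3 um pixels).
#' @param channel channel label, free text.
#' @return a [VoxelGrid-class]
#' @export
VoxelGrid <- function(data, spacing = c(2.0, 1.3, 1.3), channel = "") {
  new("VoxelGrid", data = data, spacing = as.numeric(spacing),
      channel = channel)
}

#' Construct an Image2D
#'
#' @param data numeric matrix `[y, x]`.
#' @param pixelSize numeric(2), micrometers per pixel `(py, px)`.
#' @param channel channel label.
#' @return an [Image2D-class]
#' @export
Image2D <- function(data, pixelSize = c(1.3, 1.3), channel = "") {
  new("Image2D", data = data, pixelSize = as.numeric(pixelSize),
      channel = channel)
}

#' Construct a Mask3D
#'
#' @param data logical 3D array.
#' @param spacing numeric(3), micrometers per voxel `(sz, sy, sx)`.
#' @return a [Mask3D-class]
#' @export
Mask3D <- function(data, spacing = c(2.0, 1.3, 1.3)) {
  new("Mask3D", data = data, spacing = as.numeric(spacing))
}

#' Construct a Mask2D
#'
#' @param data logical matrix `[y, x]`.
#' @param pixelSize numeric(2), micrometers per pixel `(py, px)`.
#' @return a [Mask2D-class]
#' @export
Mask2D <- function(data, pixelSize = c(1.3, 1.3)) {
  new("Mask2D", data = data, pixelSize = as.numeric(pixelSize))
}

#' Construct SegmentationParams
#'
#' @param lowFactor,highFactor hysteresis thresholds as multiples of the
#'   Otsu threshold (defaults 0.8 and 1.2).
#' @param denoiseStrength non-local means `h` as a multiple of the estimated
#'   noise sigma (default 0.8; 0 disables denoising).
#' @param targetSpacing isotropic resampling pitch in micrometers
#'   (`NA` = smallest input spacing).
#' @param minComponentVoxels minimum retained component size (default 1000).
#' @param patchRadius,searchRadius non-local means patch and search radii in
#'   voxels (defaults 1 and 3, i.e. 3^3 patches in a 7^3 window).
#' @return a [SegmentationParams-class]
#' @seealso [segmentSpheroid3D()]
#' @export
SegmentationParams <- function(lowFactor = 0.8, highFactor = 1.2,
                               denoiseStrength = 0.8,
                               targetSpacing = NA_real_,
                               minComponentVoxels = 1000,
                               patchRadius = 1L, searchRadius = 3L) {
  new("SegmentationParams", lowFactor = lowFactor, highFactor = highFactor,
      denoiseStrength = denoiseStrength,
      targetSpacing = as.numeric(targetSpacing),
      minComponentVoxels = minComponentVoxels,
      patchRadius = as.integer(patchRadius),
      searchRadius = as.integer(searchRadius))
}

# --- TIFF internals --------------------------------------------------------

.tiffTypeSize <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)

.readTagValues <- function(raw, entryOff, endian) {
  u16 <- function(o) readBin(raw[o + 1:2], "integer", 1L, size = 2L,
                             signed = FALSE, endian = endian)
  u32 <- function(o) readBin(raw[o + 1:4], "integer", 1L, size = 4L,
                             endian = endian)
  type <- u16(entryOff + 2L)
  count <- u32(entryOff + 4L)
  sz <- .tiffTypeSize[as.character(type)]
  if (is.na(sz)) return(NULL)  # unsupported value type: ignore tag
  nbytes <- sz * count
  valOff <- if (nbytes <= 4L) entryOff + 8L else u32(entryOff + 8L)
  if (type == 3L) {
    vapply(seq_len(count) - 1L, function(i) u16(valOff + 2L * i), integer(1))
  } else if (type == 4L) {
    vapply(seq_len(count) - 1L, function(i) u32(valOff + 4L * i), integer(1))
  } else {
    vapply(seq_len(count) - 1L, function(i) {
      as.integer(raw[valOff + 1L + i])
    }, integer(1))
  }
}

.parseTIFF <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L)
    stop("not a TIFF file (too short): ", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file (bad byte-order mark): ", path)
  u16 <- function(o) readBin(raw[o + 1:2], "integer", 1L, size = 2L,
                             signed = FALSE, endian = endian)
  u32 <- function(o) readBin(raw[o + 1:4], "integer", 1L, size = 4L,
                             endian = endian)
  if (u16(2L) != 42L) stop("not a TIFF file (bad magic): ", path)

  pages <- list()
  ifdOff <- u32(4L)
  while (ifdOff != 0L) {
    n <- u16(ifdOff)
    tags <- list()
    for (e in seq_len(n)) {
      eo <- ifdOff + 2L + 12L * (e - 1L)
      tag <- u16(eo)
      tags[[as.character(tag)]] <- .readTagValues(raw, eo, endian)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257)
    if (is.null(w) || is.null(h)) stop("TIFF page without dimensions: ", path)
    bits <- g(258, 1L)[1]
    comp <- g(259, 1L)[1]
    spp <- g(277, 1L)[1]
    fmt <- g(339, 1L)[1]
    if (comp != 1L)
      stop("only uncompressed TIFF is supported (Compression = ", comp, ")")
    if (spp != 1L)
      stop("only single-sample (grayscale) TIFF is supported, got ",
           spp, " samples/pixel")
    if (!bits %in% c(8L, 16L))
      stop("only 8- or 16-bit TIFF is supported, got ", bits, "-bit")
    if (fmt != 1L)
      stop("only unsigned-integer TIFF samples are supported")
    offs <- g(273); cnts <- g(279)
    if (is.null(offs)) stop("TIFF page without strip offsets: ", path)
    if (is.null(cnts)) cnts <- rep.int(w * h * bits %/% 8L, length(offs))
    vals <- integer(0)
    for (s in seq_along(offs)) {
      bytes <- raw[offs[s] + seq_len(cnts[s])]
      vals <- c(vals, readBin(bytes, "integer", n = cnts[s] %/% (bits %/% 8L),
                              size = bits %/% 8L, signed = FALSE,
                              endian = endian))
    }
    if (length(vals) < w * h) stop("truncated TIFF strip data: ", path)
    # file order is row-major (x fastest); store as [y, x]
    pages[[length(pages) + 1L]] <- t(matrix(as.numeric(vals[seq_len(w * h)]),
                                            nrow = w, ncol = h))
    ifdOff <- u32(ifdOff + 2L + 12L * n)
  }
  if (!length(pages)) stop("TIFF file contains zero pages: ", path)
  pages
}

#' Read a grayscale TIFF z-stack
#'
#' Pages are stacked along z in file order (page 1 = lowest z = plate
#' bottom). Intensities are returned as doubles; 8/16-bit integer input is
#' preserved losslessly. Voxel spacing is attached verbatim from the
#' `spacing` argument, never parsed from TIFF tags.
#'
#' @param path a single- or multi-page uncompressed grayscale TIFF.
#' @param spacing numeric(3), micrometers per voxel `(sz, sy, sx)`; default
#'   `c(2.0, 1.3, 1.3)` (light-sheet settings).
#' @param channel channel label to attach.
#' @return a [VoxelGrid-class] of dim `(pages, height, width)`
#' @seealso [writeStack()], [maxProjection()]
#' @export
readStack <- function(path, spacing = c(2.0, 1.3, 1.3), channel = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- .parseTIFF(path)
  d <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1))))
    stop("TIFF pages differ in size: ", path)
  arr <- array(0, c(length(pages), d[1], d[2]))
  for (p in seq_along(pages)) arr[p, , ] <- pages[[p]]
  VoxelGrid(arr, spacing = spacing, channel = channel)
}

#' Write a grayscale TIFF z-stack
#'
#' Writes an uncompressed little-endian baseline TIFF, one page per z slice.
#' Intensities must be non-negative integers; bit depth is chosen
#' automatically (8-bit if the maximum fits, else 16-bit) unless forced.
#' Masks are written as 8-bit 0/255.
#'
#' @param x a [VoxelGrid-class], [Mask3D-class], [Image2D-class] or
#'   [Mask2D-class]
#' @param path output file path
#' @param bitsPerSample 8, 16 or `NULL` (auto)
#' @return `path`, invisibly
#' @export
writeStack <- function(x, path, bitsPerSample = NULL) {
  if (is(x, "Mask3D")) {
    arr <- array(as.numeric(x@data) * 255, dim(x@data))
    bitsPerSample <- 8L
  } else if (is(x, "Mask2D")) {
    arr <- array(as.numeric(x@data) * 255, c(1L, dim(x@data)))
    bitsPerSample <- 8L
  } else if (is(x, "Image2D")) {
    arr <- array(x@data, c(1L, dim(x@data)))
  } else if (is(x, "VoxelGrid")) {
    arr <- x@data
  } else stop("cannot write object of class ", class(x), " as TIFF")

  v <- round(arr)
  if (max(abs(arr - v)) > 1e-6)
    stop("TIFF export requires integer intensities; quantize first")
  if (min(v) < 0) stop("TIFF export requires non-negative intensities")
  if (is.null(bitsPerSample))
    bitsPerSample <- if (max(v) <= 255) 8L else 16L
  if (bitsPerSample == 8L && max(v) > 255)
    stop("intensities exceed 8-bit range")
  if (max(v) > 65535) stop("intensities exceed 16-bit range")

  nz <- dim(v)[1]; ny <- dim(v)[2]; nx <- dim(v)[3]
  bytes <- bitsPerSample %/% 8L
  dataLen <- ny * nx * bytes
  pad <- dataLen %% 2L
  ifdLen <- 2L + 9L * 12L + 4L
  pageLen <- ifdLen + dataLen + pad

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                              endian = "little")
  tagEntry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count); w32(value)
  }
  writeBin(charToRaw("II"), con); w16(42L); w32(8L)
  for (p in seq_len(nz)) {
    ifdOff <- 8L + (p - 1L) * pageLen
    dataOff <- ifdOff + ifdLen
    w16(9L)
    tagEntry(256L, 4L, 1L, nx)                 # ImageWidth
    tagEntry(257L, 4L, 1L, ny)                 # ImageLength
    tagEntry(258L, 3L, 1L, bitsPerSample)      # BitsPerSample
    tagEntry(259L, 3L, 1L, 1L)                 # Compression: none
    tagEntry(262L, 3L, 1L, 1L)                 # Photometric: BlackIsZero
    tagEntry(273L, 4L, 1L, dataOff)            # StripOffsets
    tagEntry(277L, 3L, 1L, 1L)                 # SamplesPerPixel
    tagEntry(278L, 4L, 1L, ny)                 # RowsPerStrip
    tagEntry(279L, 4L, 1L, dataLen)            # StripByteCounts
    w32(if (p < nz) ifdOff + pageLen else 0L)  # next IFD
    slice <- as.integer(t(matrix(v[p, , ], ny, nx)))  # row-major, x fastest
    if (bitsPerSample == 8L) {
      writeBin(as.raw(slice), con)
    } else {
      writeBin(as.raw(rbind(slice %% 256L, slice %/% 256L)), con)
    }
    if (pad) writeBin(as.raw(0L), con)
  }
  invisible(path)
}

#' Maximum-intensity projection along z
#'
#' `out[y, x] = max over z of grid[z, y, x]`; the projection inherits the
#' in-plane pixel size `(sy, sx)`.
#'
#' @param grid a [VoxelGrid-class]
#' @return an [Image2D-class]
#' @export
maxProjection <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  d <- dim(grid@data)
  if (prod(d) == 0) stop("empty grid")
  proj <- grid@data[1, , ]
  if (d[1] > 1)
    for (z in 2:d[1]) proj <- pmax(proj, grid@data[z, , ])
  Image2D(matrix(proj, d[2], d[3]), pixelSize = grid@spacing[2:3],
          channel = grid@channel)
}

# --- tabular results -------------------------------------------------------

#' Write metric records to CSV
#'
#' Accepts a data frame, or a list whose elements are one-row data frames,
#' named lists, or metric objects ([Morphometrics2D-class],
#' [Morphometrics3D-class], [DeathMetrics-class]). All records must share a
#' schema; the column order of the first record is kept.
#'
#' @param records records to write (see above). An empty list writes a
#'   header-only file when `columns` is given.
#' @param path output CSV path
#' @param columns column names to use for an empty record list
#' @return `path`, invisibly
#' @export
writeMetricsTable <- function(records, path, columns = NULL) {
  if (is.data.frame(records)) {
    df <- records
  } else if (length(records) == 0L) {
    df <- as.data.frame(
      stats::setNames(rep(list(numeric(0)), length(columns)), columns))
  } else {
    rows <- lapply(records, function(r) {
      if (isVirtualClass(class(r)) || isS4(r)) r <- as.data.frame(r)
      if (is.data.frame(r)) return(r)
      as.data.frame(r, stringsAsFactors = FALSE)
    })
    nms <- lapply(rows, names)
    if (!all(vapply(nms, identical, logical(1), y = nms[[1]])))
      stop("heterogeneous record schemas: all records must share columns")
    df <- do.call(rbind, rows)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a metrics CSV written by [writeMetricsTable()]
#'
#' @param path CSV path
#' @return data frame
#' @export
readMetricsTable <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
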