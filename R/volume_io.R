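# TIFF stack input/output with physical voxel metadata.
#
# 8- and 16-bit unsigned stacks go through the tiff package. 32-bit float
# reconstructions are read by a small uncompressed-TIFF strip reader,
# because the general-purpose reader clamps float samples to [0, 1] and
# CT reconstructions use arbitrary float ranges.

.tiffExt <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

.listSliceFiles <- function(path) {
  files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!length(files))
    stop("no TIFF slices found in directory: ", path)
  files[order(basename(files), method = "radix")]
}

# Parse the header of a TIFF file just far enough to learn its sample
# format (1 = unsigned int, 3 = IEEE float) and bit depth.
.tiffSampleInfo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(magic, as.raw(c(0x49, 0x49)))) "little"
            else if (identical(magic, as.raw(c(0x4d, 0x4d)))) "big"
            else stop("not a TIFF file: ", path)
  readBin(con, "integer", 1, 2, signed = FALSE, endian = endian) # 42
  ifdOff <- readBin(con, "integer", 1, 4, endian = endian)
  seek(con, ifdOff)
  nTags <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
  bits <- 8L; fmt <- 1L
  for (i in seq_len(nTags)) {
    tag <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
    typ <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
    readBin(con, "integer", 1, 4, endian = endian) # count
    if (typ == 3L) {
      val <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
      readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
    } else {
      val <- readBin(con, "integer", 1, 4, endian = endian)
    }
    if (tag == 258L) bits <- val
    if (tag == 339L) fmt <- val
  }
  list(bits = bits, format = fmt, endian = endian)
}

# Minimal reader for uncompressed 32-bit float TIFFs (single- or
# multi-page, strip layout). Returns a list of matrices (row, column).
.readFloatTIFF <- function(path) {
  info <- .tiffSampleInfo(path)
  endian <- info$endian
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 4)
  ifdOff <- readBin(con, "integer", 1, 4, endian = endian)
  slices <- list()
  while (ifdOff != 0) {
    seek(con, ifdOff)
    nTags <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
    tags <- list()
    for (i in seq_len(nTags)) {
      tag <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
      typ <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
      cnt <- readBin(con, "integer", 1, 4, endian = endian)
      raw4 <- readBin(con, "raw", 4)
      tags[[as.character(tag)]] <- list(type = typ, count = cnt, raw = raw4)
    }
    ifdOff <- readBin(con, "integer", 1, 4, endian = endian)
    tagVal <- function(id, default = NULL) {
      tg <- tags[[as.character(id)]]
      if (is.null(tg)) return(default)
      sz <- c(1L, 1L, 2L, 4L)[tg$type]  # BYTE/ASCII/SHORT/LONG
      if (sz * tg$count <= 4L) {
        readBin(tg$raw, "integer", tg$count, sz,
                signed = sz == 4L, endian = endian)
      } else {
        off <- readBin(tg$raw, "integer", 1, 4, endian = endian)
        pos <- seek(con)
        seek(con, off)
        v <- readBin(con, "integer", tg$count, sz,
                     signed = sz == 4L, endian = endian)
        seek(con, pos)
        v
      }
    }
    width <- tagVal(256); height <- tagVal(257)
    if (tagVal(259, 1L) != 1L)
      stop("compressed float TIFF not supported: ", path)
    if (tagVal(339, 1L) != 3L || tagVal(258, 8L) != 32L)
      stop("expected 32-bit float samples in ", path)
    offs <- tagVal(273); counts <- tagVal(279)
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      vals <- c(vals, readBin(con, "double", counts[s] / 4L, 4L,
                              endian = endian))
    }
    slices[[length(slices) + 1L]] <-
      matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  }
  slices
}

# Minimal writer for uncompressed little-endian 32-bit float TIFF
# (multi-page, one strip per page). Used for tests and for float exports.
.writeFloatTIFF <- function(slices, path) {
  if (is.matrix(slices)) slices <- list(slices)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49)), con)                  # little-endian
  writeBin(42L, con, 2, endian = "little")
  writeBin(8L, con, 4, endian = "little")               # first IFD offset
  nTag <- 8L
  pos <- 8
  for (s in seq_along(slices)) {
    m <- slices[[s]]
    h <- nrow(m); w <- ncol(m)
    ifdSize <- 2 + nTag * 12 + 4
    dataOff <- pos + ifdSize
    nbytes <- 4 * h * w
    writeBin(nTag, con, 2, endian = "little")
    wTag <- function(tag, typ, cnt, val) {
      writeBin(as.integer(tag), con, 2, endian = "little")
      writeBin(as.integer(typ), con, 2, endian = "little")
      writeBin(as.integer(cnt), con, 4, endian = "little")
      if (typ == 3L) {
        writeBin(as.integer(val), con, 2, endian = "little")
        writeBin(0L, con, 2, endian = "little")
      } else writeBin(as.integer(val), con, 4, endian = "little")
    }
    wTag(256, 4, 1, w)          # ImageWidth
    wTag(257, 4, 1, h)          # ImageLength
    wTag(258, 3, 1, 32)         # BitsPerSample
    wTag(259, 3, 1, 1)          # Compression: none
    wTag(273, 4, 1, dataOff)    # StripOffsets
    wTag(278, 4, 1, h)          # RowsPerStrip
    wTag(279, 4, 1, nbytes)     # StripByteCounts
    wTag(339, 3, 1, 3)          # SampleFormat: IEEE float
    nextIFD <- if (s < length(slices)) dataOff + nbytes else 0
    writeBin(as.integer(nextIFD), con, 4, endian = "little")
    writeBin(as.numeric(t(m)), con, 4, endian = "little")
    pos <- dataOff + nbytes
  }
  invisible(path)
}

#' Downscale float gray values to the 16-bit unsigned scale
#'
#' Maps a 3D float array linearly onto [0, 65535] after symmetric quantile
#' clipping, the ingest step for 32-bit float CT reconstructions. Values
#' outside the clipped range saturate at 0 or 65535. The map is monotone:
#' the ordering of any two voxels is preserved or collapsed, never inverted.
#'
#' @param data 3D numeric array with finite values.
#' @param clipQuantiles length-2 fractions in [0, 0.5): lower and upper
#'   tail mass clipped before the linear map. Default 0.0005 per tail
#'   protects against isolated reconstruction outliers.
#' @return 3D array of integers in [0, 65535], same dim as input.
#' @examples
#' rescaleToUint16(array(c(0, 0.5, 1, 0.25), c(1, 2, 2)),
#'                 clipQuantiles = c(0, 0))
#' @export
rescaleToUint16 <- function(data, clipQuantiles = c(5e-4, 5e-4)) {
  if (!all(is.finite(data)))
    stop("float volume contains non-finite values")
  if (length(clipQuantiles) != 2L || any(clipQuantiles < 0) ||
      any(clipQuantiles >= 0.5))
    stop("clipQuantiles must be two fractions in [0, 0.5)")
  lo <- if (clipQuantiles[1] > 0)
    quantile(data, clipQuantiles[1], names = FALSE) else min(data)
  hi <- if (clipQuantiles[2] > 0)
    quantile(data, 1 - clipQuantiles[2], names = FALSE) else max(data)
  if (hi <= lo) {
    if (min(data) == max(data))
      stop("degenerate volume: zero dynamic range")
    lo <- min(data); hi <- max(data)
  }
  out <- round((data - lo) / (hi - lo) * 65535)
  out[out < 0] <- 0
  out[out > 65535] <- 65535
  array(out, dim(data))
}

#' Load a CT volume or mask from a TIFF stack
#'
#' Reads a multi-page TIFF or a directory of equally sized single-slice
#' TIFFs (lexicographic slice order). 8-bit samples are promoted to the
#' 16-bit scale by left-shift scaling (x 256); 32-bit float samples are
#' passed through \code{\link{rescaleToUint16}}.
#'
#' @param path a TIFF file or a directory of per-slice TIFFs.
#' @param voxelSize isotropic voxel edge length in mm. If missing and a
#'   sidecar JSON written by \code{\link{saveStack}} is present, it is read
#'   from there.
#' @param clipQuantiles passed to \code{\link{rescaleToUint16}} for float
#'   input.
#' @return a \linkS4class{VoxelVolume}.
#' @export
loadStack <- function(path, voxelSize = NULL, clipQuantiles = c(5e-4, 5e-4)) {
  if (!file.exists(path))
    stop("path does not exist: ", path)
  if (is.null(voxelSize)) {
    sidecar <- paste0(sub("/$", "", path), ".json")
    if (file.exists(sidecar))
      voxelSize <- jsonlite::read_json(sidecar)$voxel_size_mm
  }
  if (is.null(voxelSize))
    stop("voxelSize (mm) must be given or present in a sidecar JSON")

  files <- if (dir.exists(path)) .listSliceFiles(path) else path
  slices <- list()
  dtype <- NULL
  for (f in files) {
    info <- .tiffSampleInfo(f)
    if (info$format == 3L) {
      s <- .readFloatTIFF(f)
      dt <- "float32"
    } else {
      s <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
      dt <- if (info$bits <= 8L) "uint8" else "uint16"
    }
    if (!is.null(dtype) && dtype != dt)
      stop("mixed sample formats across slices")
    dtype <- dt
    slices <- c(slices, s)
  }
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("slices have mismatched dimensions")

  nz <- length(slices)
  arr <- array(0, c(nz, dims[1, 1], dims[2, 1]))
  for (z in seq_len(nz)) arr[z, , ] <- slices[[z]]
  if (dtype == "uint8") arr <- arr * 256
  if (dtype == "float32") arr <- rescaleToUint16(arr, clipQuantiles)
  voxelVolume(arr, voxelSize, sourceDtype = dtype)
}

#' Save a volume or mask as a TIFF stack with a JSON sidecar
#'
#' Volumes are written as 16-bit unsigned multi-page TIFF; masks as 8-bit
#' with foreground 255 and background 0. A sidecar JSON
#' (\code{<path>.json}) records the voxel size and content type so a later
#' \code{\link{loadStack}} can recover the physical scale. Saving then
#' loading reproduces the voxel data exactly.
#'
#' @param x a \linkS4class{VoxelVolume} or \linkS4class{ROIMask}.
#' @param path output TIFF file path (multi-page).
#' @return the path, invisibly.
#' @export
saveStack <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (is(x, "ROIMask")) {
    # writeTIFF maps [0,1] to the sample range; 1 -> 255 at 8 bit
    slices <- lapply(seq_len(dim(x)[1]), function(z) x@data[z, , ] * 1.0)
    tiff::writeTIFF(slices, path, bits.per.sample = 8)
    meta <- list(content = "mask", label = x@label,
                 voxel_size_mm = x@voxelSize, dim = dim(x),
                 foreground_value = 255)
  } else if (is(x, "VoxelVolume")) {
    slices <- lapply(seq_len(dim(x)[1]), function(z) x@data[z, , ] / 65535)
    tiff::writeTIFF(slices, path, bits.per.sample = 16)
    meta <- list(content = "volume", voxel_size_mm = x@voxelSize,
                 dim = dim(x), source_dtype = x@sourceDtype)
  } else stop("x must be a VoxelVolume or ROIMask")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a mask saved by saveStack
#'
#' @param path TIFF file written by \code{\link{saveStack}} for a mask.
#' @param voxelSize voxel edge length in mm (sidecar JSON consulted if
#'   missing).
#' @param label role tag for the returned mask.
#' @return an \linkS4class{ROIMask}; any non-zero pixel is foreground.
#' @export
loadMask <- function(path, voxelSize = NULL, label = "mask") {
  vol <- loadStack(path, voxelSize)
  roiMask(vol@data > 0, label = label, voxelSize = vol@voxelSize)
}
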