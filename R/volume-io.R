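# MRC2014 reader/writer.
#
# Layout on disk: 1024-byte header, optional extended header (nsymbt bytes,
# skipped on read), then data with the column (x) index fastest, matching the
# em_volume array convention data[x, y, z]. Files are written little-endian,
# mode 2 (float32), mapc/mapr/maps = 1/2/3. On read, modes 0 (int8), 1
# (int16), 2 (float32) and 6 (uint16) are accepted; non-float modes are
# converted to float with a warning. Only cubic, even-sized data is accepted.

MRC_HEADER_BYTES <- 1024L

#' Read a cubic MRC volume
#'
#' Reads an MRC2014 density map. The pixel size is taken from the header as
#' `cella / mx`; a non-positive header pixel size falls back to 1.0 Angstrom
#' with a warning. Non-cubic or odd-sized maps are rejected because the
#' resolution machinery requires a cubic, even grid.
#'
#' @param path path to an MRC file.
#' @return An [em_volume()].
#' @seealso [write_mrc()], [read_mrc_mask()]
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  hdr_raw <- readBin(con, "raw", MRC_HEADER_BYTES)
  if (length(hdr_raw) < MRC_HEADER_BYTES)
    stop("truncated MRC header in ", path, call. = FALSE)

  # Detect byte order from MACHST (bytes 213-216): 0x44 => little-endian.
  machst <- hdr_raw[213:214]
  endian <- if (identical(as.integer(machst), c(0x11L, 0x11L))) "big" else "little"

  int_at <- function(word) readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)],
                                   "integer", 1, size = 4, endian = endian)
  num_at <- function(word) readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)],
                                   "numeric", 1, size = 4, endian = endian)

  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  mode <- int_at(4)
  mx <- int_at(8)
  cella_x <- num_at(11)
  nsymbt <- int_at(24)

  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 1e5))
    stop("implausible MRC dimensions in ", path, " (corrupt header?)", call. = FALSE)
  if (nx != ny || nx != nz)
    stop("MRC data is not cubic (", nx, "x", ny, "x", nz, "); cubic maps required",
         call. = FALSE)
  if (nx %% 2L != 0L || nx < 8L)
    stop("MRC grid size must be even and >= 8; got n = ", nx, call. = FALSE)

  pixel_size <- if (mx > 0 && is.finite(cella_x) && cella_x > 0) cella_x / mx else 0
  if (!is.finite(pixel_size) || pixel_size <= 0) {
    warning("MRC header carries no usable pixel size; falling back to 1.0 A",
            call. = FALSE)
    pixel_size <- 1.0
  }

  if (nsymbt > 0) invisible(readBin(con, "raw", nsymbt))

  nvox <- as.numeric(nx) * ny * nz
  data <- switch(as.character(mode),
    "2" = readBin(con, "numeric", nvox, size = 4, endian = endian),
    "0" = {
      warning("MRC mode 0 (int8) converted to float", call. = FALSE)
      readBin(con, "integer", nvox, size = 1, signed = TRUE, endian = endian)
    },
    "1" = {
      warning("MRC mode 1 (int16) converted to float", call. = FALSE)
      readBin(con, "integer", nvox, size = 2, signed = TRUE, endian = endian)
    },
    "6" = {
      warning("MRC mode 6 (uint16) converted to float", call. = FALSE)
      readBin(con, "integer", nvox, size = 2, signed = FALSE, endian = endian)
    },
    stop("unsupported MRC mode ", mode, " in ", path, call. = FALSE)
  )
  if (length(data) < nvox)
    stop("truncated MRC data block in ", path, " (expected ", nvox,
         " voxels, got ", length(data), ")", call. = FALSE)
  if (!all(is.finite(data)))
    stop("MRC data in ", path, " contains non-finite values", call. = FALSE)

  em_volume(array(as.numeric(data), dim = c(nx, ny, nz)), pixel_size = pixel_size)
}

#' Write a volume as MRC2014
#'
#' Writes mode-2 (float32) little-endian MRC with a minimal standards-
#' compliant header recording the grid size and pixel size (`cella = n *
#' pixel_size`). Data round-trips through [read_mrc()] bit-identically at
#' float32 precision.
#'
#' @param v an [em_volume()] (or `em_mask`).
#' @param path output path; parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(v, path) {
  stopifnot(inherits(v, "em_volume"))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- v$n
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")

  wi(c(n, n, n))                      # nx ny nz
  wi(2L)                              # mode 2 = float32
  wi(c(0L, 0L, 0L))                   # nxstart nystart nzstart
  wi(c(n, n, n))                      # mx my mz
  wf(rep(n * v$pixel_size, 3))        # cella
  wf(c(90, 90, 90))                   # cellb
  wi(c(1L, 2L, 3L))                   # mapc mapr maps
  wf(c(min(v$data), max(v$data), mean(v$data)))  # dmin dmax dmean
  wi(c(1L, 0L))                       # ispg, nsymbt
  wi(rep(0L, 25))                     # extra
  wf(c(0, 0, 0))                      # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(v$data))               # rms
  wi(0L)                              # nlabl
  writeBin(raw(800L), con)            # labels

  writeBin(as.numeric(v$data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC file as a mask
#'
#' Like [read_mrc()] but returns an [em_mask()]; values are clipped to
#' \[0, 1\] (tiny float32 excursions outside the unit interval are tolerated).
#'
#' @inheritParams read_mrc
#' @return An `em_mask`.
#' @export
read_mrc_mask <- function(path) {
  v <- read_mrc(path)
  d <- pmin(pmax(v$data, 0), 1)
  em_mask(d, v$pixel_size)
}

#' Read an integer-labelled segment volume
#'
#' Reads an MRC volume whose voxel values are nonnegative integer segment
#' labels (0 = background), e.g. the output of a k-means map segmentation
#' saved per segment or as one labelled map.
#'
#' @inheritParams read_mrc
#' @return A `segment_set`: list with `labels` (integer 3D array), `n`,
#'   `pixel_size`, and `counts` (named voxel counts per nonzero label).
#' @export
read_mrc_segments <- function(path) {
  v <- read_mrc(path)
  segment_set(round(v$data), v$pixel_size)
}

#' Construct a segment set from a labelled array
#'
#' @param labels 3D array of nonnegative integer labels (0 = background).
#' @param pixel_size voxel size in Angstrom.
#' @return A `segment_set` object.
#' @export
segment_set <- function(labels, pixel_size = 1) {
  v <- em_volume(labels, pixel_size)
  if (any(labels < 0)) stop("segment labels must be nonnegative", call. = FALSE)
  tab <- table(labels[labels > 0])
  if (length(tab) == 0) stop("segment set has no nonzero labels", call. = FALSE)
  structure(list(labels = v$data, n = v$n, pixel_size = v$pixel_size,
                 counts = stats::setNames(as.integer(tab), names(tab))),
            class = "segment_set")
}
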