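#' Construct a cubic density volume
#'
#' A volume is a cubic 3D grid of real densities with an associated pixel
#' (voxel) size in Angstrom. All resolution machinery in this package assumes
#' cubic, even-sized grids: the Nyquist shell index is then exactly `n/2` and
#' Friedel symmetry of the discrete Fourier transform is handled without
#' special cases.
#'
#' Array axis convention: `data[x, y, z]` with the first index (`x`, the MRC
#' column) varying fastest in memory, then `y` (row), then `z` (section). All
#' volumes and masks combined in one calculation must share this layout, the
#' grid size and the pixel size.
#'
#' @param data 3D numeric array; all three extents equal, even, and >= 8.
#' @param pixel_size voxel edge length in Angstrom (> 0).
#' @return An object of class `em_volume`: a list with elements `data`
#'   (3D array), `n` (grid size) and `pixel_size` (Angstrom).
#' @examples
#' v <- em_volume(array(rnorm(16^3), c(16, 16, 16)), pixel_size = 1.5)
#' v$n
#' @export
em_volume <- function(data, pixel_size = 1) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  d <- dim(data)
  if (d[1] != d[2] || d[1] != d[3])
    stop("volume must be cubic; got ", paste(d, collapse = "x"), call. = FALSE)
  n <- d[1]
  if (n < 8L || n %% 2L != 0L)
    stop("grid size must be even and >= 8; got n = ", n, call. = FALSE)
  if (!all(is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  structure(list(data = data, n = as.integer(n), pixel_size = as.numeric(pixel_size)),
            class = "em_volume")
}

#' Construct a real-space mask
#'
#' A mask carries per-voxel weights in \[0, 1\] on the same grid as the
#' volumes it is applied to. Soft (tapered) masks are allowed for the
#' classical multiplicative FSC protocol; the mFSC requires a binary mask
#' (see [binarize_mask()]), whose support merely selects which voxels enter
#' the real-space correlation and therefore cannot introduce spurious
#' correlations.
#'
#' @param data 3D numeric array of weights in \[0, 1\].
#' @param pixel_size voxel size in Angstrom.
#' @return An object of class `em_mask` (inherits `em_volume`) with an extra
#'   element `count`: the number of strictly positive voxels.
#' @export
em_mask <- function(data, pixel_size = 1) {
  if (any(data < 0 | data > 1))
    stop("mask weights must lie in [0, 1]", call. = FALSE)
  v <- em_volume(data, pixel_size)
  v$count <- sum(data > 0)
  class(v) <- c("em_mask", "em_volume")
  v
}

#' @export
print.em_volume <- function(x, ...) {
  cat(sprintf("<%s> %d^3 voxels, pixel %.4g A, range [%.4g, %.4g]\n",
              class(x)[1], x$n, x$pixel_size, min(x$data), max(x$data)))
  if (!is.null(x$count))
    cat(sprintf("  positive voxels: %d (%.2f%% of volume)\n",
                x$count, 100 * x$count / x$n^3))
  invisible(x)
}

#' Binarize a soft mask
#'
#' Thresholds mask weights to \{0, 1\}: voxels strictly above `threshold`
#' become 1. The mFSC protocol binarizes soft refinement masks at 0.5 so the
#' mask acts purely as a voxel selector.
#'
#' @param m an [em_mask()].
#' @param threshold scalar in (0, 1); default 0.5.
#' @return A binary `em_mask` with updated `count`.
#' @examples
#' m <- make_mask(16, "soft-sphere", diameter = 10, edge_width = 3)
#' binarize_mask(m)$count
#' @export
binarize_mask <- function(m, threshold = 0.5) {
  stopifnot(inherits(m, "em_mask"))
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie strictly in (0, 1)", call. = FALSE)
  b <- (m$data > threshold) * 1
  if (sum(b) == 0)
    stop("binarization at ", threshold, " leaves an empty mask; mFSC is undefined on empty support",
         call. = FALSE)
  em_mask(b, m$pixel_size)
}

#' Test whether a mask is binary
#' @param m an `em_mask`.
#' @return TRUE if all weights are exactly 0 or 1.
#' @export
is_binary_mask <- function(m) {
  all(m$data == 0 | m$data == 1)
}

# Check that two volumes/masks share grid size and pixel size.
check_same_geometry <- function(a, b, what = "volumes") {
  if (a$n != b$n)
    stop(what, " differ in grid size (", a$n, " vs ", b$n, ")", call. = FALSE)
  if (abs(a$pixel_size - b$pixel_size) > 1e-6 * a$pixel_size)
    stop(what, " differ in pixel size (", a$pixel_size, " vs ", b$pixel_size, ")",
         call. = FALSE)
  invisible(TRUE)
}
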