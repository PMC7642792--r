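# Fourier-domain machinery shared by the FSC/mFSC code: radius grids in the
# native (unshifted) FFT layout, Gaussian band-pass filtering, rectangular
# shell selectors, prewhitening, rotational averages, and the masked
# real-space correlation coefficient.
#
# FFT convention: stats::fft with no normalization on the forward transform;
# inverse transforms are divided by n^3. Every quantity exposed by the
# package is a normalization-invariant ratio, so the convention never leaks.

#' Fourier radius grid
#'
#' Returns a 3D array, in the native FFT layout of [stats::fft()], whose
#' value at each reciprocal-lattice point is the Euclidean distance to the
#' Fourier-space origin in Fourier-pixel units. Frequencies along each axis
#' run 0, 1, ..., n/2, -(n/2-1), ..., -1.
#'
#' @param n even grid size.
#' @return `n x n x n` numeric array of radii.
#' @examples
#' r <- frequency_radius_grid(16)
#' r[1, 1, 1]       # origin: 0
#' r[4, 5, 1]       # (3,4,0): 5
#' @export
frequency_radius_grid <- function(n) {
  if (n %% 2L != 0L) stop("`n` must be even", call. = FALSE)
  f <- c(0:(n / 2), -((n / 2 - 1):1))
  f2 <- f^2
  sqrt(outer(outer(f2, f2, `+`), f2, `+`))
}

#' Gaussian band-pass filter around a Fourier shell
#'
#' Multiplies the Fourier transform of `v` by the radially symmetric
#' amplitude gain `G(r) = exp(-(r - k)^2 / (2 sigma_g^2))` and transforms
#' back. The Gaussian window replaces a sharp rectangular shell to suppress
#' ringing (Gibbs) artifacts in real space, at the cost of diffusing the
#' band's localization in reciprocal space. The DC term is always zeroed, so
#' the output is a zero-mean volume; radial symmetry preserves Friedel
#' symmetry, so the output is real.
#'
#' @param v an [em_volume()], or a complex 3D array already holding the
#'   forward FFT of a volume (saves repeated forward transforms in per-shell
#'   loops).
#' @param k shell center in Fourier pixels, `1 <= k <= n/2`.
#' @param sigma_g Gaussian width in Fourier pixels (default 1, the usual
#'   global-resolution setting; local analyses typically use 3).
#' @param radius optional precomputed [frequency_radius_grid()].
#' @return An `em_volume` (if `v` was one) or a real 3D array.
#' @export
gaussian_bandpass <- function(v, k, sigma_g = 1, radius = NULL) {
  is_vol <- inherits(v, "em_volume")
  ft <- if (is_vol) stats::fft(v$data) else v
  n <- dim(ft)[1]
  if (k < 1 || k > n / 2) stop("shell index k must lie in [1, n/2]", call. = FALSE)
  if (sigma_g <= 0) stop("`sigma_g` must be positive", call. = FALSE)
  if (is.null(radius)) radius <- frequency_radius_grid(n)
  g <- exp(-(radius - k)^2 / (2 * sigma_g^2))
  g[1, 1, 1] <- 0
  out <- Re(stats::fft(ft * g, inverse = TRUE)) / length(ft)
  if (is_vol) em_volume(out, v$pixel_size) else out
}

#' Rectangular shell selector
#'
#' Logical reciprocal-space selector for the classical binary shell window:
#' lattice points with `k - width/2 <= r < k + width/2`. Consecutive width-1
#' shells partition the lattice (no point falls in two shells); the origin
#' belongs to no shell.
#'
#' @param n even grid size.
#' @param k shell center index, `1 <= k <= n/2`.
#' @param width shell width in Fourier pixels (default 1).
#' @param radius optional precomputed radius grid.
#' @return Logical `n x n x n` array.
#' @export
rectangular_shell_mask <- function(n, k, width = 1, radius = NULL) {
  if (k < 1 || k > n / 2) stop("shell index k must lie in [1, n/2]", call. = FALSE)
  if (is.null(radius)) radius <- frequency_radius_grid(n)
  sel <- radius >= (k - width / 2) & radius < (k + width / 2)
  sel[1, 1, 1] <- FALSE
  sel
}

# Integer shell index of every lattice point: round(r), i.e. bin k covers
# [k - 0.5, k + 0.5). Used for FSC shell sums, prewhitening and noise shaping.
shell_index_grid <- function(n, radius = NULL) {
  if (is.null(radius)) radius <- frequency_radius_grid(n)
  idx <- floor(radius + 0.5)
  storage.mode(idx) <- "integer"
  idx[1, 1, 1] <- 0L
  idx
}

#' Masked real-space correlation coefficient
#'
#' Pearson-type correlation of two volumes restricted to the support of a
#' binary mask. Because the mask only selects which voxels enter the sum (it
#' never multiplies the data before a Fourier transform), it cannot induce
#' spurious correlations — this is the core of the mFSC's mask robustness.
#'
#' Band-passed volumes restricted to a mask need not average to zero there,
#' so by default the within-mask mean of each argument is removed before
#' correlating (`center = FALSE` disables this and computes the plain
#' normalized inner product).
#'
#' @param a,b `em_volume`s (or bare 3D arrays) of identical geometry.
#' @param m a binary [em_mask()] with at least 2 support voxels.
#' @param center subtract within-mask means (default TRUE).
#' @return Correlation in \[-1, 1\]. If either masked argument has zero
#'   variance the result is 0 with a warning (degenerate band), never an
#'   error, so empty high-frequency bands yield 0 rather than aborting a
#'   curve.
#' @export
masked_correlation <- function(a, b, m, center = TRUE) {
  ad <- if (inherits(a, "em_volume")) a$data else a
  bd <- if (inherits(b, "em_volume")) b$data else b
  stopifnot(inherits(m, "em_mask"))
  if (!is_binary_mask(m))
    stop("masked_correlation requires a binary mask; use binarize_mask()", call. = FALSE)
  if (m$count < 2) stop("mask support must contain at least 2 voxels", call. = FALSE)
  sel <- m$data > 0
  x <- ad[sel]; y <- bd[sel]
  .correlation_vec(x, y, center)
}

# correlation of two bare vectors with the package's degenerate-input policy
.correlation_vec <- function(x, y, center = TRUE) {
  if (center) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0) {
    warning("zero variance within mask; returning correlation 0", call. = FALSE)
    return(0)
  }
  max(-1, min(1, sum(x * y) / sqrt(sx * sy)))
}

#' Prewhiten a volume
#'
#' Divides the Fourier transform by the rotational average of the square
#' root of its power spectrum (per width-1 shell), so the output's
#' rotationally averaged power spectrum is flat across shells. The DC term
#' is left unchanged. Prewhitening is implied by the FSC/mFSC normalization
#' (each shell is normalized by its own norms); this explicit form exists
#' for diagnostics on noise volumes.
#'
#' @param v an [em_volume()].
#' @return A prewhitened `em_volume`.
#' @section Errors: a shell with identically zero power among indices
#'   `1..n/2` aborts with an error naming the shell.
#' @export
prewhiten <- function(v) {
  stopifnot(inherits(v, "em_volume"))
  n <- v$n
  ft <- stats::fft(v$data)
  idx <- shell_index_grid(n)
  pw_by_shell <- tapply(Mod(ft)^2, idx, mean)
  pw <- as.numeric(pw_by_shell)
  shells <- as.integer(names(pw_by_shell))
  core <- shells >= 1L & shells <= n / 2
  empty <- pw <= 1e-24 * max(pw)        # numerically zero power
  if (any(empty[core])) {
    bad <- shells[core][empty[core]]
    stop("zero-power shell(s) at k = ", paste(bad, collapse = ", "),
         "; prewhitening undefined", call. = FALSE)
  }
  amp <- sqrt(pw)
  amp[shells == 0L] <- 1          # DC untouched
  amp[empty] <- 1                 # numerically empty corner shells unscaled
  scale <- amp[match(idx, shells)]
  out <- Re(stats::fft(ft / array(scale, dim(ft)), inverse = TRUE)) / length(ft)
  em_volume(out, v$pixel_size)
}

#' Rotationally averaged power spectrum
#'
#' Mean squared Fourier amplitude per width-1 shell, indices `0..n/2`.
#'
#' @param v an [em_volume()] or a complex FFT array.
#' @return Tibble with columns `k` and `power`.
#' @export
radial_power_spectrum <- function(v) {
  ft <- if (inherits(v, "em_volume")) stats::fft(v$data) else v
  n <- dim(ft)[1]
  idx <- shell_index_grid(n)
  keep <- idx <= n / 2
  pw <- tapply(Mod(ft[keep])^2, idx[keep], mean)
  tibble::tibble(k = as.integer(names(pw)), power = as.numeric(pw))
}

#' Rotational average in real space
#'
#' Mean voxel value in concentric radial bins (width 1 voxel) about the
#' volume center `(n/2 + 1, n/2 + 1, n/2 + 1)`. Used, e.g., to inspect the
#' radial profile of a half-map difference volume: solvent noise outside the
#' particle is typically stronger than noise within it, and prewhitening
#' flattens this profile.
#'
#' @param v an [em_volume()].
#' @return Tibble with columns `radius` (bin center, voxels) and `mean`.
#' @export
rotational_average_real <- function(v) {
  stopifnot(inherits(v, "em_volume"))
  n <- v$n
  ax <- seq_len(n) - (n / 2 + 1)
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  bin <- floor(r + 0.5)
  m <- tapply(v$data, bin, mean)
  tibble::tibble(radius = as.numeric(names(m)), mean = as.numeric(m))
}
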