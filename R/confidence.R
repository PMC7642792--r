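# Fisher-z confidence machinery and the resolution-determination rule.
#
# The resolution question is posed as a one-sided test per shell: is the
# observed mFSC significantly above the cutoff threshold t, given the
# shell's ndf? The z-transform z = atanh(r) is approximately normal with
# variance 1/(ndf - 3) (valid for ndf > 25 and r < 0.95), so the test
# compares the observed value with tanh(atanh(t) + q_{1-alpha}/sqrt(ndf-3)).

#' Confidence-interval parameters
#'
#' @param t resolution cutoff threshold in correlation units; 0.143 (the
#'   usual half-map criterion) by default, 0.5 also common.
#' @param alpha one-sided significance level in (0, 0.5); default 0.01. The
#'   commonly quoted multiples of sigma correspond to one-sided alpha of
#'   2.3% (2 sigma) and 0.1% (3 sigma).
#' @param two_sided if TRUE, alpha is replaced by alpha/2, giving the
#'   two-sided interval at the same nominal level.
#' @return A `ci_params` list.
#' @export
ci_params <- function(t = 0.143, alpha = 0.01, two_sided = FALSE) {
  if (t < 0 || t >= 0.95)
    stop("`t` must lie in [0, 0.95): the Fisher approximation degrades beyond 0.95",
         call. = FALSE)
  if (alpha <= 0 || alpha >= 0.5)
    stop("`alpha` must lie in (0, 0.5)", call. = FALSE)
  structure(list(t = t, alpha = alpha, two_sided = isTRUE(two_sided)),
            class = "ci_params")
}

effective_alpha <- function(params) {
  if (params$two_sided) params$alpha / 2 else params$alpha
}

#' Fisher z-transform
#'
#' `z = atanh(r) = 0.5 log((1 + r) / (1 - r))`. Warns above 0.95, where the
#' normal approximation to the transformed correlation degrades.
#'
#' @param r correlation(s), `|r| < 1`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  if (any(abs(r) >= 0.95))
    warning("Fisher z normal approximation is unreliable for |r| >= 0.95",
            call. = FALSE)
  atanh(r)
}

#' Standard deviation of the z-transformed correlation
#'
#' `1 / sqrt(ndf - 3)`; requires ndf > 3 (enforced upstream by the
#' [ndf_masked()] floor of 4).
#'
#' @param ndf degrees of freedom, vectorized.
#' @return Standard deviation(s).
#' @export
z_sd <- function(ndf) {
  if (any(ndf <= 3)) stop("`ndf` must exceed 3", call. = FALSE)
  1 / sqrt(ndf - 3)
}

#' One-sided confidence cutoff for a correlation threshold
#'
#' The smallest observed correlation that is significantly above `t` at
#' one-sided level alpha with the given ndf:
#' `tanh(atanh(t) + qnorm(1 - alpha) / sqrt(ndf - 3))`. Strictly above `t`
#' for finite ndf, decreasing in ndf, with limit `t` as ndf grows — so
#' small masks (small ndf) demand much higher correlations before a shell
#' counts as resolved.
#'
#' @param t threshold in correlation units.
#' @param alpha one-sided significance level.
#' @param ndf degrees of freedom (> 3), vectorized.
#' @return Cutoff correlation(s) in (t, 1).
#' @examples
#' ci_cutoff(0.143, 0.01, c(61, 1e3, 1e6))
#' @export
ci_cutoff <- function(t, alpha, ndf) {
  tanh(fisher_z(t) + stats::qnorm(1 - alpha) * z_sd(ndf))
}

#' Is a shell significantly above the threshold?
#'
#' TRUE iff `curve_value >= ci_cutoff(t, alpha, ndf)`. By monotonicity of
#' tanh this is algebraically identical to requiring the one-sided lower
#' confidence bound of the observed correlation,
#' `tanh(atanh(value) - qnorm(1 - alpha) / sqrt(ndf - 3))`, to reach `t`.
#'
#' @param curve_value observed correlation(s).
#' @param t threshold.
#' @param alpha one-sided level.
#' @param ndf degrees of freedom (> 3).
#' @return Logical.
#' @export
significant <- function(curve_value, t, alpha, ndf) {
  curve_value >= ci_cutoff(t, alpha, ndf)
}

#' Determine the resolution of a curve
#'
#' Applies the per-shell significance test and reads off the resolution.
#' `k_star` is the end of the initial contiguous run of significant shells
#' ("the highest frequency at which the condition remains fulfilled"):
#' spurious excursions above the cutoff at high frequency cannot inflate
#' the resolution. The strict global-maximum reading is available via
#' `rule = "global"` for comparison. `mode = "threshold"` replaces the CI
#' cutoff by the plain constant `t`, reproducing traditional FSC-threshold
#' resolutions.
#'
#' The resolution is `n / k_star` pixels, i.e. `pixel_size * n / k_star`
#' Angstrom. If no shell is significant, `k_star = 0` flags "no resolvable
#' signal" and the resolutions are NA.
#'
#' @param curve an `fsc_curve` from [fsc()] or [mfsc()].
#' @param ndf_per_k per-shell ndf aligned with `curve$k` (e.g. from
#'   [ndf_masked()]); a scalar is recycled.
#' @param params a [ci_params()].
#' @param mode `"ci"` (default) or `"threshold"`.
#' @param rule `"contiguous"` (default) or `"global"`.
#' @return A `resolution_result`: list with `k_star`, `resolution_pixels`,
#'   `resolution_angstrom`, `curve` (the input curve with `ndf`,
#'   `ci_cutoff` and `significant` columns appended), `params`, `mode`,
#'   `rule`, `n`, `pixel_size`.
#' @examples
#' ph <- make_phantom(32, "shell-limited", k1 = 8, seed = 1)
#' pair <- make_half_pair(ph, ssnr_profile_band(32, 6), seed = 2)
#' cv <- mfsc(pair$u, pair$v)
#' determine_resolution(cv, ndf_gaussian(cv$k), ci_params())
#' @export
determine_resolution <- function(curve, ndf_per_k, params = ci_params(),
                                 mode = c("ci", "threshold"),
                                 rule = c("contiguous", "global")) {
  stopifnot(inherits(curve, "fsc_curve"))
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  nk <- nrow(curve)
  if (nk == 0) stop("empty curve", call. = FALSE)
  if (length(ndf_per_k) == 1) ndf_per_k <- rep(ndf_per_k, nk)
  if (length(ndf_per_k) != nk)
    stop("`ndf_per_k` must align with the curve's shells", call. = FALSE)

  a <- effective_alpha(params)
  cutoff <- if (mode == "ci") ci_cutoff(params$t, a, ndf_per_k)
            else rep(params$t, nk)
  sig <- curve$value >= cutoff

  k_star <- 0L
  if (any(sig)) {
    if (rule == "contiguous") {
      first <- which(sig)[1]
      run_end <- first
      while (run_end < nk && sig[run_end + 1]) run_end <- run_end + 1
      k_star <- curve$k[run_end]
    } else {
      k_star <- curve$k[max(which(sig))]
    }
  }

  n <- attr(curve, "n"); p <- attr(curve, "pixel_size")
  aug <- curve
  aug$ndf <- ndf_per_k
  aug$ci_cutoff <- cutoff
  aug$significant <- sig
  structure(list(
    k_star = k_star,
    resolution_pixels = if (k_star > 0) n / k_star else NA_real_,
    resolution_angstrom = if (k_star > 0) p * n / k_star else NA_real_,
    resolvable = k_star > 0L,
    curve = aug, params = params, mode = mode, rule = rule,
    n = n, pixel_size = p
  ), class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  if (x$resolvable) {
    cat(sprintf("<resolution_result> k* = %d / %d shells -> %.2f px = %.2f A (mode %s, t = %g, alpha = %g)\n",
                x$k_star, max(x$curve$k), x$resolution_pixels,
                x$resolution_angstrom, x$mode, x$params$t, x$params$alpha))
  } else {
    cat(sprintf("<resolution_result> no resolvable signal (mode %s, t = %g, alpha = %g)\n",
                x$mode, x$params$t, x$params$alpha))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a resolution result
#'
#' One row per shell: index, spatial frequency, curve value, ndf, cutoff
#' and significance flag.
#'
#' @param x a `resolution_result`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy resolution_result
#' @export
tidy.resolution_result <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$curve))
}

#' One-row summary of a resolution result
#'
#' @param x a `resolution_result`.
#' @param ... unused.
#' @return One-row tibble with `k_star`, resolutions, settings.
#' @method glance resolution_result
#' @export
glance.resolution_result <- function(x, ...) {
  tibble::tibble(
    k_star = x$k_star,
    resolution_pixels = x$resolution_pixels,
    resolution_angstrom = x$resolution_angstrom,
    resolvable = x$resolvable,
    t = x$params$t, alpha = x$params$alpha,
    mode = x$mode, rule = x$rule,
    method = attr(x$curve, "method"),
    sigma_g = attr(x$curve, "sigma_g"),
    mask_count = attr(x$curve, "mask_count")
  )
}
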