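---
title: "Modified Fourier shell correlation: model, statistics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modified Fourier shell correlation: model, statistics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfsc)
```

## The half-map model and what FSC measures

Single-particle cryo-EM validation rests on the half-map model: the data
are split randomly in two, each half is reconstructed independently, and

$$u = f + r_1, \qquad v = f + r_2,$$

with shared signal $f$ and independent noise realizations $r_1, r_2$. The
Fourier shell correlation between $u$ and $v$ at shell radius $k$ (Fourier
pixels; spatial frequency $s = k/n$ for an $n^3$ grid) estimates the
per-shell signal fraction, and maps to the spectral signal-to-noise ratio
through the Saxton relation

$$\mathrm{SSNR}(k) = \frac{|c(k)|}{1 - |c(k)|},$$

which the package exposes as `snr_from_correlation()`. The mapping is
sharply nonlinear — $c = 0.143 \mapsto \mathrm{SNR}\ 0.17$, $c = 0.5
\mapsto 1$, $c = 0.91 \mapsto 10$ — which is worth keeping in mind when
reading curves near the conventional thresholds. The absolute value
encodes the convention that an SNR cannot be negative; $c = -1$ means
identical volumes of opposite contrast.

## Why masking corrupts the classical FSC, and how the mFSC avoids it

The classical protocol multiplies both half-maps by a real-space mask
before transforming (`fsc()` reproduces it, soft masks allowed). Because
the Fourier transform of a product is a convolution, the mask's transform
is convolved into both half-maps — a *shared* component. Whenever the maps
carry any common background (and experimental maps always do: solvent
level, DC offset), the masked transforms share the mask's shape and the
curve is biased upward, most strongly at low frequency and for tight,
elaborate masks.

`mfsc()` inverts the order: band-pass around shell $k$ first (Gaussian
amplitude gain $G(r) = \exp[-(r-k)^2/(2\sigma_g^2)]$, replacing the sharp
shell window to suppress Gibbs ringing), then correlate in real space over
the support of a *binary* mask. Selection of voxels after filtering cannot
create correlations, so the mask choice stops mattering. The trade-off is
spectral: a Gaussian window of width $\sigma_g$ diffuses each curve point
over a band of roughly $\pm 2\sigma_g$ shells, so curves are smoother but
less spectrally detailed, and sharp spectral features (e.g. a hard band
limit) register within about one window width of their true position. The
cost is two inverse 3D FFTs per shell versus two FFTs total for the
classical FSC; the per-shell loop is embarrassingly parallel, though this
implementation runs it serially.

Two numerical choices here were genuinely open:

* **Within-mask mean subtraction.** The correlation formula assumes
  zero-mean arguments. Band-passed volumes are globally zero-mean (the DC
  term is excluded from every filter), but not necessarily over a mask's
  support, and the Gaussian tail of low-$k$ windows can leak a residue of
  the background into the band. `masked_correlation()` therefore removes
  the within-mask mean of each argument by default; `center = FALSE`
  restores the plain normalized inner product.
* **DC and Nyquist.** The $k = 0$ term is excluded from all windows and
  from prewhitening normalization (prewhitening leaves DC unchanged); the
  default `k_max = n/2 - 1` avoids the partially sampled Nyquist shell.
* **Degenerate bands.** A shell with zero variance inside the mask yields
  correlation 0 with a warning rather than an error, so curves remain
  complete and plottable at empty high-frequency bands.

## Degrees of freedom

The variance of a shell correlation is governed by the effective number of
independent samples, not the raw coefficient count. Three factors enter:

1. **Shell surface.** A width-1 shell at radius $k$ holds about $4\pi k^2$
   lattice points (the continuum form; `count_shell_lattice_points()`
   provides exact counts, which fluctuate within ~15% of it for $k \ge 3$).
   The smooth form is used because it matches the magnitudes that matter
   downstream (about $10^3$ at $k = 5$, $1.5 \times 10^6$ at $k = 200$ for
   $\sigma_g = 1$) and is monotone in $k$.
2. **Window thickness.** For a Gaussian window an exact count is not
   available, so `mc_ndf_gaussian_window()` measures it: arrays of
   N(0,1) noise are multiplied by the window, their covariance is
   accumulated, and the eigenvalue spectrum is compared rank-by-rank
   against a shuffled (randomization) control with identical marginal
   noise; the highest rank at which the data eigenvalue still exceeds the
   control is the effective ndf. Empirically ndf $\approx 3\sigma_g$
   (regression through the origin over $\sigma_g \in \{2,4,8,16\}$ gives a
   slope of 3 at array lengths 256–512), fixing the closed form
   $\mathrm{ndf}(k) = 4\pi k^2 \cdot 3\sigma_g$ used by `ndf_gaussian()`.
   The window in the estimator is the standard Gaussian
   $w(j) = \exp[-(j-c)^2/(2\sigma_g^2)]$; the estimator's precondition
   (array length $\ge 8\sigma_g$) keeps the window supported inside the
   array, so the flat-window limit is out of its domain by construction.
3. **Mask fraction and helical redundancy.** Only $|m|/n^3$ of the voxels
   enter a masked correlation, and in a helical assembly only one "unique
   disk" (an axial slab of height rise/pixel-size) is statistically
   informative, so `ndf_masked()` scales by the mask fraction and divides
   by the number of included disks. Including more disks adds voxels and
   redundancy in equal measure, leaving the ndf — and hence the reported
   resolution — invariant, which the test suite checks on a helical
   phantom.

`ndf_masked()` floors its result at 4 with a warning: the Fisher variance
$1/(\mathrm{ndf}-3)$ requires $\mathrm{ndf} > 3$, and a mask small enough
to hit the floor is uninformative — its confidence cutoff is then so close
to 1 that no realistic correlation passes, which is the intended failure
mode (degrade to "no resolvable signal", never crash, never report an
optimistic number).

## The one-sided confidence test

With $z = \operatorname{atanh}(r)$ approximately normal with standard
deviation $(\mathrm{ndf}-3)^{-1/2}$ (valid for more than ~25 samples and
$r < 0.95$; the package warns beyond 0.95), shell $k$ is accepted when

$$\mathrm{mFSC}(k) \;\ge\; \tanh\!\big(\operatorname{atanh} t + q_{1-\alpha}\,(\mathrm{ndf}_m(k)-3)^{-1/2}\big),$$

i.e. when the observed correlation is significantly above the threshold
$t$. By monotonicity of $\tanh$ this is identical to requiring the
one-sided lower confidence bound of the observed correlation to reach $t$.
The cutoff is strictly above $t$ for finite ndf and decreases like
$\mathrm{ndf}^{-1/2}$, so CI resolutions are never better than
plain-threshold resolutions. Defaults are $t = 0.143$ and one-sided
$\alpha = 1\%$; $t = 0.5$ is supported, and a two-sided mode simply
replaces $\alpha$ by $\alpha/2$. For orientation, one-sided tail areas are
2.3% at $2\sigma$ and 0.1% at $3\sigma$ (0.3% two-sided at $3\sigma$) —
the package scales in significance levels rather than sigma multiples
because the one-sided test is asymmetric.

**Reading off $k^*$.** "The highest frequency at which the condition
remains fulfilled" is implemented as the end of the *initial contiguous
run* of significant shells: genuine cryo-EM curves decrease
quasi-monotonically, so an isolated high-frequency excursion above the
cutoff is noise and must not inflate the resolution. A strict
global-maximum rule is available (`rule = "global"`) for comparison. If no
shell is significant the result is the explicit "no resolvable signal"
state ($k^* = 0$), not a number.

## Local, segment and helical variants

`local_resolution_map()` evaluates the mFSC in a small cubic box (default
$15^3$ voxels, $\sigma_g = 3$, $\alpha = 1\%$, $t = 0.143$) centred on a
stride grid of voxels, with per-box ndf from the mask-fraction formula. An
$11^3$ box has about 2.5× fewer degrees of freedom and is noticeably
under-powered; $15^3$ is the default for that reason. The band-passed
volumes are computed once per shell and shared across all boxes — by
construction this is exactly equivalent to filtering per box, at two
inverse FFTs per shell total. The default stride of 2 with
nearest-evaluated fill trades run time for map smoothness; stride 1
reproduces per-voxel evaluation. Unevaluated or unresolvable voxels carry
the sentinel 0 alongside an explicit mask of evaluated centers. An
adaptive box size (growing until the ndf supports a stable estimate) would
be a natural extension; the implementation keeps the box fixed and
user-chosen so that the ndf entering every test is transparent.

`segment_resolution()` applies the same machinery to arbitrary
integer-labelled segment masks (e.g. from k-means map segmentation, which
is deliberately out of scope here — segments are inputs). Since segments
follow the structure rather than a box, they contain less solvent and give
the more interpretable local numbers.

`helical_resolution()` builds an axis-centred cylindrical mask whose
height is a whole number of unique disks, `round(n_disks * rise / p)`
pixels (e.g. rise 5.13 Å at 1.24 Å/pixel gives a 4.14-pixel disk and a
33-pixel eight-disk mask), and divides the ndf by `n_disks`. The rounding
lives in the mask height only; the divisor stays the integer disk count.

## The synthetic-data generator

`make_phantom()` + `make_half_pair()` implement the half-map model
directly: shared signal plus two independent Gaussian noise volumes whose
per-shell power is shaped so the *expected unmasked FSC at shell $k$
equals* $\mathrm{ssnr}(k)/(1+\mathrm{ssnr}(k))$ exactly. Shaping is done
per width-1 shell in reciprocal space against the phantom's *measured*
shell power (so arbitrary phantoms calibrate correctly); within a shell
the noise is white. `ssnr = Inf` gives a noise-free band; `ssnr = 0`
removes the signal from the shell entirely and fills it with
reference-level noise. An optional solvent-only noise term reproduces the
empirical pattern that solvent noise exceeds within-particle noise, which
the radial profile of the half-map difference volume
(`half_map_difference()` + `rotational_average_real()`) makes visible.

Three phantom families cover the analysis modes: `blob-ensemble` (globular
particle with a realistic falling spectrum and a compact support),
`shell-limited` (full-volume signal with exactly known spectral content —
the right substrate for profile-recovery and uniform-SSNR tests, because
masking then removes signal and noise in equal proportion), and `helical`
(a blob motif replicated along the axis with a given rise and twist).

What passing tests on these data do *not* show: the generator has no
contrast transfer function, no projection/backprojection or alignment
errors, no map interpolation, and its noise is exactly independent between
half-maps — the very idealizations whose violation in real pipelines
motivates the confidence machinery. Synthetic validation here establishes
the statistical correctness of the estimator under the model, not the
behaviour of refinement artifacts. Two further conditioning notes: the
difference-vs-sum independence diagnostic has few effective degrees of
freedom when the spectrum is steep (the lowest shells dominate), so it is
sharp only on flat-spectrum data; and with concentrated phantoms a masked
mFSC legitimately reads higher than the global FSC target, because the
mask really does exclude solvent noise — that is signal, not bias.

## Problem sizes and numerical tolerances

The validation suite runs at $n = 32$–$64$ with up to 31 shells, 20-seed
loops for distributional claims, and Monte-Carlo ndf runs of $10^4$
iterations at array lengths 256–512 — sizes at which every property has
comfortable statistical margin while the whole suite completes in about a
minute on one CPU. Profile recovery is asserted at RMSE $\le 0.05$ over
shells 2–30 at $n = 64$; band limits at $\pm 1$ shell with $\sigma_g = 1$
and $\pm(2\sigma_g + 1)$ shells where $\sigma_g = 3$ is in play; exact
algebraic identities (sidedness, disk invariance of the ndf, SSNR
round-trip) at machine precision. MRC I/O is float32, so round trips are
exact to single precision. Curve values are clipped to $[-1, 1]$ against
rounding excursions.

## Known limitations

* Cubic, even-sized grids only; no resampling of mismatched geometries.
* Isotropic resolution only — no directional/conical FSC.
* Serial per-shell loop; large maps ($n \gtrsim 256$) with dense local
  grids are better served by coarser strides.
* The ndf model accounts for window, mask and helical-disk effects, not
  for correlations introduced upstream by interpolation or
  maximum-likelihood orientation weighting; to the extent those inflate
  the effective sample size, reported resolutions remain optimistic by the
  same amount as any FSC-based method.
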