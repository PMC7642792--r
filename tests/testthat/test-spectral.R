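# Radius grids, Gaussian band-pass gains, shell partitions, masked
# correlation, prewhitening, rotational averages.

test_that("frequency radius grid matches hand-computed distances", {
  r <- frequency_radius_grid(16)
  expect_equal(r[1, 1, 1], 0)
  expect_equal(r[9, 1, 1], 8)        # (n/2, 0, 0)
  expect_equal(r[4, 5, 1], 5)        # 3-4-5 triangle
  expect_equal(r[1, 2, 1], 1)
  expect_equal(r[16, 1, 1], 1)       # negative frequency -1
})

test_that("gaussian band-pass has the analytic radial gain", {
  n <- 32
  x <- (0:(n - 1))
  wave_k <- function(k) {
    w <- cos(2 * pi * k * x / n)
    em_volume(array(rep(w, n * n), c(n, n, n)))
  }
  v <- wave_k(6)
  out <- gaussian_bandpass(v, k = 6, sigma_g = 1)
  expect_lt(max(abs(out$data - v$data)), 1e-6 * max(abs(v$data)))

  # off-band attenuation at 3 sigma: gain exp(-9/2)
  v9 <- wave_k(9)
  out9 <- gaussian_bandpass(v9, k = 6, sigma_g = 1)
  gain <- max(abs(out9$data)) / max(abs(v9$data))
  expect_equal(gain, exp(-9 / 2), tolerance = 1e-3)
})

test_that("band-passed white noise has power proportional to the squared gain", {
  n <- 32; k0 <- 8; sg <- 2
  set.seed(3)
  v <- em_volume(array(rnorm(n^3), c(n, n, n)))
  filt <- gaussian_bandpass(v, k0, sg)
  p_in <- radial_power_spectrum(v)
  p_out <- radial_power_spectrum(filt)
  ks <- (k0 - 2 * sg):(k0 + 2 * sg)
  ratio <- p_out$power[match(ks, p_out$k)] / p_in$power[match(ks, p_in$k)]
  expect_equal(ratio, exp(-(ks - k0)^2 / sg^2), tolerance = 0.15)
})

test_that("width-1 rectangular shells partition the reciprocal lattice", {
  for (n in c(16, 32)) {
    r <- frequency_radius_grid(n)
    covered <- array(0L, dim(r))
    for (k in seq_len(n / 2))
      covered <- covered + rectangular_shell_mask(n, k, 1, r)
    inside <- r <= n / 2 & r > 0
    expect_true(all(covered[inside] == 1L))
    expect_equal(covered[1, 1, 1], 0L)  # origin in no shell
  }
  # k = 1 shell at n = 16: brute-force count of 0.5 <= r < 1.5
  r <- frequency_radius_grid(16)
  expect_equal(sum(rectangular_shell_mask(16, 1)), sum(r >= 0.5 & r < 1.5))
  # Nyquist shell nonempty
  expect_gt(sum(rectangular_shell_mask(16, 8)), 0)
})

test_that("masked correlation has Pearson structure on the mask support", {
  set.seed(4)
  n <- 16
  a <- em_volume(array(rnorm(n^3), c(n, n, n)))
  m <- make_mask(n, "sphere", diameter = 10)
  expect_equal(masked_correlation(a, a, m), 1.0)
  neg <- em_volume(-a$data)
  expect_equal(masked_correlation(a, neg, m), -1.0)
  # affine invariance b -> alpha b + beta, antisymmetry under negation
  b <- em_volume(array(rnorm(n^3), c(n, n, n)))
  c0 <- masked_correlation(a, b, m)
  expect_equal(masked_correlation(a, em_volume(2.5 * b$data + 3), m), c0)
  expect_equal(masked_correlation(a, em_volume(-b$data), m), -c0)
})

test_that("independent-noise correlation stays within its sampling band", {
  n <- 24
  m <- em_mask(array(1, c(n, n, n)))
  hits <- vapply(1:20, function(s) {
    set.seed(400 + s)
    a <- em_volume(array(rnorm(n^3), c(n, n, n)))
    b <- em_volume(array(rnorm(n^3), c(n, n, n)))
    abs(masked_correlation(a, b, m)) <= 4 / sqrt(n^3)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("degenerate masked input yields 0 with a warning, empty mask errors", {
  n <- 16
  flat <- em_volume(array(1, c(n, n, n)))
  b <- noise_volume(n, 7)
  m <- make_mask(n, "sphere", diameter = 8)
  expect_warning(r <- masked_correlation(flat, b, m), "zero variance")
  expect_equal(r, 0)
  expect_error(masked_correlation(b, b, em_mask(array(0, c(n, n, n)))))
})

test_that("prewhitening flattens an arbitrary colored spectrum", {
  n <- 32
  set.seed(8)
  w <- array(rnorm(n^3), c(n, n, n))
  r <- frequency_radius_grid(n)
  colored <- Re(fft(fft(w) / pmax(r, 1), inverse = TRUE)) / n^3
  pwh <- prewhiten(em_volume(colored))
  ps <- radial_power_spectrum(pwh)
  core <- ps$power[ps$k >= 1 & ps$k <= n / 2]
  expect_lt(max(abs(core / mean(core) - 1)), 1e-6)

  # white noise is already flat and stays so
  pw2 <- radial_power_spectrum(prewhiten(em_volume(w)))
  core2 <- pw2$power[pw2$k >= 1 & pw2$k <= n / 2]
  expect_lt(max(abs(core2 / mean(core2) - 1)), 1e-6)
})

test_that("prewhitening a band-limited volume reports the empty shells", {
  ph <- make_phantom(32, "shell-limited", k1 = 8, seed = 2)
  expect_error(prewhiten(ph$volume), "zero-power shell")
})

test_that("real-space rotational average recovers radial structure", {
  n <- 32
  flat <- em_volume(array(3.5, c(n, n, n)))
  prof <- rotational_average_real(flat)
  expect_true(all(abs(prof$mean - 3.5) < 1e-12))

  # radially symmetric Gaussian blob matches its generating profile
  ax <- seq_len(n) - (n / 2 + 1)
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  blob <- em_volume(exp(-r^2 / (2 * 4^2)))
  prof <- rotational_average_real(blob)
  inner <- prof$radius <= 10
  expect_equal(prof$mean[inner], exp(-prof$radius[inner]^2 / 32), tolerance = 0.05)
})

test_that("solvent-heavy noise shows up in the difference-volume profile", {
  n <- 32
  ph <- make_phantom(n, "blob-ensemble", seed = 11)
  pair <- make_half_pair(ph, ssnr_profile_constant(n, 2), seed = 12,
                         solvent_sd = 2)
  e <- half_map_difference(pair$u, pair$v)
  prof <- rotational_average_real(em_volume(e$data^2))
  support_r <- 0.2 * n       # blobs live inside 0.3n; compare well in vs out
  inner <- mean(prof$mean[prof$radius <= support_r])
  outer_band <- mean(prof$mean[prof$radius > 0.35 * n & prof$radius <= n / 2])
  expect_gt(outer_band, inner)
})
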