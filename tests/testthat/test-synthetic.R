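# Phantom generator, SSNR-calibrated half-map pairs, mask factory.

test_that("phantom generation is deterministic per seed", {
  a <- make_phantom(32, "blob-ensemble", seed = 3)
  b <- make_phantom(32, "blob-ensemble", seed = 3)
  expect_identical(a$volume$data, b$volume$data)
  c <- make_phantom(32, "blob-ensemble", seed = 4)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("shell-limited phantoms have no power beyond the band", {
  ph <- make_phantom(32, "shell-limited", k1 = 12, seed = 1)
  ps <- radial_power_spectrum(ph$volume)
  expect_gt(ps$power[ps$k == 10] / max(ps$power[ps$k == 20], 1e-300), 1e6)
})

test_that("blob-ensemble support occupies a plausible particle fraction", {
  ph <- make_phantom(48, "blob-ensemble", seed = 2)
  frac <- ph$support$count / 48^3
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.25)
  # signal vanishes outside support by construction of the support threshold
  expect_lt(max(ph$volume$data[ph$support$data == 0]) , 0.02 * max(ph$volume$data) + 1e-12)
})

test_that("constant SSNR 1 produces FSC near 0.5 across shells", {
  n <- 64
  ph <- make_phantom(n, "shell-limited", k1 = n / 2, seed = 8)
  pair <- make_half_pair(ph, ssnr_profile_constant(n, 1), seed = 9)
  cv <- suppressWarnings(fsc(pair$u, pair$v))
  sh <- 2:30
  expect_lt(sqrt(mean((cv$value[sh] - 0.5)^2)), 0.05)
})

test_that("zero SSNR leaves no shared signal", {
  n <- 32
  ph <- make_phantom(n, "shell-limited", k1 = n / 2, seed = 10)
  pair <- make_half_pair(ph, ssnr_profile_constant(n, 0), seed = 11)
  cv <- suppressWarnings(fsc(pair$u, pair$v))
  expect_gte(mean(abs(cv$value) <= 4 / sqrt(ndf_rectangular(cv$k))), 0.9)
})

test_that("hard-band profiles give an FSC step at the band limit", {
  n <- 32
  ph <- make_phantom(n, "shell-limited", k1 = n / 2, seed = 12)
  pair <- make_half_pair(ph, ssnr_profile_band(n, 10), seed = 13)
  cv <- suppressWarnings(fsc(pair$u, pair$v))
  expect_true(all(cv$value[1:9] > 0.99))
  expect_true(all(abs(cv$value[12:15]) < 0.3))
})

test_that("requesting finite SSNR where the phantom has no power errors", {
  ph <- make_phantom(32, "shell-limited", k1 = 8, seed = 1)
  expect_error(make_half_pair(ph, ssnr_profile_constant(32, 1), seed = 2),
               "zero power")
})

test_that("injected noise power matches the calibration target", {
  n <- 32
  phi <- sigmoid_phi(n, mid = 8, scale = 2, top = 0.9)
  rel_err <- matrix(NA_real_, 20, 10)
  for (s in 1:20) {
    ph <- make_phantom(n, "shell-limited", k1 = n / 2, seed = 2000 + s)
    profile <- ssnr_profile_from_fsc(phi)
    pair <- make_half_pair(ph, profile, seed = 3000 + s)
    e <- half_map_difference(pair$u, pair$v)
    # E[|FT(e)|^2] per shell = injected noise power / 2
    pe <- radial_power_spectrum(e)
    pf <- radial_power_spectrum(pair$phantom$volume)
    ks <- 3:12
    target <- pf$power[match(ks, pf$k)] / profile[ks]
    rel_err[s, ] <- pe$power[match(ks, pe$k)] * 2 / target - 1
  }
  expect_lt(max(abs(colMeans(rel_err))), 0.1)
})

test_that("difference and sum of half-maps are uncorrelated over the support", {
  # flat-spectrum pairs: the diagnostic has many effective dof, so the
  # per-seed correlation is tightly centred on zero
  rs <- vapply(1:5, function(s) {
    ph <- make_phantom(32, "shell-limited", k1 = 16, seed = 5000 + s)
    pair <- make_half_pair(ph, ssnr_profile_constant(32, 2), seed = 6000 + s)
    masked_correlation(half_map_difference(pair$u, pair$v),
                       em_volume(pair$u$data + pair$v$data), ph$support)
  }, numeric(1))
  expect_true(all(abs(rs) < 0.05))
})

test_that("mask factory geometry anchors hold", {
  n <- 64
  sph <- make_mask(n, "sphere", diameter = 0.7 * n)
  expect_lt(abs(sph$count / n^3 - 4 / 3 * pi * 0.35^3) / (4 / 3 * pi * 0.35^3),
            0.02)
  expect_equal(round(100 * sph$count / n^3), 18)   # ~18% of the volume

  box <- make_mask(n, "box", side = 15)
  expect_equal(box$count, 3375L)

  soft <- make_mask(n, "soft-sphere", diameter = 20, edge_width = 6)
  b <- binarize_mask(soft, 0.5)
  # binarized radius = cosine-edge midpoint radius +/- 1 voxel
  r_eff <- (3 * b$count / (4 * pi))^(1 / 3)
  expect_lt(abs(r_eff - (10 + 3)), 1)

  cyl <- make_mask(16, "cylinder", radius = 3, height = 5)
  ax <- seq_len(16) - 9
  brute <- sum(outer(sqrt(outer(ax^2, ax^2, `+`)) <= 3,
                     rep(TRUE, 5)))
  expect_equal(cyl$count, brute)
})

test_that("fixture sets write a complete, reloadable directory", {
  dir <- withr::local_tempdir()
  write_fixture_set(dir, n = 32, seed = 5)
  expect_true(all(file.exists(file.path(dir,
    c("half1.mrc", "half2.mrc", "mask.mrc", "signal.mrc", "ground_truth.json")))))
  u <- read_mrc(file.path(dir, "half1.mrc"))
  expect_equal(u$n, 32L)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(length(gt$ssnr), 16)
})
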