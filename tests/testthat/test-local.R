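# Local moving-box maps, segment-focused resolution, helical masks.

test_that("helical unique-disk mask reproduces the canonical geometry", {
  hp <- helical_params(rise = 5.13, pixel_size = 1.24, n_disks = 8, radius = 37)
  expect_equal(round(hp$disk_height, 2), 4.14)
  m <- helical_disk_mask(hp, 96)
  expect_equal(attr(m, "height_px"), 33)
  expect_equal(attr(m, "n_disks"), 8L)

  # minimal cylinder: voxel count equals brute-force lattice count
  hp1 <- helical_params(rise = 3, pixel_size = 1, n_disks = 1, radius = 2)
  m1 <- helical_disk_mask(hp1, 16)
  ax <- seq_len(16) - 9
  expect_equal(m1$count, sum(sqrt(outer(ax^2, ax^2, `+`)) <= 2) * 3)

  expect_error(helical_disk_mask(helical_params(10, 1, 8, 5), 16), "fit")
})

test_that("local map matches the global estimate under uniform SSNR", {
  n <- 48
  pair <- uniform_pair(n, c(rep(0.97, 10), rep(0, n / 2 - 10)),
                       phantom_seed = 20, noise_seed = 21)
  region <- make_mask(n, "sphere", diameter = 14)
  map <- suppressWarnings(local_resolution_map(pair$u, pair$v, region,
                                               box_side = 15, stride = 3,
                                               sigma_g = 3))
  # global reference over the same settings
  mask <- make_mask(n, "sphere", diameter = 0.8 * n)
  cv <- suppressWarnings(mfsc(pair$u, pair$v, mask, sigma_g = 3))
  ndf_k <- suppressWarnings(ndf_masked(cv$k,
    ndf_model(sigma_g = 3, mask_fraction = mask$count / n^3)))
  glob <- determine_resolution(cv, ndf_k, ci_params())
  expect_true(glob$resolvable)

  vals <- map$data$data[region$data > 0]
  k_local <- n * 1 / vals[vals > 0]
  expect_gt(length(k_local), 0)
  expect_gte(mean(abs(k_local - glob$k_star) <= 2), 0.9)
})

test_that("two-compartment phantoms give a bimodal local map", {
  # inner ball band-limited to k_in, surrounding shell to k_out < k_in. With
  # sigma_g = 3 the Gaussian window diffuses each band limit upward by a few
  # shells, so recovery is asserted within that spectral-diffusion width.
  n <- 48
  k_in <- 16; k_out <- 6
  f_in <- make_phantom(n, "shell-limited", k1 = k_in, seed = 30)$volume$data
  f_out <- make_phantom(n, "shell-limited", k1 = k_out, seed = 31)$volume$data
  ax <- seq_len(n) - (n / 2 + 1)
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  inner <- r <= 8
  signal <- ifelse(inner, f_in / stats::sd(f_in), f_out / stats::sd(f_out))
  set.seed(32)
  eps <- 0.35
  u <- em_volume(signal + array(rnorm(n^3, sd = eps), c(n, n, n)))
  v <- em_volume(signal + array(rnorm(n^3, sd = eps), c(n, n, n)))

  # evaluate well inside each compartment so a 9^3 box never straddles both
  region <- em_mask((r <= 3 | (r >= 15 & r <= 18)) * 1)
  map <- suppressWarnings(local_resolution_map(u, v, region, box_side = 9,
                                               stride = 3, sigma_g = 3))
  d <- map$data$data
  inner_vals <- d[r <= 3 & d > 0]
  outer_vals <- d[r >= 15 & r <= 18 & d > 0]
  expect_gt(length(inner_vals), 0)
  expect_gt(length(outer_vals), 0)
  # inner compartment resolves to higher frequency (smaller Angstrom value)
  expect_lt(median(inner_vals), median(outer_vals))
  k_inner <- n / median(inner_vals); k_outer <- n / median(outer_vals)
  expect_gte(k_inner, k_in - 2); expect_lte(k_inner, k_in + 2 * 3 + 1)
  expect_gte(k_outer, k_out - 2); expect_lte(k_outer, k_out + 2 * 3 + 1)
})

test_that("pure-noise pairs give an all-sentinel local map", {
  n <- 32
  region <- make_mask(n, "sphere", diameter = 10)
  all_sentinel <- vapply(1:5, function(s) {
    u <- noise_volume(n, 4000 + s)
    v <- noise_volume(n, 4100 + s)
    map <- suppressWarnings(local_resolution_map(u, v, region, box_side = 11,
                                                 stride = 4, sigma_g = 3))
    all(map$data$data == 0)
  }, logical(1))
  expect_gte(mean(all_sentinel), 0.95)
})

test_that("degenerate local map reduces to the segment result", {
  n <- 32
  pair <- uniform_pair(n, c(rep(0.95, 8), rep(0, n / 2 - 8)),
                       phantom_seed = 40, noise_seed = 41)
  # single evaluated center whose box is the whole region of interest
  center <- n / 2 + 1
  region <- em_mask(local({
    a <- array(0, c(n, n, n)); a[center, center, center] <- 1; a
  }))
  map <- suppressWarnings(local_resolution_map(pair$u, pair$v, region,
                                               box_side = 11, stride = 1,
                                               sigma_g = 3))
  lab <- array(0L, c(n, n, n))
  h <- 5
  lab[(center - h):(center + h), (center - h):(center + h),
      (center - h):(center + h)] <- 1L
  seg <- segment_resolution(pair$u, pair$v, segment_set(lab), sigma_g = 3,
                            k_max = n %/% 2 - 1)
  seg_res <- seg$results[["1"]]
  expect_equal(map$data$data[center, center, center],
               seg_res$resolution_angstrom)
})

test_that("segments with identical SSNR resolve within one shell of each other", {
  n <- 48
  pair <- uniform_pair(n, c(rep(0.97, 12), rep(0, n / 2 - 12)),
                       phantom_seed = 50, noise_seed = 51)
  lab <- array(0L, c(n, n, n))
  lab[8:20, 18:30, 18:30] <- 1L
  lab[28:40, 18:30, 18:30] <- 2L
  sr <- segment_resolution(pair$u, pair$v, segment_set(lab))
  expect_equal(nrow(sr$summary), 2)
  expect_lte(abs(sr$results[["1"]]$k_star - sr$results[["2"]]$k_star), 1)
})

test_that("a union segment's curve lies between its parts at low frequency", {
  n <- 48
  pair <- uniform_pair(n, sigmoid_phi(n, mid = 10, scale = 3),
                       phantom_seed = 52, noise_seed = 53)
  lab <- array(0L, c(n, n, n))
  lab[8:20, 18:30, 18:30] <- 1L
  lab[28:40, 18:30, 18:30] <- 2L
  union_lab <- lab
  union_lab[union_lab > 0] <- 3L
  sr <- segment_resolution(pair$u, pair$v, segment_set(lab), k_max = 10)
  su <- segment_resolution(pair$u, pair$v, segment_set(union_lab), k_max = 10)
  v1 <- sr$results[["1"]]$curve$value
  v2 <- sr$results[["2"]]$curve$value
  vu <- su$results[["3"]]$curve$value
  expect_true(all(vu >= pmin(v1, v2) - 0.1 & vu <= pmax(v1, v2) + 0.1))
})

test_that("degenerate single-voxel segments are flagged, not fatal", {
  n <- 32
  pair <- uniform_pair(n, c(rep(0.95, 8), rep(0, n / 2 - 8)),
                       phantom_seed = 54, noise_seed = 55)
  lab <- array(0L, c(n, n, n))
  lab[16, 16, 16] <- 1L
  sr <- suppressWarnings(segment_resolution(pair$u, pair$v, segment_set(lab),
                                            k_max = 10))
  expect_false(sr$results[["1"]]$resolvable)
})

test_that("helical resolution recovers the band limit and is disk-invariant", {
  n <- 64
  k1 <- 14
  ph <- make_phantom(n, "helical", seed = 60, rise = 4, radius = 14)
  pair <- make_half_pair(ph, ssnr_profile_band(n, k1), seed = 61)
  res <- lapply(c(4, 8), function(nd) {
    hp <- helical_params(rise = 4, pixel_size = 1, n_disks = nd, radius = 14)
    suppressWarnings(helical_resolution(pair$u, pair$v, hp, k_max = 24))
  })
  expect_lte(abs(res[[1]]$k_star - k1), 1)
  expect_lte(abs(res[[2]]$k_star - k1), 1)
  # invariance to the number of included disks
  expect_lte(abs(res[[1]]$k_star - res[[2]]$k_star), 1)
})

test_that("pure-noise filaments are reported unresolvable", {
  n <- 32
  u <- noise_volume(n, 70); v <- noise_volume(n, 71)
  hp <- helical_params(rise = 3, pixel_size = 1, n_disks = 3, radius = 8)
  rr <- suppressWarnings(helical_resolution(u, v, hp, k_max = 12))
  expect_false(rr$resolvable)
})

test_that("local maps export as MRC with resolutions in Angstrom", {
  n <- 32
  pair <- uniform_pair(n, c(rep(0.95, 8), rep(0, n / 2 - 8)),
                       phantom_seed = 80, noise_seed = 81)
  region <- make_mask(n, "sphere", diameter = 8)
  map <- suppressWarnings(local_resolution_map(pair$u, pair$v, region,
                                               box_side = 9, stride = 4,
                                               sigma_g = 3))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_local_map_mrc(map, f)
  back <- read_mrc(f)
  expect_equal(max(back$data), max(map$data$data), tolerance = 1e-6)
})
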