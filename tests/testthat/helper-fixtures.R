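# Shared fixtures, generated once per test run and memoized. All seeds are
# fixed so the suite is deterministic.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# white-noise volume with an optional background offset (cryo-EM maps carry
# a nonzero background; the offset is what lets a multiplicative mask
# imprint its shape on classical FSC curves)
noise_volume <- function(n, seed, offset = 0, pixel_size = 1) {
  set.seed(seed)
  em_volume(array(offset + stats::rnorm(n^3), c(n, n, n)), pixel_size)
}

# uniform-SSNR half-map pair: full-volume band-unlimited signal so that a
# mask removes signal and noise in equal proportion
uniform_pair <- function(n, phi, phantom_seed, noise_seed) {
  ph <- make_phantom(n, "shell-limited", k1 = n / 2, seed = phantom_seed)
  make_half_pair(ph, ssnr_profile_from_fsc(phi), seed = noise_seed)
}

# sigmoid target FSC profile used by the recovery tests
sigmoid_phi <- function(n, mid = 18, scale = 3, top = 0.95) {
  top / (1 + exp((seq_len(n / 2) - mid) / scale))
}

fix_recovery_pair <- function() fixture("recovery_pair", function() {
  uniform_pair(64, sigmoid_phi(64), phantom_seed = 5, noise_seed = 6)
})

fix_generous_mask64 <- function() fixture("generous_mask64", function() {
  make_mask(64, "sphere", diameter = 0.7 * 64)
})

fix_band_pair <- function() fixture("band_pair", function() {
  ph <- make_phantom(64, "shell-limited", k1 = 32, seed = 5)
  make_half_pair(ph, ssnr_profile_band(64, 20), seed = 7)
})

fix_blob_mask48 <- function() fixture("blob_mask48", function() {
  make_phantom(48, "blob-ensemble", seed = 99)$support
})
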