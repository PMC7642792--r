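# Synthetic phantoms, masks, and half-map pairs with controlled per-shell
# SSNR, following the half-map image-formation model u = f + r1, v = f + r2
# with shared signal f and independent noise realizations. Noise is shaped
# per width-1 reciprocal shell against the phantom's *measured* shell power,
# so the expected FSC at shell k equals ssnr(k) / (1 + ssnr(k)) exactly for
# arbitrary phantoms.

#' Constant per-shell SSNR profile
#' @param n grid size (profile covers shells 1..n/2).
#' @param ssnr constant SSNR value (>= 0, may be `Inf`).
#' @return Numeric vector of length n/2.
#' @export
ssnr_profile_constant <- function(n, ssnr) rep(ssnr, n / 2)

#' Hard-band SSNR profile
#'
#' Noise-free (`Inf`) up to shell `k1`, zero beyond: the expected FSC is 1
#' then 0 with a transition at `k1`, which pins the true resolution for
#' recovery tests.
#'
#' @param n grid size.
#' @param k1 last noise-free shell.
#' @return Numeric vector of length n/2.
#' @export
ssnr_profile_band <- function(n, k1) {
  ifelse(seq_len(n / 2) <= k1, Inf, 0)
}

#' SSNR profile from a target FSC curve
#' @param phi per-shell FSC values in \[0, 1\], length n/2.
#' @return SSNR profile `phi / (1 - phi)`.
#' @export
ssnr_profile_from_fsc <- function(phi) {
  if (any(phi < 0 | phi > 1)) stop("target FSC must lie in [0, 1]", call. = FALSE)
  ifelse(phi >= 1, Inf, phi / (1 - phi))
}

#' Generate a deterministic test phantom
#'
#' Three phantom families stand in for experimental maps:
#' * `"blob-ensemble"`: a sum of randomly placed smooth Gaussian blobs
#'   inside a centred sphere — a generic globular particle with realistic
#'   falling power spectrum. Support = voxels above 2% of the maximum.
#' * `"shell-limited"`: white noise sharply band-limited to shells
#'   `k <= k1` — full-volume signal with exactly known spectral content.
#' * `"helical"`: a blob motif confined to one axial disk of height
#'   `rise / pixel_size` voxels, replicated along z with that rise (and an
#'   optional twist per subunit), inside a cylinder — a filament with exact
#'   axial repeat for unique-disk masking tests.
#'
#' @param n even grid size >= 32 (>= 16 accepted for quick checks).
#' @param kind one of `"blob-ensemble"`, `"shell-limited"`, `"helical"`.
#' @param seed RNG seed; identical seeds give identical phantoms.
#' @param k1 band limit for `"shell-limited"` (default `n/4`).
#' @param n_blobs number of blobs (default 40).
#' @param blob_sigma blob width range in voxels (default `c(1.5, 3.5)`).
#' @param rise,twist,radius helical parameters: axial rise in Angstrom per
#'   subunit, twist in degrees per subunit (default 101.15), cylinder
#'   radius in pixels (default `0.3 * n`).
#' @param pixel_size voxel size in Angstrom (default 1).
#' @return A `phantom`: list with `volume` ([em_volume()]), `support`
#'   ([em_mask()]), `kind`, `seed`, and helical metadata when applicable.
#' @export
make_phantom <- function(n, kind = c("blob-ensemble", "shell-limited", "helical"),
                         seed = 1, k1 = n / 4, n_blobs = 40,
                         blob_sigma = c(1.5, 3.5), rise = 5.13, twist = 101.15,
                         radius = 0.3 * n, pixel_size = 1) {
  kind <- match.arg(kind)
  if (n %% 2L != 0L || n < 16) stop("`n` must be even and >= 16", call. = FALSE)
  set.seed(seed)
  ax <- seq_len(n) - (n / 2 + 1)
  helical_meta <- NULL

  if (kind == "shell-limited") {
    noise <- array(stats::rnorm(n^3), c(n, n, n))
    ft <- stats::fft(noise)
    r <- frequency_radius_grid(n)
    ft[r > k1 + 0.5 | r < 0.5] <- 0        # sharp band, DC removed
    dat <- Re(stats::fft(ft, inverse = TRUE)) / n^3
    support <- em_mask(array(1, c(n, n, n)), pixel_size)
  } else if (kind == "blob-ensemble") {
    dat <- array(0, c(n, n, n))
    rmax <- 0.3 * n
    centers <- matrix(NA_real_, n_blobs, 3)
    i <- 0
    while (i < n_blobs) {
      p <- stats::runif(3, -rmax, rmax)
      if (sum(p^2) <= rmax^2) { i <- i + 1; centers[i, ] <- p }
    }
    sig <- stats::runif(n_blobs, blob_sigma[1], blob_sigma[2])
    amp <- stats::runif(n_blobs, 0.5, 1)
    for (b in seq_len(n_blobs)) {
      gx <- exp(-(ax - centers[b, 1])^2 / (2 * sig[b]^2))
      gy <- exp(-(ax - centers[b, 2])^2 / (2 * sig[b]^2))
      gz <- exp(-(ax - centers[b, 3])^2 / (2 * sig[b]^2))
      dat <- dat + amp[b] * outer(outer(gx, gy), gz)
    }
    support <- em_mask((dat > 0.02 * max(dat)) * 1, pixel_size)
  } else { # helical
    disk_height <- rise / pixel_size
    n_sub <- ceiling(n / disk_height) + 4
    m_idx <- seq(-ceiling(n_sub / 2), ceiling(n_sub / 2))
    blobs_per_disk <- 6
    br <- stats::runif(blobs_per_disk, 0.2, 0.8) * radius
    bphi <- stats::runif(blobs_per_disk, 0, 2 * pi)
    bz <- stats::runif(blobs_per_disk, -disk_height / 2, disk_height / 2)
    bsig <- stats::runif(blobs_per_disk, 1.2, 2.2)
    dat <- array(0, c(n, n, n))
    for (m in m_idx) {
      rot <- m * twist * pi / 180
      for (b in seq_len(blobs_per_disk)) {
        cx <- br[b] * cos(bphi[b] + rot)
        cy <- br[b] * sin(bphi[b] + rot)
        cz <- bz[b] + m * disk_height
        if (cz < -n / 2 - 4 || cz > n / 2 + 4) next
        gx <- exp(-(ax - cx)^2 / (2 * bsig[b]^2))
        gy <- exp(-(ax - cy)^2 / (2 * bsig[b]^2))
        gz <- exp(-(ax - cz)^2 / (2 * bsig[b]^2))
        dat <- dat + outer(outer(gx, gy), gz)
      }
    }
    rxy <- sqrt(outer(ax^2, ax^2, `+`))
    cylinder <- array(rep(rxy <= radius, n), c(n, n, n)) * 1
    dat <- dat * cylinder
    support <- em_mask(cylinder, pixel_size)
    helical_meta <- list(rise = rise, twist = twist, radius = radius,
                         disk_height = disk_height)
  }

  structure(list(volume = em_volume(dat, pixel_size), support = support,
                 kind = kind, seed = seed, helical = helical_meta),
            class = "phantom")
}

#' Generate a half-map pair with a prescribed per-shell SSNR
#'
#' Returns `u = f + r1`, `v = f + r2`: the shared phantom signal plus two
#' independent Gaussian noise volumes whose per-shell power is shaped so
#' the expected unmasked FSC at shell `k` equals
#' `ssnr(k) / (1 + ssnr(k))`. Shaping uses the phantom's measured shell
#' power: the noise shell power is set exactly to `P_f(k) / ssnr(k)`.
#' `ssnr = Inf` gives a noise-free band; `ssnr = 0` removes the signal
#' from that shell entirely and fills it with reference-level noise (the
#' mean signal shell power), so no shared component remains.
#'
#' Optionally, solvent-only noise (`solvent_sd` times the overall noise
#' scale, added outside the phantom support independently per half-map)
#' emulates the empirical observation that solvent noise exceeds
#' within-particle noise. It perturbs the exact per-shell calibration and
#' is off by default.
#'
#' @param phantom a [make_phantom()] result.
#' @param profile per-shell SSNR values for k = 1..n/2 (nonnegative,
#'   `Inf` allowed).
#' @param seed RNG seed for the noise.
#' @param solvent_sd extra solvent-only noise level relative to the mean
#'   shaped-noise sd (default 0 = none).
#' @return List with `u`, `v` ([em_volume()]s), `phantom`, `profile`,
#'   `seed`.
#' @section Errors: shells where the phantom has (numerically) zero power
#'   but a finite positive SSNR is requested are impossible to calibrate
#'   and raise an error naming the shells.
#' @export
make_half_pair <- function(phantom, profile, seed = 1, solvent_sd = 0) {
  stopifnot(inherits(phantom, "phantom"))
  n <- phantom$volume$n
  if (length(profile) != n / 2)
    stop("`profile` must have length n/2 = ", n / 2, call. = FALSE)
  if (any(profile < 0)) stop("SSNR values must be nonnegative", call. = FALSE)
  set.seed(seed)

  F <- stats::fft(phantom$volume$data)
  idx <- shell_index_grid(n)
  ks <- seq_len(n / 2)
  Pf <- vapply(ks, function(k) sum(Mod(F[idx == k])^2), numeric(1))

  finite_pos <- is.finite(profile) & profile > 0
  eps <- 1e-12 * max(Pf)
  bad <- which(finite_pos & Pf <= eps)
  if (length(bad))
    stop("phantom has zero power at shell(s) ", paste(bad, collapse = ", "),
         " but finite SSNR requested there", call. = FALSE)

  base_power <- mean(Pf[Pf > eps])      # reference noise level for ssnr = 0
  target_noise <- numeric(n / 2)
  kill_signal <- logical(n / 2)
  for (k in ks) {
    if (is.infinite(profile[k])) {
      target_noise[k] <- 0
    } else if (profile[k] == 0) {
      kill_signal[k] <- TRUE
      target_noise[k] <- base_power
    } else {
      target_noise[k] <- Pf[k] / profile[k]
    }
  }

  if (any(kill_signal)) F[idx %in% ks[kill_signal]] <- 0
  f <- Re(stats::fft(F, inverse = TRUE)) / n^3

  shape_noise <- function() {
    w <- stats::rnorm(n^3)
    W <- stats::fft(array(w, c(n, n, n)))
    scale <- array(0, dim(W))           # DC and unlisted shells get no noise
    for (k in ks) {
      sel <- idx == k
      pw <- sum(Mod(W[sel])^2)
      if (pw > 0 && target_noise[k] > 0)
        scale[sel] <- sqrt(target_noise[k] / pw)
    }
    # corner shells (r > n/2) continue the Nyquist-shell noise density
    corner <- idx > n / 2
    if (any(corner)) {
      k_ny <- n / 2
      dens <- if (target_noise[k_ny] > 0)
        target_noise[k_ny] / sum(idx == k_ny) else 0
      pw_c <- Mod(W[corner])^2
      scale[corner] <- ifelse(pw_c > 0, sqrt(dens / mean(pw_c)), 0)
    }
    Re(stats::fft(W * scale, inverse = TRUE)) / n^3
  }

  r1 <- shape_noise()
  r2 <- shape_noise()
  if (solvent_sd > 0) {
    outside <- phantom$support$data == 0
    lvl <- solvent_sd * stats::sd(c(r1))
    r1[outside] <- r1[outside] + stats::rnorm(sum(outside), sd = lvl)
    r2[outside] <- r2[outside] + stats::rnorm(sum(outside), sd = lvl)
  }

  list(u = em_volume(f + r1, phantom$volume$pixel_size),
       v = em_volume(f + r2, phantom$volume$pixel_size),
       phantom = phantom, profile = profile, seed = seed)
}

#' Generate standard analysis masks
#'
#' @param n grid size.
#' @param kind one of `"sphere"`, `"soft-sphere"`, `"blob-support"`,
#'   `"cylinder"`, `"box"`.
#' @param diameter sphere diameter in voxels (default `0.7 * n`, the
#'   conventional particle-window relation; such a sphere occupies about
#'   18% of the volume).
#' @param edge_width cosine fall-off width in voxels for `"soft-sphere"`
#'   (default 5): weight 1 inside `diameter/2`, falling as
#'   `0.5 (1 + cos(pi d / edge_width))` to 0 over the edge.
#' @param phantom a [make_phantom()] result for `"blob-support"`.
#' @param dilate dilation radius in voxels for `"blob-support"` (default 0).
#' @param radius,height cylinder radius and height in voxels.
#' @param side,center box side (voxels) and center (3-vector, defaults to
#'   the volume center).
#' @param pixel_size voxel size in Angstrom.
#' @return An [em_mask()].
#' @export
make_mask <- function(n, kind = c("sphere", "soft-sphere", "blob-support",
                                  "cylinder", "box"),
                      diameter = 0.7 * n, edge_width = 5, phantom = NULL,
                      dilate = 0, radius = 0.3 * n, height = n / 2,
                      side = 15, center = NULL, pixel_size = 1) {
  kind <- match.arg(kind)
  ax <- seq_len(n) - (n / 2 + 1)
  dat <- switch(kind,
    "sphere" = {
      r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
      (r <= diameter / 2) * 1
    },
    "soft-sphere" = {
      r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
      d <- r - diameter / 2
      w <- ifelse(d <= 0, 1, ifelse(d >= edge_width, 0,
                                    0.5 * (1 + cos(pi * d / edge_width))))
      w
    },
    "blob-support" = {
      stopifnot(inherits(phantom, "phantom"))
      m <- phantom$support$data
      if (dilate > 0) {
        # dilation via Fourier convolution with a ball, thresholded
        ball <- (sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`)) <= dilate) * 1
        conv <- Re(stats::fft(stats::fft(m) *
                              stats::fft(ball[c((n/2+1):n, 1:(n/2)),
                                              c((n/2+1):n, 1:(n/2)),
                                              c((n/2+1):n, 1:(n/2))]),
                              inverse = TRUE)) / n^3
        m <- (conv > 0.5) * 1
      }
      m
    },
    "cylinder" = {
      rxy <- sqrt(outer(ax^2, ax^2, `+`))
      height <- round(height)
      z0 <- floor((n - height) / 2) + 1
      zin <- seq_len(n) >= z0 & seq_len(n) < z0 + height
      outer(rxy <= radius, zin) * 1
    },
    "box" = {
      if (is.null(center)) center <- rep(n / 2 + 1, 3)
      m <- array(0, c(n, n, n))
      h <- (side - 1) / 2
      rng <- function(c0) max(1, round(c0 - h)):min(n, round(c0 + h))
      m[rng(center[1]), rng(center[2]), rng(center[3])] <- 1
      m
    })
  if (sum(dat > 0) == 0) stop("mask construction produced an empty mask", call. = FALSE)
  em_mask(dat, pixel_size)
}

#' Half-map difference noise estimate
#'
#' `e = (u - v) / 2`: under the shared-signal model the signal cancels and
#' `e` estimates one half-map's noise. Its per-shell power should match the
#' injected noise power, and its correlation with the sum `u + v` over the
#' support should vanish if noise is uncorrelated with signal.
#'
#' @param u,v half-map [em_volume()]s.
#' @return An `em_volume` holding the noise estimate.
#' @export
half_map_difference <- function(u, v) {
  check_same_geometry(u, v)
  em_volume((u$data - v$data) / 2, u$pixel_size)
}

#' Write a complete synthetic fixture set to a directory
#'
#' Writes half-maps (`half1.mrc`, `half2.mrc`), a generous binary
#' sphere mask (`mask.mrc`), the phantom signal (`signal.mrc`), and
#' `ground_truth.json` recording the SSNR profile, the implied FSC, seeds
#' and geometry.
#'
#' @param dir output directory (created if needed).
#' @param n grid size (default 64).
#' @param kind phantom kind (default `"blob-ensemble"`).
#' @param profile SSNR profile (default: implied FSC 0.9 falling linearly
#'   to 0 at Nyquist).
#' @param seed RNG seed.
#' @param pixel_size voxel size in Angstrom.
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(dir, n = 64, kind = "blob-ensemble",
                              profile = NULL, seed = 1, pixel_size = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(profile)) {
    phi <- pmax(0, 0.9 * (1 - seq_len(n / 2) / (n / 2)))
    profile <- ssnr_profile_from_fsc(phi)
  }
  ph <- make_phantom(n, kind, seed = seed, pixel_size = pixel_size)
  pair <- make_half_pair(ph, profile, seed = seed + 1)
  write_mrc(pair$u, file.path(dir, "half1.mrc"))
  write_mrc(pair$v, file.path(dir, "half2.mrc"))
  write_mrc(ph$volume, file.path(dir, "signal.mrc"))
  write_mrc(make_mask(n, "sphere", diameter = 0.7 * n,
                      pixel_size = pixel_size),
            file.path(dir, "mask.mrc"))
  jsonlite::write_json(list(n = n, pixel_size = pixel_size, kind = kind,
                            phantom_seed = seed, noise_seed = seed + 1,
                            ssnr = profile,
                            fsc = ifelse(is.infinite(profile), 1,
                                         profile / (1 + profile))),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
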