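# Local (moving-box), segment-focused, and helical resolution.
#
# All three reuse one optimization: the Gaussian band-passed half-maps are
# computed once per shell (two inverse FFTs per shell, identical to the
# global mFSC cost) and shared across every box, segment or cylinder; each
# region then only pays for a masked correlation. Results are identical to
# filtering per region because the filter does not depend on the mask.

# Precompute band-passed u and v for shells 1..k_max; returns list of
# k -> list(u =, v =) raw arrays.
bandpassed_stack <- function(u, v, sigma_g, k_max) {
  U <- stats::fft(u$data); V <- stats::fft(v$data)
  radius <- frequency_radius_grid(u$n)
  lapply(seq_len(k_max), function(k) list(
    u = gaussian_bandpass(U, k, sigma_g, radius),
    v = gaussian_bandpass(V, k, sigma_g, radius)))
}

# mFSC curve over a logical selector, using a precomputed stack.
curve_from_stack <- function(stack, sel, n, pixel_size, sigma_g, center = TRUE) {
  val <- vapply(stack, function(s)
    suppressWarnings(.correlation_vec(s$u[sel], s$v[sel], center)), numeric(1))
  new_fsc_curve(seq_along(stack), val, method = "mfsc", n = n,
                pixel_size = pixel_size, sigma_g = sigma_g,
                mask_count = sum(sel))
}

#' Local resolution map by moving-box mFSC
#'
#' Evaluates an mFSC curve inside a small cubic box centred on a grid of
#' voxels within `region`, applies the one-sided CI resolution test with
#' the box's own ndf (`ndf_masked` with mask fraction `box_side^3 / n^3`),
#' and stores the resulting resolution (Angstrom) at each voxel. Because
#' the per-box ndf is small, the CI cutoff is high, which protects against
#' the spurious high-resolution values that plain-threshold local FSC
#' produces in small windows.
#'
#' Centers are visited every `stride` voxels (where the box fits inside
#' the volume); voxels between evaluated centers take the value of the
#' nearest evaluated center. Voxels outside `region`, or where no shell is
#' significant, carry the sentinel 0.
#'
#' @param u,v half-map [em_volume()]s.
#' @param region binary [em_mask()] selecting where to evaluate.
#' @param box_side odd box edge in voxels (default 15; 11 has ~2.5x fewer
#'   ndf and is under-powered).
#' @param stride spacing of evaluated centers in voxels (default 2).
#' @param sigma_g Gaussian window width (default 3 for local work).
#' @param params a [ci_params()].
#' @param k_max highest shell (default `n/2 - 1`).
#' @return A `local_resolution_map`: list with `data` ([em_volume()] of
#'   resolutions in Angstrom, 0 = not evaluated/not resolvable),
#'   `evaluated` (mask of evaluated centers), and the analysis settings.
#' @export
local_resolution_map <- function(u, v, region, box_side = 15, stride = 2,
                                 sigma_g = 3, params = ci_params(),
                                 k_max = NULL) {
  stopifnot(inherits(u, "em_volume"), inherits(v, "em_volume"),
            inherits(region, "em_mask"))
  check_same_geometry(u, v)
  check_same_geometry(u, region, "volume and region")
  n <- u$n
  if (box_side >= n) stop("`box_side` must be smaller than the grid", call. = FALSE)
  if (box_side < 5 || box_side %% 2 == 0)
    stop("`box_side` must be odd and >= 5", call. = FALSE)
  if (region$count == 0) stop("empty region", call. = FALSE)
  if (is.null(k_max)) k_max <- n %/% 2L - 1L

  h <- (box_side - 1L) / 2L
  stack <- bandpassed_stack(u, v, sigma_g, k_max)
  model <- ndf_model(sigma_g = sigma_g, n = n,
                     mask_fraction = box_side^3 / n^3)
  ndf_k <- suppressWarnings(ndf_masked(seq_len(k_max), model))

  # stride grid of candidate centers where the box fits
  cand <- seq(h + 1L, n - h, by = stride)
  reg <- region$data > 0
  res_at <- array(NA_real_, c(length(cand), length(cand), length(cand)))
  evaluated <- array(0, c(n, n, n))
  out <- array(0, c(n, n, n))

  dummy_curve_meta <- list(n = n, p = u$pixel_size)
  for (iz in seq_along(cand)) for (iy in seq_along(cand)) for (ix in seq_along(cand)) {
    cx <- cand[ix]; cy <- cand[iy]; cz <- cand[iz]
    if (!reg[cx, cy, cz]) next
    xr <- (cx - h):(cx + h); yr <- (cy - h):(cy + h); zr <- (cz - h):(cz + h)
    val <- vapply(stack, function(s)
      suppressWarnings(.correlation_vec(c(s$u[xr, yr, zr]),
                                        c(s$v[xr, yr, zr]))), numeric(1))
    cv <- new_fsc_curve(seq_len(k_max), val, "mfsc", n, u$pixel_size,
                        sigma_g = sigma_g, mask_count = box_side^3)
    rr <- determine_resolution(cv, ndf_k, params)
    res_at[ix, iy, iz] <- if (rr$resolvable) rr$resolution_angstrom else 0
    evaluated[cx, cy, cz] <- 1
  }

  # nearest-evaluated fill: snap every region voxel to the nearest candidate
  # center along each axis; if that center was not evaluated (outside the
  # region), the voxel keeps the sentinel.
  nearest <- function(x) {
    i <- pmax(1L, pmin(length(cand), round((x - cand[1]) / stride) + 1L))
    i
  }
  regi <- which(reg, arr.ind = TRUE)
  vals <- res_at[cbind(nearest(regi[, 1]), nearest(regi[, 2]), nearest(regi[, 3]))]
  vals[is.na(vals)] <- 0
  out[regi] <- vals

  structure(list(
    data = em_volume(out, u$pixel_size),
    evaluated = em_mask(evaluated, u$pixel_size),
    box_side = box_side, stride = stride, sigma_g = sigma_g,
    params = params, ndf_per_k = ndf_k, k_max = k_max
  ), class = "local_resolution_map")
}

#' @export
print.local_resolution_map <- function(x, ...) {
  v <- x$data$data[x$data$data > 0]
  cat(sprintf("<local_resolution_map> box %d^3, stride %d, sigma_g %g; %d evaluated centers\n",
              x$box_side, x$stride, x$sigma_g, x$evaluated$count))
  if (length(v))
    cat(sprintf("  resolution range %.2f - %.2f A (mean %.2f A over %d voxels)\n",
                min(v), max(v), mean(v), length(v)))
  else cat("  no resolvable voxels\n")
  invisible(x)
}

#' Segment-focused resolution
#'
#' Computes one mFSC curve and CI resolution per labelled segment, with
#' per-segment ndf from the segment's own voxel count. Band-passed volumes
#' are shared across segments. Empty labels are skipped with a warning.
#'
#' @param u,v half-map [em_volume()]s.
#' @param segments a [segment_set()] (integer-labelled volume, 0 =
#'   background).
#' @param sigma_g Gaussian window width (default 3).
#' @param params a [ci_params()].
#' @param k_max highest shell (default `n/2 - 1`).
#' @return List with `summary` (tibble: label, voxels, k_star,
#'   resolution_angstrom, resolvable) and `results` (named list of
#'   `resolution_result`s keyed by label).
#' @export
segment_resolution <- function(u, v, segments, sigma_g = 3,
                               params = ci_params(), k_max = NULL) {
  stopifnot(inherits(segments, "segment_set"))
  check_same_geometry(u, v)
  if (u$n != segments$n) stop("segment volume geometry mismatch", call. = FALSE)
  n <- u$n
  if (is.null(k_max)) k_max <- n %/% 2L - 1L
  stack <- bandpassed_stack(u, v, sigma_g, k_max)

  labels <- as.integer(names(segments$counts))
  results <- list()
  rows <- list()
  for (lb in labels) {
    sel <- segments$labels == lb
    cnt <- sum(sel)
    if (cnt == 0) {
      warning("segment ", lb, " is empty; skipped", call. = FALSE)
      next
    }
    cv <- curve_from_stack(stack, sel, n, u$pixel_size, sigma_g)
    model <- ndf_model(sigma_g = sigma_g, n = n, mask_fraction = cnt / n^3)
    ndf_k <- suppressWarnings(ndf_masked(cv$k, model))
    rr <- determine_resolution(cv, ndf_k, params)
    results[[as.character(lb)]] <- rr
    rows[[as.character(lb)]] <- tibble::tibble(
      label = lb, voxels = cnt, k_star = rr$k_star,
      resolution_angstrom = rr$resolution_angstrom,
      resolvable = rr$resolvable)
  }
  list(summary = do.call(rbind, rows), results = results)
}

#' Helical analysis parameters
#'
#' @param rise axial rise per asymmetric unit in Angstrom.
#' @param pixel_size voxel size in Angstrom.
#' @param n_disks number of unique disks to include in the mask (>= 1).
#' @param radius cylinder radius in pixels.
#' @return A `helical_params` list; `disk_height` is `rise / pixel_size`
#'   pixels.
#' @examples
#' helical_params(rise = 5.13, pixel_size = 1.24, n_disks = 8, radius = 37)
#' @export
helical_params <- function(rise, pixel_size, n_disks = 8, radius) {
  if (rise <= 0 || pixel_size <= 0) stop("rise and pixel_size must be positive", call. = FALSE)
  if (n_disks < 1) stop("`n_disks` must be >= 1", call. = FALSE)
  if (radius < 1) stop("`radius` must be >= 1 pixel", call. = FALSE)
  structure(list(rise = rise, pixel_size = pixel_size,
                 n_disks = as.integer(n_disks), radius = radius,
                 disk_height = rise / pixel_size), class = "helical_params")
}

#' Cylindrical unique-disk mask for helical assemblies
#'
#' An axis-centred cylinder of the given radius whose height is
#' `round(n_disks * rise / pixel_size)` pixels: an integer number of
#' helical "unique disks" (axial slabs of one asymmetric unit each).
#' Restricting the mask to whole disks minimizes the fractional-disk
#' truncation problem; the statistical redundancy of the disks beyond the
#' first is compensated downstream by dividing the ndf by `n_disks`.
#'
#' @param params a [helical_params()].
#' @param n grid size.
#' @return An [em_mask()] with attributes `disk_height` (pixels, not
#'   rounded), `n_disks`, and `height_px` (rounded total height).
#' @examples
#' hp <- helical_params(5.13, 1.24, 8, 37)
#' m <- helical_disk_mask(hp, 96)
#' attr(m, "height_px")  # 33
#' @export
helical_disk_mask <- function(params, n) {
  stopifnot(inherits(params, "helical_params"))
  height_px <- round(params$n_disks * params$disk_height)
  if (height_px > n || 2 * params$radius > n)
    stop("cylinder (radius ", params$radius, ", height ", height_px,
         " px) does not fit in a ", n, "^3 volume", call. = FALSE)
  m <- make_mask(n, "cylinder", radius = params$radius, height = height_px,
                 pixel_size = params$pixel_size)
  attr(m, "disk_height") <- params$disk_height
  attr(m, "n_disks") <- params$n_disks
  attr(m, "height_px") <- height_px
  m
}

#' Helical-assembly resolution
#'
#' mFSC over the unique-disk cylinder mask with the ndf divided by the
#' number of included disks (helical symmetry makes additional disks
#' statistically redundant, so they add voxels but not information). With
#' the division in place the reported resolution is invariant to how many
#' disks the mask spans.
#'
#' @param u,v half-map [em_volume()]s.
#' @param params a [helical_params()].
#' @param sigma_g Gaussian window width (default 1).
#' @param ci a [ci_params()].
#' @param k_max highest shell (default `n/2 - 1`).
#' @return A `resolution_result` (see [determine_resolution()]); the mask
#'   used is attached as attribute `mask`.
#' @export
helical_resolution <- function(u, v, params, sigma_g = 1, ci = ci_params(),
                               k_max = NULL) {
  check_same_geometry(u, v)
  mask <- helical_disk_mask(params, u$n)
  cv <- mfsc(u, v, mask, sigma_g = sigma_g, k_max = k_max)
  model <- ndf_model(sigma_g = sigma_g, n = u$n,
                     mask_fraction = mask$count / u$n^3,
                     disk_divisor = params$n_disks)
  ndf_k <- suppressWarnings(ndf_masked(cv$k, model))
  rr <- determine_resolution(cv, ndf_k, ci)
  attr(rr, "mask") <- mask
  rr
}

#' Write a local resolution map as MRC
#'
#' Voxel values are resolutions in Angstrom (0 = not evaluated / not
#' resolvable).
#'
#' @param map a `local_resolution_map`.
#' @param path output MRC path.
#' @return `path`, invisibly.
#' @export
write_local_map_mrc <- function(map, path) {
  stopifnot(inherits(map, "local_resolution_map"))
  write_mrc(map$data, path)
}
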