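# Analytical 2D PET acquisition simulator: parallel-beam forward projection
# with attenuation and a projection-space resolution kernel, decay-weighted
# Poisson count statistics, uniform additive scatter, and filtered
# back-projection reconstruction with attenuation/scatter correction. This
# is a documented simplified stand-in for a full system-matrix simulator;
# single slices through the lesion centers are the analysis surface.

#' PET acquisition parameters
#'
#' @param frame_interval time-activity sampling interval, s.
#' @param scan_duration total acquisition time, s; must be a positive
#'   multiple of `frame_interval`.
#' @param injected_dose injected activity, mCi.
#' @param delay_to_scan time between injection and scan start, s.
#' @param half_life radioisotope half-life, s.
#' @param positron_yield positron branching fraction.
#' @param scatter_fraction fraction of detected events that are scattered
#'   (randoms folded in), in `[0, 0.5)`.
#' @param sensitivity counts per (activity unit x mm x s); the calibration
#'   constant relating line integrals of activity to detected counts. See
#'   [calibrate_sensitivity()].
#' @return object of class `acquisition_params`.
#' @export
acquisition_params <- function(frame_interval = 120, scan_duration = 1200,
                               injected_dose = 10, delay_to_scan = 7200,
                               half_life = 6588, positron_yield = 0.97,
                               scatter_fraction = 0.15, sensitivity = 1) {
  stopifnot(frame_interval > 0, scan_duration > 0, injected_dose > 0,
            delay_to_scan >= 0, half_life > 0, positron_yield > 0,
            positron_yield <= 1, sensitivity > 0)
  if (scatter_fraction < 0 || scatter_fraction >= 0.5)
    stop("scatter_fraction must lie in [0, 0.5)")
  if (abs(scan_duration / frame_interval -
          round(scan_duration / frame_interval)) > 1e-9)
    stop("scan_duration must be a multiple of frame_interval")
  structure(list(frame_interval = frame_interval,
                 scan_duration = scan_duration,
                 injected_dose = injected_dose,
                 delay_to_scan = delay_to_scan, half_life = half_life,
                 positron_yield = positron_yield,
                 scatter_fraction = scatter_fraction,
                 sensitivity = sensitivity),
            class = "acquisition_params")
}

#' Parallel-beam projection geometry
#'
#' @param n_pixels image side length in pixels (square slice).
#' @param pixel_mm pixel size, mm; radial bins have the same pitch.
#' @param n_angles number of projection angles uniformly covering `[0, pi)`.
#' @return object of class `pet_geometry` with `angles`, `n_bins`,
#'   `bin_mm`, bin center offsets `s_mm`.
#' @export
pet_geometry <- function(n_pixels, pixel_mm, n_angles = 96) {
  stopifnot(n_pixels >= 16, pixel_mm > 0, n_angles >= 8)
  structure(list(
    n_pixels = n_pixels, pixel_mm = pixel_mm, n_angles = n_angles,
    angles = seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)],
    n_bins = n_pixels, bin_mm = pixel_mm,
    s_mm = (seq_len(n_pixels) - (n_pixels + 1) / 2) * pixel_mm),
    class = "pet_geometry")
}

# bilinear sampling of matrix `img` at fractional indices (xi, yi); 0 outside
bilinear_sample <- function(img, xi, yi) {
  nx <- nrow(img); ny <- ncol(img)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  out <- numeric(length(xi))
  at <- function(ix, iy) {
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    v <- numeric(length(ix))
    v[ok] <- img[cbind(ix[ok], iy[ok])]
    v
  }
  out <- at(x0, y0) * (1 - fx) * (1 - fy) +
    at(x0 + 1, y0) * fx * (1 - fy) +
    at(x0, y0 + 1) * (1 - fx) * fy +
    at(x0 + 1, y0 + 1) * fx * fy
  out
}

# plain Radon transform: line integrals (activity x mm), bins x angles
radon_transform <- function(img, geometry) {
  g <- geometry
  stopifnot(nrow(img) == g$n_pixels, ncol(img) == g$n_pixels)
  ctr <- (g$n_pixels + 1) / 2
  s <- g$s_mm / g$pixel_mm           # bin offsets in pixel units
  tt <- s                            # integration steps along the ray
  out <- matrix(0, g$n_bins, g$n_angles)
  for (j in seq_len(g$n_angles)) {
    a <- g$angles[j]
    n1 <- cos(a); n2 <- sin(a)       # bin-offset direction
    d1 <- -sin(a); d2 <- cos(a)      # ray direction
    xi <- ctr + outer(s * n1, tt * d1, "+")
    yi <- ctr + outer(s * n2, tt * d2, "+")
    vals <- bilinear_sample(img, as.vector(xi), as.vector(yi))
    out[, j] <- rowSums(matrix(vals, g$n_bins)) * g$pixel_mm
  }
  out
}

# Gaussian resolution kernel applied along the radial bins of a sinogram
blur_sinogram <- function(sino, geometry, fwhm_mm) {
  if (fwhm_mm <= 0) return(sino)
  sigma <- fwhm_mm / 2.354820045 / geometry$bin_mm
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  apply(sino, 2, function(p) {
    as.numeric(stats::filter(c(rep(0, half), p, rep(0, half)), k,
                             sides = 2))[(half + 1):(half + length(p))]
  })
}

#' Attenuation factors for a slice
#'
#' In PET both annihilation photons must escape, so the attenuation of a
#' coincidence ray is `exp(-integral of mu along the full chord)`,
#' independent of the emission point.
#'
#' @param mu_slice 2D linear-attenuation map, 1/mm.
#' @param geometry a [pet_geometry()].
#' @return matrix of multiplicative attenuation factors (bins x angles).
#' @export
attenuation_factors <- function(mu_slice, geometry) {
  exp(-radon_transform(mu_slice, geometry))
}

#' Forward-project an activity slice into an expected sinogram
#'
#' Line integrals of activity along each (angle, bin) ray, attenuated by
#' the full-chord attenuation factor and smoothed by the system resolution
#' kernel in projection space. Linear in the input activity. Units:
#' activity x mm per unit time per unit sensitivity.
#'
#' @param activity_slice 2D activity map.
#' @param attenuation_map 2D attenuation map congruent with the activity
#'   slice, or NULL for no attenuation.
#' @param geometry a [pet_geometry()].
#' @param fwhm_mm resolution kernel full width at half maximum, mm
#'   (default 4; 0 disables).
#' @return expected true-coincidence sinogram (bins x angles) with the
#'   attenuation-factor matrix attached as attribute `"att"`.
#' @export
forward_project <- function(activity_slice, attenuation_map = NULL,
                            geometry, fwhm_mm = 4) {
  g <- geometry
  if (nrow(activity_slice) != g$n_pixels ||
      ncol(activity_slice) != g$n_pixels)
    stop("activity slice does not match geometry")
  if (any(activity_slice < 0)) stop("negative activity")
  sino <- radon_transform(activity_slice, g)
  att <- NULL
  if (!is.null(attenuation_map)) {
    if (!all(dim(attenuation_map) == dim(activity_slice)))
      stop("attenuation map does not match activity grid")
    att <- attenuation_factors(attenuation_map, g)
    sino <- sino * att
  }
  sino <- blur_sinogram(sino, g, fwhm_mm)
  sino[sino < 0] <- 0
  attr(sino, "att") <- att
  sino
}

#' Expected total-count multiplier of an acquisition
#'
#' Integrates the radioactive decay over the scan window:
#' `sensitivity * injected_dose * positron_yield *
#' (half_life / ln 2) * (2^(-delay/T) - 2^(-(delay+duration)/T))`.
#' With no decay (infinite half-life) this reduces to
#' `sensitivity * dose * yield * duration`.
#'
#' @param acq an [acquisition_params()].
#' @return scalar multiplier converting a unit-time expected sinogram into
#'   expected counts for the whole scan.
#' @export
count_scale <- function(acq) {
  stopifnot(inherits(acq, "acquisition_params"))
  decay_integral <- if (is.infinite(acq$half_life)) acq$scan_duration else
    (acq$half_life / log(2)) *
      (2^(-acq$delay_to_scan / acq$half_life) -
         2^(-(acq$delay_to_scan + acq$scan_duration) / acq$half_life))
  acq$sensitivity * acq$injected_dose * acq$positron_yield * decay_integral
}

#' Sensitivity constant giving a target number of true counts
#'
#' @param trues_unit_sino expected true sinogram per unit time and unit
#'   sensitivity (output of [forward_project()]).
#' @param acq an [acquisition_params()]; its `sensitivity` field is
#'   ignored.
#' @param target_total_counts desired expected true counts for the scan
#'   (default 1e6, a realistic per-slice count level for a 20-min brain
#'   acquisition).
#' @return sensitivity value to store in the acquisition parameters.
#' @export
calibrate_sensitivity <- function(trues_unit_sino, acq,
                                  target_total_counts = 1e6) {
  acq$sensitivity <- 1
  base <- sum(trues_unit_sino) * count_scale(acq)
  if (base <= 0) stop("cannot calibrate on an empty sinogram")
  target_total_counts / base
}

#' Add scatter background and Poisson counting noise
#'
#' The scattered+random background is modeled as a uniform additive mean
#' equal to `scatter_fraction / (1 - scatter_fraction)` times the total
#' trues, spread over all bins; each bin then draws an independent Poisson
#' count. Deterministic for a fixed seed.
#'
#' @param expected_sinogram expected true counts per bin (scan totals).
#' @param acq an [acquisition_params()].
#' @param seed integer seed.
#' @return object of class `sinogram_data`: integer `counts`, the
#'   `scatter_mean` per bin, and the expected trues.
#' @export
add_scatter_and_noise <- function(expected_sinogram, acq, seed = 1) {
  stopifnot(inherits(acq, "acquisition_params"))
  if (any(!is.finite(expected_sinogram)) || any(expected_sinogram < 0))
    stop("expected counts must be finite and non-negative")
  sf <- acq$scatter_fraction
  scatter_mean <- sf / (1 - sf) * sum(expected_sinogram) /
    length(expected_sinogram)
  mean_counts <- expected_sinogram + scatter_mean
  counts <- withr::with_seed(seed,
    stats::rpois(length(mean_counts), as.vector(mean_counts)))
  counts <- matrix(counts, nrow(expected_sinogram))
  structure(list(counts = counts, scatter_mean = scatter_mean,
                 expected_trues = expected_sinogram),
            class = "sinogram_data")
}

# ramp filter with Hann apodization, applied per projection via FFT
fbp_filter_projections <- function(sino, geometry) {
  n <- nrow(sino)
  n_pad <- 2^ceiling(log2(2 * n))
  ds <- geometry$bin_mm
  k <- c(0:(n_pad / 2), (n_pad / 2 - 1):1)
  freq <- k / (n_pad * ds)                     # cycles per mm
  f_nyq <- 1 / (2 * ds)
  h <- freq * (0.5 + 0.5 * cos(pi * freq / f_nyq))
  apply(sino, 2, function(p) {
    pp <- c(p, rep(0, n_pad - n))
    q <- Re(stats::fft(stats::fft(pp) * h, inverse = TRUE)) / n_pad
    q[seq_len(n)]
  })
}

#' Filtered back-projection reconstruction
#'
#' Corrects the measured counts for scatter (known additive mean),
#' attenuation and the count scale, then applies ramp-filtered (Hann
#' apodized) back-projection. The normalization is such that a uniform
#' activity distribution reconstructs to its true level: the filtered
#' projections are integrated over angle with weight `pi / n_angles`.
#'
#' @param sino a `sinogram_data` (or bare counts matrix).
#' @param geometry a [pet_geometry()].
#' @param att attenuation-factor matrix used in the forward model, or NULL.
#' @param scale count-scale multiplier to divide out (see [count_scale()]);
#'   1 leaves the image in count units.
#' @return reconstructed 2D image (activity units when `scale` and `att`
#'   are supplied).
#' @export
reconstruct <- function(sino, geometry, att = NULL, scale = 1) {
  g <- geometry
  counts <- if (inherits(sino, "sinogram_data")) sino$counts else sino
  scatter <- if (inherits(sino, "sinogram_data")) sino$scatter_mean else 0
  if (!is.matrix(counts) || nrow(counts) != g$n_bins ||
      ncol(counts) != g$n_angles)
    stop("sinogram does not match geometry")
  corrected <- (counts - scatter) / scale
  if (!is.null(att)) corrected <- corrected / pmax(att, 1e-6)
  q <- fbp_filter_projections(corrected, g)
  ctr <- (g$n_pixels + 1) / 2
  xs <- (seq_len(g$n_pixels) - ctr) * g$pixel_mm
  img <- matrix(0, g$n_pixels, g$n_pixels)
  x_mat <- matrix(xs, g$n_pixels, g$n_pixels)
  y_mat <- t(x_mat)
  s0 <- g$s_mm[1]; ds <- g$bin_mm
  for (j in seq_len(g$n_angles)) {
    a <- g$angles[j]
    s <- x_mat * cos(a) + y_mat * sin(a)
    fi <- (s - s0) / ds + 1
    i0 <- floor(fi)
    fr <- fi - i0
    ok0 <- i0 >= 1 & i0 <= g$n_bins
    ok1 <- i0 + 1 >= 1 & i0 + 1 <= g$n_bins
    v <- numeric(length(fi))
    qj <- q[, j]
    v[ok0] <- qj[i0[ok0]] * (1 - fr[ok0])
    v[ok1] <- v[ok1] + qj[i0[ok1] + 1] * fr[ok1]
    img <- img + matrix(v, g$n_pixels)
  }
  img * pi / g$n_angles
}

#' Simulate a full PET scan of one or more activity slices
#'
#' Composes forward projection, count scaling, scatter + Poisson noise and
#' reconstruction. Runs are organized in pairs/triples sharing one noise
#' seed: the lesion-free and lesion-bearing slices receive the same seed
#' (so the background noise realization is shared, as required by the
#' negative-contrast SNR definition), and the lesion-only slice is
#' reconstructed without noise to define lesion ROIs.
#'
#' @param activity_slices named list of congruent 2D activity maps, e.g.
#'   `list(lesion_free =, lesion =, lesion_only =)`. A `lesion_only`
#'   element, if present, is reconstructed noiseless.
#' @param mu_slice 2D attenuation map, 1/mm.
#' @param acq an [acquisition_params()].
#' @param geometry a [pet_geometry()]; defaults to the slice dimensions
#'   with 96 angles.
#' @param seed shared noise seed.
#' @param fwhm_mm resolution kernel FWHM, mm.
#' @return named list of reconstructed images, with attribute
#'   `"total_counts"` (named numeric, detected counts per noisy image).
#' @export
simulate_scan <- function(activity_slices, mu_slice, acq,
                          geometry = NULL, seed = 1, fwhm_mm = 4) {
  stopifnot(is.list(activity_slices), length(activity_slices) >= 1,
            inherits(acq, "acquisition_params"))
  n <- nrow(activity_slices[[1]])
  if (is.null(geometry)) geometry <- pet_geometry(n, 1)
  sc <- count_scale(acq)
  out <- vector("list", length(activity_slices))
  names(out) <- names(activity_slices)
  counts_tot <- stats::setNames(rep(NA_real_, length(out)), names(out))
  for (nm in names(activity_slices)) {
    trues <- forward_project(activity_slices[[nm]], mu_slice, geometry,
                             fwhm_mm = fwhm_mm)
    att <- attr(trues, "att")
    expected <- trues * sc
    if (identical(nm, "lesion_only")) {
      img <- reconstruct(expected, geometry, att = att, scale = sc)
    } else {
      sino <- add_scatter_and_noise(expected, acq, seed = seed)
      counts_tot[nm] <- sum(sino$counts)
      img <- reconstruct(sino, geometry, att = att, scale = sc)
    }
    out[[nm]] <- img
  }
  attr(out, "total_counts") <- counts_tot
  out
}
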