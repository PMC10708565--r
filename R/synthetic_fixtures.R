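# Synthetic paired-form fixtures.
#
# Real paired-form spectra of cooked-meat dishes are rarely distributable,
# so every pipeline stage is exercised on generated data with known ground
# truth: two physical forms of the same sample set related by a smooth
# band-wise affine distortion (the form map), plus per-sample multiplicative
# scatter, a per-sample smooth heterogeneity wiggle on the full form (intact
# samples are less uniform than crushed ones) and white noise. Absorption
# peaks sit at the six locations where meat spectra show O-H/N-H/C-H
# overtone bands, and their depths are affine in the reference TVC so the
# microbial load is spectrally encoded.

#' Fixture generator configuration
#'
#' Defaults state the emulated world: 100 samples on a 256-band 885-1735 nm
#' grid, TVC drawn uniformly over 2.1347-3.8808 log10 CFU/g, absorption
#' peaks at 944/980/1076/1186/1264/1455 nm, the full form noisier and less
#' uniform than the crushed form, and a band-wise affine form map with gain
#' in \[0.7, 1.3\] and offset in \[-3, 3\] percent reflectance.
#'
#' @param n_samples sample count.
#' @param n_bands band count.
#' @param wavelength_range nm range of the grid.
#' @param peak_centers absorption peak centres (nm).
#' @param tvc_range reference-value range (log10 CFU/g).
#' @param cs_noise_sd,fs_noise_sd white-noise standard deviation
#'   (reflectance percent); the full form must be at least as noisy.
#' @param scatter_slope_sd,scatter_offset_sd per-sample multiplicative /
#'   additive scatter scales on the crushed form.
#' @param fs_scatter_mult multiplier applied to both scatter scales on the
#'   full form.
#' @param fs_heterogeneity_sd amplitude (percent reflectance) of the smooth
#'   per-sample wiggle on the full form only.
#' @param form_map `NULL` for the default smooth map, or a list with `gain`
#'   and `offset` vectors of length `n_bands`.
#' @param seed RNG seed.
#' @return a list of class `fixture_config`.
#' @export
fixture_config <- function(n_samples = 100L, n_bands = 256L,
                           wavelength_range = c(885, 1735),
                           peak_centers = c(944, 980, 1076, 1186, 1264,
                                            1455),
                           tvc_range = c(2.1347, 3.8808),
                           cs_noise_sd = 0.15, fs_noise_sd = 1.5,
                           scatter_slope_sd = 0.04,
                           scatter_offset_sd = 1.0,
                           fs_scatter_mult = 3,
                           fs_heterogeneity_sd = 2.5,
                           form_map = NULL, seed = 1L) {
  stopifnot_scalar_count(n_samples, "n_samples", min = 5L)
  stopifnot_scalar_count(n_bands, "n_bands", min = 8L)
  if (fs_noise_sd < cs_noise_sd) {
    stop("parameter error: fs_noise_sd must be >= cs_noise_sd ",
         "(full samples are the less uniform form)", call. = FALSE)
  }
  if (any(peak_centers < wavelength_range[1L]) ||
      any(peak_centers > wavelength_range[2L])) {
    stop("parameter error: peak centres outside wavelength range",
         call. = FALSE)
  }
  if (diff(tvc_range) <= 0) stop("parameter error: empty tvc_range",
                                 call. = FALSE)
  cfg <- list(n_samples = as.integer(n_samples),
              n_bands = as.integer(n_bands),
              wavelength_range = wavelength_range,
              peak_centers = peak_centers, tvc_range = tvc_range,
              cs_noise_sd = cs_noise_sd, fs_noise_sd = fs_noise_sd,
              scatter_slope_sd = scatter_slope_sd,
              scatter_offset_sd = scatter_offset_sd,
              fs_scatter_mult = fs_scatter_mult,
              fs_heterogeneity_sd = fs_heterogeneity_sd,
              form_map = form_map, seed = as.integer(seed))
  class(cfg) <- "fixture_config"
  cfg
}

# Default band-wise affine form map: smooth gain in [0.7, 1.3] and offset in
# [-3, 3] percent reflectance -- strong enough that an untransferred
# full-form prediction visibly degrades, weak enough that ~70 standards
# estimate it.
default_form_map <- function(wavelengths) {
  u <- (wavelengths - min(wavelengths)) / diff(range(wavelengths))
  list(gain = 1 + 0.3 * sin(1.5 * pi * u + 0.4),
       offset = 3 * cos(2.2 * pi * u))
}

# Peak shape parameters. Widths (nm sd) and depths (percent reflectance at
# TVC = 3 log10 CFU/g) are fixed; depths move affinely with TVC so several
# bands carry signal of both signs.
peak_params <- function(centers) {
  k <- length(centers)
  list(centers = centers,
       widths = rep_len(c(14, 12, 20, 16, 15, 30), k),
       depth0 = rep_len(c(8, 6, 10, 7, 6, 12), k),
       depth_slope = rep_len(c(2.5, -1.5, 3.0, 2.0, -1.0, 1.8), k))
}

clean_spectrum <- function(wavelengths, tvc, pk) {
  u <- (wavelengths - min(wavelengths)) / diff(range(wavelengths))
  baseline <- 50 + 12 * u - 10 * u^2 + 3 * sin(2 * pi * u)
  s <- baseline
  for (j in seq_along(pk$centers)) {
    depth <- pk$depth0[j] + pk$depth_slope[j] * (tvc - 3)
    s <- s - depth * exp(-(wavelengths - pk$centers[j])^2 /
                           (2 * pk$widths[j]^2))
  }
  s
}

#' Generate a paired crushed/full synthetic dataset
#'
#' Per sample: a TVC value is drawn uniformly over the configured range; the
#' crushed spectrum is a smooth baseline minus Gaussian absorption peaks
#' whose depths are affine in TVC, distorted by per-sample multiplicative
#' scatter and white noise; the full spectrum applies the true band-wise
#' affine form map to the same clean spectrum and adds stronger scatter, a
#' smooth per-sample heterogeneity wiggle and stronger noise. Both forms
#' share ids and reference values.
#'
#' @param config a [fixture_config()].
#' @return list with `cs` and `fs` ([spectral_dataset()] objects) and
#'   `truth` (form map, peak parameters, clean spectra, per-sample scatter
#'   draws).
#' @export
generate_dataset_pair <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  n <- config$n_samples; p <- config$n_bands
  wl <- seq(config$wavelength_range[1L], config$wavelength_range[2L],
            length.out = p)
  fm <- if (is.null(config$form_map)) default_form_map(wl) else config$form_map
  if (length(fm$gain) != p || length(fm$offset) != p) {
    stop("parameter error: form_map vectors must have n_bands entries",
         call. = FALSE)
  }
  pk <- peak_params(config$peak_centers)
  ids <- sprintf("s%03d", seq_len(n))
  out <- with_seed(config$seed, {
    tvc <- stats::runif(n, config$tvc_range[1L], config$tvc_range[2L])
    clean_cs <- t(vapply(tvc, function(t) clean_spectrum(wl, t, pk),
                         numeric(p)))
    clean_fs <- sweep(sweep(clean_cs, 2L, fm$gain, `*`), 2L, fm$offset, `+`)
    a_cs <- 1 + stats::rnorm(n, 0, config$scatter_slope_sd)
    b_cs <- stats::rnorm(n, 0, config$scatter_offset_sd)
    a_fs <- 1 + stats::rnorm(n, 0, config$scatter_slope_sd *
                                  config$fs_scatter_mult)
    b_fs <- stats::rnorm(n, 0, config$scatter_offset_sd *
                              config$fs_scatter_mult)
    u <- (wl - min(wl)) / diff(range(wl))
    het <- matrix(0, n, p)
    if (config$fs_heterogeneity_sd > 0) {
      for (m in 1:3) {
        amp <- stats::rnorm(n, 0, config$fs_heterogeneity_sd / m)
        phase <- stats::runif(n, 0, 2 * pi)
        het <- het + outer(amp, rep(1, p)) *
          sin(outer(phase, rep(1, p)) +
                2 * pi * m * outer(rep(1, n), u))
      }
    }
    X_cs <- clean_cs * a_cs + b_cs +
      matrix(stats::rnorm(n * p, 0, config$cs_noise_sd), n, p)
    X_fs <- clean_fs * a_fs + b_fs + het +
      matrix(stats::rnorm(n * p, 0, config$fs_noise_sd), n, p)
    list(tvc = tvc, clean_cs = clean_cs, clean_fs = clean_fs,
         X_cs = X_cs, X_fs = X_fs,
         scatter = list(a_cs = a_cs, b_cs = b_cs, a_fs = a_fs, b_fs = b_fs))
  })
  cs <- spectral_dataset(spectra_set(out$X_cs, wl, ids, "crushed"), out$tvc)
  fs <- spectral_dataset(spectra_set(out$X_fs, wl, ids, "full"), out$tvc)
  list(cs = cs, fs = fs,
       truth = list(form_map = fm, peaks = pk, tvc = out$tvc,
                    clean_cs = out$clean_cs, clean_fs = out$clean_fs,
                    scatter = out$scatter, wavelengths = wl))
}

#' Generate a synthetic hyperspectral cube around one spectrum
#'
#' Encodes a reflectance spectrum as raw counts consistent with emitted
#' white/dark reference frames, so the calibrate-then-extract path can be
#' verified end to end: foreground pixels carry the spectrum (plus optional
#' per-pixel noise), background pixels a small constant reflectance.
#'
#' @param sample_spectrum reflectance spectrum (percent), one value per band.
#' @param wavelengths band-centre wavelengths (nm).
#' @param nrows,ncols spatial size of the cube.
#' @param noise_sd per-pixel reflectance noise (percent; 0 = exact).
#' @param seed RNG seed for the noise.
#' @return list with `cube` (an [hsi_cube()]), `frames` (list `white`,
#'   `dark`: matrices) and `foreground` (logical matrix).
#' @export
generate_cube <- function(sample_spectrum, wavelengths,
                          nrows = 20L, ncols = 20L, noise_sd = 0,
                          seed = 1L) {
  p <- length(sample_spectrum)
  if (length(wavelengths) != p) {
    stop("dimension error: spectrum and wavelength lengths differ",
         call. = FALSE)
  }
  # spatially varying references: gradient white, constant dark
  white <- matrix(4000, nrows, ncols) +
    outer(seq_len(nrows), seq_len(ncols), function(r, c) 5 * r + 3 * c)
  dark <- matrix(100, nrows, ncols)
  fg <- matrix(FALSE, nrows, ncols)
  rr <- seq.int(max(1L, floor(nrows / 4)), min(nrows, ceiling(3 * nrows / 4)))
  cc <- seq.int(max(1L, floor(ncols / 4)), min(ncols, ceiling(3 * ncols / 4)))
  fg[rr, cc] <- TRUE
  refl <- array(2, dim = c(nrows, ncols, p))  # background: 2 % reflectance
  for (b in seq_len(p)) {
    plane <- refl[, , b]
    plane[fg] <- sample_spectrum[b]
    refl[, , b] <- plane
  }
  if (noise_sd > 0) {
    refl <- refl + with_seed(seed,
      array(stats::rnorm(nrows * ncols * p, 0, noise_sd),
            dim = c(nrows, ncols, p)))
  }
  denom <- array(rep(white - dark, p), dim = c(nrows, ncols, p))
  raw <- array(rep(dark, p), dim = c(nrows, ncols, p)) + refl / 100 * denom
  list(cube = hsi_cube(raw, wavelengths),
       frames = list(white = white, dark = dark),
       foreground = fg)
}
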