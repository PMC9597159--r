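#' Synthetic lamp-spectrum simulation specification
#'
#' Describes a ground-truth spectrometer state and lamp so that synthetic
#' reference spectra can be rendered, making the whole calibration pipeline
#' testable without instrument data.  Lines are placed on the detector by
#' the forward physical model and rendered with the same Lorentzian line
#' shape used for peak fitting (so that shape mismatch can be studied
#' separately via `shape = "gaussian"`); noise follows counting statistics
#' (Poisson on baseline + signal) by default.
#'
#' @param params True [spectrometer_params()].
#' @param lines A [lamp_lines()] table (lines falling outside the detector
#'   band are dropped at render time with a notice).
#' @param amplitude Peak height(s) above baseline in counts (scalar or
#'   per-line).  Default 1e4, a typical exposure just below the full scale
#'   of a 16-bit detector.
#' @param width Lorentzian width parameter(s) P3 in px^2 (scalar or
#'   per-line).  Default 4 (FWHM = 4 px).
#' @param baseline Constant baseline in counts.  Default 100.
#' @param noise `"poisson"` (counting statistics on baseline + signal),
#'   `"gaussian"` (additive, with `noise_sd` counts) or `"none"`.
#' @param noise_sd Standard deviation for `"gaussian"` noise, counts.
#' @param shape `"lorentzian"` (matches the fitting model) or `"gaussian"`
#'   (same FWHM, to exercise model mismatch).
#' @param m_spectra Number of spectra for [render_ensemble()].
#' @param theta_jitter_sd Per-spectrum jitter of the grating angle
#'   `theta_d` (radians, standard deviation), emulating slight grating
#'   movements between captures.
#' @param seed Random seed (mandatory; recorded in all outputs).
#' @return An object of class `"sim_spec"`.
#' @export
simulation_spec <- function(params, lines, amplitude = 1e4, width = 4,
                            baseline = 100,
                            noise = c("poisson", "gaussian", "none"),
                            noise_sd = 10,
                            shape = c("lorentzian", "gaussian"),
                            m_spectra = 1L, theta_jitter_sd = 0,
                            seed) {
  validate_params(params)
  stopifnot(inherits(lines, "lamp_lines"))
  noise <- match.arg(noise)
  shape <- match.arg(shape)
  if (missing(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("a scalar random seed is required", call. = FALSE)
  }
  n <- nrow(lines)
  amplitude <- rep_len(as.numeric(amplitude), n)
  width <- rep_len(as.numeric(width), n)
  if (any(amplitude <= 0)) stop("line amplitudes must be positive", call. = FALSE)
  if (any(width <= 0)) stop("line widths must be positive", call. = FALSE)
  if (baseline < 0) stop("baseline must be non-negative", call. = FALSE)
  structure(list(
    params = params, lines = lines, amplitude = amplitude, width = width,
    baseline = baseline, noise = noise, noise_sd = noise_sd, shape = shape,
    m_spectra = as.integer(m_spectra), theta_jitter_sd = theta_jitter_sd,
    seed = as.integer(seed)
  ), class = "sim_spec")
}

# noiseless intensity profile on the integer pixel grid
render_profile <- function(spec, params) {
  px <- seq_len(params$n_pixels)
  x_line <- wavelength_to_pixel(params, spec$lines$wavelength_nm)
  in_band <- x_line >= 1 & x_line <= params$n_pixels
  # an empty line list renders a flat baseline; a non-empty list with no line
  # on the detector is an error (nothing to calibrate against)
  if (length(in_band) && !any(in_band)) {
    stop("no lamp line falls on the detector for these parameters", call. = FALSE)
  }
  if (any(!in_band)) {
    message(sprintf("%d of %d lines fall outside the detector and are dropped",
                    sum(!in_band), length(in_band)))
  }
  y <- rep(spec$baseline, params$n_pixels)
  for (i in which(in_band)) {
    p3 <- spec$width[i]
    if (spec$shape == "lorentzian") {
      y <- y + spec$amplitude[i] * p3 / ((px - x_line[i])^2 + p3)
    } else {
      # same FWHM as the Lorentzian: FWHM = 2*sqrt(p3) -> sigma
      sigma <- 2 * sqrt(p3) / (2 * sqrt(2 * log(2)))
      y <- y + spec$amplitude[i] * exp(-(px - x_line[i])^2 / (2 * sigma^2))
    }
  }
  list(intensities = y, x_line = x_line[in_band],
       lambda_line = spec$lines$wavelength_nm[in_band])
}

apply_noise <- function(spec, y) {
  switch(spec$noise,
         none = y,
         poisson = stats::rpois(length(y), lambda = y),
         gaussian = pmax(0, y + stats::rnorm(length(y), sd = spec$noise_sd)))
}

#' Render one synthetic reference spectrum
#'
#' Evaluates the forward model to place every lamp line on the detector,
#' renders the line profiles plus baseline on the integer pixel grid,
#' applies the noise model, and returns the spectrum together with the
#' exact sub-pixel line positions as ground truth.
#'
#' @param spec A [simulation_spec()].
#' @param params Optional parameter override (used by [render_ensemble()]
#'   for per-spectrum grating jitter); defaults to `spec$params`.
#' @return A list with `spectrum` (a [spectrum()] object), `truth` (a
#'   [peak_set()] of exact sub-pixel positions and wavelengths), `params`
#'   (the parameters actually used) and `seed`.
#' @export
render_spectrum <- function(spec, params = spec$params) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  prof <- render_profile(spec, params)
  y <- apply_noise(spec, prof$intensities)
  list(
    spectrum = spectrum(y, lamp = spec$lines$label[1], label = "synthetic"),
    truth = peak_set(prof$x_line, prof$lambda_line),
    params = params,
    seed = spec$seed
  )
}

#' Render an ensemble of spectra with grating jitter
#'
#' Generates `spec$m_spectra` synthetic spectra, each with the grating
#' rotation angle perturbed by Gaussian jitter of standard deviation
#' `spec$theta_jitter_sd` (emulating recording many reference spectra with
#' slight movements of the grating between captures).  Deterministic for a
#' fixed seed.
#'
#' @param spec A [simulation_spec()].
#' @return A list of length `m_spectra`; each element as in
#'   [render_spectrum()], with the per-spectrum true `theta_d` recorded in
#'   `params`.
#' @export
render_ensemble <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  jitter <- stats::rnorm(spec$m_spectra, sd = spec$theta_jitter_sd)
  if (spec$theta_jitter_sd == 0) jitter <- rep(0, spec$m_spectra)
  out <- vector("list", spec$m_spectra)
  for (m in seq_len(spec$m_spectra)) {
    pm <- update_params(spec$params, theta_d = spec$params$theta_d + jitter[m])
    prof <- render_profile(spec, pm)
    y <- apply_noise(spec, prof$intensities)
    out[[m]] <- list(
      spectrum = spectrum(y, lamp = spec$lines$label[1],
                          label = sprintf("synthetic-%03d", m)),
      truth = peak_set(prof$x_line, prof$lambda_line),
      params = pm,
      seed = spec$seed
    )
  }
  out
}

#' Perturb peak positions with Gaussian noise
#'
#' Adds independent Gaussian noise to the sub-pixel positions of a peak
#' set, the standard way to emulate peak-localization error directly when
#' studying calibration robustness (bypassing spectrum rendering).
#'
#' @param peaks A [peak_set()].
#' @param sd Position noise standard deviation in px.
#' @return A perturbed [peak_set()].
#' @export
perturb_positions <- function(peaks, sd) {
  stopifnot(inherits(peaks, "peak_set"))
  peak_set(peaks$x0 + stats::rnorm(peaks$N, sd = sd), peaks$lambda0)
}
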