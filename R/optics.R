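#' Diffraction angle of a wavelength on the rotated grating
#'
#' Closed-form diffracted-ray angle beta (with respect to the grating normal
#' in the flat position) for a wavelength lambda on a grating rotated by
#' theta_d:
#' \deqn{\beta = \arcsin\!\big[n\lambda/d' - k\,\sin(-\alpha-\theta_d)\big]
#'   + \theta_d}
#' The arcsin argument must lie in \[-1, 1\]; outside that range the
#' wavelength is not diffracted towards the detector for these parameters
#' and an error is raised reporting the offending wavelength.
#'
#' @param params A [spectrometer_params()] object.
#' @param wavelength Wavelength(s) in nm.
#' @return Diffraction angle(s) beta in radians.
#' @export
diffraction_angle <- function(params, wavelength) {
  validate_params(params)
  u <- asin_arg(params, wavelength)
  bad <- which(abs(u) > 1)
  if (length(bad)) {
    stop(sprintf(
      "wavelength %.6g nm is outside the physical range of this configuration (asin argument %.6g)",
      wavelength[bad[1]], u[bad[1]]), call. = FALSE)
  }
  asin(u) + params$theta_d
}

# argument of the arcsin in the rotated grating equation
asin_arg <- function(params, wavelength) {
  params$n_order * wavelength / params$d_eff -
    params$k * sin(-params$alpha - params$theta_d)
}

# half-width of the detector in pixel units; pixel frame is 1-based with the
# optical axis crossing the detector at pixel (n_pixels + 1) / 2 when C = 0
frame_offset <- function(params) (params$n_pixels + 1) / 2

#' Map wavelengths to detector pixel positions (forward model)
#'
#' Forward physical model of the spectrometer: the image of a monochromatic
#' slit source of wavelength lambda falls at real-valued pixel position
#' \deqn{x = \frac{f}{T}\tan\!\big(\theta_d + \arcsin[n\lambda/d' -
#'   k\sin(-\alpha-\theta_d)] - \alpha\big) + \frac{C}{T} +
#'   \frac{n_{pix}+1}{2}}
#' in the 1-based pixel frame (pixel centres at integers 1..n_pixels; with
#' `C = 0` the axial wavelength lands at the detector centre).
#'
#' @param params A [spectrometer_params()] object.
#' @param wavelength Wavelength(s) in nm.
#' @param warn_outside If `TRUE`, warn when a result falls outside
#'   `[1, n_pixels]` (the mapping itself is still returned).
#' @return Real-valued pixel position(s).
#' @seealso [pixel_to_wavelength()] for the exact inverse.
#' @export
wavelength_to_pixel <- function(params, wavelength, warn_outside = FALSE) {
  beta <- diffraction_angle(params, wavelength)
  x <- (params$f / params$T) * tan(beta - params$alpha) +
    params$C / params$T + frame_offset(params)
  if (warn_outside && any(x < 1 | x > params$n_pixels)) {
    warning("some wavelengths map outside the detector [1, n_pixels]",
            call. = FALSE)
  }
  x
}

#' Map pixel positions to wavelengths (inverse model)
#'
#' Exact algebraic inverse of [wavelength_to_pixel()]:
#' \deqn{\lambda = \frac{d'}{n}\Big\{\sin\!\big[\arctan\!\big(\tfrac{xT - C}{f}\big)
#'   + \alpha - \theta_d\big] + k\sin(-\alpha-\theta_d)\Big\}}
#' where x is the detector-frame coordinate of the (1-based) pixel position.
#' The expression is total in x: any real pixel value is accepted, and
#' unphysical pixels may map to negative wavelengths — callers that care
#' should range-check (see [dispersion_curve()], which returns a validity
#' mask).
#'
#' @param params A [spectrometer_params()] object.
#' @param pixel Real-valued pixel position(s) in the 1-based pixel frame.
#' @return Wavelength(s) in nm.
#' @export
pixel_to_wavelength <- function(params, pixel) {
  validate_params(params)
  xdet <- (pixel - frame_offset(params)) * params$T - params$C
  (params$d_eff / params$n_order) *
    (sin(atan(xdet / params$f) + params$alpha - params$theta_d) +
       params$k * sin(-params$alpha - params$theta_d))
}

#' Axial wavelength of a configuration
#'
#' The wavelength diffracted exactly along the optical axis
#' (`beta = alpha`), i.e. the one imaged at the detector centre when
#' `C = 0`:
#' \deqn{\lambda^* = \frac{d'}{n}\big[\sin(\alpha-\theta_d) +
#'   k\sin(-\alpha-\theta_d)\big]}
#'
#' @param params A [spectrometer_params()] object.
#' @return Wavelength in nm (may be unphysical, e.g. negative, if the
#'   configuration has no on-axis diffracted order).
#' @export
axial_wavelength <- function(params) {
  validate_params(params)
  (params$d_eff / params$n_order) *
    (sin(params$alpha - params$theta_d) +
       params$k * sin(-params$alpha - params$theta_d))
}

#' Dispersion curve across the detector
#'
#' Evaluates the inverse model on the integer pixel grid and min-max
#' normalizes the wavelengths to \[0, 1\], producing the standard linearity
#' diagnostic: the deviation of the normalized curve from the straight line
#' through its endpoints measures the dispersion nonlinearity (growing with
#' grating density, shrinking with focal length).
#'
#' @param params A [spectrometer_params()] object.
#' @return A data.frame with columns `pixel`, `wavelength_nm`,
#'   `normalized` (min-max normalized wavelength), `linear_deviation`
#'   (normalized wavelength minus the straight line through the curve's
#'   endpoints) and `valid` (`TRUE` where the wavelength is positive).
#' @export
dispersion_curve <- function(params) {
  validate_params(params)
  px <- seq_len(params$n_pixels)
  lam <- pixel_to_wavelength(params, px)
  rng <- range(lam)
  norm <- (lam - rng[1]) / (rng[2] - rng[1])
  straight <- norm[1] + (norm[length(norm)] - norm[1]) *
    (px - 1) / (params$n_pixels - 1)
  data.frame(
    pixel = px,
    wavelength_nm = lam,
    normalized = norm,
    linear_deviation = norm - straight,
    valid = lam > 0
  )
}

#' Wavelength band imaged by the detector
#'
#' @param params A [spectrometer_params()] object.
#' @return Numeric vector `c(min, max)` of the wavelengths at the two
#'   detector ends, sorted ascending.
#' @export
band_limits <- function(params) {
  sort(pixel_to_wavelength(params, c(1, params$n_pixels)))
}
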