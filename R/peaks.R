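#' Spectrum container
#'
#' A recorded (or simulated) 1-D reference-lamp spectrum: non-negative
#' intensities on the implicit pixel axis `1..length(intensities)`,
#' typically the cropped centre row of a detector image.
#'
#' @param intensities Numeric vector of per-pixel counts (length >= 8, all
#'   finite and non-negative).
#' @param lamp Optional lamp name (e.g. `"neon"`).
#' @param label Optional acquisition label.
#' @return An object of class `"spec_spectrum"`.
#' @export
spectrum <- function(intensities, lamp = NULL, label = NULL) {
  intensities <- as.numeric(intensities)
  if (length(intensities) < 8L) stop("spectrum must have at least 8 pixels", call. = FALSE)
  if (any(!is.finite(intensities))) stop("spectrum intensities must all be finite", call. = FALSE)
  if (any(intensities < 0)) stop("spectrum intensities must be non-negative", call. = FALSE)
  structure(list(intensities = intensities, lamp = lamp, label = label),
            class = "spec_spectrum")
}

#' @export
print.spec_spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: %d pixels, counts in [%.4g, %.4g]",
              length(x$intensities), min(x$intensities), max(x$intensities)))
  if (!is.null(x$lamp)) cat(", lamp =", x$lamp)
  cat("\n")
  invisible(x)
}

#' Lamp line list
#'
#' Reference emission-line wavelengths (nm) of a calibration lamp such as
#' neon or krypton, with optional uncertainties, as tabulated by a
#' wavelength-standard database.
#'
#' @param wavelength_nm Strictly increasing positive wavelengths in nm.
#' @param uncertainty_nm Optional per-line uncertainties in nm (`NA`
#'   allowed).
#' @param label Optional per-line labels.
#' @return A data.frame of class `"lamp_lines"` with columns
#'   `wavelength_nm`, `uncertainty_nm`, `label`.
#' @export
lamp_lines <- function(wavelength_nm, uncertainty_nm = NULL, label = NULL) {
  w <- as.numeric(wavelength_nm)
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("line wavelengths must be finite and positive", call. = FALSE)
  }
  if (is.unsorted(w, strictly = TRUE)) {
    stop("line wavelengths must be strictly increasing", call. = FALSE)
  }
  n <- length(w)
  out <- data.frame(
    wavelength_nm = w,
    uncertainty_nm = if (is.null(uncertainty_nm)) rep(NA_real_, n) else as.numeric(uncertainty_nm),
    label = if (is.null(label)) rep(NA_character_, n) else as.character(label),
    stringsAsFactors = FALSE
  )
  class(out) <- c("lamp_lines", "data.frame")
  out
}

#' Detect candidate emission peaks
#'
#' Finds local maxima of the spectrum that exceed a prominence threshold and
#' enforces a minimum separation between retained candidates (keeping the
#' higher peak of any close pair).  Prominence of a local maximum is its
#' height above the higher of the two valley minima separating it from the
#' nearest taller samples (or the record ends).
#'
#' This is deliberately simple plumbing: the calibration algorithms only
#' need approximate integer apex positions, which [fit_lorentzian()] then
#' refines to sub-pixel precision.
#'
#' @param spec A [spectrum()] object.
#' @param min_prominence Minimum peak prominence in counts.
#' @param min_separation Minimum separation between retained peaks, px.
#' @return Integer vector of apex pixel positions, sorted ascending (may be
#'   empty).
#' @export
detect_peaks <- function(spec, min_prominence = 50, min_separation = 5) {
  stopifnot(inherits(spec, "spec_spectrum"))
  y <- spec$intensities
  n <- length(y)
  # strict local maxima (plateau apex = first sample of the plateau)
  apex <- which(diff(sign(diff(y))) < 0) + 1L
  apex <- apex[y[apex] > y[pmax(apex - 1L, 1L)] | y[apex] > y[pmin(apex + 1L, n)]]
  if (!length(apex)) return(integer(0))
  prom <- vapply(apex, function(i) {
    h <- y[i]
    left <- i - 1L
    lmin <- h
    while (left >= 1L && y[left] <= h) { lmin <- min(lmin, y[left]); left <- left - 1L }
    right <- i + 1L
    rmin <- h
    while (right <= n && y[right] <= h) { rmin <- min(rmin, y[right]); right <- right + 1L }
    # open-ended side: valley runs to the record end
    h - max(lmin, rmin)
  }, numeric(1))
  apex <- apex[prom >= min_prominence]
  if (!length(apex)) return(integer(0))
  # greedy separation filter, tallest first
  ord <- apex[order(y[apex], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || min(abs(kept - i)) >= min_separation) kept <- c(kept, i)
  }
  sort(kept)
}

#' Lorentzian sub-pixel peak localization
#'
#' Least-squares fit of the four-parameter Lorentzian line shape
#' \deqn{I(x) = \frac{P_1}{(x - P_2)^2 + P_3} + P_4}
#' to the spectrum samples in a window around an integer apex, yielding the
#' peak centre `P2` with sub-pixel precision.  `P1` is an amplitude scale
#' (counts px^2), `P3` a squared width parameter (the FWHM is
#' \eqn{2\sqrt{P_3}} px) and `P4` a constant baseline (counts).
#'
#' Starting values: `P2` at the apex, `P4` at the window minimum, and
#' `P1`, `P3` from the apex height and the half-maximum crossing.  Windows
#' containing saturated pixels (at `saturation` or above) are rejected, as
#' saturation flattens the apex and biases the centre.
#'
#' @param spec A [spectrum()] object.
#' @param apex Integer apex pixel (from [detect_peaks()]).
#' @param half_window Half-width of the fit window in px (window must lie
#'   inside the detector and contain at least 5 samples).
#' @param saturation Optional detector full-scale value; any window sample
#'   `>= saturation` rejects the peak.
#' @return An object of class `"lorentz_fit"`: list with elements `P1`,
#'   `P2`, `P3`, `P4`, `window` (pixel range fitted), `residual_norm` and
#'   `apex`.
#' @export
fit_lorentzian <- function(spec, apex, half_window = 5, saturation = NULL) {
  stopifnot(inherits(spec, "spec_spectrum"))
  n <- length(spec$intensities)
  lo <- apex - half_window
  hi <- apex + half_window
  if (lo < 1 || hi > n) {
    stop(sprintf("fit window [%d, %d] around apex %d lies outside the detector", lo, hi, apex),
         call. = FALSE)
  }
  if (hi - lo + 1 < 5) stop("fit window must contain at least 5 samples", call. = FALSE)
  x <- seq(lo, hi)
  y <- spec$intensities[x]
  if (!is.null(saturation) && any(y >= saturation)) {
    stop(sprintf("peak at apex %d rejected: saturated pixel(s) in the fit window", apex),
         call. = FALSE)
  }
  p4 <- min(y)
  height <- y[apex - lo + 1] - p4
  if (height <= 0) stop(sprintf("no peak above baseline at apex %d", apex), call. = FALSE)
  # half-maximum crossing -> HWHM estimate -> P3 = HWHM^2
  above <- y - p4 >= height / 2
  hwhm <- max(1, (sum(above)) / 2)
  p3 <- hwhm^2
  start <- list(P1 = height * p3, P2 = as.numeric(apex), P3 = p3, P4 = p4)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ P1 / ((x - P2)^2 + P3) + P4,
      data = data.frame(x = x, y = y),
      start = start,
      lower = c(P1 = 0, P2 = lo, P3 = 1e-6, P4 = -Inf),
      upper = c(P1 = Inf, P2 = hi, P3 = Inf, P4 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15)
    ),
    error = function(e) stop(sprintf("Lorentzian fit failed at apex %d: %s", apex,
                                     conditionMessage(e)), call. = FALSE)
  )
  cf <- stats::coef(fit)
  if (cf[["P3"]] <= 0) stop(sprintf("Lorentzian fit at apex %d returned non-positive width", apex),
                            call. = FALSE)
  structure(list(
    P1 = cf[["P1"]], P2 = cf[["P2"]], P3 = cf[["P3"]], P4 = cf[["P4"]],
    window = c(lo, hi),
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    apex = apex
  ), class = "lorentz_fit")
}

#' @export
print.lorentz_fit <- function(x, ...) {
  cat(sprintf("Lorentzian fit: centre P2 = %.4f px, FWHM = %.3f px, height = %.4g, baseline = %.4g\n",
              x$P2, 2 * sqrt(x$P3), x$P1 / x$P3, x$P4))
  cat(sprintf("  window [%d, %d], residual norm %.4g\n", x$window[1], x$window[2], x$residual_norm))
  invisible(x)
}

#' Paired peak positions and reference wavelengths
#'
#' The calibration input: N pairs of observed sub-pixel detector positions
#' `x0` and known reference wavelengths `lambda0`.  Positions are stored
#' sorted by `x0`; the wavelengths must then be strictly monotone
#' (increasing or decreasing, depending on the dispersion direction).
#'
#' @param x0 Observed sub-pixel positions (px).
#' @param lambda0 Reference wavelengths (nm).
#' @return An object of class `"peak_set"`.
#' @export
peak_set <- function(x0, lambda0) {
  x0 <- as.numeric(x0)
  lambda0 <- as.numeric(lambda0)
  if (length(x0) != length(lambda0)) stop("x0 and lambda0 must have equal length", call. = FALSE)
  if (any(!is.finite(x0)) || any(!is.finite(lambda0))) {
    stop("peak positions and wavelengths must be finite", call. = FALSE)
  }
  ord <- order(x0)
  x0 <- x0[ord]; lambda0 <- lambda0[ord]
  if (length(x0) > 1L) {
    if (any(diff(x0) <= 0)) stop("peak positions must be distinct", call. = FALSE)
    dl <- diff(lambda0)
    if (!(all(dl > 0) || all(dl < 0))) {
      stop("reference wavelengths must be strictly monotone in detector position", call. = FALSE)
    }
  }
  structure(list(x0 = x0, lambda0 = lambda0, N = length(x0)), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set: %d peaks, positions %.2f..%.2f px, wavelengths %.3f..%.3f nm\n",
              x$N, min(x$x0), max(x$x0), min(x$lambda0), max(x$lambda0)))
  invisible(x)
}

#' Subset a peak set
#'
#' @param peaks A [peak_set()].
#' @param idx Index vector (positions are kept sorted).
#' @return A `peak_set` with the selected peaks.
#' @export
peaks_subset <- function(peaks, idx) {
  stopifnot(inherits(peaks, "peak_set"))
  peak_set(peaks$x0[idx], peaks$lambda0[idx])
}

#' Match detected peak positions to lamp lines
#'
#' Maps each detected sub-pixel position through the inverse model of an
#' approximate parameter set (a coarse initial estimate suffices) and pairs
#' it with the nearest line-list wavelength within `tolerance` nm.  Matching
#' is one-to-one: if several positions fall nearest to the same line, the
#' closest wins and the others are reported unmatched.  If two lines lie
#' within tolerance of one position the match is ambiguous and an error
#' lists the candidates.  Unmatched positions and lines are reported, never
#' silently dropped, and the resulting pairing is checked for monotonicity.
#'
#' @param positions Detected sub-pixel positions (px).
#' @param lines A [lamp_lines()] table.
#' @param approx_params Approximate [spectrometer_params()] used to predict
#'   each position's wavelength.
#' @param tolerance Matching tolerance in nm.
#' @return A list with elements `peaks` (a [peak_set()], possibly with 0
#'   rows), `unmatched_positions` (px), `unmatched_lines` (nm).
#' @export
match_lines <- function(positions, lines, approx_params, tolerance = 0.5) {
  stopifnot(inherits(lines, "lamp_lines"))
  validate_params(approx_params)
  positions <- sort(as.numeric(positions))
  lw <- lines$wavelength_nm
  if (!length(positions) || !length(lw)) {
    return(list(peaks = peak_set(numeric(0), numeric(0)),
                unmatched_positions = positions, unmatched_lines = lw))
  }
  pred <- pixel_to_wavelength(approx_params, positions)
  cand_line <- integer(length(positions))
  cand_dist <- numeric(length(positions))
  for (i in seq_along(positions)) {
    d <- abs(lw - pred[i])
    within <- which(d <= tolerance)
    if (length(within) > 1L) {
      stop(sprintf(
        "ambiguous match for position %.3f px (predicted %.4f nm): lines %s all within %.3g nm",
        positions[i], pred[i], paste(sprintf("%.4f", lw[within]), collapse = ", "),
        tolerance), call. = FALSE)
    }
    cand_line[i] <- if (length(within) == 1L) within else NA_integer_
    cand_dist[i] <- if (length(within) == 1L) d[within] else NA_real_
  }
  # one-to-one: closest position wins a contested line
  for (j in unique(stats::na.omit(cand_line))) {
    claimants <- which(cand_line == j)
    if (length(claimants) > 1L) {
      keep <- claimants[which.min(cand_dist[claimants])]
      cand_line[setdiff(claimants, keep)] <- NA_integer_
    }
  }
  matched <- !is.na(cand_line)
  ps <- peak_set(positions[matched], lw[cand_line[matched]])
  list(peaks = ps,
       unmatched_positions = positions[!matched],
       unmatched_lines = lw[setdiff(seq_along(lw), cand_line[matched])])
}

#' Full peak extraction pipeline
#'
#' Convenience wrapper: detect apexes, fit each with a Lorentzian, and match
#' the sub-pixel centres to a line list.  Peaks whose Lorentzian fit fails
#' (including saturation rejection) are dropped with a message.
#'
#' @inheritParams detect_peaks
#' @inheritParams fit_lorentzian
#' @inheritParams match_lines
#' @return As [match_lines()], plus element `fits` (list of
#'   [fit_lorentzian()] results for the retained peaks).
#' @export
extract_peaks <- function(spec, lines, approx_params,
                          min_prominence = 50, min_separation = 5,
                          half_window = 5, saturation = NULL,
                          tolerance = 0.5) {
  apexes <- detect_peaks(spec, min_prominence, min_separation)
  n <- length(spec$intensities)
  apexes <- apexes[apexes - half_window >= 1 & apexes + half_window <= n]
  fits <- list()
  centres <- numeric(0)
  for (a in apexes) {
    f <- tryCatch(fit_lorentzian(spec, a, half_window, saturation),
                  error = function(e) { message(conditionMessage(e)); NULL })
    if (!is.null(f)) {
      fits[[length(fits) + 1L]] <- f
      centres <- c(centres, f$P2)
    }
  }
  out <- match_lines(centres, lines, approx_params, tolerance)
  out$fits <- fits
  out
}
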