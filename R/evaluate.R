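#' Signed calibration errors at the reference peaks
#'
#' For each peak, the calibrated wavelength at its observed sub-pixel
#' position minus the reference wavelength:
#' \deqn{error(\lambda_i) = calibrated(\lambda_i) - reference(\lambda_i)}
#' The calibrated wavelength is taken from the method's continuous map
#' ([predict_wavelength()]), not by interpolating the per-pixel table, which
#' would add an avoidable interpolation artifact of order 1e-4 nm.
#'
#' @param result A `"spec_calibration"`.
#' @param peaks A [peak_set()] of positions to score (not necessarily the
#'   ones used in the calibration).
#' @return Numeric vector of signed errors in nm.
#' @export
peak_errors <- function(result, peaks) {
  stopifnot(inherits(result, "spec_calibration"), inherits(peaks, "peak_set"))
  n_pix <- length(result$lambda_cal)
  if (any(peaks$x0 < 1 | peaks$x0 > n_pix)) {
    stop("peak position outside the detector [1, n_pixels]", call. = FALSE)
  }
  predict_wavelength(result, peaks$x0) - peaks$lambda0
}

#' Summary error metrics
#'
#' Mean absolute error, root-mean-square error and standard deviation of a
#' vector of signed calibration errors:
#' \deqn{MAE = \tfrac1N \sum |e_i|, \quad
#'       RMSE = \sqrt{\tfrac1N \sum e_i^2}, \quad
#'       SD = \sqrt{\tfrac{1}{N-1} \sum (e_i - \bar e)^2}}
#' The SD uses the N-1 denominator about the signed mean error.  With a
#' single error the SD is undefined and reported as `NA` (never as zero).
#'
#' @param errors Numeric vector of signed errors (nm).
#' @return Named list with `MAE`, `RMSE`, `SD`, `ME` (signed mean error)
#'   and `N`.
#' @export
summarize_errors <- function(errors) {
  errors <- as.numeric(errors)
  if (!length(errors)) stop("empty error vector", call. = FALSE)
  list(
    MAE = mean(abs(errors)),
    RMSE = sqrt(mean(errors^2)),
    SD = if (length(errors) >= 2L) stats::sd(errors) else NA_real_,
    ME = mean(errors),
    N = length(errors)
  )
}

#' Ensemble average of per-spectrum metrics
#'
#' Unweighted arithmetic means of per-spectrum MAE, RMSE and SD over M
#' spectra (not a pooled recomputation): the standard way to aggregate the
#' metrics when the same calibration procedure is repeated over many
#' recorded reference spectra.
#'
#' @param reports A list of metric sets, each as returned by
#'   [summarize_errors()] or [evaluate_scheme()].
#' @return Named list with `MAE`, `RMSE`, `SD` (ensemble means; `SD` is the
#'   mean over spectra where it is defined) and `M`.
#' @export
ensemble_metrics <- function(reports) {
  if (!length(reports)) stop("at least one report is required", call. = FALSE)
  pull <- function(field) vapply(reports, function(r) {
    v <- r[[field]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  sds <- pull("SD")
  list(
    MAE = mean(pull("MAE")),
    RMSE = mean(pull("RMSE")),
    SD = if (all(is.na(sds))) NA_real_ else mean(sds, na.rm = TRUE),
    M = length(reports)
  )
}

#' Calibrator specifications for the evaluation schemes
#'
#' A calibrator bundles a fitting method with its settings so the
#' evaluation schemes can re-run it on subsets of the peaks.  `fit` is a
#' function taking a [peak_set()] and returning a `"spec_calibration"`;
#' `min_peaks` is the smallest peak count the method accepts.
#'
#' @param params0 Nominal [spectrometer_params()] for the physical method.
#' @param grid Search grid for the physical method (default
#'   [default_physical_grid()]).
#' @param ... Further arguments passed through to [calibrate_physical()].
#' @return An object of class `"spec_calibrator"`.
#' @export
calibrator_physical <- function(params0, grid = default_physical_grid(params0), ...) {
  validate_params(params0)
  extra <- list(...)
  structure(list(
    method = "physical",
    min_peaks = 4L,
    fit = function(peaks) do.call(calibrate_physical,
                                  c(list(peaks, params0, grid), extra))
  ), class = "spec_calibrator")
}

#' @param order Polynomial order (1, 2 or 3).
#' @param n_pixels Detector length for the output axis.
#' @rdname calibrator_physical
#' @export
calibrator_polynomial <- function(order, n_pixels) {
  structure(list(
    method = paste0("poly", order),
    min_peaks = as.integer(order + 1L),
    fit = function(peaks) calibrate_polynomial(peaks, order, n_pixels)
  ), class = "spec_calibrator")
}

#' Evaluate a calibrator under the ALL / LOO / LHO schemes
#'
#' Runs a calibration method on a reference peak set under one of three
#' evaluation schemes and reports error metrics:
#' \describe{
#'   \item{ALL}{calibrate on all N peaks, score all N.  The traditional
#'     in-sample evaluation.}
#'   \item{LOO}{leave-one-out cross-validation: for each peak i, calibrate
#'     on the other N-1 and score peak i only; metrics are computed over the
#'     N held-out errors.  Estimates accuracy within the lamp band without
#'     in-sample bias.}
#'   \item{LHO}{leave-half-out: calibrate on the left half of the peaks (by
#'     detector position; odd N gives the extra peak to the left half) and
#'     score the right half, then swap.  Metrics are reported per side, as
#'     the average of the two sides, and pooled over the union of held-out
#'     errors.  Probes extrapolation beyond the outermost reference lines.}
#' }
#'
#' @param peaks A [peak_set()].
#' @param calibrator A [calibrator_physical()] or [calibrator_polynomial()].
#' @param scheme `"ALL"`, `"LOO"` or `"LHO"` (case-insensitive).
#' @return An object of class `"metrics_report"`: list with the per-peak
#'   held-out (or in-sample) `errors`, metric fields `MAE`, `RMSE`, `SD`,
#'   `ME`, `N`, the `scheme` and `method` tags, `n_calibrations`, and for
#'   LHO additionally `left`, `right` (per-side metric sets) and
#'   `side_average` (mean of the two sides' metrics).
#' @export
evaluate_scheme <- function(peaks, calibrator, scheme = c("ALL", "LOO", "LHO")) {
  stopifnot(inherits(peaks, "peak_set"), inherits(calibrator, "spec_calibrator"))
  scheme <- toupper(scheme)
  scheme <- match.arg(scheme, c("ALL", "LOO", "LHO"))
  N <- peaks$N
  need <- switch(scheme,
                 ALL = calibrator$min_peaks,
                 LOO = calibrator$min_peaks + 1L,
                 LHO = 2L * calibrator$min_peaks)
  if (N < need) {
    stop(sprintf("scheme %s with method %s needs at least %d peaks, got %d",
                 scheme, calibrator$method, need, N), call. = FALSE)
  }
  n_cal <- 0L
  fit <- function(p) { n_cal <<- n_cal + 1L; calibrator$fit(p) }

  if (scheme == "ALL") {
    cal <- fit(peaks)
    errors <- peak_errors(cal, peaks)
    extra <- list()
  } else if (scheme == "LOO") {
    errors <- vapply(seq_len(N), function(i) {
      cal <- fit(peaks_subset(peaks, -i))
      peak_errors(cal, peaks_subset(peaks, i))
    }, numeric(1))
    extra <- list()
  } else {
    n_left <- ceiling(N / 2)
    left_idx <- seq_len(n_left)
    right_idx <- seq.int(n_left + 1L, N)
    cal_left <- fit(peaks_subset(peaks, left_idx))
    err_right <- peak_errors(cal_left, peaks_subset(peaks, right_idx))
    cal_right <- fit(peaks_subset(peaks, right_idx))
    err_left <- peak_errors(cal_right, peaks_subset(peaks, left_idx))
    m_r <- summarize_errors(err_right)
    m_l <- summarize_errors(err_left)
    errors <- c(err_left, err_right)   # union of held-out errors (pooled)
    extra <- list(
      left = m_l, right = m_r,
      side_average = list(
        MAE = (m_l$MAE + m_r$MAE) / 2,
        RMSE = (m_l$RMSE + m_r$RMSE) / 2,
        SD = mean(c(m_l$SD, m_r$SD))
      )
    )
  }
  rep <- c(summarize_errors(errors),
           list(errors = errors, scheme = scheme, method = calibrator$method,
                n_calibrations = n_cal),
           extra)
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Calibration metrics [%s, %s]: N = %d peaks, %d calibration(s)\n",
              x$method, x$scheme, x$N, x$n_calibrations))
  cat(sprintf("  MAE  = %.6g nm\n  RMSE = %.6g nm\n  SD   = %.6g nm\n",
              x$MAE, x$RMSE, x$SD))
  if (!is.null(x$side_average)) {
    cat(sprintf("  LHO side-average MAE = %.6g nm (left %.6g, right %.6g)\n",
                x$side_average$MAE, x$left$MAE, x$right$MAE))
  }
  invisible(x)
}
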