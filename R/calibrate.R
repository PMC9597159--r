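#' Sum-of-squares position misfit
#'
#' The objective minimized by the grid-search calibrators:
#' \deqn{err = \sum_{i=1}^{N} (x_i^{pred} - x_i^{obs})^2}
#'
#' @param predicted Model-predicted pixel positions.
#' @param observed Observed pixel positions (same length).
#' @return Non-negative scalar.
#' @export
fit_error <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed position vectors must have equal length", call. = FALSE)
  }
  if (!length(predicted)) stop("at least one position pair is required", call. = FALSE)
  sum((predicted - observed)^2)
}

#' Search-grid axis
#'
#' One axis of a brute-force search grid: symmetric values
#' `center + (-m..m) * step` spanning `center +/- half_range`.
#' `half_range = 0` yields the single value `center` (a frozen axis).
#'
#' @param center Axis centre (the nominal parameter value).
#' @param half_range Non-negative half-range.
#' @param step Positive step size.
#' @return Numeric vector of grid values (always includes `center`).
#' @export
grid_axis <- function(center, half_range, step) {
  if (half_range < 0) stop("half_range must be non-negative", call. = FALSE)
  if (half_range > 0 && step <= 0) stop("step must be positive", call. = FALSE)
  m <- if (half_range > 0) floor(half_range / step + 1e-9) else 0L
  center + (-m:m) * step
}

#' Brute-force search grid
#'
#' A named collection of [grid_axis()] vectors over spectrometer parameters,
#' with a configurable total-cell budget.  Axis names must be parameter
#' field names (`alpha`, `d_eff`, `theta_d`, `f`, `T`, `C`).
#'
#' @param ... Named numeric vectors (typically from [grid_axis()]).
#' @param budget Maximum number of grid cells allowed when the grid is used.
#' @return An object of class `"search_grid"`.
#' @examples
#' deg <- pi / 180
#' g <- search_grid(
#'   alpha = grid_axis(21.88 * deg, 0.1 * deg, 0.01 * deg),
#'   d_eff = grid_axis(1e6 / 600, 1e6 / 600 * 5e-4, 1e6 / 600 * 5e-5),
#'   theta_d = grid_axis(12 * deg, 0.1 * deg, 0.005 * deg)
#' )
#' g
#' @export
search_grid <- function(..., budget = 1e7) {
  axes <- list(...)
  allowed <- c("alpha", "d_eff", "theta_d", "f", "T", "C")
  if (!length(axes) || is.null(names(axes)) || any(!nzchar(names(axes)))) {
    stop("search_grid() requires named axes", call. = FALSE)
  }
  bad <- setdiff(names(axes), allowed)
  if (length(bad)) stop("unknown grid axis name(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (anyDuplicated(names(axes))) stop("duplicated grid axis", call. = FALSE)
  for (nm in names(axes)) {
    v <- axes[[nm]]
    if (!is.numeric(v) || !length(v) || any(!is.finite(v))) {
      stop(sprintf("grid axis '%s' must be a finite numeric vector", nm), call. = FALSE)
    }
    axes[[nm]] <- sort(as.numeric(v))
  }
  structure(list(axes = axes, budget = budget), class = "search_grid")
}

#' @export
print.search_grid <- function(x, ...) {
  cat("Search grid:\n")
  for (nm in names(x$axes)) {
    v <- x$axes[[nm]]
    cat(sprintf("  %-8s %5d values in [%.8g, %.8g]\n", nm, length(v), min(v), max(v)))
  }
  cat(sprintf("  total %g cells (budget %g)\n", n_cells(x), x$budget))
  invisible(x)
}

#' Number of cells in a search grid
#' @param grid A [search_grid()].
#' @return Scalar cell count.
#' @export
n_cells <- function(grid) prod(vapply(grid$axes, length, numeric(1)))

#' Default three-parameter search grid
#'
#' The default grid for [calibrate_physical()]: half-deviation angle within
#' +/- 0.5 degree (step 0.01 degree), effective period within +/- 0.2
#' percent (step 0.005 percent) and grating angle within +/- 0.5 degree
#' (step 0.005 degree) of the nominal values.  These widths reflect how
#' precisely the three nonlinear parameters are typically known from the
#' instrument data sheet and a manual angle measurement; narrow or refine
#' them when better priors exist.
#'
#' @param params0 Nominal [spectrometer_params()] supplying grid centres.
#' @param budget Cell budget (passed to [search_grid()]).
#' @return A [search_grid()] over `alpha`, `d_eff`, `theta_d`.
#' @export
default_physical_grid <- function(params0, budget = 1e7) {
  validate_params(params0)
  deg <- pi / 180
  search_grid(
    alpha = grid_axis(params0$alpha, 0.5 * deg, 0.01 * deg),
    d_eff = grid_axis(params0$d_eff, 2e-3 * params0$d_eff, 5e-5 * params0$d_eff),
    theta_d = grid_axis(params0$theta_d, 0.5 * deg, 0.005 * deg),
    budget = budget
  )
}

# ---- internal grid-search machinery -----------------------------------------

# expand grid cells as a numeric matrix (cells x axes), canonical axis order
grid_cells <- function(grid) {
  total <- n_cells(grid)
  if (total > grid$budget) {
    stop(sprintf("search grid has %g cells, exceeding the budget of %g",
                 total, grid$budget), call. = FALSE)
  }
  as.matrix(expand.grid(grid$axes, KEEP.OUT.ATTRS = FALSE))
}

# order-independent argmin with tie-breaking: errors equal within 1e-15
# relative are broken by distance to the grid centre in normalized
# coordinates, then lexicographically by parameter values.
# cells: matrix; err: vector; centres/halfr: named per-axis.
select_best <- function(cells, err, centres, halfr) {
  ok <- which(is.finite(err))
  if (!length(ok)) stop("no physically valid cell in the search grid", call. = FALSE)
  emin <- min(err[ok])
  tol <- 1e-15 * max(emin, .Machine$double.xmin)
  tied <- ok[err[ok] <= emin + tol]
  if (length(tied) > 1L) {
    d2 <- rep(0, length(tied))
    for (j in seq_len(ncol(cells))) {
      hr <- halfr[j]
      if (hr > 0) d2 <- d2 + ((cells[tied, j] - centres[j]) / hr)^2
    }
    tied <- tied[order(d2, cells[tied, 1], cells[tied, min(2, ncol(cells))],
                       cells[tied, min(3, ncol(cells))])]
  }
  tied[1]
}

grid_centres <- function(grid) {
  vapply(grid$axes, function(v) (min(v) + max(v)) / 2, numeric(1))
}
grid_halfranges <- function(grid) {
  vapply(grid$axes, function(v) (max(v) - min(v)) / 2, numeric(1))
}

# predicted pixel positions for a block of cells; returns N x m matrix with
# NaN columns where the asin argument leaves [-1, 1]
predict_block <- function(params0, cells, axnames, lambda0) {
  m <- nrow(cells)
  get <- function(nm, default) if (nm %in% axnames) cells[, nm] else rep(default, m)
  f <- get("f", params0$f)
  Tt <- get("T", params0$T)
  C <- get("C", params0$C)
  dp <- get("d_eff", params0$d_eff)
  al <- get("alpha", params0$alpha)
  th <- get("theta_d", params0$theta_d)
  s <- sin(-al - th)
  off <- frame_offset(params0)
  # u: N x m
  u <- outer(params0$n_order * lambda0, 1 / dp) -
    matrix(params0$k * s, length(lambda0), m, byrow = TRUE)
  bad <- abs(u) > 1
  u[bad] <- NA_real_
  ang <- asin(u) + matrix(th - al, length(lambda0), m, byrow = TRUE)
  x <- tan(ang) * matrix(f / Tt, length(lambda0), m, byrow = TRUE) +
    matrix(C / Tt + off, length(lambda0), m, byrow = TRUE)
  x
}

# ---- Step 1: initial estimate -----------------------------------------------

#' Initial estimate of detector offset and grating angle
#'
#' First calibration step: with focal length, pixel pitch, grating period
#' and half-deviation angle frozen at their nominal values (data-sheet and
#' manual measurement), brute-force search a 2-D grid over the detector
#' centre offset `C` and the grating angle `theta_d`, choosing the cell
#' whose predicted position of a single reference peak is closest to its
#' observed position.
#'
#' @param params_nominal Nominal [spectrometer_params()].
#' @param x0 Observed sub-pixel position of the peak (px).
#' @param lambda0 Reference wavelength of the peak (nm).
#' @param grid A [search_grid()] over exactly `C` and `theta_d`.
#' @return The nominal parameter set with `C` and `theta_d` replaced by the
#'   selected grid values.
#' @export
estimate_initial <- function(params_nominal, x0, lambda0, grid) {
  validate_params(params_nominal)
  stopifnot(inherits(grid, "search_grid"))
  if (!setequal(names(grid$axes), c("C", "theta_d"))) {
    stop("estimate_initial() requires a grid over exactly C and theta_d", call. = FALSE)
  }
  if (length(x0) != 1L || length(lambda0) != 1L) {
    stop("estimate_initial() uses a single peak pair", call. = FALSE)
  }
  cells <- grid_cells(grid)
  x <- predict_block(params_nominal, cells, colnames(cells), lambda0)
  err <- as.numeric((x - x0)^2)
  err[is.na(err)] <- Inf
  best <- select_best(cells, err, grid_centres(grid), grid_halfranges(grid))
  update_params(params_nominal, C = cells[best, "C"], theta_d = cells[best, "theta_d"])
}

# ---- calibration result container -------------------------------------------

new_calibration <- function(lambda_cal, params, map, err, method, peaks,
                            grid_cell = NULL, monotone = TRUE) {
  res <- structure(list(
    lambda_cal = lambda_cal,
    params = params,
    map = map,              # list(slope, intercept): observed ~ intercept + slope * model
    err = err,
    method = method,
    grid_cell = grid_cell,
    n_peaks = peaks$N,
    peaks = peaks,
    monotone = monotone
  ), class = "spec_calibration")
  res$residuals_nm <- predict_wavelength(res, peaks$x0) - peaks$lambda0
  res
}

#' @export
print.spec_calibration <- function(x, ...) {
  cat(sprintf("Wavelength calibration (method: %s)\n", x$method))
  cat(sprintf("  peaks: %d, position misfit err = %.4g px^2\n", x$n_peaks, x$err))
  cat(sprintf("  band: %.4f .. %.4f nm over %d pixels\n",
              x$lambda_cal[1], x$lambda_cal[length(x$lambda_cal)], length(x$lambda_cal)))
  if (!is.null(x$map) && x$method == "physical") {
    cat(sprintf("  linear pixel map: observed = %.8g + %.8g * model\n",
                x$map$intercept, x$map$slope))
  }
  cat(sprintf("  per-peak residuals (nm): MAE %.3g, max %.3g\n",
              mean(abs(x$residuals_nm)), max(abs(x$residuals_nm))))
  invisible(x)
}

#' Continuous calibrated wavelength at arbitrary pixel positions
#'
#' Evaluates the calibration's continuous pixel-to-wavelength map (the
#' physical model composed with the inverse linear pixel map, or the fitted
#' polynomial) at real-valued pixel positions.  This is the map whose values
#' at the integer grid form `lambda_cal`; evaluating it directly avoids any
#' interpolation artifact when scoring sub-pixel peak positions.
#'
#' @param result A calibration from [calibrate_physical()],
#'   [calibrate_bruteforce()] or [calibrate_polynomial()].
#' @param pixel Real-valued pixel position(s).
#' @return Wavelength(s) in nm.
#' @export
predict_wavelength <- function(result, pixel) {
  stopifnot(inherits(result, "spec_calibration"))
  if (result$method %in% c("physical", "bruteforce")) {
    xm <- (pixel - result$map$intercept) / result$map$slope
    pixel_to_wavelength(result$params, xm)
  } else {
    drop(cbind(1, stats::poly(pixel, degree = length(result$coef) - 1L,
                              raw = TRUE, simple = TRUE)) %*% result$coef)
  }
}

# ---- reference algorithm: full brute force ----------------------------------

#' Full brute-force calibration (reference algorithm)
#'
#' Exhaustive search over a grid of spectrometer parameter sets: every cell
#' predicts the pixel positions of the reference wavelengths through the
#' forward model, the cell minimizing the sum-of-squares misfit
#' ([fit_error()]) is selected, and the calibrated wavelength axis is the
#' inverse model evaluated on the integer pixel grid.
#'
#' A six-parameter grid is computationally intractable at useful
#' resolutions, so this serves as the conceptual reference and
#' cross-checking oracle for [calibrate_physical()]; it is intended for
#' small grids only (the cell budget is enforced).  The grid may cover any
#' subset of `f`, `T`, `C`, `alpha`, `d_eff`, `theta_d`; parameters without
#' an axis stay at their `params0` values.
#'
#' Ties in the misfit (equal within 1e-15 relative) are broken by distance
#' to the grid centre in normalized coordinates and then lexicographically
#' by parameter values, making the selection independent of evaluation
#' order.
#'
#' @param peaks A [peak_set()].
#' @param params0 Base [spectrometer_params()] (values for axes not in the
#'   grid, plus the fixed `k`, `n_order`, `n_pixels`).
#' @param grid A [search_grid()].
#' @param chunk_cells Cells evaluated per vectorized block (memory knob).
#' @return A `"spec_calibration"` object with method `"bruteforce"` and an
#'   identity linear pixel map.
#' @export
calibrate_bruteforce <- function(peaks, params0, grid, chunk_cells = 2e5) {
  stopifnot(inherits(peaks, "peak_set"))
  validate_params(params0)
  stopifnot(inherits(grid, "search_grid"))
  if (peaks$N < 1L) stop("at least one peak is required", call. = FALSE)
  cells <- grid_cells(grid)
  centres <- grid_centres(grid)
  halfr <- grid_halfranges(grid)
  total <- nrow(cells)
  best_idx <- NA_integer_
  best_err <- Inf
  for (start in seq(1L, total, by = chunk_cells)) {
    idx <- start:min(start + chunk_cells - 1L, total)
    x <- predict_block(params0, cells[idx, , drop = FALSE], colnames(cells), peaks$lambda0)
    err <- colSums((x - peaks$x0)^2)
    err[is.na(err)] <- Inf
    # merge chunk winner with running best through the shared tie-break rule
    loc <- select_best(cells[idx, , drop = FALSE], err, centres, halfr)
    cand <- idx[loc]
    if (is.na(best_idx)) {
      best_idx <- cand; best_err <- err[loc]
    } else {
      pair <- c(best_idx, cand)
      pick <- select_best(cells[pair, , drop = FALSE], c(best_err, err[loc]), centres, halfr)
      best_idx <- pair[pick]
      best_err <- c(best_err, err[loc])[pick]
    }
  }
  sel <- as.list(cells[best_idx, ])
  params_min <- do.call(update_params, c(list(params0), sel))
  lambda_cal <- pixel_to_wavelength(params_min, seq_len(params_min$n_pixels))
  assert_monotone(lambda_cal, "bruteforce")
  new_calibration(lambda_cal, params_min, list(slope = 1, intercept = 0),
                  best_err, "bruteforce", peaks, grid_cell = sel)
}

# ---- main algorithm: 3-D search with nested least squares -------------------

#' Physical-model calibration (3-D search with nested linear regression)
#'
#' The main calibration algorithm.  The three parameters that enter the
#' model nonlinearly — half-deviation angle `alpha`, effective grating
#' period `d_eff` and grating rotation `theta_d` — are brute-force searched
#' on a grid; the remaining parameters (`f`, `T`, `C`) only shift and scale
#' the detector coordinate, so inside every grid cell they are absorbed
#' exactly by an ordinary least-squares fit of a first-order polynomial
#' mapping the model-predicted positions to the observed ones.  The cell
#' (with its fitted linear map) minimizing the sum-of-squares position
#' misfit wins.
#'
#' The calibrated wavelength axis applies the exact algebraic inverse of
#' the fitted linear map to the integer pixel grid (observed frame to model
#' frame) and then the inverse physical model, so the composition is
#' self-consistent: errors in `f` and `C` are absorbed exactly.
#'
#' Requires at least 4 peaks (as many as the effective free parameters:
#' three searched plus the two regression coefficients, with the regression
#' needing two or more distinct positions).  Tie-breaking is as in
#' [calibrate_bruteforce()], so the result is independent of
#' cell-evaluation order.
#'
#' @param peaks A [peak_set()] with `N >= 4`.
#' @param params0 Nominal [spectrometer_params()] supplying the frozen
#'   `f`, `T`, `C` and the fixed `k`, `n_order`, `n_pixels`.
#' @param grid A [search_grid()] over exactly `alpha`, `d_eff`, `theta_d`.
#'   Defaults to [default_physical_grid()].
#' @param refine If `TRUE`, run one refinement pass: a finer grid spanning
#'   one original step around the selected cell (step divided by 10).  The
#'   misfit is never larger after refinement since the selected cell is in
#'   the refined grid.
#' @param chunk_cells Cells evaluated per vectorized block (memory knob).
#' @return A `"spec_calibration"` object with method `"physical"`, carrying
#'   the selected parameters, the linear pixel map (slope, intercept of
#'   observed ~ model), the misfit `err` and per-peak residuals in nm.
#' @export
calibrate_physical <- function(peaks, params0, grid = default_physical_grid(params0),
                               refine = FALSE, chunk_cells = 2e5) {
  stopifnot(inherits(peaks, "peak_set"))
  validate_params(params0)
  stopifnot(inherits(grid, "search_grid"))
  if (!setequal(names(grid$axes), c("alpha", "d_eff", "theta_d"))) {
    stop("calibrate_physical() requires a grid over exactly alpha, d_eff and theta_d",
         call. = FALSE)
  }
  if (peaks$N < 4L) stop("calibrate_physical() requires at least 4 peaks", call. = FALSE)
  if (length(unique(peaks$x0)) < 2L) stop("degenerate regression: need 2+ distinct positions",
                                          call. = FALSE)
  res <- physical_search(peaks, params0, grid, chunk_cells)
  if (refine) {
    steps <- vapply(grid$axes, function(v) if (length(v) > 1L) min(diff(v)) else 0, numeric(1))
    fine <- list()
    for (nm in names(grid$axes)) {
      c0 <- res$grid_cell[[nm]]
      fine[[nm]] <- if (steps[nm] > 0) grid_axis(c0, steps[nm], steps[nm] / 10) else c0
    }
    fine$budget <- grid$budget
    res2 <- physical_search(peaks, params0, do.call(search_grid, fine), chunk_cells)
    if (res2$err <= res$err) res <- res2
  }
  res
}

physical_search <- function(peaks, params0, grid, chunk_cells) {
  cells <- grid_cells(grid)
  centres <- grid_centres(grid)
  halfr <- grid_halfranges(grid)
  total <- nrow(cells)
  x0 <- peaks$x0
  x0c <- x0 - mean(x0)
  N <- peaks$N
  best_idx <- NA_integer_
  best_err <- Inf
  for (start in seq(1L, total, by = chunk_cells)) {
    idx <- start:min(start + chunk_cells - 1L, total)
    x <- predict_block(params0, cells[idx, , drop = FALSE], colnames(cells), peaks$lambda0)
    # per-column simple regression x0 ~ x; residuals formed explicitly (the
    # textbook Syy - Sxy^2/Sxx shortcut cancels catastrophically near err = 0)
    mx <- colMeans(x)
    xc <- sweep(x, 2, mx)
    Sxx <- colSums(xc^2)
    slope <- as.numeric(crossprod(xc, x0c)) / Sxx
    err <- colSums((x0c - xc * rep(slope, each = N))^2)
    err[!is.finite(err) | Sxx <= 0] <- Inf
    loc <- select_best(cells[idx, , drop = FALSE], err, centres, halfr)
    cand <- idx[loc]
    if (is.na(best_idx)) {
      best_idx <- cand; best_err <- err[loc]
    } else {
      pair <- c(best_idx, cand)
      pick <- select_best(cells[pair, , drop = FALSE], c(best_err, err[loc]), centres, halfr)
      best_idx <- pair[pick]
      best_err <- c(best_err, err[loc])[pick]
    }
  }
  if (!is.finite(best_err)) stop("no physically valid cell in the search grid", call. = FALSE)
  sel <- as.list(cells[best_idx, ])
  params_min <- do.call(update_params, c(list(params0), sel))
  # final regression at the selected cell, in full precision
  xm <- wavelength_to_pixel(params_min, peaks$lambda0)
  fit <- stats::lm.fit(cbind(1, xm), x0)
  intercept <- fit$coefficients[1]
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope == 0) stop("degenerate linear pixel map", call. = FALSE)
  err <- sum(fit$residuals^2)
  px_model <- (seq_len(params_min$n_pixels) - intercept) / slope
  lambda_cal <- pixel_to_wavelength(params_min, px_model)
  assert_monotone(lambda_cal, "physical")
  new_calibration(lambda_cal, params_min,
                  list(slope = unname(slope), intercept = unname(intercept)),
                  err, "physical", peaks, grid_cell = sel)
}

assert_monotone <- function(lambda_cal, method) {
  dl <- diff(lambda_cal)
  if (!(all(dl > 0) || all(dl < 0))) {
    stop(sprintf("calibrated wavelength axis from method '%s' is not strictly monotone", method),
         call. = FALSE)
  }
  invisible(TRUE)
}

# ---- polynomial baselines ---------------------------------------------------

#' Polynomial wavelength calibration (traditional baseline)
#'
#' Ordinary least-squares fit of a first-, second- or third-order polynomial
#' wavelength(pixel) to the reference peaks, evaluated on the integer pixel
#' grid.  This is the traditional calibration approach against which the
#' physical-model method is compared; it interpolates well between reference
#' lines but extrapolates poorly beyond the outermost ones (orders >= 2).
#'
#' @param peaks A [peak_set()] with `N >= order + 1`.
#' @param order Polynomial order: 1, 2 or 3.
#' @param n_pixels Number of detector pixels for the output axis.
#' @return A `"spec_calibration"` object with method `"poly<order>"`.  If
#'   the fitted polynomial is not strictly monotone across the detector a
#'   warning is issued and the `monotone` field is set to `FALSE` (the
#'   continuous map is still usable for scoring peak positions).
#' @export
calibrate_polynomial <- function(peaks, order, n_pixels) {
  stopifnot(inherits(peaks, "peak_set"))
  if (!order %in% 1:3) stop("polynomial order must be 1, 2 or 3", call. = FALSE)
  if (peaks$N < order + 1L) {
    stop(sprintf("order-%d polynomial needs at least %d peaks, got %d",
                 order, order + 1L, peaks$N), call. = FALSE)
  }
  X <- stats::poly(peaks$x0, degree = order, raw = TRUE, simple = TRUE)
  fit <- stats::lm.fit(cbind(1, X), peaks$lambda0)
  coefs <- unname(fit$coefficients)
  px <- seq_len(n_pixels)
  lambda_cal <- drop(cbind(1, stats::poly(px, degree = order, raw = TRUE,
                                          simple = TRUE)) %*% coefs)
  mono <- all(diff(lambda_cal) > 0) || all(diff(lambda_cal) < 0)
  if (!mono) warning(sprintf("order-%d polynomial calibration is not monotone across the detector",
                             order), call. = FALSE)
  res <- structure(list(
    lambda_cal = lambda_cal,
    params = NULL,
    map = NULL,
    coef = coefs,
    err = sum(fit$residuals^2),  # wavelength-domain residual SS (nm^2)
    method = paste0("poly", order),
    grid_cell = NULL,
    n_peaks = peaks$N,
    peaks = peaks,
    monotone = mono
  ), class = "spec_calibration")
  res$residuals_nm <- predict_wavelength(res, peaks$x0) - peaks$lambda0
  res
}
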