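test_that("fit_error matches its definition", {
  expect_equal(fit_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(fit_error(c(1.5, 2.5), c(1, 2)), 0.5)  # 2 * 0.5^2
  set.seed(3)
  a <- rnorm(7); b <- rnorm(7)
  loop <- 0
  for (i in 1:7) loop <- loop + (a[i] - b[i])^2
  expect_equal(fit_error(a, b), loop, tolerance = 1e-15)
  expect_error(fit_error(1:3, 1:4), "equal length")
})

test_that("grid axes are symmetric about their centre and respect the budget", {
  v <- grid_axis(10, 0.5, 0.1)
  expect_equal(v, seq(9.5, 10.5, by = 0.1))
  expect_equal(grid_axis(3, 0, 1), 3)
  g <- search_grid(alpha = 1:100, d_eff = 1:100, theta_d = 1:100, budget = 1e5)
  p <- load_cfg("czerny_turner_600")
  expect_error(calibrate_physical(truth_peaks(p, band_wavelengths(p, 5)), p, g),
               "budget")
})

test_that("estimate_initial recovers an on-grid offset and grating angle exactly", {
  p <- load_cfg("czerny_turner_600")
  lam <- band_wavelengths(p, 1)
  th_true <- p$theta_d + 0.02 * deg
  p_true <- update_params(p, theta_d = th_true, C = 0)
  x0 <- wavelength_to_pixel(p_true, lam)
  g <- search_grid(C = grid_axis(0, 50e3, 5e3),
                   theta_d = grid_axis(p$theta_d, 0.05 * deg, 0.01 * deg))
  est <- estimate_initial(p, x0, lam, g)
  expect_equal(est$theta_d, th_true, tolerance = 1e-12)
  expect_equal(est$C, 0, tolerance = 1e-9)
})

test_that("a pure position shift is attributed to the detector offset as C = shift * T", {
  p <- load_cfg("czerny_turner_600")
  lam <- band_wavelengths(p, 1)
  x0 <- wavelength_to_pixel(p, lam) + 2    # shifted 2 px
  g <- search_grid(C = grid_axis(0, 100e3, 1e3),
                   theta_d = grid_axis(p$theta_d, 0, 1))  # theta frozen at truth
  est <- estimate_initial(p, x0, lam, g)
  expect_equal(est$C, 2 * p$T, tolerance = 1e-9)
})

test_that("off-grid truth selects the same cell as an exhaustive loop oracle", {
  p <- load_cfg("czerny_turner_600")
  lam <- band_wavelengths(p, 1)
  p_true <- update_params(p, C = 3.7e3, theta_d = p$theta_d + 0.0123 * deg)
  x0 <- wavelength_to_pixel(p_true, lam)
  C_vals <- grid_axis(0, 10e3, 2e3)
  th_vals <- grid_axis(p$theta_d, 0.03 * deg, 0.01 * deg)
  g <- search_grid(C = C_vals, theta_d = th_vals)
  est <- estimate_initial(p, x0, lam, g)
  # independent exhaustive loop
  best <- c(NA, NA); best_err <- Inf
  for (C in C_vals) for (th in th_vals) {
    xj <- wavelength_to_pixel(update_params(p, C = C, theta_d = th), lam)
    e <- abs(xj - x0)
    if (e < best_err) { best_err <- e; best <- c(C, th) }
  }
  expect_equal(est$C, best[1])
  expect_equal(est$theta_d, best[2])
})

test_that("brute force selects the generating cell with machine-zero misfit", {
  p <- load_cfg("czerny_turner_600")
  lam <- band_wavelengths(p, 6)
  p_true <- update_params(p, alpha = p$alpha + 0.01 * deg,
                          theta_d = p$theta_d - 0.005 * deg)
  peaks <- truth_peaks(p_true, lam)
  g <- centered_grid(p_true, n_half = 1)
  cal <- calibrate_bruteforce(peaks, p, g)
  expect_lt(cal$err, 1e-18)
  expect_equal(cal$grid_cell$alpha, p_true$alpha)
  expect_equal(cal$grid_cell$theta_d, p_true$theta_d)
  expect_equal(cal$grid_cell$d_eff, p_true$d_eff)
})

test_that("brute-force selection is independent of chunked evaluation order", {
  p <- load_cfg("czerny_turner_1000")
  lam <- band_wavelengths(p, 5)
  p_true <- update_params(p, alpha = p$alpha - 0.013 * deg)  # off-grid
  peaks <- truth_peaks(p_true, lam)
  g <- centered_grid(p, n_half = 2)
  cal_a <- calibrate_bruteforce(peaks, p, g, chunk_cells = 1e5)
  cal_b <- calibrate_bruteforce(peaks, p, g, chunk_cells = 7)
  expect_identical(cal_a$grid_cell, cal_b$grid_cell)
  expect_identical(cal_a$lambda_cal, cal_b$lambda_cal)
})

test_that("symmetric ties are broken deterministically toward the grid centre", {
  p <- load_cfg("czerny_turner_600")
  lam <- band_wavelengths(p, 4)
  peaks <- truth_peaks(p, lam)
  # C axis symmetric about the truth: +/- delta give identical misfit
  g <- search_grid(C = grid_axis(0, 10e3, 5e3), theta_d = p$theta_d,
                   alpha = p$alpha, d_eff = p$d_eff)
  cal <- calibrate_bruteforce(peaks, p, g)
  expect_equal(cal$grid_cell$C, 0)
  cal2 <- calibrate_bruteforce(peaks, p, g, chunk_cells = 3)
  expect_identical(cal$grid_cell, cal2$grid_cell)
})

test_that("a single-peak brute force over C alone reduces to the initial estimator", {
  p <- load_cfg("czerny_turner_600")
  lam <- band_wavelengths(p, 1)
  x0 <- wavelength_to_pixel(p, lam) + 1.5
  C_vals <- grid_axis(0, 80e3, 1e3)
  cal <- calibrate_bruteforce(peak_set(x0, lam), p,
                              search_grid(C = C_vals))
  est <- estimate_initial(p, x0, lam,
                          search_grid(C = C_vals, theta_d = p$theta_d))
  expect_equal(cal$grid_cell$C, est$C)
})

test_that("the physical calibrator reduces to the identity map on self-consistent peaks", {
  p <- load_cfg("czerny_turner_600")
  peaks <- truth_peaks(p, band_wavelengths(p, 8))
  cal <- calibrate_physical(peaks, p, centered_grid(p))
  expect_equal(cal$grid_cell$alpha, p$alpha)
  expect_equal(cal$grid_cell$d_eff, p$d_eff)
  expect_equal(cal$grid_cell$theta_d, p$theta_d)
  expect_lt(abs(cal$map$slope - 1), 1e-12)
  expect_lt(abs(cal$map$intercept), 1e-9)
  expect_lt(cal$err, 1e-18)
})

test_that("focal-length and centre-offset errors are absorbed exactly by the linear map", {
  p <- load_cfg("czerny_turner_600")
  lam <- band_wavelengths(p, 8)
  p_true <- update_params(p, f = p$f * 1.01, C = p$C + 30e3)  # 30 um shift
  peaks <- truth_peaks(p_true, lam)
  cal <- calibrate_physical(peaks, p, centered_grid(p))
  expect_equal(cal$grid_cell$alpha, p$alpha)   # truth cell reselected
  expect_lt(max(abs(peak_errors(cal, peaks))), 1e-6)
  expect_equal(cal$map$slope, 1.01, tolerance = 1e-9)
})

test_that("the 3-D search with nested regression reproduces the full brute force", {
  p <- load_cfg("czerny_turner_600")
  lam <- band_wavelengths(p, 8)
  p_true <- update_params(p, alpha = p$alpha + 0.01 * deg,
                          d_eff = p$d_eff * (1 + 1e-4))
  peaks <- truth_peaks(p_true, lam)
  g3 <- centered_grid(p_true, n_half = 1)
  # Algorithm-1 oracle searches f, T, C too, on grids containing the truth
  g6 <- search_grid(
    alpha = g3$axes$alpha, d_eff = g3$axes$d_eff, theta_d = g3$axes$theta_d,
    f = grid_axis(p$f, 0.002 * p$f, 0.001 * p$f),
    C = grid_axis(p$C, 20e3, 10e3)
  )
  cal2 <- calibrate_physical(peaks, p, g3)
  cal1 <- calibrate_bruteforce(peaks, p, g6)
  expect_lt(max(abs(cal1$lambda_cal - cal2$lambda_cal)), 1e-6)
})

test_that("one refinement pass never increases the misfit", {
  p <- load_cfg("czerny_turner_600")
  lam <- band_wavelengths(p, 8)
  p_true <- update_params(p, theta_d = p$theta_d + 0.0032 * deg)  # off-grid
  peaks <- truth_peaks(p_true, lam)
  g <- centered_grid(p, n_half = 2)
  coarse <- calibrate_physical(peaks, p, g)
  fine <- calibrate_physical(peaks, p, g, refine = TRUE)
  expect_lte(fine$err, coarse$err)
  expect_lt(max(abs(fine$residuals_nm)), max(abs(coarse$residuals_nm)) + 1e-12)
})

test_that("two peaks define an exact first-order polynomial calibration", {
  peaks <- peak_set(c(100, 900), c(600, 680))
  cal <- calibrate_polynomial(peaks, 1, 1024)
  expect_equal(cal$residuals_nm, c(0, 0), tolerance = 1e-12)
  expect_equal(predict_wavelength(cal, 500), 600 + 80 * 400 / 800, tolerance = 1e-12)
})

test_that("collinear points leave higher polynomial coefficients at zero", {
  x <- c(100, 300, 600, 900)
  peaks <- peak_set(x, 500 + 0.1 * x)
  cal <- calibrate_polynomial(peaks, 3, 1024)
  expect_equal(cal$coef[1], 500, tolerance = 1e-6)
  expect_equal(cal$coef[2], 0.1, tolerance = 1e-8)
  expect_lt(abs(cal$coef[3]), 1e-10)
  expect_lt(abs(cal$coef[4]), 1e-13)
})

test_that("cubic extrapolation beyond the last reference line is worse than the physical model", {
  p <- load_cfg("transmission_2455")
  b <- band_limits(p)
  lam <- seq(b[1] + 4, b[1] + 0.55 * diff(b), length.out = 8)  # left-biased lines
  peaks <- truth_peaks(p, lam)
  cal3 <- calibrate_polynomial(peaks, 3, p$n_pixels)
  calp <- calibrate_physical(peaks, p, centered_grid(p, n_half = 1))
  x_far <- max(peaks$x0) + 200
  lam_true <- pixel_to_wavelength(p, x_far)
  err3 <- abs(predict_wavelength(cal3, x_far) - lam_true)
  errp <- abs(predict_wavelength(calp, x_far) - lam_true)
  expect_gt(err3, errp)
})

test_that("insufficient peaks are refused with a clear message", {
  peaks <- peak_set(c(100, 500, 900), c(600, 640, 680))
  expect_error(calibrate_polynomial(peaks, 3, 1024), "at least 4 peaks")
  p <- load_cfg("czerny_turner_600")
  expect_error(calibrate_physical(peaks, p, centered_grid(p, 1)), "at least 4")
})
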