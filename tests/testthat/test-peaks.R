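make_lorentz_spectrum <- function(centres, p1 = 4000, p3 = 4, baseline = 10,
                                  n = 1024) {
  px <- seq_len(n)
  y <- rep(baseline, n)
  for (c0 in centres) y <- y + p1 / ((px - c0)^2 + p3)
  spectrum(y)
}

test_that("a flat spectrum yields no peak candidates", {
  expect_identical(detect_peaks(spectrum(rep(100, 64))), integer(0))
})

test_that("well-separated synthetic lines are each detected within 1 px of the apex", {
  p <- load_cfg("czerny_turner_600")
  lam <- band_wavelengths(p, 10)
  sim <- simulation_spec(p, lamp_lines(lam), noise = "none", seed = 1)
  out <- render_spectrum(sim)
  apexes <- detect_peaks(out$spectrum, min_prominence = 500, min_separation = 5)
  expect_length(apexes, 10)
  expect_true(all(abs(apexes - out$truth$x0) < 1))
})

test_that("two lines closer than the separation threshold collapse to one candidate", {
  s <- make_lorentz_spectrum(c(200, 203))
  expect_length(detect_peaks(s, min_prominence = 50, min_separation = 5), 1L)
  expect_length(detect_peaks(s, min_prominence = 50, min_separation = 2), 2L)
})

test_that("noiseless Lorentzian samples are refit to their exact generating centre", {
  px <- seq_len(1024)
  y <- 1000 / ((px - 512.3)^2 + 4.0) + 10
  fit <- fit_lorentzian(spectrum(y), apex = 512, half_window = 5)
  expect_lt(abs(fit$P2 - 512.3), 1e-6)
  expect_equal(fit$P1, 1000, tolerance = 1e-4)
  expect_equal(fit$P3, 4.0, tolerance = 1e-4)
  expect_equal(fit$P4, 10, tolerance = 1e-3)
})

test_that("exactly symmetric data centre the fit on the axis of symmetry", {
  px <- seq_len(64)
  y <- 500 / ((px - 30.5)^2 + 6) + 5    # symmetric about 30.5
  fit <- fit_lorentzian(spectrum(y), apex = 30, half_window = 5)
  expect_equal(fit$P2, 30.5, tolerance = 1e-9)
})

test_that("a Gaussian peak is localized to sub-pixel precision, beating the integer argmax", {
  px <- seq_len(256)
  centre <- 100.25
  y <- 2000 * exp(-(px - centre)^2 / (2 * 2^2)) + 50
  s <- spectrum(y)
  apex <- which.max(y)
  fit <- fit_lorentzian(s, apex, half_window = 5)
  # independent oracle: argmax of the continuous Gaussian on a dense grid
  dense <- seq(90, 110, by = 1e-4)
  oracle <- dense[which.max(2000 * exp(-(dense - centre)^2 / (2 * 2^2)))]
  expect_lt(abs(fit$P2 - oracle), 0.05)
  expect_lt(abs(fit$P2 - centre), abs(apex - centre))
})

test_that("the fit absorbs baseline offsets and intensity scaling without moving the centre", {
  px <- seq_len(512)
  y <- 3000 / ((px - 250.4)^2 + 5) + 20
  f0 <- fit_lorentzian(spectrum(y), 250, 5)
  f_shift <- fit_lorentzian(spectrum(y + 111), 250, 5)
  expect_equal(f_shift$P2, f0$P2, tolerance = 1e-8)
  expect_equal(f_shift$P4, f0$P4 + 111, tolerance = 1e-6)
  f_scale <- fit_lorentzian(spectrum(3 * y), 250, 5)
  expect_equal(f_scale$P2, f0$P2, tolerance = 1e-8)
  expect_equal(f_scale$P3, f0$P3, tolerance = 1e-6)
  expect_equal(f_scale$P1 / f0$P1, 3, tolerance = 1e-6)
})

test_that("saturated windows are rejected", {
  px <- seq_len(128)
  y <- pmin(5000 / ((px - 64)^2 + 4) + 10, 900)
  expect_error(fit_lorentzian(spectrum(y), 64, 5, saturation = 900), "saturated")
})

test_that("sub-pixel recovery survives counting noise in at least 95 percent of trials", {
  set.seed(7)
  px <- seq_len(64)
  truth <- 32.37
  p3 <- 4
  signal <- 1e4 * p3 / ((px - truth)^2 + p3) + 100   # amplitude 1e4 over baseline 100
  hits <- 0L
  for (trial in 1:100) {
    y <- rpois(length(px), signal)
    fit <- tryCatch(fit_lorentzian(spectrum(y), which.max(y), 5), error = function(e) NULL)
    if (!is.null(fit) && abs(fit$P2 - truth) < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("model-generated positions match their generating lines one-to-one", {
  p <- load_cfg("czerny_turner_600")
  lam <- band_wavelengths(p, 8)
  pos <- wavelength_to_pixel(p, lam)
  res <- match_lines(pos, lamp_lines(lam), p, tolerance = 0.5)
  expect_equal(res$peaks$N, 8L)
  # this reflection geometry disperses in reverse: wavelength falls with pixel
  expect_equal(res$peaks$lambda0, sort(lam, decreasing = TRUE))
  expect_length(res$unmatched_positions, 0)
  expect_length(res$unmatched_lines, 0)
})

test_that("an empty line list leaves every position unmatched", {
  p <- load_cfg("czerny_turner_600")
  res <- match_lines(c(100, 200), lamp_lines(numeric(0)), p, tolerance = 0.5)
  expect_equal(res$peaks$N, 0L)
  expect_equal(res$unmatched_positions, c(100, 200))
})

test_that("spurious detections far from any line are reported unmatched, not dropped silently", {
  p <- load_cfg("czerny_turner_600")
  lam <- band_wavelengths(p, 5)
  pos <- wavelength_to_pixel(p, lam)
  spurious <- wavelength_to_pixel(p, lam[3] + 10)  # 10 nm from any line
  res <- match_lines(c(pos, spurious), lamp_lines(lam), p, tolerance = 0.5)
  expect_equal(res$peaks$N, 5L)
  expect_equal(res$unmatched_positions, spurious)
})

test_that("two lines within tolerance of one position is an ambiguity error", {
  p <- load_cfg("czerny_turner_600")
  lam <- 640
  pos <- wavelength_to_pixel(p, lam)
  lines <- lamp_lines(c(639.9, 640.1))
  expect_error(match_lines(pos, lines, p, tolerance = 0.5), "ambiguous")
})

test_that("matched peak sets always satisfy the monotonicity invariant", {
  p <- load_cfg("czerny_turner_600")
  set.seed(11)
  for (i in 1:20) {
    lam <- sort(runif(6, band_limits(p)[1] + 3, band_limits(p)[2] - 3))
    if (min(diff(lam)) < 1.2) next
    pos <- wavelength_to_pixel(p, lam) + rnorm(6, sd = 0.1)
    res <- match_lines(pos, lamp_lines(lam), p, tolerance = 0.5)
    dl <- diff(res$peaks$lambda0)
    expect_true(all(dl > 0) || all(dl < 0))
  }
})
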