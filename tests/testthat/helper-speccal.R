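# shared fixtures and independent oracles for the test suite

deg <- pi / 180

load_cfg <- function(name) {
  read_config(system.file("extdata", paste0("config_", name, ".cfg"),
                          package = "speccal"))
}

all_configs <- function() {
  lapply(c("czerny_turner_300", "czerny_turner_600", "czerny_turner_1000",
           "transmission_2455"), load_cfg)
}

# wavelengths spread across the detector band, keeping a margin off the ends
band_wavelengths <- function(params, n, margin = 0.02) {
  b <- band_limits(params)
  span <- diff(b)
  seq(b[1] + margin * span, b[2] - margin * span, length.out = n)
}

# exact peak set implied by a parameter set and a wavelength vector
truth_peaks <- function(params, wavelengths) {
  peak_set(wavelength_to_pixel(params, wavelengths), wavelengths)
}

# ---- stepwise ray-trace oracle ----------------------------------------------
# Solves the rotated grating equation for the diffracted angle numerically by
# bisection (no closed-form arcsin), then traces the ray to the detector with
# independent trigonometry.  Used to cross-check the closed forms.

oracle_beta <- function(params, wavelength) {
  g <- function(beta) {
    sin(beta - params$theta_d) + params$k * sin(-params$alpha - params$theta_d) -
      params$n_order * wavelength / params$d_eff
  }
  lo <- params$theta_d - pi / 2 + 1e-12
  hi <- params$theta_d + pi / 2 - 1e-12
  if (g(lo) * g(hi) > 0) stop("oracle: no diffracted ray within the principal branch")
  stats::uniroot(g, c(lo, hi), tol = 1e-15)$root
}

oracle_pixel <- function(params, wavelength) {
  vapply(wavelength, function(w) {
    beta <- oracle_beta(params, w)
    (params$f / params$T) * tan(beta - params$alpha) +
      params$C / params$T + (params$n_pixels + 1) / 2
  }, numeric(1))
}

# small symmetric grid with the truth at its centre
centered_grid <- function(params, n_half = 2,
                          alpha_step = 0.01 * deg,
                          d_rel_step = 1e-4,
                          theta_step = 0.005 * deg, budget = 1e7) {
  search_grid(
    alpha = grid_axis(params$alpha, n_half * alpha_step, alpha_step),
    d_eff = grid_axis(params$d_eff, n_half * d_rel_step * params$d_eff,
                      d_rel_step * params$d_eff),
    theta_d = grid_axis(params$theta_d, n_half * theta_step, theta_step),
    budget = budget
  )
}
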