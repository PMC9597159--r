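#' Spectrometer parameter set
#'
#' Construct the full set of physical parameters describing a grating
#' spectrometer with an array detector.  All lengths are stored internally in
#' nanometres and all angles in radians; the config-file reader
#' ([read_config()]) converts from the conventional units (mm, um, degrees,
#' lines/mm) at the boundary.
#'
#' The parameter set consists of:
#' \describe{
#'   \item{f}{focal length of the focusing optic (nm).}
#'   \item{T}{detector pixel pitch (nm).}
#'   \item{C}{misalignment of the detector centre along the dispersion axis
#'     (nm); `C = 0` places the axial wavelength at the detector centre.}
#'   \item{d_eff}{effective grating period d' = d cos(gamma) (nm), where
#'     gamma is the vertical oblique angle caused by displacement of the
#'     irradiance spot along the slit.  Only the product is identifiable, so
#'     gamma is never stored separately.}
#'   \item{alpha}{half-deviation angle of the spectrometer (rad).}
#'   \item{theta_d}{grating rotation angle from the flat position (rad),
#'     counterclockwise positive.}
#'   \item{k}{sign with which the incident-angle term enters the grating
#'     equation (+1 or -1).  See Details.}
#'   \item{n_order}{signed diffraction order (typically -1 or +1).}
#'   \item{n_pixels}{number of detector pixels along the dispersion axis.}
#' }
#'
#' @details
#' The model implemented by [wavelength_to_pixel()] and
#' [pixel_to_wavelength()] writes the rotated grating equation as
#' \deqn{n \lambda / d' = \sin(\beta - \theta_d) + k \sin(-\alpha - \theta_d)}
#' The sign `k` selects how the incident-angle term combines with the
#' diffracted one.  With this equation orientation, a classical
#' Czerny-Turner reflection geometry (band centre at
#' \eqn{2 d' \cos\alpha \sin\theta_d}) corresponds to `k = +1`, and a
#' symmetric volume-holographic transmission geometry at alpha = 45 degrees
#' (band centre at \eqn{2 d' \sin\alpha}) corresponds to `k = -1`.  The
#' constructor applies this mapping when `k` is derived from `grating_type`;
#' pass `k` explicitly to override.
#'
#' @param f Focal length in nm (e.g. `5e8` for 500 mm).
#' @param T Pixel pitch in nm (e.g. `26e3` for 26 um).
#' @param d_eff Effective grating period in nm.
#' @param alpha Half-deviation angle in radians.
#' @param theta_d Grating rotation angle in radians.
#' @param C Detector-centre offset in nm.  Default 0.
#' @param grating_type `"reflection"` or `"transmission"`; sets the default
#'   sign `k` and diffraction order `n_order`.
#' @param k Incidence-term sign, +1 or -1.  Defaults from `grating_type`.
#' @param n_order Signed diffraction order.  Defaults to -1 for reflection
#'   and +1 for transmission.
#' @param n_pixels Number of detector pixels (>= 2).  Default 1024.
#' @param label Optional instrument label carried through reports.
#'
#' @return An object of class `"spec_params"` (a named list).
#' @examples
#' p <- spectrometer_params(
#'   f = 5e8, T = 26e3, d_eff = 1e6 / 600,
#'   alpha = 21.88 * pi / 180, theta_d = 12 * pi / 180,
#'   grating_type = "reflection"
#' )
#' pixel_to_wavelength(p, c(1, 512.5, 1024))
#' @seealso [read_config()], [wavelength_to_pixel()], [pixel_to_wavelength()]
#' @export
spectrometer_params <- function(f, T, d_eff, alpha, theta_d, C = 0,
                                grating_type = c("reflection", "transmission"),
                                k = NULL, n_order = NULL, n_pixels = 1024,
                                label = NULL) {
  grating_type <- match.arg(grating_type)
  if (is.null(k)) k <- if (grating_type == "reflection") 1 else -1
  if (is.null(n_order)) n_order <- if (grating_type == "reflection") -1L else 1L
  p <- list(
    f = as.numeric(f), T = as.numeric(T), C = as.numeric(C),
    d_eff = as.numeric(d_eff), alpha = as.numeric(alpha),
    theta_d = as.numeric(theta_d), k = as.numeric(k),
    n_order = as.integer(n_order), n_pixels = as.integer(n_pixels),
    grating_type = grating_type, label = label
  )
  class(p) <- "spec_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "spec_params"))
  scalars <- c("f", "T", "C", "d_eff", "alpha", "theta_d", "k")
  for (nm in scalars) {
    if (length(p[[nm]]) != 1L || !is.finite(p[[nm]])) {
      stop(sprintf("parameter '%s' must be a finite scalar", nm), call. = FALSE)
    }
  }
  if (p$f <= 0) stop("focal length f must be positive", call. = FALSE)
  if (p$T <= 0) stop("pixel pitch T must be positive", call. = FALSE)
  if (p$d_eff <= 0) stop("effective grating period d_eff must be positive", call. = FALSE)
  if (!p$k %in% c(-1, 1)) stop("k must be +1 or -1", call. = FALSE)
  if (p$n_order == 0L) stop("diffraction order n_order must be nonzero", call. = FALSE)
  if (p$n_pixels < 2L) stop("n_pixels must be at least 2", call. = FALSE)
  invisible(p)
}

#' Modify a parameter set
#'
#' Return a copy of a `spec_params` object with the named fields replaced.
#' Used heavily by the calibration search, which evaluates the model over
#' many perturbed parameter sets.
#'
#' @param params A `spec_params` object.
#' @param ... Named fields to replace (any of `f`, `T`, `C`, `d_eff`,
#'   `alpha`, `theta_d`, `k`, `n_order`, `n_pixels`).
#' @return A validated `spec_params` object.
#' @export
update_params <- function(params, ...) {
  validate_params(params)
  repl <- list(...)
  bad <- setdiff(names(repl), c("f", "T", "C", "d_eff", "alpha", "theta_d",
                                "k", "n_order", "n_pixels", "label"))
  if (length(bad)) stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (nm in names(repl)) params[[nm]] <- unname(repl[[nm]])
  if (!is.null(repl$n_order)) params$n_order <- as.integer(repl$n_order)
  if (!is.null(repl$n_pixels)) params$n_pixels <- as.integer(repl$n_pixels)
  validate_params(params)
  params
}

#' @export
print.spec_params <- function(x, ...) {
  deg <- 180 / pi
  cat("Spectrometer parameters", if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  cat(sprintf("  grating type     : %s (k = %+d, order n = %+d)\n",
              x$grating_type, as.integer(x$k), x$n_order))
  cat(sprintf("  focal length f   : %.6g mm\n", x$f / 1e6))
  cat(sprintf("  pixel pitch T    : %.6g um\n", x$T / 1e3))
  cat(sprintf("  centre offset C  : %.6g um\n", x$C / 1e3))
  cat(sprintf("  grating period d': %.8g nm (%.6g lines/mm)\n", x$d_eff, 1e6 / x$d_eff))
  cat(sprintf("  half-deviation a : %.6g deg\n", x$alpha * deg))
  cat(sprintf("  grating angle td : %.6g deg\n", x$theta_d * deg))
  cat(sprintf("  detector         : %d pixels\n", x$n_pixels))
  invisible(x)
}

#' Read a spectrometer configuration file
#'
#' Parses a flat key-value text file (one `key = value` per line, `#`
#' comments) holding a spectrometer configuration in conventional units and
#' returns a [spectrometer_params()] object in internal units (nm, rad).
#'
#' Recognised keys: `focal_length_mm`, `pixel_pitch_um`,
#' `grating_lines_per_mm`, `half_deviation_deg`, `grating_angle_deg`,
#' `grating_type` (`reflection` | `transmission`), `diffraction_order`,
#' `n_pixels`, `center_offset_um`, and optionally `incidence_sign` (+1/-1,
#' overriding the sign implied by `grating_type`) and `label`.
#' Unknown keys are rejected with their location.
#'
#' Four example configurations are shipped with the package, retrievable via
#' `system.file("extdata", ..., package = "speccal")`:
#' `config_czerny_turner_300.cfg`, `config_czerny_turner_600.cfg`,
#' `config_czerny_turner_1000.cfg` (500 mm Czerny-Turner, reflection
#' gratings) and `config_transmission_2455.cfg` (85 mm volume-holographic
#' transmission spectrometer).
#'
#' @param path Path to the configuration file.
#' @return A `spec_params` object.
#' @examples
#' cfg <- system.file("extdata", "config_czerny_turner_600.cfg", package = "speccal")
#' read_config(cfg)
#' @export
read_config <- function(path) {
  kv <- read_keyvalue(path)
  known <- c("focal_length_mm", "pixel_pitch_um", "grating_lines_per_mm",
             "half_deviation_deg", "grating_angle_deg", "grating_type",
             "diffraction_order", "n_pixels", "center_offset_um",
             "incidence_sign", "label")
  bad <- setdiff(names(kv), known)
  if (length(bad)) {
    stop(sprintf("unknown key(s) in %s: %s", path, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  req <- c("focal_length_mm", "pixel_pitch_um", "grating_lines_per_mm",
           "half_deviation_deg", "grating_angle_deg", "grating_type", "n_pixels")
  miss <- setdiff(req, names(kv))
  if (length(miss)) {
    stop(sprintf("missing key(s) in %s: %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  num <- function(key, default = NULL) {
    if (!key %in% names(kv)) return(default)
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop(sprintf("non-numeric value for '%s' in %s", key, path),
                       call. = FALSE)
    v
  }
  deg <- pi / 180
  spectrometer_params(
    f = num("focal_length_mm") * 1e6,
    T = num("pixel_pitch_um") * 1e3,
    C = num("center_offset_um", 0) * 1e3,
    d_eff = 1e6 / num("grating_lines_per_mm"),
    alpha = num("half_deviation_deg") * deg,
    theta_d = num("grating_angle_deg") * deg,
    grating_type = kv[["grating_type"]],
    k = num("incidence_sign", NULL),
    n_order = num("diffraction_order", NULL),
    n_pixels = num("n_pixels"),
    label = kv[["label"]]
  )
}

# parse "key = value" lines; '#' starts a comment; returns named character list
read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("malformed line %d in %s: '%s'", i, path, lines[i]), call. = FALSE)
    }
    out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' List the packaged example spectrometer configurations
#'
#' @return Named character vector of paths to the shipped `.cfg` files.
#' @export
example_configs <- function() {
  dir <- system.file("extdata", package = "speccal")
  files <- list.files(dir, pattern = "^config_.*\\.cfg$", full.names = TRUE)
  names(files) <- sub("^config_(.*)\\.cfg$", "\\1", basename(files))
  files
}
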