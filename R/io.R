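#' Read a spectrum from delimited text
#'
#' Accepts one-column (intensity) or two-column (pixel, intensity) files
#' with comma, tab or whitespace delimiters (auto-detected) and an optional
#' header line (auto-skipped).  Two-column files must carry contiguous
#' `1..n` pixel indices.
#'
#' @param path Path to the file.
#' @return A [spectrum()] object.
#' @export
read_spectrum <- function(path) {
  tab <- read_delimited(path, max_cols = 2L)
  if (ncol(tab) == 2L) {
    px <- tab[[1]]
    if (!isTRUE(all.equal(px, seq_along(px)))) {
      stop(sprintf("pixel index column in %s is not contiguous 1..n", path), call. = FALSE)
    }
    y <- tab[[2]]
  } else {
    y <- tab[[1]]
  }
  if (any(y < 0)) stop(sprintf("negative intensities in %s", path), call. = FALSE)
  spectrum(y, label = basename(path))
}

#' Write a spectrum as two-column text
#'
#' Comma-delimited `pixel,intensity` with a header; round-trips through
#' [read_spectrum()] exactly.
#'
#' @param spec A [spectrum()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spec_spectrum"))
  lines <- c("pixel,intensity",
             sprintf("%d,%.15g", seq_along(spec$intensities), spec$intensities))
  writeLines(lines, path)
  invisible(path)
}

#' Read a lamp line list from delimited text
#'
#' Expects a `wavelength_nm` column and optional `uncertainty_nm` and
#' `label` columns (header required when more than one column is present;
#' a bare single column of wavelengths is also accepted).  Entries are
#' sorted ascending, with a warning if the input was unsorted.
#'
#' Two example lists ship with the package under `inst/extdata`:
#' `neon_lines_nist_air.csv` (strong neon emission lines, air wavelengths,
#' compiled from the NIST Atomic Spectra Database) and
#' `krypton_like_lines_synthetic.csv` (a synthetic 12-line list spanning
#' 535-608 nm for exercising the transmission configuration; not measured
#' krypton values).
#'
#' @param path Path to the file.
#' @return A [lamp_lines()] table.
#' @export
read_linelist <- function(path) {
  tab <- read_delimited(path, max_cols = 3L, keep_char = 3L)
  if (ncol(tab) == 1L) {
    w <- tab[[1]]; u <- NULL; lab <- NULL
  } else {
    hdr <- attr(tab, "header")
    if (is.null(hdr) || !"wavelength_nm" %in% hdr) {
      stop(sprintf("%s needs a header naming a 'wavelength_nm' column", path), call. = FALSE)
    }
    names(tab) <- hdr[seq_len(ncol(tab))]
    w <- tab[["wavelength_nm"]]
    u <- if ("uncertainty_nm" %in% names(tab)) tab[["uncertainty_nm"]] else NULL
    lab <- if ("label" %in% names(tab)) tab[["label"]] else NULL
  }
  if (is.unsorted(w, strictly = TRUE)) {
    ord <- order(w)
    if (anyDuplicated(w)) stop(sprintf("duplicate wavelengths in %s", path), call. = FALSE)
    warning(sprintf("line list %s was not sorted; sorting ascending", basename(path)),
            call. = FALSE)
    w <- w[ord]
    if (!is.null(u)) u <- u[ord]
    if (!is.null(lab)) lab <- lab[ord]
  }
  lamp_lines(w, u, lab)
}

#' Write a lamp line list
#'
#' @param lines A [lamp_lines()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linelist <- function(lines, path) {
  stopifnot(inherits(lines, "lamp_lines"))
  body <- sprintf("%.15g,%s,%s", lines$wavelength_nm,
                  ifelse(is.na(lines$uncertainty_nm), "",
                         sprintf("%.6g", lines$uncertainty_nm)),
                  ifelse(is.na(lines$label), "", lines$label))
  writeLines(c("wavelength_nm,uncertainty_nm,label", body), path)
  invisible(path)
}

# shared delimited-text reader: auto delimiter (comma/tab/whitespace), auto
# header skip; columns >= keep_char stay character, empty fields become NA
read_delimited <- function(path, max_cols, keep_char = 0L) {
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(raw)) & !grepl("^\\s*#", raw)
  lineno <- which(keep)
  raw <- raw[keep]
  if (!length(raw)) stop(sprintf("%s contains no data", path), call. = FALSE)
  comma <- any(grepl(",", raw))
  split_row <- function(s) {
    if (comma) {
      trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    } else {
      parts <- strsplit(trimws(s), "[ \t]+")[[1]]
      parts[nzchar(parts)]
    }
  }
  first <- split_row(raw[1])
  header <- NULL
  start <- 1L
  if (any(is.na(suppressWarnings(as.numeric(first[nzchar(first)]))))) {
    header <- first
    start <- 2L
    if (start > length(raw)) stop(sprintf("%s has a header but no data", path), call. = FALSE)
  }
  rows <- lapply(raw[start:length(raw)], split_row)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- lineno[start - 1L + which(widths != widths[1])[1]]
    stop(sprintf("ragged row at line %d of %s", bad, path), call. = FALSE)
  }
  ncols <- widths[1]
  if (ncols > max_cols) stop(sprintf("%s has %d columns; at most %d supported",
                                     path, ncols, max_cols), call. = FALSE)
  cols <- lapply(seq_len(ncols), function(j) vapply(rows, `[[`, character(1), j))
  out <- lapply(seq_len(ncols), function(j) {
    if (keep_char > 0L && j >= keep_char) return(cols[[j]])
    v <- suppressWarnings(as.numeric(cols[[j]]))
    v[!nzchar(cols[[j]])] <- NA_real_  # empty field -> missing
    broken <- is.na(v) & nzchar(cols[[j]])
    if (any(broken)) {
      bad <- lineno[start - 1L + which(broken)[1]]
      stop(sprintf("non-numeric value at line %d of %s", bad, path), call. = FALSE)
    }
    v
  })
  out <- as.data.frame(out, col.names = paste0("V", seq_len(ncols)),
                       stringsAsFactors = FALSE)
  attr(out, "header") <- header
  out
}

#' Write calibration products
#'
#' Writes the standard calibration output files under a common prefix:
#' \describe{
#'   \item{`<prefix>_calibration.csv`}{two-column per-pixel table
#'     (`pixel,wavelength_nm`), full precision (15 significant digits, so a
#'     write/read round trip preserves wavelengths well below 1e-9 nm).}
#'   \item{`<prefix>_report.txt`}{key-value report: method, fitted
#'     parameters and grid cell, linear pixel map, misfit, peak count and
#'     per-peak residuals, and the seed when one is supplied.}
#' }
#' Output is bit-stable for fixed inputs.
#'
#' @param result A `"spec_calibration"`.
#' @param prefix Output path prefix.
#' @param seed Optional seed to record in the report.
#' @return Named character vector of the files written, invisibly.
#' @export
write_calibration <- function(result, prefix, seed = NULL) {
  stopifnot(inherits(result, "spec_calibration"))
  tab_path <- paste0(prefix, "_calibration.csv")
  rep_path <- paste0(prefix, "_report.txt")
  px <- seq_along(result$lambda_cal)
  writeLines(c("pixel,wavelength_nm",
               sprintf("%d,%.15g", px, result$lambda_cal)), tab_path)
  rep <- c(
    sprintf("method = %s", result$method),
    sprintf("n_peaks = %d", result$n_peaks),
    sprintf("err_px2 = %.15g", result$err),
    sprintf("n_pixels = %d", length(result$lambda_cal)),
    sprintf("monotone = %s", result$monotone)
  )
  if (!is.null(seed)) rep <- c(rep, sprintf("seed = %d", as.integer(seed)))
  if (!is.null(result$params)) {
    p <- result$params
    rep <- c(rep,
             sprintf("f_nm = %.15g", p$f), sprintf("T_nm = %.15g", p$T),
             sprintf("C_nm = %.15g", p$C), sprintf("d_eff_nm = %.15g", p$d_eff),
             sprintf("alpha_rad = %.15g", p$alpha),
             sprintf("theta_d_rad = %.15g", p$theta_d),
             sprintf("k = %+d", as.integer(p$k)),
             sprintf("n_order = %+d", p$n_order))
  }
  if (!is.null(result$grid_cell)) {
    for (nm in names(result$grid_cell)) {
      rep <- c(rep, sprintf("grid_%s = %.15g", nm, result$grid_cell[[nm]]))
    }
  }
  if (!is.null(result$map)) {
    rep <- c(rep, sprintf("map_slope = %.15g", result$map$slope),
             sprintf("map_intercept = %.15g", result$map$intercept))
  }
  if (!is.null(result$coef)) {
    rep <- c(rep, sprintf("poly_coef_%d = %.15g",
                          seq_along(result$coef) - 1L, result$coef))
  }
  rep <- c(rep, sprintf("residual_nm_%02d = %.15g",
                        seq_along(result$residuals_nm), result$residuals_nm))
  writeLines(rep, rep_path)
  invisible(c(calibration = tab_path, report = rep_path))
}
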