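# Receptor-based visual modelling of irradiance spectra:
# spectra -> quantum catches -> achromatic photon catch and Michelson
# relative catches for a trichromatic (UV/B/LW) eye.

# Planck constant (J s) and speed of light (m s^-1), CODATA 2018 exact values.
.PLANCK_H <- 6.62607015e-34
.LIGHT_C <- 2.99792458e8

#' Default peak sensitivities of the model visual system
#'
#' Peak absorbance wavelengths (nm) of the three visual pigments of the
#' trichromatic nymphalid model eye used throughout: UV = 340 nm, blue =
#' 435 nm, long-wavelength = 545 nm.
#'
#' @return Named numeric vector with elements `UV`, `B`, `LW`.
#' @export
default_lambda_max <- function() {
  c(UV = 340, B = 435, LW = 545)
}

#' Construct a spectrum object
#'
#' A spectrum is a wavelength grid with one irradiance value per wavelength,
#' in either energy units (W m-2 nm-1) or quantal units
#' (photons s-1 m-2 nm-1).
#'
#' @param wavelengths_nm Strictly increasing numeric vector of wavelengths (nm).
#' @param values Non-negative irradiance values, same length.
#' @param units `"energy"` or `"quantal"`.
#' @param meta Optional list of instrument metadata (e.g. integration time).
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavelengths_nm, values, units = c("energy", "quantal"),
                     meta = list()) {
  units <- match.arg(units)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values)) {
    stop("wavelengths and values must have equal length")
  }
  if (length(wavelengths_nm) < 1L) stop("empty spectrum")
  if (anyNA(wavelengths_nm) || anyNA(values) ||
      any(!is.finite(wavelengths_nm)) || any(!is.finite(values))) {
    stop("spectrum contains non-finite entries")
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths must be strictly increasing (duplicates not allowed)")
  }
  if (any(values < 0)) stop("irradiance values must be >= 0")
  structure(list(wavelengths_nm = wavelengths_nm, values = values,
                 units = units, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.0f-%.0f nm, units: %s\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), x$units))
  invisible(x)
}

#' Read a two-column spectrum file
#'
#' Parses plain-text files with two numeric columns (wavelength nm,
#' irradiance) separated by whitespace or commas; `#` starts a comment.
#' Rows are sorted by wavelength; duplicated wavelengths are an error.
#'
#' @param path File path.
#' @return A [spectrum()] with `units = "energy"`.
#' @export
load_spectrum <- function(path) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  wl <- numeric(0)
  val <- numeric(0)
  for (i in keep) {
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    if (length(fields) != 2L) {
      stop(sprintf("parse error at line %d of %s: expected 2 columns, got %d",
                   i, path, length(fields)))
    }
    num <- suppressWarnings(as.numeric(fields))
    if (anyNA(num)) {
      stop(sprintf("parse error at line %d of %s: non-numeric field", i, path))
    }
    wl <- c(wl, num[1])
    val <- c(val, num[2])
  }
  if (length(wl) == 0L) stop("no data rows in ", path)
  ord <- order(wl)
  wl <- wl[ord]
  val <- val[ord]
  if (anyDuplicated(wl)) {
    stop("validation error: duplicated wavelength(s) in ", path, ": ",
         paste(unique(wl[duplicated(wl)]), collapse = ", "))
  }
  if (any(val < 0)) {
    warning("negative raw readings clipped to 0")
    val[val < 0] <- 0
  }
  spectrum(wl, val, units = "energy")
}

#' Read a calibration curve
#'
#' Same plain-text dialect as [load_spectrum()]; the second column is a
#' multiplicative gain mapping raw device counts to absolute irradiance.
#'
#' @param path File path.
#' @return List with `wavelengths_nm` and `gain`, class `"calibration_curve"`.
#' @export
load_calibration <- function(path) {
  s <- load_spectrum(path)
  if (any(s$values <= 0)) stop("calibration gain must be > 0 everywhere")
  structure(list(wavelengths_nm = s$wavelengths_nm, gain = s$values),
            class = "calibration_curve")
}

#' Apply a spectral calibration
#'
#' Multiplies a raw spectrum pointwise by the (linearly interpolated)
#' calibration gain. The calibration must cover the spectrum's span.
#'
#' @param raw A [spectrum()] in energy units (raw device counts).
#' @param cal A calibration curve from [load_calibration()], or a list with
#'   `wavelengths_nm` and `gain`.
#' @return Calibrated [spectrum()], energy units.
#' @export
apply_calibration <- function(raw, cal) {
  stopifnot(inherits(raw, "spectrum"))
  if (min(raw$wavelengths_nm) < min(cal$wavelengths_nm) ||
      max(raw$wavelengths_nm) > max(cal$wavelengths_nm)) {
    stop("coverage error: spectrum span outside calibration span")
  }
  g <- stats::approx(cal$wavelengths_nm, cal$gain,
                     xout = raw$wavelengths_nm)$y
  spectrum(raw$wavelengths_nm, raw$values * g, units = "energy",
           meta = raw$meta)
}

#' Convert an energy spectrum to quantal units
#'
#' Photon energy at wavelength lambda is \eqn{hc/\lambda}; irradiance in
#' W m-2 nm-1 therefore converts to photons s-1 m-2 nm-1 by multiplying with
#' \eqn{\lambda \cdot 10^{-9}/(hc)}.
#'
#' @param s A [spectrum()] with `units = "energy"`.
#' @return The spectrum in quantal units.
#' @export
to_quantal <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  if (s$units != "energy") stop("state error: spectrum already quantal")
  factor <- s$wavelengths_nm * 1e-9 / (.PLANCK_H * .LIGHT_C)
  spectrum(s$wavelengths_nm, s$values * factor, units = "quantal",
           meta = s$meta)
}

#' Visual-pigment spectral sensitivity template
#'
#' Builds the Govardovskii et al. (2000) A1 visual-pigment alpha-band
#' template, optionally with the beta-band, normalized to peak 1 at
#' `lambda_max_nm`.
#'
#' @param lambda_max_nm Peak wavelength (nm), in \[300, 650\].
#' @param grid Wavelength evaluation grid (nm); default 300-700 at 1 nm.
#' @param include_beta_band Add the beta (cis) absorption band? Default FALSE.
#' @param channel_label Optional label (`"UV"`, `"B"`, `"LW"`).
#' @return Object of class `"sensitivity_template"` with fields
#'   `lambda_max_nm`, `wavelengths_nm`, `curve`, `channel_label`.
#' @export
receptor_sensitivity <- function(lambda_max_nm, grid = seq(300, 700, by = 1),
                                 include_beta_band = FALSE,
                                 channel_label = NA_character_) {
  if (lambda_max_nm < 300 || lambda_max_nm > 650) {
    stop("domain error: lambda_max must lie in [300, 650] nm")
  }
  curve <- govardovskii_a1(grid, lambda_max_nm, include_beta_band)
  # renormalize so the grid maximum is exactly 1 (the analytic peak can fall
  # between grid points, and the beta band perturbs the alpha peak slightly)
  curve <- curve / max(curve)
  structure(list(lambda_max_nm = lambda_max_nm, wavelengths_nm = grid,
                 curve = curve, channel_label = channel_label,
                 include_beta_band = include_beta_band),
            class = "sensitivity_template")
}

# Closed-form A1 template (alpha band; optional beta band), evaluable at any
# wavelength. Peak of the alpha band is 1 at lambda = lambda_max by
# construction of the rational form.
govardovskii_a1 <- function(lambda, lambda_max, include_beta_band = FALSE) {
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
  b <- 0.922; cc <- 1.104
  alpha <- 1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D)
  if (!include_beta_band) return(alpha)
  lmb <- 189 + 0.315 * lambda_max
  bb <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((lambda - lmb) / bb)^2)
  alpha + beta
}

# Evaluate a sensitivity template at arbitrary wavelengths using its analytic
# form (not interpolation of the stored grid), keeping the stored peak
# normalization. Zero outside any physically meaningful range is not imposed:
# the template decays naturally.
eval_sensitivity <- function(t, lambda) {
  stopifnot(inherits(t, "sensitivity_template"))
  raw <- govardovskii_a1(lambda, t$lambda_max_nm, t$include_beta_band)
  peak <- max(govardovskii_a1(t$wavelengths_nm, t$lambda_max_nm,
                              t$include_beta_band))
  raw / peak
}

#' Quantum catch of one receptor
#'
#' Integrates quantal irradiance weighted by the receptor sensitivity over
#' `integration_range` (default 310-670 nm): trapezoid rule on a common fine
#' grid; the measured spectrum is linearly interpolated, the sensitivity
#' template evaluated analytically.
#'
#' @param s A [spectrum()] in quantal units (energy spectra are converted).
#' @param template A [receptor_sensitivity()] template.
#' @param integration_range Length-2 numeric, nm.
#' @param grid_step Quadrature step (nm). The default 0.05 nm keeps the
#'   trapezoid error below 1e-7 relative for smooth field spectra.
#' @return Scalar quantum catch (quanta s-1 m-2).
#' @export
quantum_catch <- function(s, template, integration_range = c(310, 670),
                          grid_step = 0.05) {
  stopifnot(inherits(s, "spectrum"))
  if (s$units == "energy") s <- to_quantal(s)
  lo <- max(integration_range[1], min(s$wavelengths_nm))
  hi <- min(integration_range[2], max(s$wavelengths_nm))
  if (hi <= lo) stop("coverage error: spectrum does not overlap integration range")
  grid <- seq(lo, hi, by = grid_step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  iq <- stats::approx(s$wavelengths_nm, s$values, xout = grid)$y
  sv <- eval_sensitivity(template, grid)
  f <- iq * sv
  sum(diff(grid) * (f[-1] + f[-length(f)]) / 2)
}

#' Michelson relative catch
#'
#' Contrast of one channel's catch against the mean of the remaining two:
#' \eqn{(Q_a - M)/(Q_a + M)} with \eqn{M = (Q_b + Q_c)/2}. Lies in \[-1, 1\].
#'
#' @param q_a,q_b,q_c Non-negative quantum catches; not all zero.
#' @return Scalar contrast in \[-1, 1\].
#' @export
michelson_relative_catch <- function(q_a, q_b, q_c) {
  if (any(c(q_a, q_b, q_c) < 0)) stop("catches must be >= 0")
  m <- (q_b + q_c) / 2
  if (q_a + m == 0) stop("undefined-contrast error: all catches zero")
  (q_a - m) / (q_a + m)
}

#' Full catch set for one spectrum
#'
#' Computes the quantum catches of the UV, B and LW receptors, the achromatic
#' photon-catch measures (LW catch, and the mean of the three channels) and
#' the three Michelson relative catches.
#'
#' @param s A [spectrum()] (energy spectra are converted to quantal).
#' @param lambda_max Named numeric of peak sensitivities; default
#'   [default_lambda_max()].
#' @param integration_range,grid_step Passed to [quantum_catch()].
#' @param include_beta_band Passed to [receptor_sensitivity()].
#' @return Object of class `"catch_set"`: `q_uv`, `q_b`, `q_lw`,
#'   `photon_catch_lw`, `photon_catch_mean`, `rel_uv`, `rel_b`, `rel_lw`.
#' @export
catch_set <- function(s, lambda_max = default_lambda_max(),
                      integration_range = c(310, 670), grid_step = 0.05,
                      include_beta_band = FALSE) {
  templates <- lapply(lambda_max, receptor_sensitivity,
                      include_beta_band = include_beta_band)
  q <- vapply(templates, function(t)
    quantum_catch(s, t, integration_range, grid_step), numeric(1))
  names(q) <- names(lambda_max)
  structure(list(
    q_uv = q[["UV"]], q_b = q[["B"]], q_lw = q[["LW"]],
    photon_catch_lw = q[["LW"]],
    photon_catch_mean = mean(q),
    rel_uv = michelson_relative_catch(q[["UV"]], q[["B"]], q[["LW"]]),
    rel_b = michelson_relative_catch(q[["B"]], q[["UV"]], q[["LW"]]),
    rel_lw = michelson_relative_catch(q[["LW"]], q[["UV"]], q[["B"]])
  ), class = "catch_set")
}

#' @export
print.catch_set <- function(x, ...) {
  cat(sprintf("<catch_set> Q_UV=%.4g Q_B=%.4g Q_LW=%.4g  rel=(%.3f, %.3f, %.3f)\n",
              x$q_uv, x$q_b, x$q_lw, x$rel_uv, x$rel_b, x$rel_lw))
  invisible(x)
}

#' Log10 photon catch
#'
#' @param c A [catch_set()].
#' @return Named numeric: `log10_photon_catch_lw`, `log10_photon_catch_mean`.
#' @export
log10_photon_catch <- function(c) {
  stopifnot(inherits(c, "catch_set"))
  if (c$photon_catch_lw <= 0 || c$photon_catch_mean <= 0) {
    stop("transform error: zero photon catch")
  }
  c(log10_photon_catch_lw = log10(c$photon_catch_lw),
    log10_photon_catch_mean = log10(c$photon_catch_mean))
}

#' Catch table for a directory of spectra
#'
#' Runs [catch_set()] over every spectrum file and assembles a data frame,
#' one row per file.
#'
#' @param paths Character vector of spectrum file paths.
#' @param cal Optional calibration curve applied to each raw spectrum.
#' @param ... Passed to [catch_set()].
#' @return data.frame with catch, photon-catch, contrast and log10 columns.
#' @export
catch_table <- function(paths, cal = NULL, ...) {
  rows <- lapply(paths, function(p) {
    s <- load_spectrum(p)
    if (!is.null(cal)) s <- apply_calibration(s, cal)
    cs <- catch_set(s, ...)
    lg <- log10_photon_catch(cs)
    data.frame(file = basename(p), q_uv = cs$q_uv, q_b = cs$q_b,
               q_lw = cs$q_lw, photon_catch_lw = cs$photon_catch_lw,
               photon_catch_mean = cs$photon_catch_mean,
               rel_uv = cs$rel_uv, rel_b = cs$rel_b, rel_lw = cs$rel_lw,
               log10_photon_catch_lw = lg[[1]],
               log10_photon_catch_mean = lg[[2]])
  })
  do.call(rbind, rows)
}
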