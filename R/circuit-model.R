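#' Frequency grid for impedance sweeps
#'
#' Constructs a validated, strictly ascending frequency grid (Hz). The default
#' window \code{[0.1, 1e5]} Hz matches the instrument sweep used for barrier
#' monitoring; the angular frequency \eqn{\omega = 2\pi f} is always derived on
#' the fly and never stored.
#'
#' @param frequencies numeric vector of frequencies in Hz, strictly ascending,
#'   finite and positive; at least 2 points.
#' @param window length-2 numeric, the admissible global frequency window in Hz.
#' @return an object of class \code{frequency_grid} (a numeric vector).
#' @seealso [default_grid()]
#' @export
frequency_grid <- function(frequencies, window = c(0.1, 1e5)) {
  f <- as.numeric(frequencies)
  if (length(f) < 2L)
    stop("frequency_grid needs at least 2 points", call. = FALSE)
  if (any(!is.finite(f)) || any(f <= 0))
    stop("frequencies must be finite and > 0", call. = FALSE)
  if (is.unsorted(f, strictly = TRUE))
    stop("frequencies must be strictly ascending", call. = FALSE)
  if (f[1] < window[1] - 1e-12 || f[length(f)] > window[2] * (1 + 1e-12))
    stop(sprintf("frequencies outside the global window [%g, %g] Hz",
                 window[1], window[2]), call. = FALSE)
  structure(f, class = "frequency_grid", window = window)
}

#' Default log-spaced frequency grid
#'
#' @param fmin,fmax sweep bounds in Hz.
#' @param n number of points, log-spaced (default 51 over 0.1 Hz - 100 kHz,
#'   the sweep used throughout the package).
#' @return a [frequency_grid()].
#' @export
default_grid <- function(fmin = 0.1, fmax = 1e5, n = 51L) {
  frequency_grid(10^seq(log10(fmin), log10(fmax), length.out = n),
                 window = c(min(fmin, 0.1), max(fmax, 1e5)))
}

#' Four-element equivalent-circuit parameters
#'
#' The barrier measurement is modelled by the circuit \code{[R1(R2C2)C1]}: a
#' series solution/interface resistance R1 and series interfacial capacitance
#' C1, followed by the parallel pair R2 || C2 representing the cell barrier.
#' R2 (ohm) is the barrier-resistance readout of interest.
#'
#' @param R1 series resistance, ohm.
#' @param C1 series interfacial capacitance, F.
#' @param R2 barrier resistance, ohm.
#' @param C2 barrier capacitance, F.
#' @return an object of class \code{circuit_params}.
#' @export
circuit_params <- function(R1, C1, R2, C2) {
  p <- list(R1 = unname(R1), C1 = unname(C1), R2 = unname(R2), C2 = unname(C2))
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("circuit parameter '%s' must be a single finite value > 0", nm),
           call. = FALSE)
  }
  structure(p, class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf("[R1(R2C2)C1] circuit: R1 = %.4g ohm, C1 = %.4g F, R2 = %.4g ohm, C2 = %.4g F\n",
              x$R1, x$C1, x$R2, x$C2))
  invisible(x)
}

#' Impedance spectrum container
#'
#' A frequency-indexed complex impedance with measurement metadata.
#'
#' @param frequencies a [frequency_grid()] or numeric vector coercible to one.
#' @param z complex impedance values, ohm, one per frequency.
#' @param well,electrode,side,timepoint metadata labels (side is
#'   \code{"apical"} or \code{"basal"} when given).
#' @return an object of class \code{impedance_spectrum}.
#' @export
impedance_spectrum <- function(frequencies, z, well = NA_character_,
                               electrode = NA_character_, side = NA_character_,
                               timepoint = NA_character_) {
  grid <- if (inherits(frequencies, "frequency_grid")) frequencies
          else frequency_grid(frequencies)
  z <- as.complex(z)
  if (length(z) != length(grid))
    stop("length(z) must equal the number of frequencies", call. = FALSE)
  if (any(!is.finite(Mod(z))) || any(Mod(z) <= 0))
    stop("impedance magnitude must be finite and > 0 at every frequency",
         call. = FALSE)
  if (!is.na(side) && !side %in% c("apical", "basal"))
    stop("side must be 'apical' or 'basal'", call. = FALSE)
  structure(list(frequency_hz = as.numeric(grid), z = z,
                 well = as.character(well), electrode = as.character(electrode),
                 side = as.character(side), timepoint = as.character(timepoint)),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("impedance spectrum: %d frequencies, %.3g - %.3g Hz\n",
              length(x$frequency_hz), min(x$frequency_hz), max(x$frequency_hz)))
  meta <- c(well = x$well, electrode = x$electrode, side = x$side,
            timepoint = x$timepoint)
  meta <- meta[!is.na(meta)]
  if (length(meta))
    cat("  ", paste(names(meta), meta, sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  |Z| range: %.4g - %.4g ohm\n", min(Mod(x$z)), max(Mod(x$z))))
  invisible(x)
}

#' Forward impedance of the four-element circuit
#'
#' Evaluates \deqn{Z(\omega) = R_1 + \frac{1}{j\omega C_1} +
#'   \frac{R_2}{1 + j\omega R_2 C_2}} at every grid frequency
#' (\eqn{\omega = 2\pi f}). The circuit is purely capacitive, so
#' \eqn{\mathrm{Im}\,Z \le 0} and \eqn{\mathrm{Re}\,Z \ge R_1} everywhere.
#'
#' @param params a [circuit_params()].
#' @param grid a [frequency_grid()] (default: [default_grid()]).
#' @param ... metadata passed to [impedance_spectrum()].
#' @return an [impedance_spectrum()].
#' @export
impedance <- function(params, grid = default_grid(), ...) {
  stopifnot(inherits(params, "circuit_params"))
  if (!inherits(grid, "frequency_grid")) grid <- frequency_grid(grid)
  w <- 2 * pi * as.numeric(grid)
  z <- params$R1 + 1 / (1i * w * params$C1) +
    params$R2 / (1 + 1i * w * params$R2 * params$C2)
  impedance_spectrum(grid, z, ...)
}

#' Bode representation of a spectrum
#'
#' @param spectrum an [impedance_spectrum()].
#' @return a data.frame with columns \code{frequency_hz}, \code{z_mod_ohm}
#'   (modulus, ohm) and \code{z_phase_deg} (argument, degrees; in
#'   \eqn{(-90, 0]} for spectra generated by [impedance()]).
#' @export
bode <- function(spectrum) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  data.frame(frequency_hz = spectrum$frequency_hz,
             z_mod_ohm = Mod(spectrum$z),
             z_phase_deg = Arg(spectrum$z) * 180 / pi)
}

#' Characteristic frequency of the barrier branch
#'
#' The frequency \eqn{f^\ast = 1/(2\pi R_2 C_2)} at which the parallel barrier
#' branch contributes its maximal reactive part; used as a fit-initialization
#' diagnostic and to flag sweeps that do not resolve the barrier plateau.
#'
#' @param params a [circuit_params()].
#' @return frequency in Hz.
#' @export
characteristic_frequency <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  1 / (2 * pi * params$R2 * params$C2)
}

#' Series composite of stacked barriers (bulk EVOM-style measurement)
#'
#' Models a conventional bulk measurement across several stacked barriers: one
#' shared series R1/C1 (taken from the first entry) plus the sum of each
#' barrier's parallel R2 || C2 branch,
#' \deqn{Z(\omega) = R_1 + \frac{1}{j\omega C_1} +
#'   \sum_k \frac{R_{2k}}{1 + j\omega R_{2k} C_{2k}}.}
#' With a single entry this reduces exactly to [impedance()]. The low-frequency
#' resistive plateau of the composite is dominated by the highest-resistance
#' barrier, which is why a bulk two-barrier reading carries little information
#' about the weaker (endothelial) barrier.
#'
#' @param params_list list of [circuit_params()]; R1 and C1 of the first entry
#'   are the shared series elements.
#' @param grid a [frequency_grid()].
#' @param ... metadata passed to [impedance_spectrum()].
#' @return an [impedance_spectrum()].
#' @export
series_composite <- function(params_list, grid = default_grid(), ...) {
  if (inherits(params_list, "circuit_params")) params_list <- list(params_list)
  if (!is.list(params_list) || length(params_list) == 0L)
    stop("params_list must be a non-empty list of circuit_params", call. = FALSE)
  stopifnot(all(vapply(params_list, inherits, logical(1), "circuit_params")))
  if (!inherits(grid, "frequency_grid")) grid <- frequency_grid(grid)
  w <- 2 * pi * as.numeric(grid)
  shared <- params_list[[1]]
  z <- shared$R1 + 1 / (1i * w * shared$C1)
  for (p in params_list)
    z <- z + p$R2 / (1 + 1i * w * p$R2 * p$C2)
  impedance_spectrum(grid, z, ...)
}

#' Low-frequency resistive plateau of a spectrum
#'
#' The DC-limit resistive plateau \eqn{R_1 + \sum_k R_{2k}} is read off as the
#' real part of the impedance at the lowest swept frequency (the series
#' capacitance C1 affects only the imaginary part, so Re Z at the bottom of the
#' sweep is the plateau estimate).
#'
#' @param spectrum an [impedance_spectrum()].
#' @return plateau resistance, ohm.
#' @export
resistive_plateau <- function(spectrum) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  Re(spectrum$z[which.min(spectrum$frequency_hz)])
}
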