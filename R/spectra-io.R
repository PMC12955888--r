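#' Write spectra to the shared CSV dialect
#'
#' Cartesian dialect: header
#' \code{frequency_hz,z_real_ohm,z_imag_ohm,well,electrode,side,timepoint},
#' one row per frequency, UTF-8, '.' decimal separator. Polar dialect:
#' \code{frequency_hz,z_mod_ohm,z_phase_deg,...} with the same metadata
#' columns; the two round-trip losslessly at 12 significant digits.
#'
#' @param spectra an [impedance_spectrum()] or a list of them.
#' @param path output file path.
#' @param dialect \code{"cartesian"} (default) or \code{"polar"}.
#' @return invisibly, the number of data rows written.
#' @export
write_spectra <- function(spectra, path, dialect = c("cartesian", "polar")) {
  dialect <- match.arg(dialect)
  if (inherits(spectra, "impedance_spectrum")) spectra <- list(spectra)
  stopifnot(all(vapply(spectra, inherits, logical(1), "impedance_spectrum")))
  num <- function(v) sprintf("%.12g", v)
  rows <- lapply(spectra, function(s) {
    if (dialect == "cartesian")
      data.frame(frequency_hz = num(s$frequency_hz),
                 z_real_ohm = num(Re(s$z)), z_imag_ohm = num(Im(s$z)),
                 well = s$well, electrode = s$electrode, side = s$side,
                 timepoint = s$timepoint, stringsAsFactors = FALSE)
    else
      data.frame(frequency_hz = num(s$frequency_hz),
                 z_mod_ohm = num(Mod(s$z)),
                 z_phase_deg = num(Arg(s$z) * 180 / pi),
                 well = s$well, electrode = s$electrode, side = s$side,
                 timepoint = s$timepoint, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.csv(tab, utf8, row.names = FALSE, quote = FALSE, na = "")
  invisible(nrow(tab))
}

#' Read spectra from the shared CSV dialect
#'
#' Accepts both the Cartesian (\code{z_real_ohm,z_imag_ohm}) and polar
#' (\code{z_mod_ohm,z_phase_deg}) dialects; polar values are converted exactly.
#' Rows are validated (finite numbers, positive frequencies) with parse errors
#' naming the offending line; within each (well, electrode, side, timepoint)
#' group frequencies must be strictly ascending.
#'
#' @param path input file path.
#' @return list of [impedance_spectrum()], one per (well, electrode, side,
#'   timepoint) group, in file order of first appearance.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  cart <- all(c("frequency_hz", "z_real_ohm", "z_imag_ohm") %in% names(tab))
  polar <- all(c("frequency_hz", "z_mod_ohm", "z_phase_deg") %in% names(tab))
  if (!cart && !polar)
    stop("malformed header: expected the cartesian or polar spectrum dialect",
         call. = FALSE)
  vcols <- if (cart) c("z_real_ohm", "z_imag_ohm") else c("z_mod_ohm", "z_phase_deg")

  numcol <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop(sprintf("parse error in column '%s' at data row %d", col, bad[1]),
           call. = FALSE)
    v
  }
  f <- numcol("frequency_hz")
  neg <- which(f <= 0)
  if (length(neg))
    stop(sprintf("parse error: non-positive frequency at data row %d", neg[1]),
         call. = FALSE)
  a <- numcol(vcols[1]); b <- numcol(vcols[2])
  z <- if (cart) complex(real = a, imaginary = b)
       else complex(modulus = a, argument = b * pi / 180)

  meta <- function(col) if (col %in% names(tab)) tab[[col]] else
    rep(NA_character_, nrow(tab))
  key <- paste(meta("well"), meta("electrode"), meta("side"),
               meta("timepoint"), sep = "\r")
  groups <- split(seq_len(nrow(tab)), factor(key, levels = unique(key)))
  lapply(groups, function(idx) {
    fg <- f[idx]
    if (is.unsorted(fg, strictly = TRUE))
      stop(sprintf(
        "data error: frequencies not strictly ascending in group starting at data row %d",
        idx[1]), call. = FALSE)
    impedance_spectrum(frequency_grid(fg, window = range(fg)), z[idx],
                       well = meta("well")[idx[1]],
                       electrode = meta("electrode")[idx[1]],
                       side = meta("side")[idx[1]],
                       timepoint = meta("timepoint")[idx[1]])
  })
}

#' Write per-electrode fit results to the fits CSV
#'
#' Columns: \code{well,side,timepoint,electrode,R1,C1,R2,C2,se_R1,se_C1,se_R2,
#' se_C2,residual_norm,converged,excluded,reason}.
#'
#' @param fits list of [fit_spectrum()] results.
#' @param path output path.
#' @param exclusions optional data.frame (well, side, timepoint, electrode,
#'   reason) from well aggregation.
#' @return invisibly, the data.frame written.
#' @export
write_fits <- function(fits, path, exclusions = NULL) {
  rows <- lapply(fits, function(r) {
    data.frame(well = r$well, side = r$side, timepoint = r$timepoint,
               electrode = r$electrode,
               R1 = r$params$R1, C1 = r$params$C1,
               R2 = r$params$R2, C2 = r$params$C2,
               se_R1 = r$standard_errors[["R1"]],
               se_C1 = r$standard_errors[["C1"]],
               se_R2 = r$standard_errors[["R2"]],
               se_C2 = r$standard_errors[["C2"]],
               residual_norm = r$residual_norm, converged = r$converged,
               excluded = FALSE, reason = "", stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(exclusions) && nrow(exclusions)) {
    for (k in seq_len(nrow(exclusions))) {
      hit <- tab$well == exclusions$well[k] & tab$side == exclusions$side[k] &
        tab$timepoint == exclusions$timepoint[k] &
        tab$electrode == exclusions$electrode[k]
      tab$excluded[hit] <- TRUE
      tab$reason[hit] <- exclusions$reason[k]
    }
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(tab)
}
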