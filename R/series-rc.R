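#' Series resistance and capacitance of a complex impedance
#'
#' Interprets a measured complex well impedance at frequency `f` as a series
#' RC element: `R = Re(Z)` and `C = -1 / (2 pi f Im(Z))`. Records whose
#' imaginary part is not capacitive (`Im(Z) >= 0`) keep their resistance but
#' are flagged, with `capacitance_f` set to `NA`.
#'
#' @param z complex impedance, Ohm (vectorised).
#' @param frequency_hz frequency in Hz, > 0 (recycled against `z`).
#' @return A tibble with columns `resistance_ohm`, `capacitance_f` and
#'   `capacitance_valid`.
#' @examples
#' extract_series_rc(100 - 1i / (2 * pi * 4000 * 1e-8), 4000)
#' @export
extract_series_rc <- function(z, frequency_hz) {
  if (any(frequency_hz <= 0)) abort("Frequencies must be > 0.")
  z <- as.complex(z)
  valid <- Im(z) < 0
  tibble(
    resistance_ohm = Re(z),
    capacitance_f = ifelse(valid, -1 / (2 * pi * frequency_hz * Im(z)), NA_real_),
    capacitance_valid = valid
  )
}

#' Add series R/C columns to long-format impedance records
#'
#' Pipeline verb: takes a long impedance table with columns `frequency_hz`,
#' `z_real_ohm`, `z_imag_ohm` and appends `resistance_ohm`, `capacitance_f`
#' and `capacitance_valid` via [extract_series_rc()].
#'
#' @param data a data frame of impedance records.
#' @return The input as a tibble with the three series-RC columns appended.
#' @export
add_series_rc <- function(data) {
  require_columns(data, c("frequency_hz", "z_real_ohm", "z_imag_ohm"))
  rc <- extract_series_rc(complex(real = data$z_real_ohm,
                                  imaginary = data$z_imag_ohm),
                          data$frequency_hz)
  dplyr::bind_cols(as_tibble(data), rc)
}

# internal: fail with the offending column names
require_columns <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing))
    abort(paste0("Missing required column(s): ",
                 paste(missing, collapse = ", "), "."))
  invisible(data)
}
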