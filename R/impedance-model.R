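#' Default ECIS measurement frequency grid
#'
#' The standard nine-frequency multifrequency acquisition grid used by
#' 96-well ECIS arrays: a doubling series from 250 Hz to 64,000 Hz.
#'
#' @return Numeric vector of 9 frequencies in Hz, strictly increasing.
#' @examples
#' ecis_frequencies()
#' @export
ecis_frequencies <- function() {
  250 * 2^(0:8)
}

#' Electrode and well electrical parameters
#'
#' Describes the cell-free electrode/well equivalent circuit: a
#' constant-phase-element (CPE) electrode-electrolyte interface in series
#' with the bulk solution resistance, scaled by the effective electrode area.
#'
#' The defaults are a calibrated "96W20idf-like" profile (interdigitated
#' gold-film array, effective single-area model). They were chosen so that
#' (i) the cell-free series capacitance at 64 kHz is well above the 20 nF
#' confluency threshold while a confluent monolayer falls below it, and
#' (ii) the impedance/resistance/capacitance frequency optima of a default
#' confluent monolayer land at 16 kHz, 4 kHz and 64 kHz respectively.
#'
#' @param cpe_magnitude_Q CPE admittance coefficient, S s^n cm^-2. Must be > 0.
#' @param cpe_exponent_n CPE exponent, dimensionless in (0, 1]. `n = 1` is an
#'   ideal capacitor, `n = 0` a resistor.
#' @param solution_resistance_Rsol series (bulk medium) resistance, Ohm. >= 0.
#' @param electrode_area_A effective electrode area, cm^2. Must be > 0.
#' @return An object of class `ecis_electrode` (a named list).
#' @examples
#' electrode_parameters()
#' @export
electrode_parameters <- function(cpe_magnitude_Q = 4e-6,
                                 cpe_exponent_n = 0.90,
                                 solution_resistance_Rsol = 150,
                                 electrode_area_A = 0.025) {
  if (!is.numeric(cpe_magnitude_Q) || cpe_magnitude_Q <= 0)
    abort("`cpe_magnitude_Q` must be > 0.")
  if (cpe_exponent_n <= 0 || cpe_exponent_n > 1)
    abort("`cpe_exponent_n` must lie in (0, 1].")
  if (solution_resistance_Rsol < 0)
    abort("`solution_resistance_Rsol` must be >= 0.")
  if (electrode_area_A <= 0)
    abort("`electrode_area_A` must be > 0.")
  structure(
    list(cpe_magnitude_Q = cpe_magnitude_Q,
         cpe_exponent_n = cpe_exponent_n,
         solution_resistance_Rsol = solution_resistance_Rsol,
         electrode_area_A = electrode_area_A),
    class = "ecis_electrode"
  )
}

#' Barrier parameters of a cell-covered electrode
#'
#' The three-parameter description of an endothelial monolayer on an ECIS
#' electrode: `Rb`, the paracellular (cell-cell junction) resistance in
#' Ohm cm^2; `alpha`, the cell-substrate constraint parameter in Ohm cm^(1/2)
#' reflecting basolateral adhesion geometry; and `Cm`, the combined
#' (apical + basal, in series) membrane capacitance in uF/cm^2.
#'
#' When `Rb` is exactly 0 the paracellular pathway is an electrical short and
#' `alpha` and `Cm` cease to be identifiable from impedance data; the
#' modelability flags are forced to `FALSE` in that case.
#'
#' @param Rb paracellular resistance, Ohm cm^2, >= 0.
#' @param alpha cell-substrate constraint parameter, Ohm cm^(1/2), >= 0.
#' @param Cm membrane capacitance, uF/cm^2, > 0.
#' @param alpha_modelable,cm_modelable logical identifiability flags.
#' @return An object of class `ecis_barrier` (a named list).
#' @examples
#' barrier_parameters(Rb = 6, alpha = 8, Cm = 1.5)
#' @export
barrier_parameters <- function(Rb, alpha, Cm,
                               alpha_modelable = TRUE,
                               cm_modelable = TRUE) {
  if (Rb < 0) abort("`Rb` must be >= 0.")
  if (alpha < 0) abort("`alpha` must be >= 0.")
  if (Cm <= 0) abort("`Cm` must be > 0.")
  if (Rb == 0) {
    alpha_modelable <- FALSE
    cm_modelable <- FALSE
  }
  structure(
    list(Rb = Rb, alpha = alpha, Cm = Cm,
         alpha_modelable = alpha_modelable, cm_modelable = cm_modelable),
    class = "ecis_barrier"
  )
}

#' Default confluent-monolayer barrier parameters
#'
#' The calibrated barrier triplet of a mature, confluent human retinal
#' endothelial monolayer used as the generator's plateau and the reference
#' point for frequency selection: Rb = 3 Ohm cm^2, alpha = 12 Ohm cm^(1/2),
#' Cm = 1.5 uF/cm^2. The high alpha relative to Rb keeps the 64 kHz series
#' capacitance dominated by cell spreading rather than the paracellular
#' pathway, as the measurement convention assumes.
#'
#' @return An `ecis_barrier` object.
#' @export
confluent_barrier <- function() {
  barrier_parameters(Rb = 3, alpha = 12, Cm = 1.5)
}

#' Specific impedance of the cell-free electrode interface
#'
#' Constant-phase-element model of the electrode-electrolyte interface:
#' `Zn(f) = 1 / (Q * (i 2 pi f)^n)` (principal branch). With `n = 1` this is
#' an ideal capacitor, with `n -> 0` a pure resistor of value `1/Q`.
#'
#' @param f frequency in Hz (vectorised), all > 0.
#' @param electrode an [electrode_parameters()] object.
#' @return Complex specific impedance, Ohm cm^2. `Re >= 0`, `Im <= 0`.
#' @examples
#' cpe_interface_impedance(4000, electrode_parameters())
#' @export
cpe_interface_impedance <- function(f, electrode = electrode_parameters()) {
  if (any(f <= 0)) abort("Frequencies must be > 0.")
  1 / (electrode$cpe_magnitude_Q * (2i * pi * f)^electrode$cpe_exponent_n)
}

#' Specific impedance of the cell membranes
#'
#' Apical and basal plasma membranes in series, purely capacitive:
#' `Zm(f) = 2 / (i 2 pi f Cm)` with `Cm` in uF/cm^2 (the 1e-6 factor is
#' applied here, at the formula boundary).
#'
#' @param f frequency in Hz (vectorised), > 0.
#' @param Cm membrane capacitance, uF/cm^2, > 0.
#' @return Complex specific impedance, Ohm cm^2 (purely imaginary).
#' @examples
#' membrane_impedance(4000, Cm = 1.5)
#' @export
membrane_impedance <- function(f, Cm) {
  if (any(f <= 0)) abort("Frequencies must be > 0.")
  if (any(Cm <= 0)) abort("`Cm` must be > 0.")
  2 / (2i * pi * f * Cm * 1e-6)
}

#' Ratio of modified Bessel functions I0(x)/I1(x)
#'
#' Numerically stable evaluation of `I0(x)/I1(x)` for complex arguments with
#' `Re(x) >= 0`, the current-spreading kernel of the cell-covered-electrode
#' model. Uses the Gauss continued fraction for `I1(x)/I0(x)` evaluated by
#' the modified Lentz algorithm, which avoids overflow of the individual
#' Bessel functions and is accurate from `|x| ~ 1e-6` to `1e6`.
#'
#' The ratio diverges as `2/x` for `x -> 0` and tends to 1 as `|x| -> Inf`.
#'
#' @param x complex (or numeric) argument, vectorised; `x != 0`.
#' @return Complex vector `I0(x)/I1(x)`.
#' @examples
#' bessel_ratio(1)        # 2.24019...
#' bessel_ratio(1e4 + 0i) # ~ 1
#' @export
bessel_ratio <- function(x) {
  x <- as.complex(x)
  if (any(x == 0)) abort("`x` must be nonzero (ratio diverges as 2/x).")
  vapply(x, bessel_ratio_one, complex(1))
}

# I1(x)/I0(x) = 1/(2/x + 1/(4/x + 1/(6/x + ...))); modified Lentz.
bessel_ratio_one <- function(z) {
  tiny <- 1e-300
  f <- tiny
  C <- f
  D <- 0
  for (k in 1:5000) {
    b <- 2 * k / z
    D <- b + D
    if (abs(D) < tiny) D <- tiny
    C <- b + 1 / C
    if (abs(C) < tiny) C <- tiny
    D <- 1 / D
    delta <- C * D
    f <- f * delta
    if (abs(delta - 1) < 1e-16) break
  }
  1 / f
}

#' Specific impedance of a cell-covered electrode
#'
#' The Giaever-Keese model of current flow beneath and around a confluent
#' cell layer on a microelectrode. With `Zn` the cell-free interface
#' impedance, `Zm` the series membrane impedance, `S = 1/Zn + 1/Zm` and
#' `gamma = alpha * sqrt(S)` (principal root), the cell-covered specific
#' impedance `Zc` satisfies
#'
#' `1/Zc = (1/Zn) * ( Zn/(Zn+Zm) + (Zm/(Zn+Zm)) / ( (gamma/2) * I0(gamma)/I1(gamma) + Rb * S ) )`
#'
#' Limits: `Zc = Zn` exactly at `Rb = 0, alpha = 0` (no barrier), and
#' `Zc -> Zn + Zm` as `Rb -> Inf` (all current transcellular).
#'
#' @param f frequency in Hz (vectorised), > 0.
#' @param electrode an [electrode_parameters()] object.
#' @param barrier an [barrier_parameters()] object.
#' @return Complex specific impedance, Ohm cm^2.
#' @examples
#' cell_covered_impedance(4000, electrode_parameters(), confluent_barrier())
#' @export
cell_covered_impedance <- function(f, electrode = electrode_parameters(),
                                   barrier = confluent_barrier()) {
  Zn <- cpe_interface_impedance(f, electrode)
  Zm <- membrane_impedance(f, barrier$Cm)
  S <- 1 / Zn + 1 / Zm
  gamma <- barrier$alpha * sqrt(S)
  stopifnot(all(Re(gamma) >= 0))
  spread <- ifelse(gamma == 0, 1 + 0i,
                   (gamma / 2) * bessel_ratio(gamma + (gamma == 0)))
  inv <- (1 / Zn) * (Zn / (Zn + Zm) +
                       (Zm / (Zn + Zm)) / (spread + barrier$Rb * S))
  1 / inv
}

#' Well-level impedance
#'
#' Maps specific (per-area) impedance to the impedance measured at the well:
#' `Z_well(f) = Rsol + Zspec(f) / A`, where `Zspec` is the cell-free
#' interface impedance when `barrier` is `NULL`, and the cell-covered
#' impedance otherwise.
#'
#' @param f frequency in Hz (vectorised), > 0.
#' @param electrode an [electrode_parameters()] object.
#' @param barrier an [barrier_parameters()] object, or `NULL` for a
#'   cell-free well.
#' @return Complex well impedance, Ohm.
#' @examples
#' well_impedance(64000, electrode_parameters())                      # cell-free
#' well_impedance(64000, electrode_parameters(), confluent_barrier()) # confluent
#' @export
well_impedance <- function(f, electrode = electrode_parameters(),
                           barrier = NULL) {
  zspec <- if (is.null(barrier)) {
    cpe_interface_impedance(f, electrode)
  } else {
    cell_covered_impedance(f, electrode, barrier)
  }
  electrode$solution_resistance_Rsol + zspec / electrode$electrode_area_A
}
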