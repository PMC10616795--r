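#' Physical constants used throughout the package
#'
#' CODATA 2018 values. All voltages in the package are millivolts, times in
#' milliseconds, currents in picoamperes and conductances in nanosiemens;
#' unitary (single-channel) quantities are reported in femtoamperes and
#' femtosiemens (1 pA = 1000 fA, 1 nS = 1e6 fS, fS x mV = 1e-3 fA).
#'
#' @format A list with elements:
#' \describe{
#'   \item{R}{gas constant, J mol^-1 K^-1}
#'   \item{F}{Faraday constant, C mol^-1}
#'   \item{k}{Boltzmann constant, J K^-1}
#'   \item{e0}{elementary charge, C}
#'   \item{T_default}{default temperature, K (294.15 K, i.e. ~21 degC room
#'     temperature)}
#' }
#' @export
hv_constants <- list(
  R = 8.314462618,
  F = 96485.33212,
  k = 1.380649e-23,
  e0 = 1.602176634e-19,
  T_default = 294.15
)

#' Thermal voltage RT/F in millivolts
#'
#' @param temperature temperature in Kelvin.
#' @return RT/F in mV (about 25.35 mV at 294.15 K).
#' @export
thermal_voltage <- function(temperature = hv_constants$T_default) {
  stopifnot(is.finite(temperature), temperature > 0)
  1000 * hv_constants$R * temperature / hv_constants$F
}

#' Construct a pH condition
#'
#' Describes the transmembrane pH gradient of a recording. The gradient
#' convention is delta_pH = pH_out - pH_in: a one-unit outward-acidic
#' gradient (pH_in 6, pH_out 7) gives delta_pH = +1 and a proton reversal
#' potential near -58 mV at room temperature.
#'
#' @param pH_in internal (bath-facing, inside-out patch) pH.
#' @param pH_out external (pipette) pH.
#' @return An object of class \code{ph_condition} with fields \code{pH_in},
#'   \code{pH_out} and derived \code{delta_pH}.
#' @export
ph_condition <- function(pH_in, pH_out) {
  if (!is.finite(pH_in) || !is.finite(pH_out)) {
    stop("pH values must be finite")
  }
  if (pH_in < 0 || pH_in > 14 || pH_out < 0 || pH_out > 14) {
    stop("pH values must lie in [0, 14]")
  }
  structure(
    list(pH_in = pH_in, pH_out = pH_out, delta_pH = pH_out - pH_in),
    class = "ph_condition"
  )
}

#' @export
print.ph_condition <- function(x, ...) {
  cat(sprintf("pH condition: pH_in %.2f / pH_out %.2f (delta pH = %+.2f)\n",
              x$pH_in, x$pH_out, x$delta_pH))
  invisible(x)
}

#' Nernst reversal potential for protons
#'
#' V_rev = (RT/F) ln([H+]_out-free form) reduces, in pH units, to
#' -ln(10) (RT/F) (pH_out - pH_in): about -58.4 mV per unit of delta_pH at
#' 294.15 K.
#'
#' @param condition a \code{\link{ph_condition}}.
#' @param temperature temperature in Kelvin.
#' @return Reversal potential in mV.
#' @export
nernst_potential <- function(condition, temperature = hv_constants$T_default) {
  if (!inherits(condition, "ph_condition")) stop("condition must be a ph_condition")
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be finite and positive")
  }
  -log(10) * thermal_voltage(temperature) * condition$delta_pH
}

#' Evaluate a Boltzmann activation curve
#'
#' amplitude_max / (1 + exp(-z_delta F (V - V_half) / RT)). With z_delta > 0
#' the curve increases with depolarization and equals half its maximum at
#' V_half. The same form serves current-voltage (I_max) and
#' conductance-voltage (G_max) relations.
#'
#' @param V voltage(s), mV.
#' @param amplitude_max saturating amplitude (pA or nS).
#' @param z_delta effective gating charge, elementary charges.
#' @param V_half midpoint voltage, mV.
#' @param temperature temperature, K.
#' @return Amplitudes at \code{V}, same units as \code{amplitude_max}.
#' @export
boltzmann_curve <- function(V, amplitude_max, z_delta, V_half,
                            temperature = hv_constants$T_default) {
  stopifnot(is.numeric(V), is.finite(amplitude_max), is.finite(z_delta),
            is.finite(V_half))
  vt <- thermal_voltage(temperature)
  amplitude_max / (1 + exp(-z_delta * (V - V_half) / vt))
}

#' Ohmic conversion of current to conductance
#'
#' G = I / (V - V_rev). With I in pA and voltages in mV the result is in nS;
#' the same formula applied to a unitary current in fA gives femtosiemens
#' after the 1e-3 scale (use \code{unitary = TRUE}).
#'
#' @param I current, pA (or fA with \code{unitary = TRUE}).
#' @param V membrane voltage, mV.
#' @param V_rev reversal potential, mV.
#' @param unitary if TRUE, treat \code{I} as fA and return fS.
#' @return Conductance in nS (or fS when \code{unitary}).
#' @export
ohmic_conductance <- function(I, V, V_rev, unitary = FALSE) {
  drive <- V - V_rev
  if (any(drive == 0)) stop("undefined driving force: V equals V_rev")
  g <- I / drive
  if (unitary) g * 1000 else g  # fA/mV = pS = 1000 fS
}
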