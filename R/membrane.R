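#' Membrane biophysical parameters
#'
#' Container for the passive electrical constants of a single neuronal
#' membrane.  All quantities are held internally in coherent SI units
#' (volts, seconds, farads and ohms per square metre, ohm metres, metres),
#' which keeps the model equation dimensionally consistent:
#' `R_m * C_m` is a time in seconds and `rho_ext * I / (4 * pi * r)` is a
#' potential in volts.
#'
#' The defaults are the standard cortical point-neuron values used throughout
#' the package: rest at -65 mV, excitation threshold at -55 mV, spike peak at
#' +55 mV, hyperpolarising reset at -70 mV, specific capacitance
#' 2e-2 F/m^2, specific resistance 1e-1 Ohm m^2 (membrane time constant
#' 2 ms), extracellular resistivity 3.5 Ohm m and a 50 micrometre distance
#' between the field electrode and the recording site.
#'
#' @param V_rest Resting potential (V).
#' @param V_thresh Excitation threshold (V); must exceed `V_rest`.
#' @param V_peak Spike peak / reset-trigger potential (V); must exceed
#'   `V_thresh`.
#' @param c_reset Post-spike hyperpolarisation value (V); at most `V_rest`.
#' @param C_m Specific membrane capacitance (F/m^2), positive.
#' @param R_m Specific membrane resistance (Ohm m^2), positive.
#' @param rho_ext Extracellular resistivity (Ohm m), positive.
#' @param r_dist Distance between the stimulating electrode and the membrane
#'   site (m), positive.
#' @return An object of class `membrane_parameters`.
#' @seealso [damage_parameters()], [effective_time_constant()]
#' @examples
#' mp <- membrane_parameters()
#' mp$R_m * mp$C_m   # 2 ms membrane time constant
#' @export
membrane_parameters <- function(V_rest = -65e-3, V_thresh = -55e-3,
                                V_peak = 55e-3, c_reset = -70e-3,
                                C_m = 2e-2, R_m = 1e-1,
                                rho_ext = 3.5, r_dist = 50e-6) {
  check_scalar(V_rest, "V_rest")
  check_scalar(V_thresh, "V_thresh")
  check_scalar(V_peak, "V_peak")
  check_scalar(c_reset, "c_reset")
  check_scalar(C_m, "C_m", positive = TRUE)
  check_scalar(R_m, "R_m", positive = TRUE)
  check_scalar(rho_ext, "rho_ext", positive = TRUE)
  check_scalar(r_dist, "r_dist", positive = TRUE)
  if (!(V_rest < V_thresh && V_thresh < V_peak))
    stop_with("ephapsim_domain_error",
              "need V_rest < V_thresh < V_peak (got %g, %g, %g V)",
              V_rest, V_thresh, V_peak)
  if (c_reset > V_rest)
    stop_with("ephapsim_domain_error",
              "c_reset (%g V) must not exceed V_rest (%g V)", c_reset, V_rest)
  structure(list(V_rest = V_rest, V_thresh = V_thresh, V_peak = V_peak,
                 c_reset = c_reset, C_m = C_m, R_m = R_m,
                 rho_ext = rho_ext, r_dist = r_dist),
            class = "membrane_parameters")
}

#' @export
print.membrane_parameters <- function(x, ...) {
  cat("Membrane parameters (SI units)\n")
  cat(sprintf("  V_rest   %8.1f mV   V_thresh %8.1f mV\n",
              x$V_rest * 1e3, x$V_thresh * 1e3))
  cat(sprintf("  V_peak   %8.1f mV   c_reset  %8.1f mV\n",
              x$V_peak * 1e3, x$c_reset * 1e3))
  cat(sprintf("  C_m  %g F/m^2   R_m  %g Ohm.m^2   (tau = %g ms)\n",
              x$C_m, x$R_m, x$R_m * x$C_m * 1e3))
  cat(sprintf("  rho_ext  %g Ohm.m   r_dist  %g um\n",
              x$rho_ext, x$r_dist * 1e6))
  invisible(x)
}

#' Membrane damage fractions
#'
#' The two impairment fractions of the damaged-membrane model.  `b` is the
#' proportion of inactivated ion channels, which raises the specific membrane
#' resistance to `R_m / (1 - b)`; `h` is the proportion of impaired bilayer
#' (capacitive) patches, which lowers the specific capacitance to
#' `C_m * (1 - h)`.  Both fractions live on `[0, 1)`: the value 1 is the
#' singular total-damage limit and is rejected.  Fractions above 0.2, where
#' entrainment is expected to disappear, are valid inputs.
#'
#' @param b Channel-inactivation fraction in `[0, 1)`.
#' @param h Bilayer-impairment fraction in `[0, 1)`.
#' @return An object of class `damage_parameters`.
#' @examples
#' damage_parameters(0.04, 0.04)
#' @export
damage_parameters <- function(b = 0, h = 0) {
  check_scalar(b, "b")
  check_scalar(h, "h")
  if (b < 0 || b >= 1)
    stop_with("ephapsim_domain_error", "b must satisfy 0 <= b < 1 (got %g)", b)
  if (h < 0 || h >= 1)
    stop_with("ephapsim_domain_error", "h must satisfy 0 <= h < 1 (got %g)", h)
  structure(list(b = b, h = h), class = "damage_parameters")
}

#' @export
print.damage_parameters <- function(x, ...) {
  cat(sprintf("Damage fractions: b = %g (channels), h = %g (bilayer)\n",
              x$b, x$h))
  invisible(x)
}

#' Dysfunctional membrane resistance
#'
#' Specific membrane resistance after a fraction `b` of the ion channels has
#' been inactivated.  With the open-channel conductances in parallel, removing
#' a fraction `b` of them rescales the resistance to `R_m / (1 - b)`:
#' strictly increasing in `b` and equal to `R_m` for an intact membrane.
#'
#' @param R_m Healthy specific membrane resistance (Ohm m^2), positive.
#' @param b Channel-inactivation fraction in `[0, 1)`.
#' @return The damaged specific resistance (Ohm m^2).
#' @examples
#' dysfunctional_resistance(0.1, 0.5)  # doubles to 0.2
#' @export
dysfunctional_resistance <- function(R_m, b) {
  check_scalar(R_m, "R_m", positive = TRUE)
  check_scalar(b, "b")
  if (b < 0 || b >= 1)
    stop_with("ephapsim_domain_error", "b must satisfy 0 <= b < 1 (got %g)", b)
  R_m / (1 - b)
}

#' Dysfunctional membrane capacitance
#'
#' Specific membrane capacitance after a fraction `h` of the bilayer patches
#' has been impaired.  Unit capacitors add, so the damaged capacitance is the
#' linear rescaling `C_m * (1 - h)`.
#'
#' @param C_m Healthy specific membrane capacitance (F/m^2), positive.
#' @param h Bilayer-impairment fraction in `[0, 1)`.
#' @return The damaged specific capacitance (F/m^2).
#' @examples
#' dysfunctional_capacitance(0.02, 0.25)  # 0.015
#' @export
dysfunctional_capacitance <- function(C_m, h) {
  check_scalar(C_m, "C_m", positive = TRUE)
  check_scalar(h, "h")
  if (h < 0 || h >= 1)
    stop_with("ephapsim_domain_error", "h must satisfy 0 <= h < 1 (got %g)", h)
  C_m * (1 - h)
}

#' Effective membrane time constant under damage
#'
#' Product of the damaged resistance and capacitance,
#' `R_m * C_m * (1 - h) / (1 - b)`.  When `b == h` the two damages cancel in
#' the time constant (the synaptic drive coefficient `1 / (C_m (1 - h))`
#' still changes, which is what shifts the firing rate).
#'
#' @param mp A [membrane_parameters()] object.
#' @param dp A [damage_parameters()] object.
#' @return Effective time constant in seconds.
#' @examples
#' effective_time_constant(membrane_parameters(), damage_parameters())  # 2 ms
#' @export
effective_time_constant <- function(mp, dp) {
  stopifnot(inherits(mp, "membrane_parameters"),
            inherits(dp, "damage_parameters"))
  dysfunctional_resistance(mp$R_m, dp$b) *
    dysfunctional_capacitance(mp$C_m, dp$h)
}

#' Rheobase synaptic current density
#'
#' Smallest tonic synaptic current density at which the damaged quadratic
#' model loses its fixed points and fires tonically:
#' `(V_thresh - V_rest) / (4 * R_dfl)`.  Only channel damage enters; the
#' bilayer fraction `h` rescales every term of the voltage equation equally
#' and therefore cancels from the firing condition.
#'
#' @inheritParams effective_time_constant
#' @return Rheobase current density (A/m^2).
#' @examples
#' rheobase_current(membrane_parameters(), damage_parameters())  # 0.025 A/m^2
#' @export
rheobase_current <- function(mp, dp = damage_parameters()) {
  stopifnot(inherits(mp, "membrane_parameters"),
            inherits(dp, "damage_parameters"))
  (mp$V_thresh - mp$V_rest) / (4 * dysfunctional_resistance(mp$R_m, dp$b))
}
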