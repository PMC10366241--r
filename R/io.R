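# JSON config serialization.  Membrane keys follow the conventional symbol
# names (V_rest, V_thresh, V_peak, c, C_m, R_m, rho_ext, r); every file
# carries an explicit "units" block since all values are stored in SI.

membrane_units <- c(V_rest = "V", V_thresh = "V", V_peak = "V", c = "V",
                    C_m = "F/m^2", R_m = "Ohm.m^2", rho_ext = "Ohm.m",
                    r = "m")

stimulus_units <- c(f_stim = "Hz", A_eph = "A", I_0 = "A/m^2",
                    sigma_noise = "A.s^(1/2)/m^2", phase0 = "rad")

#' Write a parameter set to a JSON config file
#'
#' Serializes a [membrane_parameters()], [damage_parameters()] or
#' [stimulus_spec()] object as a flat key-value JSON object with a `units`
#' block.  Read back with [read_membrane_parameters()],
#' [read_damage_parameters()] or [read_stimulus_spec()].
#'
#' @param x The parameter object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_config(membrane_parameters(), f)
#' read_membrane_parameters(f)
#' @export
write_config <- function(x, path) {
  if (inherits(x, "membrane_parameters")) {
    vals <- list(V_rest = x$V_rest, V_thresh = x$V_thresh, V_peak = x$V_peak,
                 c = x$c_reset, C_m = x$C_m, R_m = x$R_m,
                 rho_ext = x$rho_ext, r = x$r_dist)
    units <- membrane_units
  } else if (inherits(x, "stimulus_spec")) {
    vals <- unclass(x)
    units <- stimulus_units
  } else if (inherits(x, "damage_parameters")) {
    vals <- unclass(x)
    units <- c(b = "fraction", h = "fraction")
  } else {
    stop_with("ephapsim_domain_error",
              "cannot serialize objects of class '%s'", class(x)[1])
  }
  jsonlite::write_json(c(vals, list(units = as.list(units))), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read membrane parameters from a JSON config file
#'
#' @param path File written by [write_config()].
#' @return A [membrane_parameters()] object.
#' @export
read_membrane_parameters <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  membrane_parameters(V_rest = j$V_rest, V_thresh = j$V_thresh,
                      V_peak = j$V_peak, c_reset = j$c,
                      C_m = j$C_m, R_m = j$R_m,
                      rho_ext = j$rho_ext, r_dist = j$r)
}

#' Read a stimulus specification from a JSON config file
#'
#' @param path File written by [write_config()].
#' @return A [stimulus_spec()] object.
#' @export
read_stimulus_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulus_spec(f_stim = j$f_stim, A_eph = j$A_eph, I_0 = j$I_0,
                sigma_noise = j$sigma_noise, phase0 = j$phase0)
}

#' Read damage fractions from a JSON config file
#'
#' @param path File written by [write_config()].
#' @return A [damage_parameters()] object.
#' @export
read_damage_parameters <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  damage_parameters(b = j$b, h = j$h)
}
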