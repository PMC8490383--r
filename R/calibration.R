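#' Loading-device calibration: pressure, force, and gas-cartridge physics
#'
#' The pneumatic posterior-drawer loading rig is pressure-controlled: its
#' operating point of 2.3 bar transfers 147 N (= 15 kilopond) of posterior
#' force to the tibia, and the CO2 drive cartridge holds 16 g of liquid gas.
#' These helpers document the unit and physics conversions behind those
#' numbers.
#'
#' @param operating_pressure Operating pressure in bar (default 2.3).
#' @param rated_force Rated force at that pressure in N (default 147).
#' @return A `device_calibration` with the derived effective piston area
#'   (m^2).
#' @export
device_calibration <- function(operating_pressure = 2.3, rated_force = 147) {
  if (operating_pressure <= 0 || rated_force <= 0) {
    rlang::abort("Pressure and force must be positive.")
  }
  area <- rated_force / (operating_pressure * 1e5)
  structure(
    list(
      operating_pressure = operating_pressure,
      rated_force = rated_force,
      effective_area = area
    ),
    class = "device_calibration"
  )
}

#' @export
print.device_calibration <- function(x, ...) {
  cat(sprintf(
    "<device_calibration> %.3g bar -> %.5g N (effective area %.3g cm^2)\n",
    x$operating_pressure, x$rated_force, x$effective_area * 1e4
  ))
  invisible(x)
}

#' Convert kilopond (kilogram-force) to newton
#'
#' 1 kP = 9.80665 N (standard gravity). The device's 15 kP rating is
#' 147.1 N, printed as 147 N.
#'
#' @param f Force in kilopond (>= 0).
#' @return Force in newton.
#' @examples
#' kilopond_to_newton(15) # 147.09975
#' @export
kilopond_to_newton <- function(f) {
  if (any(f < 0)) rlang::abort("Force must be >= 0 kP.")
  f * 9.80665
}

#' Force transferred to the joint at a given pressure
#'
#' Linear pressure-to-force conversion through the calibrated effective
#' area: `F = p[Pa] * area`.
#'
#' @param p Pressure in bar (>= 0).
#' @param cal A `device_calibration`.
#' @return Force in newton.
#' @examples
#' pressure_to_force(2.3, device_calibration()) # 147
#' @export
pressure_to_force <- function(p, cal = device_calibration()) {
  if (!inherits(cal, "device_calibration")) {
    rlang::abort("`cal` must be a device_calibration.")
  }
  if (any(p < 0)) rlang::abort("Pressure must be >= 0 bar.")
  p * 1e5 * cal$effective_area
}

#' Expanded ideal-gas volume of a CO2 cartridge
#'
#' Ideal-gas volume of a given liquid CO2 mass after expansion:
#' `V = (m / M) R T / P` with M(CO2) = 44.01 g/mol. The 16 g drive
#' cartridge expands to 8.7 l at 15 degrees C and 1 bar.
#'
#' @param mass_g CO2 mass in grams (> 0).
#' @param T_K Temperature in kelvin (default 288.15, i.e. 15 degrees C).
#' @param P_bar Expansion pressure in bar (default 1).
#' @return Volume in litres.
#' @examples
#' gas_expansion_volume(16) # ~8.7 l
#' @export
gas_expansion_volume <- function(mass_g, T_K = 288.15, P_bar = 1) {
  if (any(mass_g < 0) || any(T_K <= 0) || any(P_bar <= 0)) {
    rlang::abort("Mass must be >= 0; temperature and pressure must be positive.")
  }
  R <- 8.31446261815324 # J / (mol K)
  M <- 44.01 # g/mol
  (mass_g / M) * R * T_K / (P_bar * 1e5) * 1e3
}
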