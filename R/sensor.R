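#' Sensor geometry
#'
#' Geometry and elastic constants of the rectangular film biosensor, in SI
#' units.
#'
#' @param width width W in m.
#' @param thickness thickness T in m.
#' @param length_ length L in m (trailing underscore avoids masking
#'   `base::length`).
#' @param youngs_mod tensile (Young's) modulus E in Pa.
#' @param poisson Poisson's ratio (0 <= nu < 0.5).
#' @return an object of class `sensor_geometry`.
#' @examples
#' g <- sensor_geometry(width = 25e-3, thickness = 0.3e-3,
#'                      length_ = 60e-3, youngs_mod = 286e3)
#' cantilever_constant(g)
#' @export
sensor_geometry <- function(width, thickness, length_, youngs_mod,
                            poisson = 0.3) {
  check_scalar(width, "width", positive = TRUE)
  check_scalar(thickness, "thickness", positive = TRUE)
  check_scalar(length_, "length_", positive = TRUE)
  check_scalar(youngs_mod, "youngs_mod", positive = TRUE)
  check_scalar(poisson, "poisson")
  if (poisson < 0 || poisson >= 0.5) {
    stop("poisson must satisfy 0 <= nu < 0.5", call. = FALSE)
  }
  structure(list(width = width, thickness = thickness, length_ = length_,
                 youngs_mod = youngs_mod, poisson = poisson),
            class = "sensor_geometry")
}

# Exponent of pi in the load-deflection formula.  Plate-deflection theory
# carries a pi^4 term; kept as a named constant so the alternative pi/4
# reading of the typography is a one-line change.
LOAD_DEFLECTION_PI_EXPONENT <- 4

#' Cantilever elastic constant
#'
#' `K = E W T^3 / (6 L^3)` for a rectangular film cantilever: linear in the
#' width, cubic in the thickness, inverse-cubic in the length.
#'
#' @param g a [sensor_geometry()].
#' @return elastic constant K in N/m.
#' @export
cantilever_constant <- function(g) {
  stopifnot(inherits(g, "sensor_geometry"))
  g$youngs_mod * g$width * g$thickness^3 / (6 * g$length_^3)
}

#' Load-deflection pressure
#'
#' `P = pi^4 E T^3 c / (6 (1 - nu^2) L^4)`: the pressure on the film that
#' produces a central deflection `c`.
#'
#' @param g a [sensor_geometry()].
#' @param deflection deflection c in m.
#' @return pressure P in Pa.
#' @export
load_deflection_pressure <- function(g, deflection) {
  stopifnot(inherits(g, "sensor_geometry"))
  check_scalar(deflection, "deflection")
  if (abs(g$poisson) >= 1) stop("|nu| must be < 1", call. = FALSE)
  pi^LOAD_DEFLECTION_PI_EXPONENT * g$youngs_mod * g$thickness^3 *
    deflection / (6 * (1 - g$poisson^2) * g$length_^4)
}

#' Young's modulus from a tensile test
#'
#' `E = F L / (A dL)`: force F over cross-section A divided by the relative
#' elongation dL/L.
#'
#' @param force tensile force F in N.
#' @param length_ rest length L in m.
#' @param area cross-sectional area A in m^2.
#' @param elongation elongation dL in m.
#' @return Young's modulus E in Pa.
#' @examples
#' youngs_modulus(0.07, 1, 1.25e-5, 0.2)  # 0.07 N at 20% strain -> 28 kPa
#' @export
youngs_modulus <- function(force, length_, area, elongation) {
  check_scalar(force, "force", positive = TRUE)
  check_scalar(length_, "length_", positive = TRUE)
  check_scalar(area, "area", positive = TRUE)
  check_scalar(elongation, "elongation", positive = TRUE)
  force * length_ / (area * elongation)
}

#' Resistivity and conductivity by voltammetry
#'
#' `rho = Ut S / (It L)` from the applied voltage `Ut`, measured current
#' `It`, cross-section `S` and length `L`; the reciprocal is returned as the
#' conductivity.  (The device literature sometimes labels this quantity
#' "conductivity"; the formula itself yields resistivity, so both are
#' returned explicitly named.)
#'
#' @param voltage applied voltage Ut in V.
#' @param current measured current It in A.
#' @param section cross-sectional area S in m^2.
#' @param length_ sample length L in m.
#' @return list with `resistivity` (Ohm m) and `conductivity` (S/m).
#' @examples
#' resistivity(2, 0.001, 5e-6, 0.01)$resistivity  # 1 Ohm m
#' @export
resistivity <- function(voltage, current, section, length_) {
  check_scalar(voltage, "voltage", positive = TRUE)
  check_scalar(current, "current", positive = TRUE)
  check_scalar(section, "section", positive = TRUE)
  check_scalar(length_, "length_", positive = TRUE)
  rho <- voltage * section / (current * length_)
  list(resistivity = rho, conductivity = 1 / rho)
}
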