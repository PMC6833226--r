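#' Physical constants of the microtubule magneto-mechanics model
#'
#' Bundles every material constant the closed-form magneto-physics needs,
#' in strict SI units. Defaults are the values for tubulin/microtubules at
#' the zebrafish rearing temperature of 28.5 degC.
#'
#' @param delta_chi Magnetizability-anisotropy volume of one tubulin dimer,
#'   m^3. The alpha-beta axis is the weakest diamagnetic axis, so dimers
#'   (and hence microtubules) tend to align with the field.
#' @param mu0 Vacuum permeability, T m/A.
#' @param kB Boltzmann constant, J/K.
#' @param T_abs Absolute temperature, K. Default 301.65 K (28.5 degC).
#' @param d0 Tubulin dimer length, m.
#' @param EI Microtubule flexural rigidity, N m^2. Default 3.312e-23 N m^2
#'   (= 33.12 pN um^2), the standard magnitude for a single microtubule.
#' @param xi Viscous drag coefficient per unit microtubule length,
#'   N s/m^2 (= 1 pN s/nm per nm of length, i.e. 1e-3 in SI).
#' @param v0 Zero-field microtubule polymerization speed, m/s
#'   (default 0.125 um/s).
#'
#' @return An object of class `physical_constants` (a named list).
#' @examples
#' consts <- physical_constants()
#' consts$delta_chi
#' @export
physical_constants <- function(delta_chi = 1.243e-32,
                               mu0 = 4e-7 * pi,
                               kB = 1.380649e-23,
                               T_abs = 301.65,
                               d0 = 8e-9,
                               EI = 3.312e-23,
                               xi = 1e-3,
                               v0 = 1.25e-7) {
  vals <- list(delta_chi = delta_chi, mu0 = mu0, kB = kB, T_abs = T_abs,
               d0 = d0, EI = EI, xi = xi, v0 = v0)
  for (nm in names(vals)) stop_unless_number(vals[[nm]], nm, positive = TRUE)
  structure(vals, class = "physical_constants")
}

#' Homogeneous static magnetic field specification
#'
#' @param B Magnetic flux density, T. `B = 0` disables every magnetic term
#'   exactly (bitwise zero torques and deflections, unchanged rates).
#' @param direction_angle Lab-frame field direction, rad. In the planar
#'   simulator the cell long axis is the x axis; the default `pi/2` points
#'   the field along the short axis.
#'
#' @return An object of class `field_spec`.
#' @examples
#' field_spec(9)           # the 9 T exposure condition
#' field_spec(0)           # control
#' @export
field_spec <- function(B = 9, direction_angle = pi / 2) {
  if (!is.numeric(B) || length(B) != 1L || !is.finite(B) || B < 0)
    abort_invalid_field("`B` must be a single finite non-negative number (tesla)")
  stop_unless_number(direction_angle, "direction_angle")
  structure(list(B = B, direction_angle = direction_angle),
            class = "field_spec")
}

as_field_spec <- function(x) {
  if (inherits(x, "field_spec")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(field_spec(B = x))
  abort_invalid_field("expected a `field_spec` or a single field strength in tesla")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants (SI):\n")
  for (nm in names(x)) cat(sprintf("  %-9s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("Static magnetic field: B = %g T, direction = %g rad\n",
              x$B, x$direction_angle))
  invisible(x)
}
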