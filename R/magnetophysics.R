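# Closed-form magneto-physics of tubulin dimers and microtubules in a
# homogeneous static magnetic field (SMF). All quantities in SI; angles are
# measured between the dimer/microtubule axis and the field direction.
#
# The driving scale is the orientation energy/torque amplitude
#   A = delta_chi * B^2 / (2 * mu0)   [J, or N m for the torque]
# which at 9 T is ~4e-25 J, i.e. ~1e-4 kBT per dimer: tiny per dimer, but a
# microtubule carries 13 L / d0 dimers, so torque and bending grow with
# length and become significant for the hundreds-of-micrometre astral
# microtubules of early cleavage-stage blastomeres.

torque_amplitude <- function(field, consts) {
  consts$delta_chi * field$B^2 / (2 * consts$mu0)
}

#' Magnetic torque on one tubulin dimer
#'
#' The diamagnetic anisotropy of the dimer gives an orientation-dependent
#' magnetic energy; the resulting torque is
#' \deqn{M_0(\theta) = \frac{\Delta\chi B^2}{2\mu_0}\sin 2\theta,}
#' with period pi in the angle theta between the dimer axis and the field.
#'
#' @param theta Angle(s) between the dimer axis and the field direction, rad.
#' @param field A [field_spec()].
#' @param consts A [physical_constants()].
#' @return Torque in N m, same length as `theta`. Exactly zero when `B = 0`.
#' @examples
#' dimer_torque(pi / 4, field_spec(9), physical_constants())
#' @export
dimer_torque <- function(theta, field = field_spec(), consts = physical_constants()) {
  field <- as_field_spec(field)
  if (!all(is.finite(theta))) abort_domain("`theta` must be finite")
  torque_amplitude(field, consts) * sin(2 * theta)
}

#' Orientation energy of one tubulin dimer in the field
#'
#' Energy required to hold a dimer at angle theta against the magnetic
#' torque: \deqn{E(\theta) = \frac{\Delta\chi B^2}{2\mu_0}\sin^2\theta.}
#' Its derivative in theta equals [dimer_torque()].
#'
#' @inheritParams dimer_torque
#' @return Energy in J, non-negative.
#' @export
dimer_orientation_energy <- function(theta, field = field_spec(),
                                     consts = physical_constants()) {
  field <- as_field_spec(field)
  if (!all(is.finite(theta))) abort_domain("`theta` must be finite")
  torque_amplitude(field, consts) * sin(theta)^2
}

#' Boltzmann orientation density of dissociative tubulin dimers
#'
#' Free dimers in cytoplasm orient following the Boltzmann distribution
#' \deqn{P(\theta) = k_0\, e^{-E(\theta)/k_B T},}
#' with the normalization constant fixed numerically over the chosen
#' support. The planar support is theta in \[-pi/2, pi/2) (consistent with
#' the planar simulator); `support = "spherical"` adds the sin(theta)
#' solid-angle weight on \[0, pi\].
#'
#' @inheritParams dimer_torque
#' @param support `"planar"` (default) or `"spherical"`.
#' @return Probability density in 1/rad at `theta`; integrates to 1 over
#'   the support. Uniform when `B = 0`.
#' @export
dimer_orientation_pdf <- function(theta, field = field_spec(),
                                  consts = physical_constants(),
                                  support = c("planar", "spherical")) {
  field <- as_field_spec(field)
  support <- match.arg(support)
  if (!all(is.finite(theta))) abort_domain("`theta` must be finite")
  unnorm <- function(th) {
    w <- exp(-dimer_orientation_energy(th, field, consts) /
               (consts$kB * consts$T_abs))
    if (support == "spherical") w <- w * sin(th)
    w
  }
  lims <- if (support == "planar") c(-pi / 2, pi / 2) else c(0, pi)
  Z <- stats::integrate(unnorm, lims[1], lims[2], rel.tol = 1e-12)$value
  unnorm(theta) / Z
}

#' Direction-dependent polymerization rate under the field
#'
#' Growth at a microtubule end adds dimers whose alignment cost rises with
#' the angle to the field, giving
#' \deqn{v(\theta) = v_0\, e^{-\Delta\chi B^2 \sin^2\theta / 2\mu_0 k_B T}.}
#' Growth parallel to the field proceeds at exactly `v0`; the perpendicular
#' direction is slowest.
#'
#' @inheritParams dimer_torque
#' @return Speed in m/s.
#' @examples
#' polymerization_rate(0, field_spec(9))        # = v0 exactly
#' polymerization_rate(pi / 2, field_spec(9))   # slowest direction
#' @export
polymerization_rate <- function(theta, field = field_spec(),
                                consts = physical_constants()) {
  field <- as_field_spec(field)
  if (!all(is.finite(theta))) abort_domain("`theta` must be finite")
  consts$v0 * exp(-dimer_orientation_energy(theta, field, consts) /
                    (consts$kB * consts$T_abs))
}

#' Magnetic torque on a whole microtubule treated as a rigid rod
#'
#' A microtubule of length L holds `13 L / d0` dimers across its 13
#' protofilaments, so the rigid-rod torque is
#' \deqn{M(L,\theta) = \frac{13 L}{d_0}\,M_0(\theta).}
#'
#' @param L Microtubule length(s), m; strictly positive.
#' @inheritParams dimer_torque
#' @return Torque in N m, linear in `L`.
#' @export
mt_torque <- function(L, theta, field = field_spec(),
                      consts = physical_constants()) {
  if (!all(is.finite(L)) || any(L <= 0))
    abort_invalid_geometry("`L` must be finite and strictly positive")
  (13 * L / consts$d0) * dimer_torque(theta, field, consts)
}

#' Field-induced rotation rate of a microtubule
#'
#' Balancing the rigid-rod magnetic torque against rotational viscous drag
#' (drag coefficient `xi` per unit length) gives the angular speed
#' \deqn{\dot\phi = \frac{2 M(L,\theta)}{\xi L^2},}
#' largest at theta = pi/4. The sign follows sin(2 theta): a positive value
#' means rotation toward field alignment for theta in (0, pi/2).
#'
#' @inheritParams mt_torque
#' @return Angular speed in rad/s.
#' @export
mt_rotation_rate <- function(L, theta, field = field_spec(),
                             consts = physical_constants()) {
  2 * mt_torque(L, theta, field, consts) / (consts$xi * L^2)
}

#' Bending moment distributed along a microtubule
#'
#' The magnetic torque acts on every dimer, so the internal moment at
#' distance x from the anchored (minus) end is
#' \deqn{M(x) = \frac{13\,\Delta\chi B^2}{2 d_0 \mu_0}(L - x)\sin 2\theta,}
#' zero at the free tip and maximal at the anchor.
#'
#' @param x Position(s) along the microtubule, m, with `0 <= x <= L`.
#' @inheritParams mt_torque
#' @return Moment in N m.
#' @export
bending_moment <- function(x, L, theta, field = field_spec(),
                           consts = physical_constants()) {
  if (!all(is.finite(L)) || any(L <= 0))
    abort_invalid_geometry("`L` must be finite and strictly positive")
  if (any(x < 0 | x > L)) abort_domain("`x` must lie in [0, L]")
  field <- as_field_spec(field)
  (13 * consts$delta_chi * field$B^2 / (2 * consts$d0 * consts$mu0)) *
    (L - x) * sin(2 * theta)
}

#' Euler-Bernoulli deflection of a microtubule under the distributed torque
#'
#' Treating the microtubule as a cantilever clamped at the spindle pole
#' (deflection and slope zero at x = 0), the small-deformation deflection is
#' \deqn{\omega(x) = \frac{13\,\Delta\chi B^2 \sin 2\theta}{2 d_0 \mu_0 EI}
#'   \left(\tfrac12 L x^2 - \tfrac16 x^3\right),}
#' the double integral of [bending_moment()] divided by `EI`. The maximal
#' deflection is at the free end: `omega_max = omega(L)`, proportional to
#' L^3 and B^2. The microtubule bends toward the field direction.
#'
#' @inheritParams mt_torque
#' @param n_points Number of sampling positions along the rod (>= 2).
#' @return A `deflection_profile` with fields `x` (m), `moment` (N m),
#'   `deflection` (m) and `omega_max` (m, signed like sin(2 theta)).
#' @examples
#' prof <- deflection(50e-6, pi / 4, field_spec(9))
#' prof$omega_max * 1e6   # ~0.82 um at 50 um length
#' @export
deflection <- function(L, theta, field = field_spec(),
                       consts = physical_constants(), n_points = 101) {
  if (!is.finite(L) || L <= 0)
    abort_invalid_geometry("`L` must be finite and strictly positive")
  if (n_points < 2) abort_domain("`n_points` must be >= 2")
  field <- as_field_spec(field)
  x <- seq(0, L, length.out = n_points)
  K <- 13 * consts$delta_chi * field$B^2 * sin(2 * theta) /
    (2 * consts$d0 * consts$mu0 * consts$EI)
  w <- K * (L * x^2 / 2 - x^3 / 6)
  structure(list(x = x,
                 moment = bending_moment(x, L, theta, field, consts),
                 deflection = w,
                 omega_max = K * L^3 / 3),
            class = "deflection_profile")
}

#' @export
as.data.frame.deflection_profile <- function(x, ...) {
  data.frame(x_m = x$x, moment_Nm = x$moment, deflection_m = x$deflection)
}

#' @export
print.deflection_profile <- function(x, ...) {
  cat(sprintf("Deflection profile: L = %.3g m, omega_max = %.3g m (%d points)\n",
              max(x$x), x$omega_max, length(x$x)))
  invisible(x)
}

#' Clamp a tip deflection below the rod length
#'
#' The small-deformation formula can exceed the rod length for long
#' microtubules at high field; the chord-projection force reduction is only
#' real-valued for |omega_max| < L. This clamps the magnitude at
#' `frac * L` and reports whether clamping occurred.
#'
#' @param omega_max Tip deflection(s), same length unit as `L`.
#' @param L Rod length(s).
#' @param frac Clamping fraction, default 0.99.
#' @return List with `omega` (clamped, magnitudes) and `clamped` (logical).
#' @export
clamp_deflection <- function(omega_max, L, frac = 0.99) {
  w <- abs(omega_max)
  clamped <- w > frac * L
  list(omega = pmin(w, frac * L), clamped = clamped)
}

#' Effective pulling force along a bent microtubule
#'
#' A bent microtubule of arc length L with tip deflection omega_max spans a
#' shorter chord; the pulling force transmitted along the chord is reduced
#' by the chord projection
#' \deqn{f^* = f_c\,\frac{\sqrt{L^2 - \omega_{max}^2}}{L},}
#' equal to `f_c` for an unbent rod and vanishing as the deflection
#' approaches the length.
#'
#' @param f_c Pulling force on the unbent microtubule (any force unit,
#'   non-negative).
#' @param L Microtubule length (any length unit, positive).
#' @param omega_max Tip deflection magnitude, same unit as `L`, with
#'   `0 <= omega_max < L` (clamp first with [clamp_deflection()]).
#' @return Force in the unit of `f_c`; never exceeds `f_c`.
#' @examples
#' effective_pulling_force(1, 50, 30)  # 3-4-5 triangle: 0.8
#' @export
effective_pulling_force <- function(f_c, L, omega_max) {
  if (any(f_c < 0)) abort_domain("`f_c` must be non-negative")
  if (any(L <= 0)) abort_invalid_geometry("`L` must be strictly positive")
  if (any(omega_max < 0)) abort_domain("`omega_max` must be non-negative")
  if (any(omega_max >= L))
    abort_degenerate_bending("`omega_max` must be < L; clamp the deflection first")
  f_c * sqrt(L^2 - omega_max^2) / L
}
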