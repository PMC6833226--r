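# Planar elliptical cell geometry and the rigid spindle. Simulator length
# unit is the micrometre; the long axis of the cell is the x axis.

#' Elliptical cell geometry
#'
#' The planar cell cross-section through the long axis. Defaults correspond
#' to the first cleavage of the zebrafish blastodisc: a 600 x 300 um
#' ellipse.
#'
#' @param a Semi-major axis, um.
#' @param b Semi-minor axis, um; `a >= b > 0`.
#' @return A `cell_geometry` object.
#' @export
cell_geometry <- function(a = 300, b = 150) {
  stop_unless_number(a, "a", positive = TRUE)
  stop_unless_number(b, "b", positive = TRUE)
  if (a < b) abort_invalid_geometry("semi-major axis `a` must be >= semi-minor `b`")
  structure(list(a = a, b = b), class = "cell_geometry")
}

#' Scale a cell geometry by a linear factor
#' @param geom A [cell_geometry()].
#' @param factor Linear scale factor (> 0).
#' @return A scaled `cell_geometry`.
#' @export
scale_geometry <- function(geom, factor) {
  stop_unless_number(factor, "factor", positive = TRUE)
  cell_geometry(geom$a * factor, geom$b * factor)
}

# Signed "ellipse coordinate": < 1 inside, 1 on the boundary.
ellipse_level <- function(x, y, geom) (x / geom$a)^2 + (y / geom$b)^2

inside_ellipse <- function(x, y, geom, margin = 0) {
  ellipse_level(x, y, cell_geometry(geom$a - margin, geom$b - margin)) < 1
}

# Distance from an interior point along direction psi to the ellipse
# boundary (vectorized over points/directions). Solves the ray-ellipse
# quadratic; the point must be inside.
ray_to_boundary <- function(px, py, psi, geom) {
  cx <- cos(psi); sy <- sin(psi)
  A <- (cx / geom$a)^2 + (sy / geom$b)^2
  Bq <- px * cx / geom$a^2 + py * sy / geom$b^2
  Cq <- ellipse_level(px, py, geom) - 1
  disc <- Bq^2 - A * Cq
  (-Bq + sqrt(pmax(disc, 0))) / A
}

#' Rigid spindle state
#'
#' The spindle is a rigid body: two poles at `center +/- s (cos alpha,
#' sin alpha)`, with the pole half-separation `s` fixed within a run (in
#' large blastomeres the spindle size sits at its upper limit).
#'
#' @param center Numeric length-2, spindle centre, um.
#' @param alpha Orientation angle to the cell long axis, rad.
#' @param half_separation Pole half-distance `s`, um (default 30).
#' @param geom Optional [cell_geometry()]; if supplied both poles are
#'   checked to lie strictly inside the cell.
#' @return A `spindle_state` object.
#' @export
spindle_state <- function(center = c(0, 0), alpha = 0, half_separation = 30,
                          geom = NULL) {
  if (!is.numeric(center) || length(center) != 2L || !all(is.finite(center)))
    abort_invalid_geometry("`center` must be a finite length-2 numeric")
  stop_unless_number(alpha, "alpha")
  stop_unless_number(half_separation, "half_separation", positive = TRUE)
  st <- structure(list(center = as.numeric(center), alpha = alpha,
                       half_separation = half_separation),
                  class = "spindle_state")
  if (!is.null(geom)) {
    p <- spindle_poles(st)
    if (!all(inside_ellipse(p[, 1], p[, 2], geom)))
      abort_invalid_geometry("both spindle poles must lie strictly inside the cell")
  }
  st
}

#' Pole positions of a spindle state
#' @param state A [spindle_state()].
#' @return A 2 x 2 matrix; rows are the two poles (x, y) in um.
#' @export
spindle_poles <- function(state) {
  u <- c(cos(state$alpha), sin(state$alpha))
  rbind(state$center + state$half_separation * u,
        state$center - state$half_separation * u)
}

#' Orientation error relative to the cell long axis
#'
#' The spindle axis is a line (period pi); this wraps an angle to the
#' equivalent error in \[-pi/2, pi/2\].
#'
#' @param alpha Angle(s), rad.
#' @return Wrapped angle(s) in rad.
#' @export
axis_error <- function(alpha) {
  ((alpha + pi / 2) %% pi) - pi / 2
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("Elliptical cell: %g x %g um (semi-axes %g, %g)\n",
              2 * x$a, 2 * x$b, x$a, x$b))
  invisible(x)
}

#' @export
print.spindle_state <- function(x, ...) {
  cat(sprintf("Spindle: center (%.2f, %.2f) um, alpha %.3f rad, s = %g um\n",
              x$center[1], x$center[2], x$alpha, x$half_separation))
  invisible(x)
}
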