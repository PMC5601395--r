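# Closed-form Poiseuille hemodynamics in an idealized straight cylinder.

#' Poiseuille wall shear stress
#'
#' For fully developed laminar flow of a Newtonian fluid in a straight
#' cylindrical conduit the wall shear stress is `tau = 4 mu Q / (pi R^3)`.
#' The hybrid engine re-evaluates this quasi-statically from the current
#' lumen radius at every step, closing the mechanical feedback loop: plaque
#' intrusion narrows the lumen and raises the shear stress of the narrowed
#' segment.
#'
#' @param mu dynamic viscosity (Pa s), > 0.
#' @param Q volumetric flow (m^3/s), >= 0.
#' @param R lumen radius (m), > 0.
#' @return Wall shear stress (Pa).
#' @examples
#' wall_shear_stress(0.004, 7.5e-6, 3e-3) # ~1.41 Pa, a healthy coronary value
#' @export
wall_shear_stress <- function(mu, Q, R) {
  if (any(mu <= 0)) stop("wall_shear_stress: mu must be positive")
  if (any(Q < 0)) stop("wall_shear_stress: Q must be nonnegative")
  if (any(R <= 0)) stop("wall_shear_stress: R must be positive")
  4 * mu * Q / (pi * R^3)
}

#' Lumen radius after plaque intrusion
#'
#' Inverts the annulus-volume relation: a plaque volume `V_intrude`
#' displacing the lumen of an initially circular segment of radius `R0` and
#' length `L` leaves a circular lumen of radius
#' `R = sqrt(R0^2 - V_intrude / (pi L))`, so that
#' `pi L (R0^2 - R^2) = V_intrude` exactly (inward remodeling, uniform along
#' the segment).
#'
#' @param R0 initial lumen radius (m), > 0.
#' @param L segment length (m), > 0.
#' @param V_intrude plaque volume protruding into the lumen (m^3), in
#'   `[0, pi R0^2 L)`.
#' @return Remodeled lumen radius (m).
#' @export
lumen_radius_from_intrusion <- function(R0, L, V_intrude) {
  if (any(R0 <= 0) || any(L <= 0))
    stop("lumen_radius_from_intrusion: R0 and L must be positive")
  if (any(V_intrude < 0))
    stop("lumen_radius_from_intrusion: V_intrude must be nonnegative")
  V_lumen <- pi * R0^2 * L
  if (any(V_intrude >= V_lumen))
    stop("lumen_radius_from_intrusion: occlusion (intruding volume >= lumen volume)")
  sqrt(R0^2 - V_intrude / (pi * L))
}
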