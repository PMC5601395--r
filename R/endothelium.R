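# Kedem-Katchalsky transendothelial transport with shear-modulated
# hydraulic conductivity.  These functions are unit-agnostic: they return
# results in whatever consistent units their arguments carry (the engine
# calls them with the per-hour internal bundle, the documented examples use
# SI seconds).

#' Transmural filtration velocity (volume flux)
#'
#' Kedem-Katchalsky volume flux across the endothelium,
#' `Jv = Lp * (dp - osmotic_term)` where `osmotic_term` is the product of the
#' reflection coefficient and the osmotic pressure difference (sigma * dPi).
#' A negative result is mathematically permitted; clamping is caller policy.
#'
#' @param Lp hydraulic conductivity (m Pa^-1 per unit time), >= 0.
#' @param dp transmural pressure difference (Pa).
#' @param sigma reflection coefficient (unused in the volume flux itself;
#'   accepted so callers can pass the full coefficient set).
#' @param osmotic_term sigma * delta-osmotic-pressure (Pa).
#' @return Filtration velocity (m per unit time).
#' @examples
#' transmural_velocity(3e-12, 2400) # 7.2e-9 m/s
#' @export
transmural_velocity <- function(Lp, dp, sigma = NULL, osmotic_term = 0) {
  if (any(Lp < 0)) stop("transmural_velocity: Lp must be nonnegative")
  Lp * (dp - osmotic_term)
}

#' Transendothelial LDL solute flux
#'
#' Kedem-Katchalsky solute flux per unit endothelial area: a diffusive term
#' plus the convective drag of the filtration flow on the fraction of solute
#' not reflected by the membrane,
#' `Js = P0 * dc + (1 - sigma) * Jv * cbar`.
#' With `sigma = 1` convection is fully reflected and only diffusion remains.
#'
#' @param P0 diffusive permeability (m per unit time), >= 0.
#' @param dc lumen-minus-wall LDL concentration difference (nmol/L).
#' @param Jv filtration velocity from [transmural_velocity()].
#' @param sigma reflection coefficient in \[0,1\].
#' @param cbar mean endothelial LDL concentration (nmol/L), >= 0; taken by
#'   the engine as the arithmetic mean of the lumen- and wall-side values.
#' @return Solute flux ((nmol/L) * m per unit time).
#' @export
ldl_flux <- function(P0, dc, Jv, sigma, cbar) {
  if (any(P0 < 0)) stop("ldl_flux: P0 must be nonnegative")
  if (any(cbar < 0)) stop("ldl_flux: cbar must be nonnegative")
  P0 * dc + (1 - sigma) * Jv * cbar
}

#' Shear-dependent hydraulic conductivity
#'
#' Monotone non-increasing response of endothelial hydraulic conductivity to
#' wall shear stress: low-shear (atheroprone) regions are leakiest, high
#' shear tightens intercellular junctions down to a floor,
#' `Lp(tau) = Lp_ref * (f + (1 - f) * tau0 / (tau0 + tau))`
#' with floor fraction `f`, so `Lp(0) = Lp_ref` and
#' `Lp(Inf) = f * Lp_ref`.
#'
#' @param tau wall shear stress (Pa), >= 0.
#' @param Lp_ref zero-shear hydraulic conductivity.
#' @param tau0 shear scale of the decline (Pa), > 0.
#' @param floor_fraction high-shear floor in \[0,1\].
#' @return Effective hydraulic conductivity, same units as `Lp_ref`.
#' @export
hydraulic_conductivity <- function(tau, Lp_ref, tau0, floor_fraction) {
  if (any(tau < 0)) stop("hydraulic_conductivity: tau must be nonnegative")
  if (any(floor_fraction < 0 | floor_fraction > 1))
    stop("hydraulic_conductivity: floor_fraction must lie in [0, 1]")
  Lp_ref * (floor_fraction + (1 - floor_fraction) * tau0 / (tau0 + tau))
}
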