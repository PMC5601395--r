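# Well-mixed arterial-wall inflammation compartment: native LDL, oxidized
# LDL, monocytes, macrophages and foam cells.  The spatial
# convection-diffusion-reaction transport in the wall is reduced to a single
# compartment; the advective/diffusive loss pathways are represented by the
# first-order clearance constants d_m, d_lox, d_M, d_F.

#' Effective monocyte recruitment velocity
#'
#' Monocyte penetration from the circulation, saturating in the local
#' oxidized-LDL burden (the inflammatory attractant) and declining with wall
#' shear stress (recruitment localizes to low-shear, atheroprone regions):
#' `rec = chi * rec_max * Lox / (Lox + K_Lox) * 1 / (1 + tau / tau_half)`.
#' The result is an effective transfer velocity; multiplied by the luminal
#' monocyte concentration it gives the recruitment flux per unit endothelial
#' area.
#'
#' @param tau wall shear stress (Pa), >= 0.
#' @param Lox wall oxidized-LDL concentration (nmol/L), >= 0.
#' @param rec_max maximal recruitment velocity (m per unit time).
#' @param K_Lox half-saturation oxidized-LDL level (nmol/L).
#' @param tau_half shear stress halving recruitment (Pa).
#' @param chi dimensionless calibration scalar.
#' @return Recruitment velocity, same units as `rec_max`.
#' @export
monocyte_recruitment <- function(tau, Lox, rec_max, K_Lox, tau_half, chi) {
  if (any(c(tau, Lox, rec_max, K_Lox, tau_half, chi) < 0))
    stop("monocyte_recruitment: all arguments must be nonnegative")
  chi * rec_max * (Lox / (Lox + K_Lox)) / (1 + tau / tau_half)
}

#' Time derivatives of the arterial-wall state
#'
#' The inflammation cascade in a well-mixed wall compartment:
#' \itemize{
#'   \item native LDL enters across the endothelium (`Js` scaled by the
#'     surface-to-volume ratio) and is lost to oxidation;
#'   \item oxidized LDL is produced by oxidation, consumed by macrophage
#'     uptake and cleared at `d_lox`;
#'   \item monocytes are recruited across the endothelium, differentiate to
#'     macrophages at `rho1` and are cleared at `d_m`;
#'   \item macrophages convert to foam cells by ingesting `eta` oxidized-LDL
#'     particles each (consumed 1:1 on conversion) and are cleared at `d_M`;
#'   \item foam cells accumulate and are cleared at `d_F`.
#' }
#' Oxidized-LDL bookkeeping converts between molar concentration and particle
#' number (1 nmol/L = 6.022e17 particles/m^3), so that particles consumed
#' equal `eta` times foam cells produced, exactly.
#'
#' Unit-agnostic: rates in `p` and the flux `Js` must share one time unit.
#'
#' @param ws named list or vector with components `L_w`, `Lox` (nmol/L),
#'   `m`, `M`, `F` (cells/m^3); all >= 0.
#' @param p parameter list carrying `r_w`, `d_lox`, `d_m`, `d_M`, `d_F`,
#'   `rho1`, `k_m`, `eta`, `rec_max`, `K_Lox`, `tau_half`, `chi`, `m_lumen`
#'   (cells/m^3).
#' @param Js transendothelial LDL flux from [ldl_flux()].
#' @param tau wall shear stress (Pa).
#' @param geometry list with `S_endo` (m^2) and `V_wall` (m^3).
#' @return Named numeric vector of derivatives
#'   `(L_w, Lox, m, M, F)` per unit time.
#' @export
wall_derivatives <- function(ws, p, Js, tau, geometry) {
  ws <- as.list(ws)
  state <- c(ws$L_w, ws$Lox, ws$m, ws$M, ws$F)
  if (any(state < 0))
    stop("wall_derivatives: negative state component")
  s_over_v <- geometry$S_endo / geometry$V_wall
  Lox_p <- ws$Lox * .NA_PER_NMOL_L                  # particles/m^3
  foam_prod <- p$k_m * ws$M * Lox_p / p$eta          # cells/m^3 per time
  uptake_L <- foam_prod * p$eta / .NA_PER_NMOL_L     # nmol/L per time
  rec <- monocyte_recruitment(tau, ws$Lox, p$rec_max, p$K_Lox, p$tau_half,
                              p$chi)
  c(
    L_w = Js * s_over_v - p$r_w * ws$L_w,
    Lox = p$r_w * ws$L_w - uptake_L - p$d_lox * ws$Lox,
    m = rec * s_over_v * p$m_lumen - p$rho1 * ws$m - p$d_m * ws$m,
    M = p$rho1 * ws$m - foam_prod - p$d_M * ws$M,
    F = foam_prod - p$d_F * ws$F
  )
}
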