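# Plaque volume bookkeeping, the constant-volume -> plaque-growing discrete
# event, and the %TAV clinical endpoint.
#
# Volume model: live wall cells occupy `V_wall * (v_mono*m + v_mac*M +
# v_foam*F)`; cleared foam cells additionally deposit their volume
# irreversibly as necrotic/lipid debris (tracked by the engine as the
# `V_nec` state).  While total occupied volume stays below the interstitial
# capacity `phi * V_wall` the wall accommodates it at constant outer volume
# ("constant volume" phase); once it crosses the capacity the excess
# displaces the lumen inward and counts as atheroma growth ("plaque
# growing" phase, an irreversible discrete event located by the integrator).

#' Volume occupied by species in the wall
#'
#' Linear volume bookkeeping over the cellular species, plus the accumulated
#' necrotic deposit.  The contribution of dissolved LDL mass is negligible at
#' physiological concentrations and can be switched on via
#' `v_ldl_per_nmol_l` if desired.
#'
#' @param ws wall state as in [wall_derivatives()].
#' @param p parameter list carrying `v_mono`, `v_mac`, `v_foam`.
#' @param V_wall wall compartment volume (m^3).
#' @param V_necrotic accumulated necrotic deposit volume (m^3).
#' @param v_ldl_per_nmol_l optional volume per (nmol/L of wall LDL + oxLDL)
#'   per m^3 of wall; default 0.
#' @return Occupied volume (m^3).
#' @export
occupied_volume <- function(ws, p, V_wall, V_necrotic = 0,
                            v_ldl_per_nmol_l = 0) {
  ws <- as.list(ws)
  V_wall * (p$v_mono * ws$m + p$v_mac * ws$M + p$v_foam * ws$F +
              v_ldl_per_nmol_l * (ws$L_w + ws$Lox)) + V_necrotic
}

#' Growth-event indicator
#'
#' Signed volume whose zero upcrossing is the constant-volume to
#' plaque-growing transition: occupied volume minus interstitial capacity.
#' The engine locates its root and switches phase irreversibly.
#'
#' @param ps list with `V_occupied` and `V_capacity` (m^3).
#' @return `V_occupied - V_capacity` (m^3).
#' @export
growth_event_value <- function(ps) {
  ps$V_occupied - ps$V_capacity
}

#' Percent change in total atheroma volume
#'
#' The model's clinical endpoint: `100 * (V_t - V_0) / V_0`.
#'
#' @param V_atheroma_t atheroma volume at time t (m^3).
#' @param V_atheroma_0 initial atheroma volume (m^3), > 0.
#' @return Percent change.
#' @export
percent_tav <- function(V_atheroma_t, V_atheroma_0) {
  if (any(V_atheroma_0 <= 0))
    stop("percent_tav: initial atheroma volume must be positive")
  100 * (V_atheroma_t - V_atheroma_0) / V_atheroma_0
}
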