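# Bundled scenario presets matching the study's comparison design:
# an untreated control, a fully adherent patient on one year of daily
# simvastatin, the same regimen filtered through the Markov adherence chain
# with p_t = 0.90 / q_nt = 0.25, and a virtual-population scenario.

.preset_names <- c("control", "regular_treatment", "imperfect_adherence",
                   "population")

#' Bundled scenario presets
#'
#' \describe{
#'   \item{control}{no dosing; disease progression only.}
#'   \item{regular_treatment}{40 mg daily for the first year (8760 h),
#'     every dose taken.}
#'   \item{imperfect_adherence}{same regimen, doses filtered through the
#'     two-state Markov chain with `p_t = 0.90`, `q_nt = 0.25`.}
#'   \item{population}{control disease parameters; used together with
#'     [population_spec()] for variability studies.}
#' }
#' Presets are constructed fresh on every call (immutable by construction)
#' and always validate.
#'
#' @param name preset name.
#' @param seed seed stored in the adherence specification of
#'   `imperfect_adherence` (ignored by the others).
#' @return A `scenario` object.
#' @export
scenario_preset <- function(name = .preset_names, seed = 1L) {
  name <- match.arg(name)
  sc <- load_scenario("")   # all defaults
  sc$adherence <- NULL
  switch(name,
    control = ,
    population = {
      sc$regimen <- regimen(dose_mg = 0, duration_h = 0)
    },
    regular_treatment = {
      sc$regimen <- regimen(dose_mg = 40, interval_h = 24, start_h = 0,
                            duration_h = 8760)
    },
    imperfect_adherence = {
      sc$regimen <- regimen(dose_mg = 40, interval_h = 24, start_h = 0,
                            duration_h = 8760)
      sc$adherence <- adherence_spec(p_t = 0.90, q_nt = 0.25, seed = seed)
    }
  )
  sc
}
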