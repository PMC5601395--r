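---
title: "The atheroQSP model: assumptions, parameters and scenario design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The atheroQSP model: assumptions, parameters and scenario design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

atheroQSP simulates the early growth of an atherosclerotic plaque in an
idealized arterial segment, the lowering of circulating LDL by daily
simvastatin, and the consequences of imperfect medication adherence.  It is
a hybrid simulator: stiff continuous dynamics (deSolve's `lsodar`) coupled
to two kinds of discrete events — oral doses, and the irreversible switch
from a "constant volume" wall to a "growing plaque".  This vignette states
the model, the assumptions behind every reconstructed constant, and what the
shipped scenarios do and do not demonstrate.

## The coupled system

The engine integrates ten states.

**Pharmacokinetics (mg, per hour).**  A depot/parent/metabolite cascade with
first-order absorption (`Ka`), apparent parent elimination `CL2/V2` and
metabolite elimination `CL3/V3`.  Conversion of parent to metabolite is
taken as complete: the apparent metabolite volume and clearance absorb the
formation fraction, which is why `V3`/`CL3` should be read as
formation-scaled quantities.  Doses are instantaneous increments of the
depot amount; the integrator is stopped and restarted at every taken dose,
so no solver step straddles a dose.

**Pharmacodynamics.**  Circulating LDL follows an inhibitory
indirect-response (turnover) model,
`dLDL/dt = K_in (1 - E) - K_out LDL`, driven by the metabolite
concentration through `E = Emax C / (EC50 + C)`.  `K_out` is not a free
parameter: it is derived as `K_in / LDL_baseline` so that the drug-free
steady state is exactly the baseline (1400 nmol/L for the typical patient).
With `Emax = 0.489`, sustained dosing can lower LDL at most to
`1400 * 0.511 = 715.4` nmol/L.

**Hemodynamics.**  Quasi-steady Poiseuille flow in a straight cylinder:
`tau_w = 4 mu Q / (pi R^3)`.  Wall shear stress and lumen radius are
recomputed algebraically from the current state at every derivative
evaluation — there is no pulsatility and no axial variation.  For the
typical patient the healthy-lumen value is about 1.41 Pa.

**Endothelial transport.**  Kedem-Katchalsky fluxes:
`Jv = Lp (dp - sigma dPi)` and `Js = P0 dc + (1 - sigma) Jv cbar`, with
`cbar` the arithmetic mean of the lumen- and wall-side LDL concentrations
and `dc` their difference.  The lumen-side concentration is the circulating
LDL of the PD model, which is the path by which the statin slows the
disease.  Shear modulates the hydraulic conductivity only:
`Lp(tau) = Lp_ref (f + (1 - f) tau0 / (tau0 + tau))`, monotone decreasing
from `Lp_ref` at zero shear to a floor fraction `f` — low-shear regions are
the leaky, atheroprone ones.  The diffusive permeability `P0` is held
shear-independent; both choices are configurable.  The osmotic term
defaults to zero, a common simplification in arterial LDL-transport
modelling.

**Wall inflammation.**  One well-mixed compartment for native LDL, oxidized
LDL, monocytes, macrophages and foam cells.  Native LDL enters across the
endothelium (`Js` times the surface-to-volume ratio of the segment) and is
oxidized at `r_w`; oxidized LDL attracts monocytes, which differentiate to
macrophages (`rho1`); macrophages ingest `eta` oxidized-LDL particles to
become foam cells (formation constant `k_m`, with exact particle/molar
bookkeeping at 1 nmol/L = 6.022e17 particles/m^3, macrophages consumed 1:1
on conversion); every species is cleared at its first-order `d_*` rate.
Monocyte recruitment saturates in oxidized LDL (`K_Lox`) and declines with
shear (`tau_half`), and carries the calibration scalar `chi`.

**Plaque volume and the growth event.**  Live cells occupy
`V_wall (v_mono m + v_mac M + v_foam F)`.  In addition, cleared foam cells
deposit their volume irreversibly as necrotic/lipid debris (state `V_nec`).
This deposit is the model's memory: all Table-level clearance constants are
of order 1e-5 s^-1, so the live species equilibrate within weeks, and
without an integrating state the plaque volume would plateau there — no
two-year dynamics, no lasting treatment effect.  Mechanistically the
deposit is the necrotic core: apoptotic foam cells are poorly cleared and
their lipid remains.  Only foam-cell debris is deposited; monocyte and
macrophage turnover is assumed efficiently efferocytosed.

Total occupied volume (live + deposit) below the interstitial capacity
`phi V_wall` is accommodated at constant outer geometry ("constant
volume").  The integrator's root finder locates the capacity crossing; from
then on ("plaque growing", an irreversible phase) the excess displaces the
lumen inward, `R = sqrt(R0^2 - V_excess / (pi L))`, raising shear and
(through `Lp` and recruitment) partially damping further influx.  The
clinical endpoint is `%TAV = 100 (V_atheroma - V_wall) / V_wall`, zero by
construction at t = 0.  A second root guards against occlusion (intrusion
reaching 99.5% of the lumen), where the simulation halts with a logged
event.

## Parameters: given, derived, reconstructed

The typical-patient disease and PKPD constants (`R_lumen` 3 mm, `k_m`
9.25e-24 m^3/cell/s, the `d_*` clearances, `r_w`, `mu`, `rho1`,
`delta_p` 2400 Pa, `Q` 0.0075 l/s, `m_lumen` 5.5e8 cells/l, `sigma` 0.997;
`CL2/V2/CL3/V3`, `Ka` 2.76/h, `K_in` 29.52 nmol/L/h, `Emax` 0.489, `EC50`
0.0868 ng/mL, `LDL_baseline` 1400 nmol/L) are the published values and ship
as defaults of `athero_params()` / `pkpd_params()`.

Everything the wall model needs beyond those is a documented reconstruction,
chosen once on physical grounds and configurable:

* **Geometry**: segment length 10 mm, wall (intima+media) thickness 0.5 mm —
  a typical proximal coronary segment.
* **Transport**: `Lp_ref = 3e-12 m/Pa/s`, `P0 = 1e-11 m/s`, in the range
  used by arterial-wall transport studies; osmotic term 0.
* **Shear shapes**: `tau0 = tau_half = 1.5 Pa`, the order of the healthy
  segment's own shear (1.41 Pa), so the modelled segment sits on the
  sensitive part of both curves; conductivity floor 0.25.
* **Recruitment**: `K_Lox = 1 nmol/L`, the order of the wall oxidized-LDL
  level the transport submodel itself produces (~1.8 nmol/L), so
  recruitment is neither linear nor saturated; `rec_max = 1e-9 m/s`, an
  effective transfer velocity whose absolute scale is absorbed by `chi`.
* **Cell volumes**: monocyte 4e-16, macrophage 5e-15, foam cell
  1.5e-14 m^3 — order-of-magnitude cytology (8, 21 and 30 um diameter).
* **Capacity fraction**: `phi = 0.1` of the initial wall volume.  Reading
  the growth trigger as "species volume exceeds the whole wall" is
  unreachable at realistic densities; a 10% interstitial capacity is the
  adopted interpretation.
* **Foam-cell stoichiometry**: `eta = 300` effective oxidized-LDL particle
  quanta per foam cell.  This is deliberately far below a literal lipid
  count: with the published `k_m` and the ~1.8 nmol/L wall oxidized-LDL
  level, per-macrophage uptake is ~1e-5 particles/s, and a literal
  `eta = 1e4` would require macrophage densities whose own volume exceeds
  the wall to sustain observed growth rates.  `eta` therefore lumps local
  lipid enrichment that the well-mixed reduction cannot represent; it is a
  calibration-facing constant, not a measurement.

## Calibration convention

The recruitment scalar `chi` is the one deliberately fitted constant.
`calibrate_control_growth()` bisects `chi` (log-scale, monotone objective)
until the *untreated* typical patient reaches a declared control growth.
The shipped convention is **%TAV = 5 at the 2-year horizon** (2.5%/yr),
a mid-range figure for control-arm atheroma progression in intravascular
ultrasound statin trials, and the shipped default `chi = 400.81` is the
bisection output under that convention.  Users calibrating to their own
cohort should re-run the calibration and override `chi` in the scenario
configuration.  Under this convention the typical control patient crosses
into the growing phase around day 430; the treated patient, around day 650.

## Units and numerics

All rates are converted once, at load time, to a canonical internal
convention (hours, metres, nmol/L, cells/m^3) — the published per-second
disease constants are multiplied by 3600 and never mixed with the per-hour
PK constants inside the dynamics.  The solver is `lsodar` with
`rtol = 1e-8`, `atol = 1e-10`; dose times partition the integration exactly;
the phase transition is located by the root finder rather than by grid
inspection.  Derivative evaluations clamp tolerance-scale negative
excursions to zero; every loss term in the wall cascade vanishes with its
own species, so the continuous system preserves nonnegativity by
construction.  The output grid (default 24 h) only samples the dense
solution: halving it changes the 2-year endpoint by well under 0.1%.
Degenerate inputs are handled explicitly: zero-dose or zero-duration
regimens mean "control", `p_t = q_nt = 1` is rejected as a degenerate
chain, occlusion halts the run with a logged event, and a patient with zero
recruitment never leaves the constant-volume phase.

## The shipped scenarios and what they show

* `control` — no dosing, 2 years.
* `regular_treatment` — 40 mg daily (the standard simvastatin trial dose;
  the dose size is a package decision, not a published value) for the first
  365 days of a 730-day horizon, every dose taken.
* `imperfect_adherence` — the same regimen filtered through the two-state
  Markov chain with `p_t = 0.90`, `q_nt = 0.25` (stationary missed fraction
  2/17 = 11.8%, i.e. "missing about 10% of doses").
* `population` — 50 patients, each varied parameter (`k_m`, `r_w`,
  `rec_max`, `m_lumen`, `LDL_baseline` — spanning the foam-cell, lipid and
  recruitment axes) drawn log-normally with median at the typical value and
  CV 0.25.  Log-normal sampling preserves positivity; the spread statistic
  `100 (max - min) / min` is computed over patients whose plaque actually
  grew, since a zero-growth patient cannot anchor a relative spread.

Under the shipped calibration the treatment effect at 2 years is about
3.6 percentage points of %TAV, and the Markov-adherent patient loses on
average about 0.3 percentage points of that benefit.  Two honest caveats.
First, the treatment effect scales nearly linearly with the declared
control-growth convention (and with `phi`), so its absolute size is a
statement about the calibration as much as about the drug.  Second, the
adherence penalty is structurally bounded in this model: circulating LDL is
a linear filter of the inhibition signal, so missing 11.8% of doses
removes at most ~12% of the time-averaged LDL deficit, and the wall cascade
amplifies that only mildly — the simulated penalty-to-effect ratio is
~8%, and no defensible re-parameterization of this reconstruction makes a
~40% ratio generic (it can arise transiently when an arm sits exactly at
the capacity crossing at the horizon).

## What the synthetic scenarios do not show

The virtual population emulates inter-individual kinetic variability only;
it does not model covariates, genetics, plaque composition, pleiotropic
(LDL-independent) statin effects, pulsatile or patient-specific
hemodynamics, or discontinuation behaviour (the Markov chain models
implementation, not persistence).  Passing scenario checks therefore says
the coupled mechanisms behave as designed — not that the model is validated
against any particular clinical cohort.

## Reproducing the headline numbers

```{r}
library(atheroQSP)

ctrl <- simulate_patient(scenario_preset("control"), horizon_h = 17520)
trt <- simulate_patient(scenario_preset("regular_treatment"), horizon_h = 17520)
compare_scenarios(list(control = ctrl, treated = trt))

pop <- run_population(population_spec(n = 50, seed = 1), horizon_h = 17520)
growth_spread(pop$summary$pct_tav[pop$summary$pct_tav > 0])
```

`scripts/acceptance.R` in the source repository runs exactly these
computations (plus the 20-seed adherence comparison) and writes the three
endpoint numbers as JSON.
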