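# Scenario configuration schema for atheroQSP.
# All sections and keys are optional; missing keys take the typical-patient
# defaults.  Keys are lower_snake_case; units are fixed as documented below
# (natural units -- the engine converts all rates to per-hour internally at
# load time).
athero:
  R_lumen_mm: "initial lumen radius [mm] (default 3.0)"
  k_m: "foam cell formation constant [m^3 cell^-1 s^-1] (default 9.25e-24)"
  d_m: "monocyte clearance out of the wall [s^-1] (default 5.75e-6)"
  d_lox: "oxidized-LDL clearance [s^-1] (default 2.4e-5)"
  d_M: "macrophage clearance [s^-1] (default 5.75e-6)"
  d_F: "foam-cell clearance [s^-1] (default 5.75e-6)"
  r_w: "LDL oxidation rate [s^-1] (default 3e-4)"
  mu: "blood viscosity [Pa s] (default 0.004)"
  rho1: "monocyte differentiation rate [s^-1] (default 1.15e-6)"
  delta_p: "endothelial pressure difference [Pa] (default 2400)"
  Q_l_s: "blood flow [l/s] (default 0.0075)"
  m_lumen: "blood monocyte concentration [cells/l] (default 5.5e8)"
  sigma: "endothelial reflection coefficient [-] in [0,1] (default 0.997)"
  segment_length_mm: "modelled segment length [mm] (default 10)"
  wall_thickness_mm: "intima/media thickness [mm] (default 0.5)"
  Lp_ref: "zero-shear hydraulic conductivity [m Pa^-1 s^-1] (default 3e-12)"
  P0: "diffusive LDL permeability [m/s] (default 1e-11)"
  osmotic_term: "sigma * delta-osmotic-pressure [Pa] (default 0)"
  tau0: "shear scale of conductivity decline [Pa] (default 1.5)"
  Lp_floor_fraction: "high-shear conductivity floor [-] in [0,1] (default 0.25)"
  rec_max: "max monocyte recruitment velocity [m/s] (default 1e-9)"
  K_Lox: "ox-LDL half-saturation of recruitment [nmol/L] (default 1.0)"
  tau_half: "shear halving recruitment [Pa] (default 1.5)"
  eta: "effective ox-LDL particles per foam cell [-] (default 300)"
  phi: "interstitial capacity fraction of wall volume [-] (default 0.1)"
  v_mono: "monocyte unit volume [m^3] (default 4e-16)"
  v_mac: "macrophage unit volume [m^3] (default 5e-15)"
  v_foam: "foam cell unit volume [m^3] (default 1.5e-14)"
  chi: "recruitment calibration scalar [-] (default: shipped calibration)"
pkpd:
  CL2: "parent apparent clearance [L/hr] (default 1740)"
  V2: "parent apparent volume [L] (default 8980)"
  CL3: "metabolite apparent clearance [L/hr] (default 383)"
  V3: "metabolite apparent volume [L] (default 1190)"
  Ka: "absorption rate constant [1/hr] (default 2.76)"
  K_in: "LDL production rate [nmol/L/hr] (default 29.52)"
  Emax: "max fractional inhibition [-] in [0,1] (default 0.489)"
  EC50: "metabolite conc. at half-max effect [ng/mL] (default 0.0868)"
  LDL_baseline: "baseline circulating LDL [nmol/L] (default 1400)"
regimen:
  dose_mg: "amount per dose [mg] (default 40; 0 disables dosing)"
  interval_h: "dosing interval [h] (default 24)"
  start_h: "treatment initiation [h] (default 0)"
  duration_h: "treatment length [h] (default 8760)"
adherence:   # omit the whole section (or set to ~) for full adherence
  p_t: "P(take | took previous) [-] (default 0.90)"
  q_nt: "P(miss | missed previous) [-] (default 0.25)"
  seed: "integer seed for the adherence generator"
  initial_state: "taking | not_taking (default taking)"
engine:
  rtol: "relative solver tolerance (default 1e-8)"
  atol: "absolute solver tolerance (default 1e-10)"
  dt_out_h: "output grid spacing [h] (default 24)"
  root_tol_h: "event location accuracy [h] (default 1e-6)"
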