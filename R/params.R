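# Parameter containers, validation, unit conversion and scenario I/O.
#
# Two layers of units are used deliberately:
#   * "natural" units: the units in which the quantities are usually reported
#     (per-second disease rate constants, per-hour PK constants, mm lengths,
#     l/s flow).  Constructors and serialized configurations use these.
#   * "internal" units: a single canonical convention used by the dynamics
#     (time in hours, lengths in m, volumes in m^3, lipids in nmol/L, cells
#     in cells/m^3).  `internal_params()` performs the conversion once, at
#     load time, so the coupled ODE system never mixes time scales.

#' Stop with a validation error naming the offending field
#' @noRd
validation_error <- function(field, msg) {
  stop(structure(
    class = c("atheroqsp_validation_error", "error", "condition"),
    list(message = sprintf("invalid parameter '%s': %s", field, msg),
         call = sys.call(-1))
  ))
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    validation_error(field, "must be a single positive finite number")
  x
}

check_nonnegative <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    validation_error(field, "must be a single nonnegative finite number")
  x
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    validation_error(field, "must lie in [0, 1]")
  x
}

#' Atherosclerosis model parameters for a typical patient
#'
#' Builds the disease-side parameter set: vessel geometry, blood rheology,
#' endothelial transport constants and the arterial-wall inflammation rate
#' constants.  Defaults are the typical-patient values (rates in natural
#' per-second units), plus documented reconstruction constants for the parts
#' of the wall model that the primary sources leave open (recruitment
#' saturation, wall shear stress shape constants, cell unit volumes,
#' interstitial capacity, foam-cell lipid stoichiometry and the recruitment
#' calibration scalar `chi`).
#'
#' @param R_lumen_mm initial lumen radius (mm).
#' @param k_m foam-cell formation constant (m^3 cell^-1 s^-1).
#' @param d_m,d_M,d_F first-order clearance of monocytes, macrophages and
#'   foam cells out of the wall (s^-1).
#' @param d_lox first-order clearance of oxidized LDL (s^-1).
#' @param r_w LDL oxidation rate constant in the wall (s^-1).
#' @param mu blood dynamic viscosity (Pa s).
#' @param rho1 monocyte-to-macrophage differentiation rate (s^-1).
#' @param delta_p transmural (endothelial) pressure difference (Pa).
#' @param Q_l_s blood flow through the segment (l/s).
#' @param m_lumen circulating monocyte concentration (cells/l).
#' @param sigma endothelial reflection coefficient (dimensionless, in \[0,1\]).
#' @param segment_length_mm modelled segment length (mm).
#' @param wall_thickness_mm intima/media thickness (mm).
#' @param Lp_ref reference hydraulic conductivity at zero shear (m Pa^-1 s^-1).
#' @param P0 diffusive endothelial permeability to LDL (m/s).
#' @param osmotic_term the product sigma * delta-osmotic-pressure (Pa);
#'   defaults to 0 (osmotic contribution neglected).
#' @param tau0 shear scale of the hydraulic-conductivity decline (Pa).
#' @param Lp_floor_fraction high-shear floor of hydraulic conductivity as a
#'   fraction of `Lp_ref` (in \[0,1\]).
#' @param rec_max maximal effective monocyte recruitment velocity (m/s).
#' @param K_Lox oxidized-LDL half-saturation of recruitment (nmol/L).
#' @param tau_half wall shear stress at which recruitment is halved (Pa).
#' @param eta effective oxidized-LDL particles consumed per foam cell formed
#'   (dimensionless lumped stoichiometry).
#' @param phi interstitial capacity fraction of the initial wall volume that
#'   can be occupied before the plaque starts displacing the lumen (in \[0,1\]).
#' @param v_mono,v_mac,v_foam unit cell volumes (m^3).
#' @param chi dimensionless recruitment calibration scalar.  The shipped
#'   default is the value returned by [calibrate_control_growth()] under the
#'   package's control-growth convention (see the methods vignette).
#'
#' @return An object of class `athero_params` (validated named list, natural
#'   units as documented above).
#' @seealso [pkpd_params()], [internal_params()], [load_scenario()]
#' @export
athero_params <- function(R_lumen_mm = 3.0,
                          k_m = 9.25e-24,
                          d_m = 5.75e-6,
                          d_lox = 2.4e-5,
                          d_M = 5.75e-6,
                          d_F = 5.75e-6,
                          r_w = 3e-4,
                          mu = 0.004,
                          rho1 = 1.15e-6,
                          delta_p = 2400,
                          Q_l_s = 0.0075,
                          m_lumen = 5.5e8,
                          sigma = 0.997,
                          segment_length_mm = 10,
                          wall_thickness_mm = 0.5,
                          Lp_ref = 3e-12,
                          P0 = 1e-11,
                          osmotic_term = 0,
                          tau0 = 1.5,
                          Lp_floor_fraction = 0.25,
                          rec_max = 1e-9,
                          K_Lox = 1.0,
                          tau_half = 1.5,
                          eta = 300,
                          phi = 0.1,
                          v_mono = 4e-16,
                          v_mac = 5e-15,
                          v_foam = 1.5e-14,
                          chi = .chi_default) {
  p <- list(
    R_lumen_mm = check_positive(R_lumen_mm, "R_lumen_mm"),
    k_m = check_positive(k_m, "k_m"),
    d_m = check_positive(d_m, "d_m"),
    d_lox = check_positive(d_lox, "d_lox"),
    d_M = check_positive(d_M, "d_M"),
    d_F = check_positive(d_F, "d_F"),
    r_w = check_positive(r_w, "r_w"),
    mu = check_positive(mu, "mu"),
    rho1 = check_positive(rho1, "rho1"),
    delta_p = check_positive(delta_p, "delta_p"),
    Q_l_s = check_positive(Q_l_s, "Q_l_s"),
    m_lumen = check_positive(m_lumen, "m_lumen"),
    sigma = check_fraction(sigma, "sigma"),
    segment_length_mm = check_positive(segment_length_mm, "segment_length_mm"),
    wall_thickness_mm = check_positive(wall_thickness_mm, "wall_thickness_mm"),
    Lp_ref = check_positive(Lp_ref, "Lp_ref"),
    P0 = check_positive(P0, "P0"),
    osmotic_term = check_nonnegative(osmotic_term, "osmotic_term"),
    tau0 = check_positive(tau0, "tau0"),
    Lp_floor_fraction = check_fraction(Lp_floor_fraction, "Lp_floor_fraction"),
    rec_max = check_positive(rec_max, "rec_max"),
    K_Lox = check_positive(K_Lox, "K_Lox"),
    tau_half = check_positive(tau_half, "tau_half"),
    eta = check_positive(eta, "eta"),
    phi = check_fraction(phi, "phi"),
    v_mono = check_positive(v_mono, "v_mono"),
    v_mac = check_positive(v_mac, "v_mac"),
    v_foam = check_positive(v_foam, "v_foam"),
    chi = check_nonnegative(chi, "chi")
  )
  class(p) <- "athero_params"
  p
}

#' Simvastatin PKPD parameters for a typical patient
#'
#' Parent/metabolite compartmental pharmacokinetics (apparent clearances and
#' volumes, first-order absorption) and the inhibitory indirect-response
#' pharmacodynamics on circulating LDL.  All PK/PD rates are per hour.
#' The LDL elimination constant is derived, not free:
#' `K_out = K_in / LDL_baseline`, so that the drug-free steady state is
#' exactly `LDL_baseline`.
#'
#' @param CL2 apparent clearance of the parent compartment (L/hr).
#' @param V2 apparent volume of the parent compartment (L).
#' @param CL3 apparent clearance of the metabolite compartment (L/hr).
#' @param V3 apparent volume of the metabolite compartment (L).
#' @param Ka first-order absorption rate constant (1/hr).
#' @param K_in zero-order LDL production rate (nmol/L/hr).
#' @param Emax maximal fractional inhibition of LDL production (in \[0,1\]).
#' @param EC50 metabolite concentration at half-maximal effect (ng/mL).
#' @param LDL_baseline drug-free steady-state circulating LDL (nmol/L).
#'
#' @return An object of class `pkpd_params` with the derived field `K_out`
#'   (1/hr).
#' @export
pkpd_params <- function(CL2 = 1740,
                        V2 = 8980,
                        CL3 = 383,
                        V3 = 1190,
                        Ka = 2.76,
                        K_in = 29.52,
                        Emax = 0.489,
                        EC50 = 0.0868,
                        LDL_baseline = 1400) {
  p <- list(
    CL2 = check_positive(CL2, "CL2"),
    V2 = check_positive(V2, "V2"),
    CL3 = check_positive(CL3, "CL3"),
    V3 = check_positive(V3, "V3"),
    Ka = check_positive(Ka, "Ka"),
    K_in = check_positive(K_in, "K_in"),
    Emax = check_fraction(Emax, "Emax"),
    EC50 = check_positive(EC50, "EC50"),
    LDL_baseline = check_positive(LDL_baseline, "LDL_baseline")
  )
  p$K_out <- p$K_in / p$LDL_baseline
  class(p) <- "pkpd_params"
  p
}

#' Typical-patient default parameters
#'
#' @return A list with elements `athero` ([athero_params()]) and `pkpd`
#'   ([pkpd_params()]), all at their defaults.
#' @export
default_params <- function() {
  list(athero = athero_params(), pkpd = pkpd_params())
}

#' Dosing regimen
#'
#' @param dose_mg amount per dose (mg).
#' @param interval_h dosing interval (hours).
#' @param start_h treatment initiation time (hours from simulation start).
#' @param duration_h treatment length (hours); doses are planned at
#'   `start_h + k * interval_h` strictly before `start_h + duration_h`.
#' @return An object of class `regimen`.
#' @export
regimen <- function(dose_mg = 40, interval_h = 24, start_h = 0,
                    duration_h = 8760) {
  r <- list(
    dose_mg = check_nonnegative(dose_mg, "dose_mg"),
    interval_h = check_positive(interval_h, "interval_h"),
    start_h = check_nonnegative(start_h, "start_h"),
    duration_h = check_nonnegative(duration_h, "duration_h")
  )
  class(r) <- "regimen"
  r
}

#' Two-state Markov adherence specification
#'
#' @param p_t probability of taking a dose given the previous dose was taken.
#' @param q_nt probability of missing a dose given the previous dose was
#'   missed.
#' @param seed integer seed for the adherence generator (or `NULL`).
#' @param initial_state `"taking"` or `"not_taking"`; the state the chain
#'   conditions on when drawing the first dose.
#' @return An object of class `adherence_spec`.
#' @export
adherence_spec <- function(p_t = 0.90, q_nt = 0.25, seed = NULL,
                           initial_state = c("taking", "not_taking")) {
  initial_state <- match.arg(initial_state)
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      validation_error("seed", "must be a single finite number or NULL")
    seed <- as.integer(seed)
  }
  s <- list(
    p_t = check_fraction(p_t, "p_t"),
    q_nt = check_fraction(q_nt, "q_nt"),
    seed = seed,
    initial_state = initial_state
  )
  class(s) <- "adherence_spec"
  s
}

#' Hybrid integrator settings
#'
#' @param rtol,atol relative/absolute solver tolerances.
#' @param dt_out_h output grid spacing (hours).
#' @param root_tol_h documented accuracy bound on reported event times
#'   (hours).  The solver's own root refinement is much finer; this value is
#'   recorded with the run metadata as the guaranteed bound.
#' @return An object of class `engine_settings`.
#' @export
engine_settings <- function(rtol = 1e-8, atol = 1e-10, dt_out_h = 24,
                            root_tol_h = 1e-6) {
  s <- list(
    rtol = check_positive(rtol, "rtol"),
    atol = check_positive(atol, "atol"),
    dt_out_h = check_positive(dt_out_h, "dt_out_h"),
    root_tol_h = check_positive(root_tol_h, "root_tol_h")
  )
  class(s) <- "engine_settings"
  s
}

#' Convert a parameter bundle to the canonical internal units
#'
#' Produces the single-unit-convention bundle used by the coupled dynamics:
#' time in hours (all per-second rate constants multiplied by 3600), lengths
#' in m, volumes in m^3, monocyte concentration in cells/m^3.  Also
#' precomputes the segment geometry: wall volume, endothelial surface area,
#' surface-to-volume ratio, capacity volume and lumen volume.
#'
#' @param athero an [athero_params()] object.
#' @param pkpd a [pkpd_params()] object.
#' @return A named list of class `athero_internal`.
#' @export
internal_params <- function(athero = athero_params(), pkpd = pkpd_params()) {
  stopifnot(inherits(athero, "athero_params"), inherits(pkpd, "pkpd_params"))
  a <- athero
  R0 <- a$R_lumen_mm * 1e-3
  L <- a$segment_length_mm * 1e-3
  h <- a$wall_thickness_mm * 1e-3
  V_wall <- pi * ((R0 + h)^2 - R0^2) * L
  S_endo <- 2 * pi * R0 * L
  ip <- list(
    # geometry (m, m^2, m^3)
    R0 = R0, L = L, h_wall = h,
    V_wall = V_wall, S_endo = S_endo, S_over_V = S_endo / V_wall,
    V_lumen = pi * R0^2 * L,
    V_capacity = a$phi * V_wall,
    # hemodynamics (SI; wall shear stress is algebraic, not a rate)
    mu = a$mu, Q = a$Q_l_s * 1e-3,
    # endothelium, per hour
    Lp_ref = a$Lp_ref * 3600, P0 = a$P0 * 3600,
    delta_p = a$delta_p, sigma = a$sigma, osmotic_term = a$osmotic_term,
    tau0 = a$tau0, Lp_floor_fraction = a$Lp_floor_fraction,
    # wall cascade, per hour
    r_w = a$r_w * 3600, d_lox = a$d_lox * 3600,
    d_m = a$d_m * 3600, d_M = a$d_M * 3600, d_F = a$d_F * 3600,
    rho1 = a$rho1 * 3600, k_m = a$k_m * 3600,
    rec_max = a$rec_max * 3600, K_Lox = a$K_Lox, tau_half = a$tau_half,
    chi = a$chi, eta = a$eta,
    m_lumen = a$m_lumen * 1000,
    v_mono = a$v_mono, v_mac = a$v_mac, v_foam = a$v_foam,
    # PKPD, already per hour
    Ka = pkpd$Ka, k_parent = pkpd$CL2 / pkpd$V2, k_met = pkpd$CL3 / pkpd$V3,
    V3 = pkpd$V3, K_in = pkpd$K_in, K_out = pkpd$K_out,
    Emax = pkpd$Emax, EC50 = pkpd$EC50, LDL_baseline = pkpd$LDL_baseline
  )
  class(ip) <- "athero_internal"
  ip
}

# nmol/L -> particles/m^3 (Avogadro * 1e-9 mol / 1e-3 m^3)
.NA_PER_NMOL_L <- 6.02214076e17

.scenario_sections <- c("athero", "pkpd", "regimen", "adherence", "engine")

#' Load and validate a scenario configuration
#'
#' Parses a YAML scenario document with the (all optional) sections
#' `athero`, `pkpd`, `regimen`, `adherence` and `engine`, fills every
#' missing key with the typical-patient default, validates the result, and
#' converts all rates to the canonical internal time unit (hours).  Keys use
#' the same names and natural units as the corresponding constructors
#' ([athero_params()], [pkpd_params()], [regimen()], [adherence_spec()],
#' [engine_settings()]); a machine-readable schema ships as
#' `system.file("extdata", "scenario_schema.yaml", package = "atheroQSP")`.
#'
#' Passing `adherence: ~` (or omitting the section) means full adherence.
#'
#' @param config a YAML string, or a path to a YAML file.
#' @return An object of class `scenario`: a list with elements `athero`,
#'   `pkpd`, `regimen`, `adherence` (or `NULL`), `engine` and the converted
#'   `internal` bundle.
#' @export
load_scenario <- function(config) {
  txt <- if (length(config) == 1L && file.exists(config))
    paste(readLines(config, warn = FALSE), collapse = "\n") else
    paste(config, collapse = "\n")
  doc <- yaml::yaml.load(txt)
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) validation_error("(document)", "not a key-value document")
  unknown <- setdiff(names(doc), .scenario_sections)
  if (length(unknown) > 0)
    validation_error(unknown[1], "unknown configuration section")
  build_section <- function(section, ctor) {
    args <- doc[[section]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad) > 0)
      validation_error(paste0(section, ".", bad[1]), "unknown key")
    do.call(ctor, args)
  }
  sc <- list(
    athero = build_section("athero", athero_params),
    pkpd = build_section("pkpd", pkpd_params),
    regimen = build_section("regimen", regimen),
    adherence = if (is.null(doc$adherence)) NULL else
      build_section("adherence", adherence_spec),
    engine = build_section("engine", engine_settings)
  )
  sc$internal <- internal_params(sc$athero, sc$pkpd)
  class(sc) <- "scenario"
  sc
}

#' Serialize a scenario back to YAML
#'
#' Writes all parameters in their natural units, so that
#' `load_scenario(serialize_scenario(x))` reproduces `x` exactly.
#'
#' @param sc a `scenario` object from [load_scenario()] or
#'   [scenario_preset()].
#' @return A YAML string.
#' @export
serialize_scenario <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  doc <- list(
    athero = unclass(sc$athero),
    pkpd = unclass(sc$pkpd)[setdiff(names(sc$pkpd), "K_out")],
    regimen = unclass(sc$regimen),
    adherence = if (is.null(sc$adherence)) NULL else unclass(sc$adherence),
    engine = unclass(sc$engine)
  )
  yaml::as.yaml(doc, precision = 15)
}

#' @export
print.scenario <- function(x, ...) {
  cat("<atheroQSP scenario>\n")
  cat(sprintf("  lumen radius %.3g mm, wall %.3g mm, segment %.3g mm\n",
              x$athero$R_lumen_mm, x$athero$wall_thickness_mm,
              x$athero$segment_length_mm))
  if (x$regimen$dose_mg > 0 && x$regimen$duration_h > 0) {
    cat(sprintf("  regimen: %g mg every %g h for %g h (start %g h)\n",
                x$regimen$dose_mg, x$regimen$interval_h,
                x$regimen$duration_h, x$regimen$start_h))
  } else {
    cat("  regimen: no dosing (control)\n")
  }
  if (is.null(x$adherence)) {
    cat("  adherence: full\n")
  } else {
    cat(sprintf("  adherence: Markov p_t=%.3g q_nt=%.3g (seed %s)\n",
                x$adherence$p_t, x$adherence$q_nt,
                if (is.null(x$adherence$seed)) "unset" else x$adherence$seed))
  }
  invisible(x)
}
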