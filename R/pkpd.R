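# Simvastatin parent/metabolite pharmacokinetics and the inhibitory
# indirect-response (turnover) pharmacodynamics on circulating LDL.

#' Pharmacokinetic derivatives
#'
#' First-order absorption from a depot, complete first-order conversion of
#' parent (simvastatin) to metabolite (simvastatin acid), first-order
#' metabolite elimination, with apparent rate constants `Ka`, `CL2/V2` and
#' `CL3/V3` (all per hour):
#' \deqn{dA_{gut}/dt = -Ka A_{gut}}
#' \deqn{dA_{parent}/dt = Ka A_{gut} - (CL2/V2) A_{parent}}
#' \deqn{dA_{met}/dt = (CL2/V2) A_{parent} - (CL3/V3) A_{met}}
#'
#' @param s named list or vector with `A_gut`, `A_parent`, `A_met` (mg),
#'   all >= 0.
#' @param p a [pkpd_params()] object (or a list with `Ka`, `CL2`, `V2`,
#'   `CL3`, `V3`).
#' @return Named vector of derivatives (mg/h).
#' @export
pk_derivatives <- function(s, p) {
  s <- as.list(s)
  if (any(c(s$A_gut, s$A_parent, s$A_met) < 0))
    stop("pk_derivatives: negative drug amount")
  k20 <- p$CL2 / p$V2
  k30 <- p$CL3 / p$V3
  c(
    A_gut = -p$Ka * s$A_gut,
    A_parent = p$Ka * s$A_gut - k20 * s$A_parent,
    A_met = k20 * s$A_parent - k30 * s$A_met
  )
}

#' Metabolite concentration from amount
#'
#' `C_met = 1000 * A_met / V3` converts mg in an apparent volume of V3
#' litres to ng/mL.
#'
#' @param A_met metabolite amount (mg).
#' @param V3 apparent metabolite volume (L).
#' @return Concentration (ng/mL).
#' @export
metabolite_concentration <- function(A_met, V3) {
  1000 * A_met / V3
}

#' Fractional inhibition of LDL production
#'
#' Saturable inhibitory effect driven by the metabolite concentration,
#' `E = Emax * C / (EC50 + C)`, bounded by `Emax`.
#'
#' @param C_met metabolite concentration (ng/mL), >= 0.
#' @param Emax maximal fractional inhibition in \[0,1\].
#' @param EC50 concentration at half-maximal effect (ng/mL).
#' @return Fractional inhibition in \[0, Emax\].
#' @export
drug_effect <- function(C_met, Emax, EC50) {
  if (any(C_met < 0)) stop("drug_effect: C_met must be nonnegative")
  Emax * C_met / (EC50 + C_met)
}

#' Circulating-LDL turnover derivative
#'
#' Inhibitory indirect-response model: the statin inhibits LDL production,
#' `dLDL/dt = K_in (1 - E) - K_out LDL`, with `K_out = K_in / LDL_baseline`
#' so the drug-free steady state is exactly the baseline.  Evaluated in the
#' algebraically equivalent form `K_in ((1 - E) - LDL / LDL_baseline)`,
#' which makes the derivative exactly zero at the drug-free baseline in
#' floating point as well.
#'
#' @param LDL circulating LDL (nmol/L), >= 0.
#' @param E fractional inhibition in \[0,1\].
#' @param p a [pkpd_params()] object (needs `K_in` and `LDL_baseline`).
#' @return dLDL/dt (nmol/L/h).
#' @export
ldl_derivative <- function(LDL, E, p) {
  if (any(LDL < 0)) stop("ldl_derivative: LDL must be nonnegative")
  if (any(E < 0 | E > 1)) stop("ldl_derivative: E must lie in [0, 1]")
  p$K_in * ((1 - E) - LDL / p$LDL_baseline)
}

#' Simulate the PKPD block alone
#'
#' Integrates depot/parent/metabolite amounts and circulating LDL under a
#' sequence of instantaneous oral doses.  Used for PK-only analyses and as
#' the superposition oracle for the coupled engine.
#'
#' @param pkpd a [pkpd_params()] object.
#' @param dose_times_h dose times (hours).
#' @param dose_mg amount per dose (mg), recycled.
#' @param horizon_h end time (hours).
#' @param dt_out_h output spacing (hours).
#' @param rtol,atol solver tolerances.
#' @return A data.frame with columns `time_h`, `A_gut`, `A_parent`, `A_met`,
#'   `c_met_ng_ml`, `ldl_plasma_nmol_l`, `cum_eliminated_mg`.
#' @export
simulate_pkpd <- function(pkpd, dose_times_h = numeric(), dose_mg = 40,
                          horizon_h = 24 * 28, dt_out_h = 0.5,
                          rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(pkpd, "pkpd_params"))
  k20 <- pkpd$CL2 / pkpd$V2
  k30 <- pkpd$CL3 / pkpd$V3
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)  # tolerance-scale solver excursions
    E <- drug_effect(metabolite_concentration(y[3], pkpd$V3),
                     pkpd$Emax, pkpd$EC50)
    list(c(
      -pkpd$Ka * y[1],
      pkpd$Ka * y[1] - k20 * y[2],
      k20 * y[2] - k30 * y[3],
      ldl_derivative(y[4], E, pkpd),
      k30 * y[3]
    ))
  }
  y0 <- c(A_gut = 0, A_parent = 0, A_met = 0, LDL = pkpd$LDL_baseline,
          elim = 0)
  times <- sort(unique(c(seq(0, horizon_h, by = dt_out_h), horizon_h)))
  dose_times_h <- dose_times_h[dose_times_h < horizon_h]
  if (length(dose_times_h) > 0) {
    dose_mg <- rep_len(dose_mg, length(dose_times_h))
    ev <- data.frame(var = "A_gut", time = dose_times_h, value = dose_mg,
                     method = "add")
    times <- sort(unique(c(times, dose_times_h)))
    out <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                        events = list(data = ev), rtol = rtol, atol = atol)
  } else {
    out <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
  }
  out <- as.data.frame(out)
  data.frame(
    time_h = out$time,
    A_gut = out$A_gut, A_parent = out$A_parent, A_met = out$A_met,
    c_met_ng_ml = metabolite_concentration(out$A_met, pkpd$V3),
    ldl_plasma_nmol_l = out$LDL,
    cum_eliminated_mg = out$elim
  )
}
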