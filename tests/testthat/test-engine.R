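# engine tests run at short horizons with a small interstitial capacity
# (helper fast_params) so the growth transition occurs within days

test_that("the inlined engine RHS agrees with the composed module functions", {
  p <- default_params()
  ip <- internal_params(p$athero, p$pkpd)
  set.seed(51)
  for (i in 1:20) {
    y <- c(runif(1, 0, 40), runif(1, 0, 20), runif(1, 0, 10),
           runif(1, 100, 1500), runif(1, 0, 2), runif(1, 0, 5),
           runif(1, 0, 1e13), runif(1, 0, 1e13), runif(1, 0, 1e12),
           runif(1, 0, 0.3 * ip$V_wall))
    phase <- sample(0:1, 1)
    fast <- atheroQSP:::.engine_rhs(0, y, list(ip = ip, phase = phase))[[1]]
    # composed route, step by step through the module surface
    V_occ <- occupied_volume(list(L_w = y[5], Lox = y[6], m = y[7], M = y[8],
                                  F = y[9]), ip, ip$V_wall, V_necrotic = y[10])
    intr <- if (phase > 0) max(0, growth_event_value(
      list(V_occupied = V_occ, V_capacity = ip$V_capacity))) else 0
    R <- lumen_radius_from_intrusion(ip$R0, ip$L, intr)
    tau <- wall_shear_stress(ip$mu, ip$Q, R)
    Lp <- hydraulic_conductivity(tau, ip$Lp_ref, ip$tau0, ip$Lp_floor_fraction)
    Jv <- transmural_velocity(Lp, ip$delta_p, ip$sigma, ip$osmotic_term)
    Js <- ldl_flux(ip$P0, y[4] - y[5], Jv, ip$sigma, (y[4] + y[5]) / 2)
    wd <- wall_derivatives(list(L_w = y[5], Lox = y[6], m = y[7], M = y[8],
                                F = y[9]), ip, Js, tau,
                           list(S_endo = ip$S_endo, V_wall = ip$V_wall))
    pkd <- pk_derivatives(list(A_gut = y[1], A_parent = y[2], A_met = y[3]),
                          list(Ka = ip$Ka, CL2 = ip$k_parent, V2 = 1,
                               CL3 = ip$k_met, V3 = 1))
    E <- drug_effect(metabolite_concentration(y[3], ip$V3), ip$Emax, ip$EC50)
    dLDL <- ldl_derivative(y[4], E, list(K_in = ip$K_in,
                                         LDL_baseline = ip$LDL_baseline))
    composed <- c(pkd, dLDL, wd, ip$v_foam * ip$d_F * y[9] * ip$V_wall)
    expect_equal(unname(fast), unname(composed), tolerance = 1e-12)
  }
})

test_that("without LDL entry into the wall there is no plaque growth", {
  p <- fast_params(Lp_ref = 1e-40, P0 = 1e-40)
  r <- simulate_patient(p, regimen = NULL, horizon_h = 24 * 120)
  expect_true(all(r$grid$pct_tav == 0))
  expect_true(is.na(r$metadata$transition_time_h))
  expect_true(all(r$states$F < 1e-6))
})

test_that("%TAV starts at zero, grows monotonically and narrows the lumen", {
  r <- simulate_patient(fast_params(), regimen = NULL, horizon_h = 24 * 90)
  expect_identical(r$grid$pct_tav[1], 0)
  expect_false(is.na(r$metadata$transition_time_h))
  expect_true(all(diff(r$grid$time_h) > 0))
  expect_true(all(is.finite(as.matrix(r$grid[, -1]))))
  post <- r$grid$time_h >= r$metadata$transition_time_h
  expect_true(all(diff(r$grid$pct_tav[post]) > 0))
  expect_true(all(diff(r$grid$lumen_radius_mm[post]) < 0))
  expect_true(all(diff(r$grid$wss_pa[post]) > 0))
})

test_that("treated %TAV never exceeds control %TAV pointwise", {
  p <- fast_params()
  ctrl <- simulate_patient(p, regimen = NULL, horizon_h = 24 * 90)
  trt <- simulate_patient(p, regimen = regimen(duration_h = 24 * 60),
                          horizon_h = 24 * 90)
  expect_true(all(trt$grid$pct_tav <= ctrl$grid$pct_tav + 1e-9))
  expect_lt(final_pct_tav(trt), final_pct_tav(ctrl))
})

test_that("engine PK equals the standalone PKPD block and dose superposition", {
  p <- default_params()
  doses <- c(0, 24, 48)
  r <- simulate_patient(p, regimen = regimen(duration_h = 72),
                        horizon_h = 240,
                        settings = engine_settings(dt_out_h = 4))
  oracle <- simulate_pkpd(p$pkpd, dose_times_h = doses, dose_mg = 40,
                          horizon_h = 240, dt_out_h = 4)
  expect_equal(r$grid$c_met_ng_ml, oracle$c_met_ng_ml, tolerance = 1e-6)
  # superposition of shifted single-dose runs (linear PK)
  single <- simulate_pkpd(p$pkpd, dose_times_h = 0, dose_mg = 40,
                          horizon_h = 240, dt_out_h = 4)
  shift <- function(x, k) c(rep(0, k), x[1:(length(x) - k)])
  sup <- single$c_met_ng_ml + shift(single$c_met_ng_ml, 6) +
    shift(single$c_met_ng_ml, 12)
  expect_equal(r$grid$c_met_ng_ml, sup, tolerance = 1e-6)
})

test_that("dose bookkeeping: delivered drug equals dose times taken events", {
  p <- fast_params()
  trace <- c(1L, 0L, 1L, 1L, 0L, 1L, 1L, 1L, 0L, 1L)
  r <- simulate_patient(p, regimen = regimen(duration_h = 240),
                        adherence = trace, horizon_h = 360)
  expect_identical(r$metadata$n_planned, 10L)
  expect_identical(r$metadata$n_taken, 7L)
  expect_equal(r$metadata$total_dose_mg, 40 * 7, tolerance = 1e-12)
  dose_rows <- r$events[r$events$event == "dose", ]
  expect_identical(as.integer(dose_rows$value), trace)
  expect_true(!is.unsorted(r$events$time_h))
})

test_that("halving the output step leaves the endpoint unchanged", {
  p <- fast_params()
  r24 <- simulate_patient(p, regimen = NULL, horizon_h = 24 * 60,
                          settings = engine_settings(dt_out_h = 24))
  r12 <- simulate_patient(p, regimen = NULL, horizon_h = 24 * 60,
                          settings = engine_settings(dt_out_h = 12))
  expect_equal(final_pct_tav(r12), final_pct_tav(r24), tolerance = 1e-3)
})

test_that("states remain nonnegative under random parameter draws", {
  set.seed(53)
  for (i in 1:6) {
    fac <- exp(rnorm(5, 0, 0.3))
    p <- fast_params(k_m = 9.25e-24 * fac[1], r_w = 3e-4 * fac[2],
                     rec_max = 1e-9 * fac[3], m_lumen = 5.5e8 * fac[4],
                     d_F = 5.75e-6 * fac[5])
    r <- simulate_patient(p, regimen = regimen(duration_h = 24 * 20),
                          horizon_h = 24 * 40)
    states <- as.matrix(r$states[, -1])
    expect_true(all(states >= 0))
    expect_true(all(is.finite(states)))
  }
})

test_that("higher realized adherence stochastically lowers growth", {
  p <- fast_params()
  reg <- regimen(duration_h = 24 * 45)
  res <- vapply(1:50, function(s) {
    r <- simulate_patient(p, regimen = reg,
                          adherence = adherence_spec(0.8, 0.4, seed = s),
                          horizon_h = 24 * 60)
    c(taken_fraction(r$metadata$trace), final_pct_tav(r))
  }, c(0, 0))
  rho <- stats::cor(res[1, ], res[2, ], method = "spearman")
  expect_lt(rho, 0)
})

test_that("an overwhelming inflammatory load ends in a logged occlusion", {
  p <- fast_params(chi = 5e7)
  r <- simulate_patient(p, regimen = NULL, horizon_h = 24 * 365)
  expect_false(is.na(r$metadata$occlusion_time_h))
  expect_true("occlusion" %in% r$events$event)
  expect_lt(max(r$grid$time_h), 24 * 365)
  expect_true(all(r$grid$lumen_radius_mm > 0))
})

test_that("scenario comparison reports zero for identical runs and interpolates", {
  p <- fast_params()
  a <- simulate_patient(p, regimen = NULL, horizon_h = 24 * 30)
  b <- simulate_patient(p, regimen = NULL, horizon_h = 24 * 30,
                        settings = engine_settings(dt_out_h = 12))
  cmp <- compare_scenarios(list(x = a, y = b))
  expect_equal(cmp$pct_tav_diff, 0, tolerance = 1e-6)
  expect_equal(cmp$ldl_diff_nmol_l, 0, tolerance = 1e-6)
})

test_that("calibration is monotone in chi and honours its exit contract", {
  p <- fast_params()
  f <- function(chi) {
    a <- unclass(p$athero); a$chi <- chi
    final_pct_tav(simulate_patient(list(athero = do.call(athero_params, a),
                                        pkpd = p$pkpd),
                                   regimen = NULL, horizon_h = 24 * 60))
  }
  g1 <- f(atheroQSP:::.chi_default)
  g2 <- f(2 * atheroQSP:::.chi_default)
  expect_gt(g2, g1)
  chi <- calibrate_control_growth(p, target_pct_tav = 3, horizon_h = 24 * 60,
                                  tol = 0.05, chi_range = c(10, 1e6))
  expect_lte(abs(attr(chi, "achieved_pct_tav") - 3), 0.05)
  expect_equal(f(as.numeric(chi)), attr(chi, "achieved_pct_tav"),
               tolerance = 1e-9)
})
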