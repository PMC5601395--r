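test_that("planned dose times enumerate the regimen", {
  expect_identical(build_dose_times(regimen(duration_h = 0)), numeric(0))
  expect_identical(build_dose_times(regimen(dose_mg = 0)), numeric(0))
  expect_identical(build_dose_times(regimen(interval_h = 24, duration_h = 48)),
                   c(0, 24))
  yr <- build_dose_times(regimen(interval_h = 24, duration_h = 8760))
  expect_length(yr, 365)
  expect_identical(yr[1], 0)
  expect_identical(yr[365], 24 * 364)
  shifted <- build_dose_times(regimen(interval_h = 12, start_h = 6,
                                      duration_h = 36))
  expect_identical(shifted, c(6, 18, 30))
})

test_that("the transition matrix is row stochastic with the stated entries", {
  P <- transition_matrix(0.90, 0.25)
  expect_equal(unname(P), matrix(c(0.90, 0.10, 0.75, 0.25), 2, byrow = TRUE),
               tolerance = 1e-15)
  expect_equal(unname(rowSums(P)), c(1, 1), tolerance = 1e-15)
  expect_identical(unname(transition_matrix(1, 1)), diag(2))
  set.seed(41)
  for (i in 1:10) {
    P <- transition_matrix(runif(1), runif(1))
    expect_equal(unname(rowSums(P)), c(1, 1), tolerance = 1e-15)
  }
  expect_error(transition_matrix(1.2, 0.5), "p_t")
})

test_that("degenerate chains behave as designed", {
  all_take <- simulate_adherence(adherence_spec(p_t = 1, q_nt = 0, seed = 1),
                                 50)
  expect_identical(as.integer(all_take), rep(1L, 50))
  # absorbing not-taking state: once missed, always missed
  tr <- simulate_adherence(adherence_spec(p_t = 0.5, q_nt = 1, seed = 3), 200)
  first_miss <- match(0L, as.integer(tr))
  expect_false(is.na(first_miss))
  expect_true(all(tr[first_miss:length(tr)] == 0L))
  # starting from the not-taking state with q_nt = 1 nothing is ever taken
  tr2 <- simulate_adherence(adherence_spec(p_t = 0.9, q_nt = 1, seed = 4,
                                           initial_state = "not_taking"), 100)
  expect_identical(as.integer(tr2), rep(0L, 100))
})

test_that("fixed seeds give bit-identical traces and leave the global RNG alone", {
  spec <- adherence_spec(p_t = 0.9, q_nt = 0.25, seed = 99)
  t1 <- simulate_adherence(spec, 365)
  set.seed(1234)
  expected_next <- stats::runif(1)
  set.seed(1234)
  t2 <- simulate_adherence(spec, 365)
  expect_identical(as.integer(t1), as.integer(t2))
  expect_identical(stats::runif(1), expected_next)
})

test_that("empirical transition frequencies recover p_t and q_nt", {
  n <- 1e5
  tr <- as.integer(simulate_adherence(
    adherence_spec(p_t = 0.9, q_nt = 0.25, seed = 7), n))
  prev <- tr[-n]; cur <- tr[-1]
  p_hat <- mean(cur[prev == 1L])
  q_hat <- 1 - mean(cur[prev == 0L])
  se_p <- sqrt(0.9 * 0.1 / sum(prev == 1L))
  se_q <- sqrt(0.25 * 0.75 / sum(prev == 0L))
  expect_lt(abs(p_hat - 0.90), 3 * se_p)
  expect_lt(abs(q_hat - 0.25), 3 * se_q)
})

test_that("stationary missed fraction matches the left eigenvector oracle", {
  # analytic value
  expect_equal(stationary_missed_fraction(0.90, 0.25), 2 / 17,
               tolerance = 1e-12)
  expect_equal(stationary_missed_fraction(0.90, 0.25), 0.11765,
               tolerance = 1e-4)
  expect_identical(stationary_missed_fraction(1, 0.25), 0)
  expect_equal(stationary_missed_fraction(0.4, 0.4), 0.5, tolerance = 1e-12)
  expect_error(stationary_missed_fraction(1, 1), "degenerate")
  # independent oracle: stationary distribution from the eigen decomposition
  set.seed(43)
  for (i in 1:10) {
    p_t <- runif(1, 0.05, 0.95); q_nt <- runif(1, 0.05, 0.95)
    P <- transition_matrix(p_t, q_nt)
    ev <- eigen(t(P))
    k <- which.min(abs(Re(ev$values) - 1))
    v <- Re(ev$vectors[, k]); v <- v / sum(v)
    expect_equal(stationary_missed_fraction(p_t, q_nt), v[2],
                 tolerance = 1e-10)
  }
})

test_that("ensemble taken fraction converges to the stationary value", {
  expect_identical(taken_fraction(rep(1L, 10)), 1)
  expect_identical(taken_fraction(rep(c(1L, 0L), 10)), 0.5)
  expect_error(taken_fraction(integer(0)), "empty")
  fracs <- vapply(1:200, function(s) {
    taken_fraction(simulate_adherence(
      adherence_spec(p_t = 0.9, q_nt = 0.25, seed = s), 365))
  }, 0)
  target <- 1 - stationary_missed_fraction(0.9, 0.25)  # 15/17
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - target), 4 * se)
})
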