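# Planned dose schedules and the two-state Markov chain of medication
# adherence that turns a plan into a realized taken/missed sequence.

#' Planned dose event times
#'
#' Doses are planned at `start_h + k * interval_h`, `k = 0, 1, ...`, with the
#' first dose at initiation and none at or after `start_h + duration_h`.
#'
#' @param r a [regimen()] object.
#' @return Numeric vector of event times (hours); empty when `duration_h`
#'   is 0 or `dose_mg` is 0.
#' @export
build_dose_times <- function(r) {
  stopifnot(inherits(r, "regimen"))
  if (r$duration_h <= 0 || r$dose_mg <= 0) return(numeric(0))
  n <- floor(r$duration_h / r$interval_h)
  r$start_h + (seq_len(n) - 1) * r$interval_h
}

#' Markov transition matrix of adherence
#'
#' Row-stochastic matrix over the states (taking, not taking):
#' rows `(p_t, 1 - p_t)` and `(1 - q_nt, q_nt)`.
#'
#' @param p_t probability of taking given the previous dose was taken.
#' @param q_nt probability of missing given the previous dose was missed.
#' @return A 2x2 matrix with dimnames `c("taking", "not_taking")`.
#' @export
transition_matrix <- function(p_t, q_nt) {
  check_fraction(p_t, "p_t")
  check_fraction(q_nt, "q_nt")
  m <- matrix(c(p_t, 1 - p_t, 1 - q_nt, q_nt), nrow = 2, byrow = TRUE,
              dimnames = list(c("taking", "not_taking"),
                              c("taking", "not_taking")))
  m
}

#' Simulate a realized adherence trace
#'
#' Draws a taken/missed sequence of length `n_doses` from the two-state
#' Markov chain; the first element is drawn from the transition out of
#' `initial_state`.  With a non-`NULL` seed the trace is reproducible and
#' the global RNG state is left untouched.
#'
#' @param spec an [adherence_spec()] object.
#' @param n_doses number of planned doses, >= 0.
#' @return An integer vector of 0/1 (1 = taken) of length `n_doses`, class
#'   `adherence_trace`.
#' @export
simulate_adherence <- function(spec, n_doses) {
  stopifnot(inherits(spec, "adherence_spec"))
  n_doses <- as.integer(n_doses)
  if (n_doses < 0) stop("simulate_adherence: n_doses must be >= 0")
  if (!is.null(spec$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed))
        rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec$seed)
  }
  taken <- integer(n_doses)
  prev <- spec$initial_state == "taking"
  u <- stats::runif(n_doses)
  for (i in seq_len(n_doses)) {
    prob_take <- if (prev) spec$p_t else 1 - spec$q_nt
    prev <- u[i] < prob_take
    taken[i] <- as.integer(prev)
  }
  structure(taken, class = "adherence_trace")
}

#' Stationary fraction of missed doses
#'
#' Long-run probability of the not-taking state of the adherence chain,
#' `(1 - p_t) / ((1 - p_t) + (1 - q_nt))`.
#'
#' @inheritParams transition_matrix
#' @return Stationary missed fraction.
#' @export
stationary_missed_fraction <- function(p_t, q_nt) {
  check_fraction(p_t, "p_t")
  check_fraction(q_nt, "q_nt")
  if (p_t == 1 && q_nt == 1)
    stop("stationary_missed_fraction: degenerate chain (p_t = q_nt = 1)")
  (1 - p_t) / ((1 - p_t) + (1 - q_nt))
}

#' Fraction of doses taken in a trace
#'
#' @param t an adherence trace (0/1 vector).
#' @return Taken count / length.
#' @export
taken_fraction <- function(t) {
  if (length(t) == 0) stop("taken_fraction: empty trace")
  mean(as.numeric(t))
}
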