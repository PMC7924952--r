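# Shared fixtures: parameter sets and small simulated cohorts built in code.

men_params <- function() dubbo_parameters("men")
women_params <- function() dubbo_parameters("women")

# A generator with positive rates on every allowed transition, randomized.
random_generator <- function(seed) {
  set.seed(seed)
  rates <- stats::runif(7, 0.01, 0.5)
  names(rates) <- allowed_transitions()$transition
  build_generator(model_parameters(alpha = log(rates)))
}

# Hand-built sojourn records (covariate columns filled with the reference
# profile so covariate-free likelihood code paths have what they need).
make_records <- function(subject_id, state, entry, exit, to) {
  n <- length(state)
  prof <- reference_profile()
  tibble::tibble(
    subject_id = subject_id, state = as.integer(state),
    entry = entry, exit = exit, to = as.integer(to),
    sex = prof$sex, age = prof$age_at_event - entry,
    age_at_event = prof$age_at_event,
    fnbmd_tscore = prof$fnbmd_tscore, bmi = prof$bmi,
    falls = prof$falls, prior_fracture = prof$prior_fracture,
    cardiovascular = 0L, cancer = 0L, neurological = 0L, rheumatoid = 0L,
    respiratory = 0L, diabetes = 0L
  )
}

small_cohort <- function(seed, n_women = 300, n_men = 200, ...) {
  simulate_cohort(cohort_config(n_women = n_women, n_men = n_men, ...),
                  seed = seed)
}

# Matrix-ODE oracle: integrate P'(t) = P(t) Q with lsoda, independent of the
# matrix-exponential path under test.
ode_transition_probability <- function(Q, t) {
  deriv <- function(time, y, parms) {
    P <- matrix(y, 5, 5)
    list(as.vector(P %*% parms))
  }
  out <- deSolve::lsoda(as.vector(diag(5)), c(0, t), deriv, Q,
                        rtol = 1e-10, atol = 1e-12)
  matrix(out[2, -1], 5, 5)
}
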