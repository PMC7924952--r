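test_that("state space has 7 progressive transitions and an absorbing death", {
  allowed <- allowed_transitions()
  expect_equal(nrow(allowed), 7)
  expect_true(all(allowed$to > allowed$from))
  expect_false(any(allowed$from == 5))
  expect_length(state_labels(), 5)
})

test_that("linear predictor codes deviations from the reference profile", {
  beta <- c(fnbmd_tscore = log(1.16), age_at_event = 0.2, sex = -0.5)
  expect_equal(linear_predictor(reference_profile(), beta), 0)

  # one SD lower T-score with the published BMD hazard ratio
  expect_equal(
    linear_predictor(reference_profile(fnbmd_tscore = -2.5),
                     c(fnbmd_tscore = log(1.16))),
    0.1484, tolerance = 1e-3
  )

  # contributions are additive and scale linearly in the coefficient
  prof <- reference_profile(sex = "male", falls = 1L, age_at_event = 80)
  b1 <- c(sex = 0.3, falls = 0.2, age_at_event = 0.1)
  by_hand <- 0.3 * 1 + 0.2 * 1 + 0.1 * (80 - 70) / 5
  expect_equal(linear_predictor(prof, b1), by_hand)
  expect_equal(linear_predictor(prof, c(sex = 0.6)),
               2 * linear_predictor(prof, c(sex = 0.3)))

  expect_error(linear_predictor(reference_profile(), c(nonsense = 1)),
               "coding")
})

test_that("generator matches published men's intensities at the reference", {
  Q <- build_generator(men_params(), reference_profile())
  expect_equal(Q[1, 2], 0.017)
  expect_equal(Q[1, 5], 0.032)
  expect_equal(Q[2, 3], 0.041)
  expect_equal(Q[2, 5], 0.050)
  expect_equal(Q[3, 4], 0.133)
  expect_equal(Q[3, 5], 0.165)
  expect_equal(Q[4, 5], 0.339)
  expect_equal(Q[1, 1], -0.049)
  expect_equal(unname(rowSums(Q)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(Q[5, ]), rep(0, 5))
  expect_equal(Q[1, 3], 0)  # disallowed jump stays exactly zero
})

test_that("covariate effects scale intensities multiplicatively", {
  params <- dubbo_parameters()  # women's baselines + sex/BMD/age effects
  q_ref <- build_generator(params, reference_profile())
  prof <- reference_profile(fnbmd_tscore = -3.5)  # two SD lower
  q_low <- build_generator(params, prof)
  expect_equal(q_low[1, 2], q_ref[1, 2] * 1.16^2, tolerance = 1e-10)
  expect_equal(q_low[2, 5], q_ref[2, 5] * 1.16^2, tolerance = 1e-10)

  # with no covariates the profile is irrelevant: Q = exp(alpha) pattern
  p0 <- women_params()
  expect_equal(
    build_generator(p0, reference_profile(sex = "male", bmi = 40)),
    build_generator(p0, reference_profile())
  )

  bad <- model_parameters(
    alpha = setNames(rep(1000, 7), allowed_transitions()$transition)
  )
  expect_error(build_generator(bad, reference_profile()), "Non-finite")
})

test_that("five-year probabilities reproduce the published men's table", {
  Q <- build_generator(men_params())
  P <- transition_probability(Q, 5)
  expect_equal(P[1, 1], 0.783, tolerance = 5e-4)
  expect_equal(P[1, 2], 0.060, tolerance = 5e-4)
  expect_equal(P[2, 3], 0.081, tolerance = 5e-4)
})

test_that("transition_probability handles t = 0 and rejects t < 0", {
  Q <- random_generator(1)
  expect_equal(unname(transition_probability(Q, 0)), diag(5))
  expect_error(transition_probability(Q, -1), "non-negative")
})

test_that("matrix exponential agrees with independent ODE integration", {
  skip_if_not_installed("deSolve")
  for (seed in c(2, 7, 19)) {
    Q <- random_generator(seed)
    expect_equal(unname(transition_probability(Q, 3)),
                 ode_transition_probability(Q, 3), tolerance = 1e-8)
  }
})

test_that("P(t) is row-stochastic, progressive, and Chapman-Kolmogorov", {
  set.seed(99)
  for (seed in 1:10) {
    Q <- random_generator(seed)
    s <- runif(1, 0, 10)
    t <- runif(1, 0, 10)
    Ps <- transition_probability(Q, s)
    Pt <- transition_probability(Q, t)
    Pst <- transition_probability(Q, s + t)
    expect_equal(unname(rowSums(Pst)), rep(1, 5), tolerance = 1e-8)
    expect_true(all(Pst >= 0 & Pst <= 1 + 1e-12))
    expect_equal(Pst, Ps %*% Pt, tolerance = 1e-8)
    # progressive: no probability of moving to a lower-numbered state
    expect_true(all(Pst[lower.tri(Pst)] == 0))
  }
})

test_that("absorption into death is monotone and complete", {
  Q <- build_generator(men_params())
  grid <- seq(0, 50, by = 2)
  for (r in 1:4) {
    mort <- vapply(grid, function(t) transition_probability(Q, t)[r, 5], 1)
    expect_true(all(diff(mort) >= -1e-12))
  }
  expect_equal(unname(transition_probability(Q, 500)[, 5]), rep(1, 5),
               tolerance = 1e-6)
})

test_that("piecewise products respect the semigroup property", {
  Q1 <- random_generator(3)
  Q2 <- random_generator(4)
  expect_equal(piecewise_transition_probability(list(Q1), 4),
               transition_probability(Q1, 4))
  expect_equal(
    piecewise_transition_probability(list(Q1, Q1), c(2.5, 2.5)),
    transition_probability(Q1, 5), tolerance = 1e-10
  )
  # empty segment list is the identity
  expect_equal(unname(piecewise_transition_probability(list(), numeric())),
               diag(5))
  expect_error(piecewise_transition_probability(list(Q1), -1),
               "non-negative")

  skip_if_not_installed("deSolve")
  # alternating generators vs brute-force ODE with a switching intensity
  deriv <- function(time, y, parms) {
    Q <- if (time %% 2 < 1) parms$Q1 else parms$Q2
    list(as.vector(matrix(y, 5, 5) %*% Q))
  }
  out <- deSolve::lsoda(as.vector(diag(5)), seq(0, 4, by = 1), deriv,
                        list(Q1 = Q1, Q2 = Q2), rtol = 1e-10, atol = 1e-12)
  P_ode <- matrix(out[nrow(out), -1], 5, 5)
  P_pw <- piecewise_transition_probability(
    list(Q1, Q2, Q1, Q2), rep(1, 4)
  )
  expect_equal(unname(P_pw), P_ode, tolerance = 1e-7)
})

test_that("sojourn times reproduce the published values", {
  men <- sojourn_times(build_generator(men_params()))
  expect_equal(round(men$sojourn_years[1], 1), 20.4)  # 1/(0.017+0.032)
  expect_equal(round(men$sojourn_years[2], 1), 11.0)
  women <- sojourn_times(build_generator(women_params()))
  expect_equal(round(women$sojourn_years[2], 1), 14.5)
  expect_equal(round(women$sojourn_years[3], 1), 11.8)
  expect_true(men$absorbing[5])
  expect_true(is.na(men$sojourn_years[5]))
})

test_that("degenerate sojourns: single exit is 1/lambda, no exit is Inf", {
  lam <- 0.37
  rates <- setNames(c(0, 0, 0, 0, 0, 0, lam),
                    allowed_transitions()$transition)
  Q <- build_generator(model_parameters(alpha = log(rates)))
  sj <- sojourn_times(Q)
  expect_equal(sj$sojourn_years[4], 1 / lam)
  expect_equal(sj$sojourn_years[1], Inf)  # transient, all exits zero
})

test_that("sojourn equals mean simulated exponential holding time", {
  Q <- build_generator(men_params())
  lambda <- -Q[1, 1]
  set.seed(11)
  holds <- rexp(10000, lambda)
  mc_se <- sd(holds) / sqrt(length(holds))
  expect_lt(abs(mean(holds) - sojourn_times(Q)$sojourn_years[1]), 3 * mc_se)
})

test_that("validate_generator rejects malformed matrices", {
  Q <- build_generator(men_params())
  bad <- Q; bad[2, 1] <- 0.1
  expect_error(validate_generator(bad), "isallowed|sum")
  bad2 <- Q; bad2[5, 5] <- -0.1; bad2[5, 4] <- 0.1
  expect_error(validate_generator(bad2))
})
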