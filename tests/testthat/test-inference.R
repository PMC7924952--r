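test_that("event sequences become sojourn records", {
  # censored fracture-free at 10y: a single censored record in state 1
  ev <- tibble::tibble(subject_id = "a", time_years = c(0, 10),
                       state = c(1L, 1L), age = 70, sex = "female")
  rec <- records_from_events(ev)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$state, 1L)
  expect_equal(rec$exit, 10)
  expect_true(is.na(rec$to))

  # fracture at 4y then death at 7y: two records, no trailing censoring
  ev2 <- tibble::tibble(subject_id = "b", time_years = c(0, 4, 7),
                        state = c(1L, 2L, 5L), age = 68, sex = "male")
  rec2 <- records_from_events(ev2)
  expect_equal(nrow(rec2), 2)
  expect_equal(rec2$state, c(1L, 2L))
  expect_equal(rec2$entry, c(0, 4))
  expect_equal(rec2$exit, c(4, 7))
  expect_equal(rec2$to, c(2L, 5L))
  # age refreshed at state entry
  expect_equal(rec2$age_at_event, c(68, 72))

  # backward or skipping jumps are validation errors naming the subject
  bad <- tibble::tibble(subject_id = "oops", time_years = c(0, 3),
                        state = c(2L, 1L), age = 70, sex = "female")
  expect_error(records_from_events(bad), "oops")
  skip2 <- tibble::tibble(subject_id = "skippy", time_years = c(0, 3),
                          state = c(1L, 3L), age = 70, sex = "female")
  expect_error(records_from_events(skip2), "skippy")
})

test_that("records round-trip through the long event format", {
  coh <- small_cohort(5)
  ev <- events_from_records(coh$records)
  back <- records_from_events(ev)
  expect_equal(event_history_summary(back),
               event_history_summary(coh$records))
})

test_that("exact-time log-likelihood matches closed forms and brute force", {
  params <- women_params()
  q12 <- 0.027; q15 <- 0.018; lam <- q12 + q15

  rec_cens <- make_records("a", 1, 0, 10, NA)
  expect_equal(exact_time_loglik(params, rec_cens), -lam * 10)

  rec_ev <- make_records("a", 1, 0, 10, 2)
  expect_equal(exact_time_loglik(params, rec_ev), -lam * 10 + log(q12))

  # brute-force per-record summation on a simulated cohort
  coh <- small_cohort(8, 60, 40)
  recs <- coh$records
  p <- dubbo_parameters()
  ll <- exact_time_loglik(p, recs)
  brute <- 0
  for (i in seq_len(nrow(recs))) {
    Q <- build_generator(p, recs[i, ])
    r <- recs$state[i]
    brute <- brute + Q[r, r] * (recs$exit[i] - recs$entry[i])
    if (!is.na(recs$to[i])) brute <- brute + log(Q[r, recs$to[i]])
  }
  expect_equal(ll, brute, tolerance = 1e-10)

  # additivity over disjoint subject sets
  ids <- unique(recs$subject_id)
  a <- recs[recs$subject_id %in% ids[1:30], ]
  b <- recs[!recs$subject_id %in% ids[1:30], ]
  expect_equal(exact_time_loglik(p, a) + exact_time_loglik(p, b), ll)

  # realized transition with zero intensity is -Inf with a diagnostic
  p0 <- model_parameters(alpha = setNames(
    c(-Inf, log(0.018), log(0.048), log(0.021), log(0.063), log(0.022),
      log(0.129)), allowed_transitions()$transition))
  expect_warning(ll0 <- exact_time_loglik(p0, rec_ev), "zero intensity")
  expect_equal(ll0, -Inf)
})

test_that("panel likelihood: closed form, path sums, and exact-time limit", {
  # effectively two-state: only 1->2 can happen
  lam <- 0.2
  p2 <- model_parameters(alpha = setNames(
    c(log(lam), rep(-Inf, 6)), allowed_transitions()$transition))
  pan <- tibble::tibble(subject_id = "a", time_years = c(0, 2),
                        state = c(1L, 1L), age = 70, sex = "female")
  expect_equal(panel_loglik(p2, pan), -lam * 2)

  # a 1 -> 3 net movement must pass through state 2: expm oracle
  params <- women_params()
  pan13 <- tibble::tibble(subject_id = "a", time_years = c(0, 2),
                          state = c(1L, 3L), age = 70, sex = "female")
  P2 <- transition_probability(build_generator(params), 2)
  expect_gt(P2[1, 3], 0)
  expect_equal(panel_loglik(params, pan13), log(P2[1, 3]))

  # observed on a very fine grid, the panel likelihood converges to the
  # exact-time likelihood up to the interval measure factor: an
  # interval-observed transition contributes P_rs(dt) ~ q_rs * dt, an exact
  # time contributes the density q_rs, so the logs differ by log(dt) per
  # interval-observed (non-death) event. Time-invariant covariates only:
  # panel snapshots refresh age continuously, exact records fix it at state
  # entry, so an age effect would compare two different models.
  coh <- small_cohort(13, 40, 30,
                      params = dubbo_parameters(effects = c("sex",
                                                            "fnbmd_tscore")))
  dt <- 0.05
  pan_fine <- apply_observation(coh, "panel", interval = dt)
  ll_exact <- exact_time_loglik(coh$config$params, coh$records)
  ll_panel <- panel_loglik(coh$config$params, pan_fine)
  n_fx <- sum(tapply(pan_fine$state, pan_fine$subject_id,
                     function(s) sum(diff(s[s != 5]) != 0)))
  expect_lt(abs((ll_panel - n_fx * log(dt)) - ll_exact) / abs(ll_exact),
            0.005)
})

test_that("closed-form MLE is events over person-years", {
  rec <- make_records(c("a", "b"), c(1, 1), c(0, 0), c(6, 4), c(2, 2))
  cf <- closed_form_mle(rec)
  expect_equal(cf$table$rate[cf$table$transition == "1->2"], 0.2)

  # the published men's first-fracture rate: 184 events over 11,968 PY
  rec2 <- make_records(sprintf("s%03d", 1:200), rep(1, 200),
                       rep(0, 200), rep(11968 / 200, 200),
                       c(rep(2, 184), rep(NA, 16)))
  cf2 <- closed_form_mle(rec2)
  q12 <- cf2$table$rate[cf2$table$transition == "1->2"]
  expect_equal(q12, 184 / 11968)
  expect_equal(round(1000 * q12), 15)

  # zero events: boundary flag, rate 0, no crash
  expect_true(all(cf2$table$boundary[cf2$table$transition != "1->2"]))
  expect_equal(cf2$table$rate[cf2$table$transition == "4->5"], 0)
})

test_that("fit_mle with no covariates equals the closed form", {
  coh <- small_cohort(21, 400, 250)
  cf <- closed_form_mle(coh$records)
  fit <- fit_mle(coh$records)
  est <- fit$params$alpha
  truth <- cf$params$alpha
  ok <- is.finite(truth)
  expect_equal(signif(exp(est[ok]), 4), signif(exp(truth[ok]), 4))
})

test_that("fit_mle matches an independent Poisson-regression oracle", {
  coh <- small_cohort(31, 500, 300)
  covs <- c("sex", "fnbmd_tscore")
  fit <- fit_mle(coh$records, covariates = covs)
  recs <- coh$records
  coding <- covariate_coding()
  for (key in c("1->2", "1->5", "2->5")) {
    from <- as.integer(substr(key, 1, 1))
    to <- as.integer(substr(key, 4, 4))
    d <- recs[recs$state == from, ]
    y <- as.integer(!is.na(d$to) & d$to == to)
    z_sex <- as.numeric(tolower(d$sex) == "male")
    z_bmd <- (d$fnbmd_tscore - (-1.5)) / -1
    g <- glm(y ~ z_sex + z_bmd + offset(log(d$exit - d$entry)),
             family = poisson())
    ours <- fit$coef[fit$coef$transition == key, ]
    expect_equal(unname(ours$estimate), unname(coef(g)), tolerance = 1e-5)
    expect_equal(unname(ours$std.error),
                 unname(sqrt(diag(vcov(g)))), tolerance = 1e-4)
  }
})

test_that("the score vanishes at the optimum", {
  coh <- small_cohort(41, 600, 400)
  fit <- fit_mle(coh$records, covariates = "sex")
  est <- fit$coef$estimate
  keys <- allowed_transitions()$transition
  pack <- function(theta) {
    m <- matrix(theta, nrow = 2)
    model_parameters(alpha = setNames(m[1, ], keys),
                     beta = setNames(lapply(seq_len(7), function(j) {
                       c(sex = m[2, j])
                     }), keys))
  }
  ll <- function(theta) exact_time_loglik(pack(theta), coh$records)
  eps <- 1e-6
  grad <- vapply(seq_along(est), function(k) {
    up <- est; up[k] <- up[k] + eps
    dn <- est; dn[k] <- dn[k] - eps
    (ll(up) - ll(dn)) / (2 * eps)
  }, 1)
  n_ev <- sum(!is.na(coh$records$to))
  expect_lt(max(abs(grad)) / n_ev, 1e-4)
})

test_that("parameters are recovered within 3 SE on a large cohort", {
  cfg <- cohort_config(n_women = 2500, n_men = 1500)
  coh <- simulate_cohort(cfg, seed = 51)
  fit <- fit_mle(coh$records,
                 covariates = c("sex", "fnbmd_tscore", "age_at_event"))
  truth <- c(rbind(
    cfg$params$alpha,
    vapply(cfg$params$beta, `[[`, 1, "sex"),
    vapply(cfg$params$beta, `[[`, 1, "fnbmd_tscore"),
    vapply(cfg$params$beta, `[[`, 1, "age_at_event")
  ))
  dev <- abs(fit$coef$estimate - truth) / fit$coef$std.error
  expect_true(all(dev < 3))
})

test_that("zero observed deaths leave death baselines on the boundary", {
  params <- model_parameters(alpha = setNames(
    log(c(0.05, 1e-12, 0.05, 1e-12, 0.05, 1e-12, 1e-12)),
    allowed_transitions()$transition))
  cfg <- cohort_config(n_women = 150, n_men = 100, params = params)
  coh <- simulate_cohort(cfg, seed = 61)
  expect_true(all(is.na(coh$records$to) | coh$records$to != 5))
  fit <- fit_mle(coh$records)
  death_keys <- c("1->5", "2->5", "3->5", "4->5")
  flagged <- fit$transitions$boundary[fit$transitions$transition %in%
                                        death_keys]
  expect_true(all(flagged))
  expect_true(all(fit$params$alpha[death_keys] == -Inf))
})

test_that("hazard-ratio table matches direct Wald recomputation", {
  stub <- tibble::tibble(
    transition = c("2->5", "1->2"), term = c("sex", "fnbmd_tscore"),
    estimate = c(log(2.40), 0), std.error = c(0.1487, 0.2)
  )
  tab <- hazard_ratio_table(stub)
  # published men-vs-women HR on post-first-fracture mortality
  row <- tab[tab$transition == "2->5", ]
  expect_equal(row$hr, 2.40, tolerance = 1e-6)
  expect_equal(row$conf.low, 1.79, tolerance = 0.01)
  expect_equal(row$conf.high, 3.21, tolerance = 0.01)
  expect_true(row$significant)
  # direct recomputation of the Wald endpoints
  expect_equal(row$conf.low, exp(log(2.40) - qnorm(0.975) * 0.1487))
  expect_equal(row$conf.high, exp(log(2.40) + qnorm(0.975) * 0.1487))
  # a null coefficient gives HR 1 with CI containing 1
  null_row <- tab[tab$transition == "1->2", ]
  expect_equal(null_row$hr, 1)
  expect_true(null_row$conf.low < 1 && null_row$conf.high > 1)
  expect_false(null_row$significant)
})

test_that("dropping a covariate with true effect zero barely moves baselines", {
  params <- dubbo_parameters(effects = "sex")  # bmi truly null
  cfg <- cohort_config(n_women = 1200, n_men = 800, params = params)
  coh <- simulate_cohort(cfg, seed = 71)
  fit_full <- fit_mle(coh$records, covariates = c("sex", "bmi"))
  fit_red <- fit_mle(coh$records, covariates = "sex")
  base_full <- fit_full$coef[fit_full$coef$term == "(baseline)", ]
  base_red <- fit_red$coef[fit_red$coef$term == "(baseline)", ]
  dev <- abs(base_full$estimate - base_red$estimate) / base_red$std.error
  expect_true(all(dev[is.finite(dev)] < 3))
})

test_that("panel fitting recovers rates from snapshot data", {
  params <- dubbo_parameters(effects = character())  # covariate-free women
  cfg <- cohort_config(n_women = 250, n_men = 0, params = params)
  coh <- simulate_cohort(cfg, seed = 81)
  pan <- apply_observation(coh, "panel", interval = 2)
  fit <- fit_mle(pan, likelihood = "panel")
  expect_true(fit$converged)
  # the frequent transitions should be near truth (sparse ones are noisy)
  expect_equal(unname(exp(fit$params$alpha["1->2"])), 0.027,
               tolerance = 0.35)
  expect_equal(unname(exp(fit$params$alpha["1->5"])), 0.018,
               tolerance = 0.35)
  expect_equal(fit$loglik, panel_loglik(fit$params, pan))
})
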