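# Resolve fit-like objects to msm_params (and keep vcov when present).
as_msm_params <- function(object) {
  if (inherits(object, "msm_params")) return(object)
  if (inherits(object, c("msm_fit", "msm_closed_fit"))) return(object$params)
  abort("Expected an `msm_params`, `msm_fit` or `msm_closed_fit` object.")
}

#' Instantaneous-risk table for a covariate profile
#'
#' Per-year transition intensities for one individual, displayed as the
#' familiar percent-per-year scale (`q_rs x 100`). For a fitted model the
#' uncertainty comes from the delta method on the log-intensity:
#' `Var(log q) = c' V c` with `c = (1, z)` over that transition's
#' coefficient block, giving `q * exp(+/- z_0.975 SE)` limits.
#'
#' @param object An `msm_fit`, `msm_closed_fit` or `msm_params` object.
#' @param profile A one-row profile tibble ([reference_profile()]).
#' @param conf.level Confidence level for the delta-method interval.
#' @return A tibble: `transition`, `from`, `to`, `risk_pct` (%/year),
#'   `conf.low`, `conf.high` (`NA` when no covariance is available).
#' @export
#' @examples
#' instantaneous_risk_table(dubbo_parameters("women"), reference_profile())
instantaneous_risk_table <- function(object, profile = reference_profile(),
                                     conf.level = 0.95) {
  params <- as_msm_params(object)
  rates <- transition_rates(params, profile)[1L, ]
  allowed <- allowed_transitions()
  out <- allowed |>
    dplyr::mutate(risk_pct = 100 * unname(rates[.data$transition]),
                  conf.low = NA_real_, conf.high = NA_real_)
  zq <- qnorm(1 - (1 - conf.level) / 2)
  if (inherits(object, "msm_fit")) {
    covs <- object$covariates
    z <- if (length(covs)) {
      drop(code_covariates(profile, covs, object$coding))
    } else {
      numeric()
    }
    cvec <- c(1, z)
    for (j in seq_len(nrow(out))) {
      idx <- paste0(out$transition[j], ":", c("(baseline)", covs))
      V <- object$vcov[idx, idx, drop = FALSE]
      if (!anyNA(V)) {
        se <- sqrt(drop(t(cvec) %*% V %*% cvec))
        out$conf.low[j] <- out$risk_pct[j] * exp(-zq * se)
        out$conf.high[j] <- out$risk_pct[j] * exp(zq * se)
      }
    }
  } else if (inherits(object, "msm_closed_fit")) {
    se <- object$table$se_alpha
    out$conf.low <- out$risk_pct * exp(-zq * se)
    out$conf.high <- out$risk_pct * exp(zq * se)
  }
  out
}

#' K-year transition-probability table for a profile
#'
#' Builds the profile-specific generator and returns `100 * expm(h Q)`:
#' the percent probability of being in each state after `horizon` years,
#' by starting state, in the layout of a published transition table.
#'
#' @param object A fit, parameter set, or a bare 5x5 generator matrix.
#' @param profile One-row profile tibble (ignored when `object` is a matrix).
#' @param horizon Horizon in years (default 5; must be `>= 0`).
#' @return A tibble with a `from` label column and one percent column per
#'   destination state. The unrounded matrix is in `attr(, "matrix")`.
#' @export
#' @examples
#' five_year_matrix(dubbo_parameters("men"))
five_year_matrix <- function(object, profile = reference_profile(),
                             horizon = 5) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 0) {
    abort("`horizon` must be a single non-negative number of years.")
  }
  Q <- if (is.matrix(object)) object else {
    build_generator(as_msm_params(object), profile)
  }
  P <- 100 * transition_probability(Q, horizon)
  out <- tibble::as_tibble(P, rownames = "from")
  attr(out, "matrix") <- P
  out
}

#' Cumulative mortality curve from a starting state
#'
#' The probability of having died by each time on a grid, for an individual
#' occupying `start_state` at time zero: `P_{start,5}(t)`. Nondecreasing in
#' `t` and bounded by \[0, 1\].
#'
#' @param object A fit, parameter set, or generator matrix.
#' @param profile One-row profile tibble.
#' @param start_state Starting state, 1-4.
#' @param times Sorted non-negative time grid (years).
#' @return A tibble (`time`, `mortality`), class `msm_mortality_curve`,
#'   carrying the starting state and profile as attributes.
#' @export
#' @examples
#' cumulative_mortality_curve(dubbo_parameters("men"), times = 0:10)
cumulative_mortality_curve <- function(object,
                                       profile = reference_profile(),
                                       start_state = 1L,
                                       times = seq(0, 10, by = 0.25)) {
  if (!start_state %in% 1:4) abort("`start_state` must be in 1..4.")
  if (is.unsorted(times) || any(times < 0)) {
    abort("`times` must be a sorted grid of non-negative years.")
  }
  Q <- if (is.matrix(object)) object else {
    build_generator(as_msm_params(object), profile)
  }
  mort <- vapply(times, function(t) {
    transition_probability(Q, t)[start_state, absorbing_state()]
  }, 1)
  structure(
    tibble::tibble(time = times, mortality = mort),
    class = c("msm_mortality_curve", class(tibble::tibble())),
    start_state = start_state
  )
}

#' Sojourn-time table across bone-density profiles
#'
#' Expected sojourn time in each pre-death state for a sequence of femoral
#' neck BMD T-scores, holding the rest of the profile fixed — the layout of
#' a published sojourn table (columns T-score 0, -1.5, -2.5 by default).
#'
#' @param object A fit or parameter set.
#' @param profile Base profile; its `fnbmd_tscore` is swept over `tscores`.
#' @param tscores Numeric vector of T-scores (one output column each).
#' @return A tibble: `state`, `label`, then one `tscore_<x>` column per
#'   T-score, in years.
#' @export
#' @examples
#' sojourn_table(dubbo_parameters(), reference_profile(sex = "male"))
sojourn_table <- function(object, profile = reference_profile(),
                          tscores = c(0, -1.5, -2.5)) {
  params <- as_msm_params(object)
  cols <- lapply(tscores, function(ts) {
    p <- profile
    p$fnbmd_tscore <- ts
    sojourn_times(build_generator(params, p)) |>
      dplyr::filter(!.data$absorbing) |>
      dplyr::pull(.data$sojourn_years)
  })
  out <- tibble::tibble(state = 1:4, label = state_labels()[1:4])
  for (i in seq_along(tscores)) {
    out[[paste0("tscore_", tscores[i])]] <- cols[[i]]
  }
  out
}

#' Skeletal age: an effective-age translation of a mortality hazard ratio
#'
#' A risk factor with mortality hazard ratio `H` shifts an individual's
#' effective age by `log(H)/log(h)` years, where `h` is the annual
#' proportional growth of mortality risk (about 1.1 in people aged 60+,
#' i.e. mortality rises ~10% per year of age). Skeletal age is the
#' chronological age plus those years: a 70-year-old man with a
#' post-fracture mortality HR of 1.67 has lost ~5.4 years, skeletal age
#' ~75.4. `H < 1` gives negative years lost, i.e. years gained.
#'
#' @param age Chronological age in years (vectorized).
#' @param hazard_ratio Mortality hazard ratio `H > 0` (vectorized).
#' @param h Annual mortality growth factor, `> 1` (default 1.1).
#' @return A tibble: `age`, `hazard_ratio`, `h`, `years_lost`,
#'   `skeletal_age`.
#' @export
#' @examples
#' skeletal_age(70, 1.67)
skeletal_age <- function(age, hazard_ratio, h = 1.1) {
  if (any(!is.finite(hazard_ratio)) || any(hazard_ratio <= 0)) {
    abort("`hazard_ratio` must be positive.")
  }
  if (!is.numeric(h) || length(h) != 1L || h <= 1) {
    abort("`h` must be a single number greater than 1.")
  }
  years_lost <- log(hazard_ratio) / log(h)
  tibble::tibble(
    age = age, hazard_ratio = hazard_ratio, h = h,
    years_lost = years_lost, skeletal_age = age + years_lost
  )
}

#' Incidence rate per 1000 person-years with exact Poisson CI
#'
#' `1000 * events / person_years`, with the exact (Garwood) Poisson
#' confidence interval for the event count scaled to the same units.
#'
#' @param events Non-negative event count (vectorized).
#' @param person_years Positive person-years at risk (vectorized).
#' @param conf.level Confidence level (default 0.95).
#' @return A tibble: `events`, `person_years`, `rate_per_1000`,
#'   `conf.low`, `conf.high`.
#' @export
#' @examples
#' incidence_rate(184, 11968)
incidence_rate <- function(events, person_years, conf.level = 0.95) {
  if (any(person_years <= 0)) abort("`person_years` must be positive.")
  if (any(events < 0)) abort("`events` must be non-negative.")
  ci <- mapply(function(x, t) {
    poisson.test(x, T = t, conf.level = conf.level)$conf.int
  }, events, person_years)
  tibble::tibble(
    events = events, person_years = person_years,
    rate_per_1000 = 1000 * events / person_years,
    conf.low = 1000 * ci[1, ], conf.high = 1000 * ci[2, ]
  )
}

#' Crude percentage
#'
#' `100 * count / denominator`, the crude proportion used for descriptive
#' statements ("31% of women fractured").
#'
#' @param count Numerator, `0 <= count <= denominator`.
#' @param denominator Positive denominator.
#' @param digits Optional rounding for display; `NULL` (default) = exact.
#' @return Numeric percentage(s).
#' @export
#' @examples
#' crude_proportion(632, 2046)
crude_proportion <- function(count, denominator, digits = NULL) {
  if (any(denominator <= 0)) abort("`denominator` must be positive.")
  if (any(count < 0 | count > denominator)) {
    abort("`count` must lie in [0, denominator].")
  }
  p <- 100 * count / denominator
  if (!is.null(digits)) p <- round(p, digits)
  p
}
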