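#' Convert sojourn records back to the long event format
#'
#' Inverse of [records_from_events()]: per subject, a baseline row at study
#' entry, one row per observed transition at its exact time, and a trailing
#' censoring row (same state) unless the trajectory ends in death.
#'
#' @param records A record tibble.
#' @return A long tibble (`subject_id`, `time_years`, `state`, covariates).
#' @export
events_from_records <- function(records) {
  covs <- intersect(cohort_covariate_columns(), names(records))
  records |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$entry)
      k <- nrow(d)
      times <- c(d$entry[1], d$exit)
      states <- c(d$state, if (is.na(d$to[k])) d$state[k] else d$to[k])
      out <- tibble::tibble(time_years = times, state = as.integer(states))
      for (cv in covs) out[[cv]] <- d[[cv]][1L]
      out
    }) |>
    dplyr::ungroup()
}

#' Write a cohort to CSV
#'
#' Serializes an event-history dataset (records or a simulated cohort) to
#' the long CSV format, preceded by a `#`-prefixed metadata header (package
#' version, content hash, seed when known) so that every output file
#' records its provenance.
#'
#' @param x A record tibble or an `msm_cohort`.
#' @param path Output file path.
#' @param seed Seed to record in the header (taken from the cohort when
#'   available).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, seed = NULL) {
  if (inherits(x, "msm_cohort")) {
    seed <- seed %||% x$seed
    x <- x$records
  }
  events <- events_from_records(x) |>
    dplyr::arrange(.data$subject_id, .data$time_years)
  header <- c(
    paste0("# fracmsm cohort v",
           as.character(utils::packageVersion("fracmsm"))),
    paste0("# hash: ", rlang::hash(events)),
    if (!is.null(seed)) paste0("# seed: ", seed)
  )
  writeLines(header, path)
  readr::write_csv(events, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Parses the long event format, validates the schema (required columns,
#' states in 1..5, non-negative and nondecreasing times within subject),
#' and converts to sojourn records via [records_from_events()]. Schema
#' violations name the offending column and rows.
#'
#' @param path CSV path (lines starting `#` are metadata and skipped).
#' @return A record tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  events <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                            progress = FALSE)
  required <- c("subject_id", "time_years", "state")
  miss <- setdiff(required, names(events))
  if (length(miss)) {
    abort(paste0("Cohort file lacks required column(s): ", toString(miss)))
  }
  bad_state <- which(!events$state %in% seq_len(n_states()))
  if (length(bad_state)) {
    abort(paste0("Column `state` outside 1..5 at row(s): ",
                 toString(head(bad_state, 5))))
  }
  bad_time <- which(events$time_years < 0 | !is.finite(events$time_years))
  if (length(bad_time)) {
    abort(paste0("Column `time_years` invalid at row(s): ",
                 toString(head(bad_time, 5))))
  }
  records_from_events(events)
}

#' Descriptive baseline table by sex
#'
#' Mean (SD) for continuous covariates and n (%) for binary covariates, by
#' sex, with two-sample Welch t-test or chi-squared (without continuity
#' correction) p-values — the standard layout of a cohort's "Table 1". A
#' zero-variance variable gets an undefined (`NA`) p-value rather than an
#' error.
#'
#' @param baseline A baseline covariate table ([sample_baseline()]).
#' @return A tibble: `variable`, `type`, `female`, `male` (formatted),
#'   `female_mean`, `male_mean` (means or proportions), `p.value`.
#' @export
baseline_table <- function(baseline) {
  if (!"sex" %in% names(baseline)) abort("`baseline` needs a `sex` column.")
  is_f <- sex_indicator(baseline$sex) == 0
  continuous <- intersect(c("age", "bmi", "fnbmd", "fnbmd_tscore"),
                          names(baseline))
  binary <- intersect(c("falls", "prior_fracture", "cardiovascular",
                        "cancer", "neurological", "rheumatoid",
                        "respiratory", "diabetes"), names(baseline))
  cont_rows <- purrr::map_dfr(continuous, function(v) {
    xf <- baseline[[v]][is_f]
    xm <- baseline[[v]][!is_f]
    p <- tryCatch(t.test(xf, xm)$p.value, error = function(e) NA_real_)
    tibble::tibble(
      variable = v, type = "continuous",
      female = sprintf("%.2f (%.2f)", mean(xf), stats::sd(xf)),
      male = sprintf("%.2f (%.2f)", mean(xm), stats::sd(xm)),
      female_mean = mean(xf), male_mean = mean(xm), p.value = p
    )
  })
  bin_rows <- purrr::map_dfr(binary, function(v) {
    xf <- baseline[[v]][is_f]
    xm <- baseline[[v]][!is_f]
    tab <- rbind(c(sum(xf), sum(1 - xf)), c(sum(xm), sum(1 - xm)))
    p <- if (any(colSums(tab) == 0)) NA_real_ else {
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
    tibble::tibble(
      variable = v, type = "binary",
      female = sprintf("%d (%.1f)", sum(xf), 100 * mean(xf)),
      male = sprintf("%d (%.1f)", sum(xm), 100 * mean(xm)),
      female_mean = mean(xf), male_mean = mean(xm), p.value = p
    )
  })
  dplyr::bind_rows(cont_rows, bin_rows)
}

#' Observed-vs-predicted calibration table
#'
#' Stratifies sojourn records by sex, age band at state entry and occupied
#' state, and compares the observed probability of leaving the state within
#' a horizon (Kaplan-Meier estimate at the horizon, robust to independent
#' censoring) with the model's mean predicted exit probability
#' `1 - exp(-sum_s q_rs(z) * h)` over the stratum. Strata below a minimum
#' size are flagged, never silently dropped.
#'
#' @param fit An `msm_fit`, `msm_closed_fit` or `msm_params`.
#' @param records Record tibble to calibrate against (may be the training
#'   data itself: self-calibration).
#' @param horizon Years ahead (default 5).
#' @param age_breaks Age-band cut points for age at state entry.
#' @param by_sex Stratify by sex.
#' @param min_n Flag strata smaller than this.
#' @return A tibble: stratum columns, `n`, `observed`, `predicted`,
#'   `difference`, `se` (binomial), `flag`.
#' @export
calibration_table <- function(fit, records, horizon = 5,
                              age_breaks = c(60, 70, 80, Inf),
                              by_sex = TRUE, min_n = 10) {
  params <- as_msm_params(fit)
  rates <- transition_rates(params, records)
  allowed <- allowed_transitions()
  out_rate <- rowSums(matrix(vapply(seq_len(nrow(allowed)), function(j) {
    rates[, j] * (records$state == allowed$from[j])
  }, numeric(nrow(records))), nrow = nrow(records)))
  d <- records |>
    dplyr::mutate(
      duration = .data$exit - .data$entry,
      event = !is.na(.data$to),
      predicted_i = 1 - exp(-out_rate * horizon),
      age_band = cut(.data$age_at_event, breaks = age_breaks, right = FALSE,
                     include.lowest = TRUE)
    )
  keys <- c(if (by_sex) "sex", "age_band", "state")
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(g, key) {
      sf <- survival::survfit(
        survival::Surv(g$duration, g$event) ~ 1
      )
      surv_h <- summary(sf, times = min(horizon, max(g$duration)),
                        extend = TRUE)$surv
      obs <- 1 - surv_h
      pred <- mean(g$predicted_i)
      tibble::tibble(
        n = nrow(g), observed = obs, predicted = pred,
        difference = obs - pred,
        se = sqrt(pred * (1 - pred) / nrow(g))
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(flag = .data$n < min_n)
}
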