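#' Configuration of a synthetic cohort
#'
#' Describes the cohort the generator emulates: a population-based study of
#' 2046 women and 1205 men aged 60+, with baseline covariate distributions
#' matching the source cohort's published moments and prevalences, true
#' transition parameters defaulting to the published typical-profile
#' intensities plus covariate effects ([dubbo_parameters()]), exponential
#' dropout calibrated to a 9-year median follow-up, administrative
#' censoring 21 years after study start, and entry staggered uniformly over
#' a 5-year recruitment window.
#'
#' @param n_women,n_men Cohort sizes.
#' @param params True [model_parameters()] (joint model), or a named list
#'   `list(female = , male = )` of sex-specific parameter sets.
#' @param baseline Per-sex covariate distributions; see the default for the
#'   expected structure (means/SDs for age, BMI, femoral neck BMD; the
#'   young-adult BMD reference mean/SD used to derive T-scores; Bernoulli
#'   prevalences for the binaries).
#' @param dropout_rate Per-year exponential dropout rate; the default
#'   `log(2)/9` puts the median censoring time at 9 years.
#' @param admin_censor Administrative censoring, years after study start.
#' @param recruitment_window Uniform entry stagger (years); each subject's
#'   maximum follow-up is `admin_censor` minus their entry offset.
#' @param min_age Lower truncation of the entry-age distribution.
#' @return A list of class `msm_cohort_config`.
#' @export
cohort_config <- function(n_women = 2046, n_men = 1205,
                          params = dubbo_parameters(),
                          baseline = default_baseline_distributions(),
                          dropout_rate = log(2) / 9,
                          admin_censor = 21,
                          recruitment_window = 5,
                          min_age = 60) {
  stopifnot(n_women >= 0, n_men >= 0, dropout_rate >= 0, admin_censor > 0,
            recruitment_window >= 0)
  for (sx in names(baseline)) {
    prev <- unlist(baseline[[sx]]$prevalence)
    if (any(prev < 0 | prev > 1)) {
      abort("Baseline prevalences must lie in [0, 1].")
    }
  }
  structure(
    list(n_women = n_women, n_men = n_men, params = params,
         baseline = baseline, dropout_rate = dropout_rate,
         admin_censor = admin_censor,
         recruitment_window = recruitment_window, min_age = min_age),
    class = "msm_cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_baseline_distributions <- function() {
  list(
    female = list(
      age = c(mean = 70, sd = 7),
      bmi = c(mean = 26.5, sd = 5.1),
      fnbmd = c(mean = 0.81, sd = 0.14),
      bmd_reference = c(mean = 1.00, sd = 0.12),
      prevalence = c(falls = 0.379, prior_fracture = 0.175,
                     cardiovascular = 0.309, cancer = 0.085,
                     neurological = 0.069, rheumatoid = 0.041,
                     respiratory = 0.108, diabetes = 0.107)
    ),
    male = list(
      age = c(mean = 70, sd = 6),
      bmi = c(mean = 26.8, sd = 3.9),
      fnbmd = c(mean = 0.92, sd = 0.15),
      bmd_reference = c(mean = 1.04, sd = 0.12),
      prevalence = c(falls = 0.263, prior_fracture = 0.115,
                     cardiovascular = 0.390, cancer = 0.090,
                     neurological = 0.057, rheumatoid = 0.021,
                     respiratory = 0.117, diabetes = 0.131)
    )
  )
}

# Exact truncated-normal sampler by inverse-CDF (lower truncation only).
rnorm_truncated <- function(n, mean, sd, lower = -Inf) {
  p0 <- pnorm(lower, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

#' Sample a baseline covariate table
#'
#' Draws entry age (normal truncated at the minimum age), BMI, femoral neck
#' BMD (truncated at zero) and the binary risk factors from the configured
#' per-sex distributions. The BMD T-score is derived from the sampled BMD
#' through the young-adult reference, `(BMD - ref_mean) / ref_sd`, so its
#' spread propagates from the BMD spread.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; mandatory (no silent default).
#' @return A tibble with one row per subject: `subject_id`, `sex`, `age`,
#'   `bmi`, `fnbmd`, `fnbmd_tscore` and the eight binary covariates.
#' @export
sample_baseline <- function(config, seed) {
  if (missing(seed)) abort("`seed` is required for sample_baseline().")
  set.seed(seed)
  one_sex <- function(n, sex) {
    d <- config$baseline[[sex]]
    fnbmd <- rnorm_truncated(n, d$fnbmd["mean"], d$fnbmd["sd"], lower = 0)
    out <- tibble::tibble(
      sex = sex,
      age = rnorm_truncated(n, d$age["mean"], d$age["sd"],
                            lower = config$min_age),
      bmi = rnorm_truncated(n, d$bmi["mean"], d$bmi["sd"], lower = 10),
      fnbmd = fnbmd,
      fnbmd_tscore = (fnbmd - d$bmd_reference["mean"]) / d$bmd_reference["sd"]
    )
    for (nm in names(d$prevalence)) {
      out[[nm]] <- rbinom(n, 1L, d$prevalence[[nm]])
    }
    out
  }
  dplyr::bind_rows(
    one_sex(config$n_women, "female"),
    one_sex(config$n_men, "male")
  ) |>
    dplyr::mutate(subject_id = sprintf("S%05d", dplyr::row_number()),
                  .before = 1)
}

params_for_sex <- function(params, sex) {
  if (inherits(params, "msm_params")) return(params)
  p <- params[[sex]]
  if (is.null(p)) abort(paste0("No parameter set for sex `", sex, "`."))
  p
}

#' Simulate continuous-time trajectories under known parameters
#'
#' Each subject starts fracture-free. Within each occupied state the exit
#' mechanism is competing exponentials: one clock per allowed exit with
#' rate `q_rs` evaluated at the profile on state entry (the age covariate
#' is refreshed to the age at entry), and the minimum wins. Trajectories
#' stop at death or at the subject's censoring time — the minimum of
#' exponential dropout and the administrative limit net of the staggered
#' entry offset. A transient state whose exit rates are all zero censors
#' the subject at the administrative limit, with a warning.
#'
#' @param params True parameters (joint `msm_params` or per-sex list).
#' @param baseline A baseline table from [sample_baseline()].
#' @param config A [cohort_config()].
#' @param seed Integer seed; mandatory.
#' @return A list of class `msm_cohort`: `baseline`, `records` (exactly
#'   observed, censoring applied), `censor_time` (per subject), `config`,
#'   `seed`.
#' @export
simulate_paths <- function(params, baseline, config, seed) {
  if (missing(seed)) abort("`seed` is required for simulate_paths().")
  set.seed(seed)
  n <- nrow(baseline)
  offset <- runif(n, 0, config$recruitment_window)
  dropout <- if (config$dropout_rate > 0) {
    rexp(n, config$dropout_rate)
  } else {
    rep(Inf, n)
  }
  censor <- pmin(dropout, config$admin_censor - offset)

  allowed <- allowed_transitions()
  recs <- vector("list", 4L)
  active <- seq_len(n)      # row indices of subjects currently in `state`
  entry <- rep(0, n)
  zero_rate_warned <- FALSE
  for (state in 1:4) {
    if (!length(active)) break
    prof <- baseline[active, , drop = FALSE]
    prof$age_at_event <- prof$age + entry[active]
    exits <- which(allowed$from == state)
    # per-sex parameter sets are allowed; evaluate rates sex by sex
    rates <- matrix(0, nrow(prof), length(exits))
    for (sx in unique(prof$sex)) {
      rows <- which(prof$sex == sx)
      p <- params_for_sex(params, sx)
      rates[rows, ] <- transition_rates(p, prof[rows, , drop = FALSE])[,
        exits, drop = FALSE]
    }
    lambda <- rowSums(rates)
    if (any(lambda == 0) && !zero_rate_warned) {
      warn(paste0("All exit rates are zero in state ", state,
                  " for some subjects; censoring at the administrative",
                  " limit."))
      zero_rate_warned <- TRUE
    }
    hold <- ifelse(lambda > 0, rexp(length(active), pmax(lambda, 1e-300)),
                   Inf)
    dest <- allowed$to[exits[1]]
    if (length(exits) == 2L) {
      u <- runif(length(active))
      dest <- ifelse(u <= rates[, 1] / pmax(lambda, 1e-300),
                     allowed$to[exits[1]], allowed$to[exits[2]])
    }
    exit_time <- entry[active] + hold
    censored <- exit_time >= censor[active] | !is.finite(exit_time)
    recs[[state]] <- tibble::tibble(
      subject_id = prof$subject_id,
      state = state,
      entry = entry[active],
      exit = ifelse(censored, censor[active], exit_time),
      to = ifelse(censored, NA_integer_, as.integer(dest))
    ) |>
      dplyr::bind_cols(prof[setdiff(names(prof), "subject_id")])
    progressing <- !censored & dest == state + 1L
    entry[active[progressing]] <- exit_time[progressing]
    active <- active[progressing]
  }
  records <- dplyr::bind_rows(recs) |>
    dplyr::arrange(.data$subject_id, .data$entry)
  structure(
    list(baseline = baseline, records = records,
         censor_time = setNames(censor, baseline$subject_id),
         config = config, seed = seed),
    class = "msm_cohort"
  )
}

#' Simulate a full cohort
#'
#' Convenience wrapper: [sample_baseline()] then [simulate_paths()] under
#' one seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; mandatory.
#' @return An `msm_cohort` (see [simulate_paths()]).
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_women = 50, n_men = 30), seed = 7)
#' event_history_summary(coh$records)
simulate_cohort <- function(config = cohort_config(), seed) {
  if (missing(seed)) abort("`seed` is required for simulate_cohort().")
  baseline <- sample_baseline(config, seed = seed)
  simulate_paths(config$params, baseline, config, seed = seed + 1L)
}

#' Apply an observation scheme to a simulated cohort
#'
#' `"exact"` passes the exactly observed, censoring-applied records
#' through — fracture and death dates are known to the day. `"panel"`
#' emulates scheduled follow-up visits: the fracture state is only
#' reported at visit times (default biennial), while death keeps its
#' exact registry date; the result is a long snapshot table for
#' [panel_loglik()], which necessarily carries less information (observed
#' fracture counts can only fall).
#'
#' @param cohort An `msm_cohort`.
#' @param scheme `"exact"` or `"panel"`.
#' @param interval Visit spacing in years for the panel scheme.
#' @return For `"exact"`, the record tibble; for `"panel"`, a long
#'   snapshot tibble (`subject_id`, `time_years`, `state`, covariates).
#' @export
apply_observation <- function(cohort, scheme = c("exact", "panel"),
                              interval = 2) {
  scheme <- match.arg(scheme)
  if (scheme == "exact") return(cohort$records)
  covs <- intersect(cohort_covariate_columns(), names(cohort$baseline))
  cohort$records |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) {
      end <- max(d$exit)
      died <- any(!is.na(d$to) & d$to == absorbing_state())
      visits <- seq(0, end, by = interval)
      if (died) visits <- c(visits[visits < end], end)
      state_at <- vapply(visits, function(t) {
        if (died && t >= end) return(absorbing_state())
        as.integer(d$state[findInterval(t, d$entry)])
      }, integer(1))
      tibble::tibble(time_years = visits, state = state_at)
    }) |>
    dplyr::ungroup() |>
    dplyr::left_join(
      dplyr::select(cohort$baseline, "subject_id",
                    dplyr::all_of(covs)),
      by = "subject_id"
    )
}

#' Parameter-recovery simulation study
#'
#' Repeatedly simulates cohorts from known parameters, refits, and reports
#' per-parameter bias, empirical and mean reported standard errors, and
#' 95% Wald CI coverage. Replicates where a parameter sits on the boundary
#' (zero events) are counted and excluded for that parameter.
#'
#' @param config A [cohort_config()]; its `params` are the truth. A
#'   per-sex parameter list triggers sex-stratified refitting.
#' @param n_replicates Number of simulation replicates.
#' @param seed Integer seed; replicate `i` uses `seed + i`.
#' @param fit_method `"closed_form"` (covariate-free truth) or `"mle"`.
#' @param covariates Covariates for `fit_method = "mle"`.
#' @param conf.level CI level assessed for coverage.
#' @return A tibble: `parameter`, `truth`, `n_used`, `n_boundary`, `bias`,
#'   `empirical_se`, `mean_se`, `coverage`.
#' @export
parameter_recovery <- function(config, n_replicates, seed,
                               fit_method = c("closed_form", "mle"),
                               covariates = character(),
                               conf.level = 0.95) {
  if (missing(seed)) abort("`seed` is required for parameter_recovery().")
  fit_method <- match.arg(fit_method)
  stopifnot(n_replicates >= 1)
  zq <- qnorm(1 - (1 - conf.level) / 2)
  stratified <- !inherits(config$params, "msm_params")

  truth_tab <- if (stratified) {
    purrr::map_dfr(names(config$params), function(sx) {
      tibble::tibble(
        parameter = paste0(sx, ":", names(config$params[[sx]]$alpha)),
        truth = unname(config$params[[sx]]$alpha)
      )
    })
  } else {
    keys <- names(config$params$alpha)
    dplyr::bind_rows(
      tibble::tibble(parameter = paste0(keys, ":(baseline)"),
                     truth = unname(config$params$alpha)),
      purrr::map_dfr(keys, function(k) {
        b <- config$params$beta[[k]]
        tibble::tibble(parameter = paste0(k, ":", names(b)),
                       truth = unname(b))
      })
    ) |>
      dplyr::filter(.data$parameter %in%
                      paste0(rep(keys, each = 1 + length(covariates)),
                             ":", c("(baseline)", covariates)))
  }

  one_rep <- function(i) {
    coh <- simulate_cohort(config, seed = seed + i)
    if (stratified) {
      purrr::map_dfr(names(config$params), function(sx) {
        recs <- coh$records[coh$records$sex == sx, , drop = FALSE]
        est <- if (fit_method == "closed_form") {
          closed_form_mle(recs)$table |>
            dplyr::transmute(
              parameter = paste0(sx, ":", .data$transition),
              estimate = .data$alpha, se = .data$se_alpha,
              boundary = .data$boundary
            )
        } else {
          f <- fit_mle(recs, covariates = covariates)
          f$coef |>
            dplyr::transmute(
              parameter = paste0(sx, ":", .data$transition),
              estimate = .data$estimate, se = .data$std.error,
              boundary = !is.finite(.data$estimate)
            )
        }
        est
      })
    } else if (fit_method == "closed_form") {
      closed_form_mle(coh$records)$table |>
        dplyr::transmute(parameter = paste0(.data$transition, ":(baseline)"),
                         estimate = .data$alpha, se = .data$se_alpha,
                         boundary = .data$boundary)
    } else {
      f <- fit_mle(coh$records, covariates = covariates)
      f$coef |>
        dplyr::transmute(
          parameter = paste0(.data$transition, ":", .data$term),
          estimate = .data$estimate, se = .data$std.error,
          boundary = !is.finite(.data$estimate)
        )
    }
  }

  ests <- purrr::map_dfr(seq_len(n_replicates), one_rep)
  ests |>
    dplyr::inner_join(truth_tab, by = "parameter") |>
    dplyr::group_by(.data$parameter, .data$truth) |>
    dplyr::summarise(
      n_used = sum(!.data$boundary),
      n_boundary = sum(.data$boundary),
      bias = mean(.data$estimate[!.data$boundary]) - .data$truth[1],
      empirical_se = stats::sd(.data$estimate[!.data$boundary]),
      mean_se = mean(.data$se[!.data$boundary]),
      coverage = mean(
        abs(.data$estimate[!.data$boundary] - .data$truth[1]) <=
          zq * .data$se[!.data$boundary]
      ),
      .groups = "drop"
    )
}
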