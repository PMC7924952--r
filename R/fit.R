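#' Closed-form maximum-likelihood intensities (no covariates)
#'
#' With exactly observed sojourns and no covariates, the exact-time
#' likelihood maximizer has the closed form `q_rs = n_rs / T_r`: events
#' divided by person-years at risk in the source state. The standard error
#' of the log rate is `1/sqrt(n_rs)` (inverse observed information). A
#' transition with zero events sits on the parameter-space boundary (rate 0,
#' log rate `-Inf`) and is flagged rather than erroring.
#'
#' @param records A record tibble from [records_from_events()].
#' @param coding A [covariate_coding()] object (carried on the parameters).
#' @return An object of class `msm_closed_fit`: list with `params`
#'   (an [model_parameters()] object) and `table` (per-transition tibble
#'   with `n_events`, `person_years`, `rate`, `alpha`, `se_alpha`,
#'   `boundary`).
#' @export
closed_form_mle <- function(records, coding = covariate_coding()) {
  tab <- event_history_summary(records) |>
    dplyr::mutate(
      rate = dplyr::if_else(.data$person_years > 0,
                            .data$n_events / .data$person_years, 0),
      alpha = dplyr::if_else(.data$rate > 0, log(.data$rate), -Inf),
      se_alpha = dplyr::if_else(.data$n_events > 0,
                                1 / sqrt(.data$n_events), NA_real_),
      boundary = .data$n_events == 0L
    )
  params <- model_parameters(
    alpha = setNames(tab$alpha, tab$transition), coding = coding
  )
  structure(list(params = params, table = tab), class = "msm_closed_fit")
}

#' @export
print.msm_closed_fit <- function(x, ...) {
  cat("<msm_closed_fit> q_rs = n_rs / T_r\n")
  print(x$table)
  invisible(x)
}

# one Poisson-process block: records of one source state, events to one
# destination. Analytic gradient and Hessian; theta = (alpha, beta).
fit_transition_block <- function(rows, dest, covariates, coding, control) {
  dur <- rows$exit - rows$entry
  y <- !is.na(rows$to) & rows$to == dest
  X <- cbind(`(baseline)` = 1,
             code_covariates(rows, covariates, coding))
  k <- ncol(X)
  if (!any(y)) {
    return(list(theta = c(-Inf, rep(0, k - 1)), vcov = matrix(NA_real_, k, k),
                converged = TRUE, boundary = TRUE,
                n_events = 0L, max_grad = 0))
  }
  nll <- function(theta) {
    eta <- drop(X %*% theta)
    sum(exp(eta) * dur) - sum(eta[y])
  }
  gr <- function(theta) {
    lam <- exp(drop(X %*% theta)) * dur
    drop(crossprod(X, lam)) - colSums(X[y, , drop = FALSE])
  }
  start <- c(log(sum(y) / sum(dur)), rep(0, k - 1))
  opt <- optim(start, nll, gr, method = "BFGS",
               control = list(maxit = control$maxit,
                              reltol = control$reltol))
  lam <- exp(drop(X %*% opt$par)) * dur
  H <- crossprod(X, X * lam)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
  g <- gr(opt$par)
  list(theta = opt$par, vcov = vc,
       converged = opt$convergence == 0 &&
         max(abs(g)) < control$grad_tol * max(1, sum(y)),
       boundary = FALSE, n_events = sum(y), max_grad = max(abs(g)))
}

#' Fit the multistate model by maximum likelihood
#'
#' Estimates, for each of the seven allowed transitions, a baseline
#' log-intensity and log hazard ratios for the requested covariates, by
#' maximizing the exact-time likelihood ([exact_time_loglik()]; the
#' default) or the panel likelihood ([panel_loglik()]).
#'
#' Under exact-time observation the likelihood factorizes over transitions,
#' so each block is optimized separately (BFGS with analytic gradient,
#' started at the closed-form rate) and the covariance comes from the
#' inverse of the analytic observed information, block-diagonal across
#' transitions. Transitions with zero observed events are boundary-flagged
#' (rate 0), never estimated. Panel fits optimize all parameters jointly
#' with a numerically differenced Hessian.
#'
#' @param data A record tibble ([records_from_events()]) for
#'   `likelihood = "exact"`, or a long snapshot tibble for `"panel"`.
#' @param covariates Character vector of covariate names (see
#'   [covariate_coding()]); empty for a baseline-only fit.
#' @param likelihood `"exact"` (default) or `"panel"`.
#' @param exact_death For panel fits, treat death times as exact.
#' @param coding A [covariate_coding()] object.
#' @param control List: `maxit`, `reltol` (log-likelihood convergence
#'   tolerance), `grad_tol` (scaled score tolerance at the optimum).
#' @return An object of class `msm_fit` with elements `params`, `coef`
#'   (tidy coefficient tibble), `vcov`, `loglik`, `transitions`
#'   (per-transition diagnostics), `converged`, `covariates`, `likelihood`.
#' @export
#' @examples
#' \donttest{
#' cfg <- cohort_config(n_women = 300, n_men = 200)
#' coh <- simulate_cohort(cfg, seed = 1)
#' fit <- fit_mle(coh$records, covariates = "sex")
#' tidy(fit)
#' }
fit_mle <- function(data, covariates = character(),
                    likelihood = c("exact", "panel"), exact_death = TRUE,
                    coding = covariate_coding(),
                    control = list()) {
  likelihood <- match.arg(likelihood)
  control <- utils::modifyList(
    list(maxit = 500L, reltol = 1e-12, grad_tol = 1e-4), control
  )
  if (likelihood == "exact") {
    fit_mle_exact(data, covariates, coding, control)
  } else {
    fit_mle_panel(data, covariates, exact_death, coding, control)
  }
}

fit_mle_exact <- function(records, covariates, coding, control) {
  allowed <- allowed_transitions()
  keys <- allowed$transition
  terms <- c("(baseline)", covariates)
  blocks <- lapply(seq_len(nrow(allowed)), function(j) {
    rows <- records[records$state == allowed$from[j], , drop = FALSE]
    fit_transition_block(rows, allowed$to[j], covariates, coding, control)
  })
  names(blocks) <- keys

  alpha <- setNames(vapply(blocks, function(b) b$theta[1], 1), keys)
  beta <- setNames(lapply(blocks, function(b) {
    setNames(b$theta[-1], covariates)
  }), keys)
  params <- model_parameters(alpha, beta, coding)

  pnames <- unlist(lapply(keys, function(k) paste0(k, ":", terms)))
  vcov <- matrix(NA_real_, length(pnames), length(pnames),
                 dimnames = list(pnames, pnames))
  for (j in seq_along(keys)) {
    idx <- (j - 1) * length(terms) + seq_along(terms)
    vcov[idx, idx] <- blocks[[j]]$vcov
  }
  coef_tab <- tibble::tibble(
    transition = rep(keys, each = length(terms)),
    term = rep(terms, length(keys)),
    estimate = unlist(lapply(blocks, `[[`, "theta")),
    std.error = sqrt(pmax(diag(vcov), 0))
  )
  diag_tab <- allowed |>
    dplyr::mutate(
      n_events = vapply(blocks, `[[`, 1L, "n_events"),
      boundary = vapply(blocks, `[[`, TRUE, "boundary"),
      converged = vapply(blocks, `[[`, TRUE, "converged"),
      max_grad = vapply(blocks, `[[`, 1, "max_grad")
    )
  converged <- all(diag_tab$converged)
  if (!converged) {
    warn(paste0("fit_mle did not converge for transition(s): ",
                toString(diag_tab$transition[!diag_tab$converged]),
                "; estimates are the last iterate."))
  }
  structure(list(
    params = params, coef = coef_tab, vcov = vcov,
    loglik = exact_time_loglik(params, records),
    transitions = diag_tab, converged = converged,
    covariates = covariates, likelihood = "exact", coding = coding,
    n_records = nrow(records)
  ), class = "msm_fit")
}

fit_mle_panel <- function(panel, covariates, exact_death, coding, control) {
  keys <- allowed_transitions()$transition
  terms <- c("(baseline)", covariates)
  k <- length(terms)
  unpack <- function(theta) {
    m <- matrix(theta, nrow = k)
    model_parameters(
      alpha = setNames(m[1, ], keys),
      beta = setNames(lapply(seq_along(keys), function(j) {
        setNames(m[-1, j], covariates)
      }), keys),
      coding = coding
    )
  }
  nll <- function(theta) -panel_loglik(unpack(theta), panel, exact_death)
  start <- rep(c(log(0.05), rep(0, k - 1)), length(keys))
  opt <- optim(start, nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = control$maxit,
                              reltol = max(control$reltol, 1e-8)))
  params <- unpack(opt$par)
  pnames <- unlist(lapply(keys, function(kk) paste0(kk, ":", terms)))
  vcov <- tryCatch(solve(opt$hessian),
                   error = function(e) matrix(NA_real_, length(pnames),
                                              length(pnames)))
  dimnames(vcov) <- list(pnames, pnames)
  converged <- opt$convergence == 0
  if (!converged) warn("Panel fit did not converge; last iterate returned.")
  structure(list(
    params = params,
    coef = tibble::tibble(
      transition = rep(keys, each = k), term = rep(terms, length(keys)),
      estimate = opt$par, std.error = sqrt(pmax(diag(vcov), 0))
    ),
    vcov = vcov, loglik = -opt$value,
    transitions = allowed_transitions(), converged = converged,
    covariates = covariates, likelihood = "panel", coding = coding,
    n_records = nrow(panel)
  ), class = "msm_fit")
}

#' Fit the model separately within strata
#'
#' Runs [fit_mle()] within each level of a stratifying column (typically
#' `sex`), mirroring a fully interacted model. Returns a named list of
#' `msm_fit` objects.
#'
#' @inheritParams fit_mle
#' @param by Name of the stratifying column.
#' @return Named list of `msm_fit` objects, one per stratum.
#' @export
fit_mle_stratified <- function(data, by = "sex", covariates = character(),
                               ...) {
  if (!by %in% names(data)) abort(paste0("No column `", by, "` in data."))
  split(data, data[[by]]) |>
    lapply(fit_mle, covariates = covariates, ...)
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("<msm_fit> ", x$likelihood, "-time likelihood, logLik = ",
      format(x$loglik), if (!x$converged) " (NOT converged)", "\n", sep = "")
  cat("baseline intensities (per year):\n")
  print(round(exp(x$params$alpha), 4))
  invisible(x)
}

#' @rdname msm_fit_methods
#' @title Broom-style methods for fitted multistate models
#' @description `tidy()` returns one row per transition per term with Wald
#'   statistics; `glance()` returns a one-row model summary.
#' @param x An `msm_fit` object.
#' @param exponentiate Report hazard-ratio scale estimates/CIs.
#' @param conf.level Confidence level for Wald intervals.
#' @param ... Unused.
#' @export
tidy.msm_fit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  zq <- qnorm(1 - (1 - conf.level) / 2)
  out <- x$coef |>
    dplyr::mutate(
      statistic = .data$estimate / .data$std.error,
      p.value = 2 * pnorm(-abs(.data$statistic)),
      conf.low = .data$estimate - zq * .data$std.error,
      conf.high = .data$estimate + zq * .data$std.error
    )
  if (exponentiate) {
    out <- dplyr::mutate(
      out,
      dplyr::across(c("estimate", "conf.low", "conf.high"), exp)
    )
  }
  out
}

#' @rdname msm_fit_methods
#' @export
glance.msm_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    n_records = x$n_records,
    n_parameters = sum(is.finite(x$coef$estimate)),
    n_boundary = if ("boundary" %in% names(x$transitions)) {
      sum(x$transitions$boundary)
    } else NA_integer_,
    converged = x$converged
  )
}

#' Hazard-ratio table with Wald confidence intervals
#'
#' For every covariate on every transition: `HR = exp(beta)` with
#' `exp(beta +/- z * SE)` confidence limits and a 5%-level significance
#' flag. Accepts a fitted model or a coefficient tibble with columns
#' `transition`, `term`, `estimate`, `std.error`.
#'
#' @param fit An `msm_fit`, or a coefficient tibble.
#' @param conf.level Confidence level (default 0.95).
#' @return A tibble: `transition`, `term`, `hr`, `conf.low`, `conf.high`,
#'   `p.value`, `significant`. CI columns are `NA` when no standard error
#'   is available.
#' @export
hazard_ratio_table <- function(fit, conf.level = 0.95) {
  coef_tab <- if (inherits(fit, "msm_fit")) fit$coef else tibble::as_tibble(fit)
  need <- c("transition", "term", "estimate", "std.error")
  miss <- setdiff(need, names(coef_tab))
  if (length(miss)) abort(paste0("Missing column(s): ", toString(miss)))
  zq <- qnorm(1 - (1 - conf.level) / 2)
  coef_tab |>
    dplyr::filter(.data$term != "(baseline)") |>
    dplyr::mutate(
      hr = exp(.data$estimate),
      conf.low = exp(.data$estimate - zq * .data$std.error),
      conf.high = exp(.data$estimate + zq * .data$std.error),
      p.value = 2 * pnorm(-abs(.data$estimate / .data$std.error)),
      significant = !is.na(.data$p.value) & .data$p.value < 0.05
    ) |>
    dplyr::select("transition", "term", "hr", "conf.low", "conf.high",
                  "p.value", "significant")
}
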