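#' Exact-time event-history log-likelihood
#'
#' With fracture and death dates observed exactly, each sojourn record in
#' state `r` of length `d` contributes `-(sum_s q_rs(z)) * d`, plus
#' `log q_rs(z)` when the sojourn ends with an observed transition to `s`.
#' The likelihood therefore factorizes over transitions into independent
#' Poisson-process terms, which [fit_mle()] exploits.
#'
#' @param params An [model_parameters()] object.
#' @param records A record tibble from [records_from_events()].
#' @return The log-likelihood (scalar). `-Inf`, with a warning naming the
#'   offending transition, if a realized transition has zero intensity.
#' @export
exact_time_loglik <- function(params, records) {
  if (!nrow(records)) return(0)
  rates <- transition_rates(params, records)
  allowed <- allowed_transitions()
  dur <- records$exit - records$entry
  # total exit intensity of each record's state
  out_rate <- rowSums(matrix(vapply(seq_len(nrow(allowed)), function(j) {
    rates[, j] * (records$state == allowed$from[j])
  }, numeric(nrow(records))), nrow = nrow(records)))
  ll <- -sum(out_rate * dur)
  ev <- !is.na(records$to)
  if (any(ev)) {
    key <- transition_key(records$state[ev], records$to[ev])
    if (any(!key %in% allowed$transition)) {
      abort("Record has a disallowed realized transition.")
    }
    q_ev <- rates[cbind(which(ev), match(key, colnames(rates)))]
    if (any(q_ev == 0)) {
      warn(paste0("Realized transition with zero intensity: ",
                  toString(unique(key[q_ev == 0]))))
      return(-Inf)
    }
    ll <- ll + sum(log(q_ev))
  }
  ll
}

#' Panel-observed log-likelihood
#'
#' For data observed only at discrete visits (e.g. biennial follow-up), each
#' consecutive pair of snapshots `(t_i, r)` and `(t_{i+1}, s)` contributes
#' `log P_rs(t_{i+1} - t_i)`, a matrix-exponential entry. Death times are
#' typically known exactly from registries, in which case a terminal death
#' snapshot contributes the density `sum_k P_rk(dt) q_k5` instead: the state
#' path up to the moment of death is unknown, but its time is.
#'
#' @param params An [model_parameters()] object.
#' @param panel Long-format snapshot tibble (`subject_id`, `time_years`,
#'   `state`, baseline covariates incl. `age`).
#' @param exact_death Treat death times as exactly observed (default TRUE).
#' @return The log-likelihood. `-Inf`, with a warning, if a snapshot pair
#'   implies an impossible (probability-zero) net movement.
#' @export
panel_loglik <- function(params, panel, exact_death = TRUE) {
  panel <- dplyr::arrange(panel, .data$subject_id, .data$time_years)
  pairs <- panel |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(
      to_state = dplyr::lead(.data$state),
      dt = dplyr::lead(.data$time_years) - .data$time_years
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$to_state))
  if (!nrow(pairs)) return(0)
  if ("age" %in% names(pairs)) {
    pairs$age_at_event <- pairs$age + pairs$time_years
  }
  rates <- transition_rates(params, pairs)
  # one expm per unique (intensity vector, interval) pair
  key <- apply(cbind(signif(rates, 12), signif(pairs$dt, 12)), 1, paste,
               collapse = ",")
  groups <- split(seq_len(nrow(pairs)), key)
  ll <- 0
  for (idx in groups) {
    i1 <- idx[1]
    Q <- generator_from_rates(rates[i1, ])
    P <- transition_probability(Q, pairs$dt[i1])
    for (i in idx) {
      r <- pairs$state[i]
      s <- pairs$to_state[i]
      contrib <- if (s == absorbing_state() && exact_death) {
        sum(P[r, -absorbing_state()] * Q[-absorbing_state(),
                                         absorbing_state()])
      } else {
        P[r, s]
      }
      if (contrib <= 0) {
        warn(paste0("Snapshot pair implies impossible movement ", r, "->",
                    s, " for subject ", pairs$subject_id[i]))
        return(-Inf)
      }
      ll <- ll + log(contrib)
    }
  }
  ll
}
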