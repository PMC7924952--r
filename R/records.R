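cohort_covariate_columns <- function() {
  c("sex", "age", "fnbmd_tscore", "bmi", "falls", "prior_fracture",
    "cardiovascular", "cancer", "neurological", "rheumatoid", "respiratory",
    "diabetes")
}

#' Convert per-subject event sequences into sojourn records
#'
#' Takes a long-format event table (one row per observation: `subject_id`,
#' `time_years` on the study clock, `state`, plus baseline covariates) and
#' returns one record per occupied state, the unit of the exact-time
#' likelihood: state, entry and exit times, destination state (or `NA` when
#' the sojourn ends in censoring), and the covariate profile at state entry.
#' The time-variant `age_at_event` column is the baseline age plus the entry
#' time, i.e. the age at the beginning of each state — refreshing age at
#' state entry avoids immortal-time bias.
#'
#' Consecutive rows in the same state are treated as continued observation
#' (the last one marks the censoring time). A backward move, or a jump that
#' skips a state, is a data-validation error naming the subject — unless
#' `split_jumps = TRUE`, in which case a forward skip (e.g. two fractures
#' between visits of panel-observed data) is decomposed into the
#' progressive chain with zero-length intermediate sojourns at the
#' observation time.
#'
#' @param events Long-format tibble; see [read_cohort()] for the schema.
#' @param split_jumps Decompose forward skips instead of erroring.
#' @return A tibble of sojourn records with columns `subject_id`, `state`,
#'   `entry`, `exit`, `to`, `age_at_event`, and the baseline covariates.
#' @export
records_from_events <- function(events, split_jumps = FALSE) {
  required <- c("subject_id", "time_years", "state")
  miss <- setdiff(required, names(events))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", toString(miss)))
  }
  if (any(!events$state %in% seq_len(n_states()))) {
    abort("`state` must be an integer in 1..5.")
  }
  if (any(events$time_years < 0)) abort("`time_years` must be non-negative.")

  events <- dplyr::arrange(events, .data$subject_id, .data$time_years)
  if (split_jumps) {
    # expand forward skips among fracture states: 1->3 becomes 1->2->3
    # with the intermediate entry at the observation time
    events <- events |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::group_modify(function(d, key) {
        nxt <- c(d$state[-1], NA)
        need <- which(!is.na(nxt) & nxt != absorbing_state() &
                        nxt > d$state + 1L)
        if (!length(need)) return(d)
        extra <- dplyr::bind_rows(lapply(need, function(i) {
          mid <- seq(d$state[i] + 1L, nxt[i] - 1L)
          out <- d[rep(i + 1L, length(mid)), , drop = FALSE]
          out$state <- as.integer(mid)
          out
        }))
        dplyr::arrange(dplyr::bind_rows(d, extra), .data$time_years,
                       .data$state)
      }) |>
      dplyr::ungroup()
  }
  bad <- events |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(next_state = dplyr::lead(.data$state)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$next_state), .data$next_state != .data$state,
                  !is_allowed_transition(.data$state, .data$next_state))
  if (nrow(bad)) {
    abort(paste0("Disallowed or backward transition for subject(s): ",
                 toString(unique(bad$subject_id))))
  }

  covs <- intersect(cohort_covariate_columns(), names(events))
  recs <- events |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) {
      # collapse consecutive same-state rows, keeping first entry + last exit
      s <- d$state
      t <- d$time_years
      keep <- c(TRUE, s[-1] != s[-length(s)])
      entry <- t[keep]
      st <- s[keep]
      k <- length(st)
      exit <- c(entry[-1], t[length(t)])
      to <- c(st[-1], NA_integer_)
      # a trajectory ending in death has no trailing censored record
      if (k > 1 && st[k] == absorbing_state()) {
        st <- st[-k]; entry <- entry[-k]; exit <- exit[-k]; to <- to[-k]
        k <- k - 1
      } else if (st[k] == absorbing_state()) {
        abort(paste0("Subject enters in the absorbing state: ",
                     key$subject_id))
      }
      out <- tibble::tibble(state = as.integer(st), entry = entry,
                            exit = exit, to = as.integer(to))
      for (cv in covs) out[[cv]] <- d[[cv]][1L]
      out
    }) |>
    dplyr::ungroup()
  if ("age" %in% names(recs)) {
    recs$age_at_event <- recs$age + recs$entry
  }
  if (any(recs$exit < recs$entry)) abort("Record exit precedes entry.")
  recs
}

#' Event counts and time at risk of an event-history dataset
#'
#' Per allowed transition: the number of observed events `n_rs` and the
#' person-years at risk in the source state `T_r` (shared by both exits from
#' that state). These are the sufficient statistics of the covariate-free
#' exact-time likelihood.
#'
#' @param records A record tibble from [records_from_events()].
#' @return A tibble with columns `transition`, `from`, `to`, `n_events`,
#'   `person_years`.
#' @export
event_history_summary <- function(records) {
  allowed <- allowed_transitions()
  at_risk <- records |>
    dplyr::group_by(state = .data$state) |>
    dplyr::summarise(person_years = sum(.data$exit - .data$entry),
                     .groups = "drop")
  events <- records |>
    dplyr::filter(!is.na(.data$to)) |>
    dplyr::count(.data$state, .data$to, name = "n_events")
  allowed |>
    dplyr::left_join(events, by = c(from = "state", to = "to")) |>
    dplyr::left_join(at_risk, by = c(from = "state")) |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      person_years = dplyr::coalesce(.data$person_years, 0)
    ) |>
    dplyr::select("transition", "from", "to", "n_events", "person_years")
}
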