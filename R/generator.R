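# Per-year intensities for each allowed transition, one row per profile row.
# Returns an n x 7 matrix with columns named by transition key.
transition_rates <- function(params, profiles) {
  stopifnot(inherits(params, "msm_params"))
  keys <- allowed_transitions()$transition
  covs <- param_covariates(params)
  z <- code_covariates(profiles, covs, params$coding)
  rates <- vapply(keys, function(k) {
    b <- params$beta[[k]]
    lp <- if (length(b)) {
      drop(z[, names(b), drop = FALSE] %*% b)
    } else {
      rep(0, nrow(profiles))
    }
    exp(params$alpha[[k]] + lp)
  }, numeric(nrow(profiles)))
  matrix(rates, nrow = nrow(profiles), ncol = length(keys),
         dimnames = list(NULL, keys))
}

#' Build a covariate-specific generator matrix
#'
#' Assembles the 5x5 transition-intensity (generator) matrix for one
#' covariate profile: `q_rs = exp(alpha_rs + beta_rs . z)` on the seven
#' allowed transitions, zero elsewhere, the diagonal set so each row sums to
#' zero, and the death row identically zero.
#'
#' @param params An [model_parameters()] object.
#' @param profile A one-row data frame (see [reference_profile()]).
#' @return A 5x5 matrix of per-year intensities, dimnames = state labels.
#' @export
#' @examples
#' Q <- build_generator(dubbo_parameters("men"), reference_profile())
#' round(Q, 3)
build_generator <- function(params, profile = reference_profile()) {
  if (nrow(profile) != 1L) abort("`profile` must be a single row.")
  rates <- transition_rates(params, profile)[1L, ]
  if (any(!is.finite(rates))) {
    bad <- names(rates)[!is.finite(rates)]
    abort(paste0("Non-finite intensity for transition(s): ", toString(bad)))
  }
  generator_from_rates(rates)
}

# 5x5 generator from a named per-year rate vector keyed "r->s".
generator_from_rates <- function(rates) {
  allowed <- allowed_transitions()
  rates <- rates[allowed$transition]
  Q <- matrix(0, n_states(), n_states(),
              dimnames = list(state_labels(), state_labels()))
  Q[cbind(allowed$from, allowed$to)] <- rates
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition-probability matrix over a fixed horizon
#'
#' `P(t) = expm(t Q)`, the matrix exponential of the scaled generator,
#' giving the probability of occupying state `s` at time `t` for an
#' individual in state `r` at time 0 under time-constant intensities.
#'
#' @param Q A generator matrix from [build_generator()].
#' @param t Horizon in years (`t >= 0`).
#' @return A 5x5 row-stochastic matrix.
#' @export
#' @examples
#' Q <- build_generator(dubbo_parameters("men"))
#' round(100 * transition_probability(Q, 5), 1)
transition_probability <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    abort("`t` must be a single non-negative number of years.")
  }
  validate_generator(Q)
  if (t == 0) {
    return(diag(n_states()) |>
             `dimnames<-`(list(state_labels(), state_labels())))
  }
  P <- as.matrix(Matrix::expm(Q * t))
  # expm can leave O(eps) negatives; clamp without disturbing row sums
  P[P < 0 & P > -1e-12] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

#' Transition probabilities under piecewise-constant intensities
#'
#' When intensities change at known times (e.g. the age covariate is
#' refreshed), the horizon splits into segments with constant generators and
#' the overall transition matrix is the ordered product of the per-segment
#' matrix exponentials (Chapman-Kolmogorov).
#'
#' @param generators List of generator matrices, in time order.
#' @param durations Numeric vector of segment lengths (years), same length.
#' @return A 5x5 row-stochastic matrix; the identity for no segments.
#' @export
piecewise_transition_probability <- function(generators, durations) {
  if (length(generators) != length(durations)) {
    abort("`generators` and `durations` must have equal length.")
  }
  if (any(durations < 0)) abort("Segment durations must be non-negative.")
  P <- diag(n_states())
  dimnames(P) <- list(state_labels(), state_labels())
  for (i in seq_along(generators)) {
    P <- P %*% transition_probability(generators[[i]], durations[i])
  }
  P
}

#' Expected sojourn times per state
#'
#' The expected time an individual stays in a state before any exit is
#' `-1/q_rr` under time-constant intensities. The absorbing death state has
#' no sojourn; a transient state with all exit intensities zero gets an
#' infinite sojourn (flagged, not an error).
#'
#' @param Q A generator matrix.
#' @return A tibble with columns `state`, `label`, `sojourn_years`,
#'   `absorbing`.
#' @export
#' @examples
#' sojourn_times(build_generator(dubbo_parameters("men")))
sojourn_times <- function(Q) {
  validate_generator(Q)
  d <- unname(diag(Q))
  tibble::tibble(
    state = seq_len(n_states()),
    label = state_labels(),
    sojourn_years = dplyr::if_else(
      .data$state == absorbing_state(), NA_real_,
      dplyr::if_else(d == 0, Inf, -1 / d)
    ),
    absorbing = .data$state == absorbing_state()
  )
}
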