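#' The five bone-health states
#'
#' The model tracks an individual through five states: alive without an
#' incident fracture (1), first incident fracture (2), second fracture (3),
#' third or further fracture (4), and death (5). Death is absorbing; all
#' transitions are progressive (the destination index always exceeds the
#' source index), so recovery moves are structurally impossible.
#'
#' @return Character vector of length 5, ordered by state number.
#' @export
#' @examples
#' state_labels()
state_labels <- function() {
  c("no_fracture", "first_fracture", "second_fracture", "third_fracture",
    "death")
}

#' The seven allowed transitions
#'
#' From each pre-death state an individual can either progress to the next
#' fracture state or die: 1->2, 1->5, 2->3, 2->5, 3->4, 3->5, 4->5. State 4
#' absorbs all further fractures, so its only exit is death.
#'
#' @return A tibble with columns `from`, `to` (state numbers) and
#'   `transition` (a `"r->s"` key used to index parameters).
#' @export
#' @examples
#' allowed_transitions()
allowed_transitions <- function() {
  tibble::tibble(
    from = c(1L, 1L, 2L, 2L, 3L, 3L, 4L),
    to = c(2L, 5L, 3L, 5L, 4L, 5L, 5L),
    transition = transition_key(c(1, 1, 2, 2, 3, 3, 4), c(2, 5, 3, 5, 4, 5, 5))
  )
}

transition_key <- function(from, to) paste0(from, "->", to)

n_states <- function() 5L

absorbing_state <- function() 5L

is_allowed_transition <- function(from, to) {
  transition_key(from, to) %in% allowed_transitions()$transition
}

#' Validate a generator (intensity) matrix
#'
#' Checks the structural invariants of a 5x5 generator: non-negative
#' off-diagonal intensities confined to the allowed transitions, exact zeros
#' elsewhere, rows summing to zero, and an all-zero absorbing row.
#'
#' @param Q A 5x5 numeric matrix of per-year transition intensities.
#' @param tol Tolerance for the row-sum check (default `1e-10`).
#' @return `Q`, invisibly, if valid; otherwise an error.
#' @export
validate_generator <- function(Q, tol = 1e-10) {
  if (!is.matrix(Q) || any(dim(Q) != n_states())) {
    abort("`Q` must be a 5x5 numeric matrix.")
  }
  allowed <- allowed_transitions()
  mask <- matrix(FALSE, n_states(), n_states())
  mask[cbind(allowed$from, allowed$to)] <- TRUE
  off <- !diag(n_states()) & !mask
  if (any(Q[off] != 0)) {
    abort("Generator has non-zero intensities on disallowed transitions.")
  }
  if (any(Q[mask] < 0)) {
    abort("Generator has negative transition intensities.")
  }
  if (any(abs(rowSums(Q)) > tol)) {
    abort("Generator rows must sum to zero.")
  }
  if (any(Q[absorbing_state(), ] != 0)) {
    abort("The absorbing (death) row must be all zeros.")
  }
  invisible(Q)
}
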