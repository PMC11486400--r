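#' Session completion percentage
#'
#' Share of scheduled exercise sessions a participant completed, in
#' percent.
#'
#' @param completed sessions completed (vectorized).
#' @param total sessions scheduled (default 36: 3 sessions/week over a
#'   12-week intervention).
#' @return Percentages in \[0, 100\].
#' @export
session_completion_pct <- function(completed, total = 36) {
  stopifnot(all(is.finite(completed)), all(completed >= 0),
            all(completed <= total), total > 0)
  100 * completed / total
}

#' Adherence inclusion minimum
#'
#' The smallest number of completed sessions satisfying the adherence
#' fraction required for a participant's data to enter the analysis
#' (75% of 36 sessions = 27 in the reference protocol).
#'
#' @param total scheduled sessions.
#' @param fraction required adherence fraction.
#' @return Integer minimum number of sessions.
#' @export
adherence_minimum <- function(total = 36, fraction = 0.75) {
  stopifnot(total > 0, fraction > 0, fraction <= 1)
  as.integer(ceiling(fraction * total))
}
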