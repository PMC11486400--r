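#' Build a measurement series
#'
#' A measurement series is one participant x measure x side sequence of
#' repeated assessments stored long: one row per scheduled assessment with
#' its week index (1-based), phase label and value. Missing assessments are
#' kept as `NA` values rather than dropped, so downstream code always sees
#' the full schedule. Weeks must be strictly increasing and phases must
#' appear in temporal order (baseline, then intervention, then follow-up)
#' without interleaving.
#'
#' @param week integer week indices, strictly increasing.
#' @param phase phase labels (see [phase_labels()]).
#' @param value numeric values; `NA` marks a missed assessment.
#' @param participant,measure,side series key.
#' @return Tibble with columns `participant`, `measure`, `side`, `week`,
#'   `phase`, `value`.
#' @examples
#' s <- sced_series(1:8, rep(c("baseline", "intervention"), c(3, 5)),
#'                  c(64, 64, 65, 50, 50, 51, 50, 50))
#' phase_mean(s, "baseline")
#' @export
sced_series <- function(week, phase, value,
                        participant = "A", measure = "measure", side = "none") {
  stopifnot(length(week) == length(phase), length(week) == length(value))
  phase <- as_phase(phase)
  if (anyNA(phase)) stop("phase labels must not be missing", call. = FALSE)
  if (length(week) > 1 && any(diff(week) <= 0)) {
    stop("week indices must be strictly increasing", call. = FALSE)
  }
  if (is.unsorted(as.integer(phase))) {
    stop("phases must be non-interleaved and in order baseline < intervention < follow_up",
         call. = FALSE)
  }
  tibble::tibble(participant = participant, measure = measure, side = side,
                 week = as.integer(week), phase = phase,
                 value = as.numeric(value))
}

#' Extract the non-missing values of one phase
#'
#' Returns the available (non-missing) values of the requested phase in
#' time order. An empty vector is a legitimate result (e.g. a series with
#' no follow-up assessments); an unknown phase label is an error.
#'
#' @param series a series tibble (see [sced_series()]); any data frame with
#'   `week`, `phase` and `value` columns works.
#' @param phase one of `"baseline"`, `"intervention"`, `"follow_up"`.
#' @return Numeric vector, possibly empty.
#' @export
phase_values <- function(series, phase) {
  phase <- as.character(phase)
  stopifnot(length(phase) == 1L)
  as_phase(phase)  # errors on unknown labels
  rows <- series[as.character(series$phase) == phase & !is.na(series$value), ,
                 drop = FALSE]
  rows <- rows[order(rows$week), , drop = FALSE]
  as.numeric(rows$value)
}

#' Phase level (mean)
#'
#' The "level" of a phase is its arithmetic mean over available points.
#'
#' @inheritParams phase_values
#' @return Numeric scalar.
#' @export
phase_mean <- function(series, phase) {
  v <- phase_values(series, phase)
  if (length(v) == 0) {
    stop("phase '", phase, "' has no non-missing points; series unanalyzable",
         call. = FALSE)
  }
  mean(v)
}

#' Is a series analyzable?
#'
#' A series enters the visual analysis only when both the baseline and the
#' intervention phase hold at least three non-missing points; otherwise it
#' is flagged, never silently dropped.
#'
#' @inheritParams phase_values
#' @param min_points minimum non-missing points per analyzed phase.
#' @return Logical scalar with attribute `"reason"` when `FALSE`.
#' @export
series_analyzable <- function(series, min_points = 3L) {
  nb <- length(phase_values(series, "baseline"))
  ni <- length(phase_values(series, "intervention"))
  if (nb >= min_points && ni >= min_points) return(TRUE)
  structure(FALSE,
            reason = sprintf("needs >=%d non-missing points per phase (baseline: %d, intervention: %d)",
                             min_points, nb, ni))
}

#' Participant design plan
#'
#' One row of a staggered multiple-baseline design: the participant's
#' baseline duration in weeks (one assessment per baseline week) and the
#' number of intervention and follow-up assessment points.
#'
#' @param participant_id identifier.
#' @param baseline_weeks integer baseline duration (weeks, one data point
#'   per week).
#' @param age participant age in years (used by [hr_max()]); may be `NA`.
#' @param intervention_weeks intervention duration in weeks.
#' @param n_intervention_points,n_followup_points assessment points in the
#'   intervention and follow-up phases.
#' @return One-row tibble.
#' @export
participant_plan <- function(participant_id, baseline_weeks, age = NA_real_,
                             intervention_weeks = 12L,
                             n_intervention_points = 5L,
                             n_followup_points = 3L) {
  tibble::tibble(participant_id = as.character(participant_id),
                 age = as.numeric(age),
                 baseline_weeks = as.integer(baseline_weeks),
                 intervention_weeks = as.integer(intervention_weeks),
                 n_intervention_points = as.integer(n_intervention_points),
                 n_followup_points = as.integer(n_followup_points))
}

#' Validate a multiple-baseline design
#'
#' Checks a set of participant plans against the design standards for
#' single-case multiple-baseline studies: at least three participants, all
#' baselines starting concurrently at week 1, baseline durations staggered
#' (strictly increasing by one week per successive participant), and at
#' least three assessment points per phase. Violations are reported, not
#' raised, so a non-conforming design can still be described.
#'
#' @param plans tibble of plans (rows from [participant_plan()]).
#' @return Tibble of violations with columns `participant`, `rule`,
#'   `message`; zero rows means the design conforms.
#' @examples
#' validate_design(generate_design())        # no violations
#' validate_design(generate_design(n_participants = 2))
#' @export
validate_design <- function(plans) {
  stopifnot(nrow(plans) >= 1)
  v <- list()
  add <- function(participant, rule, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(participant = participant,
                                           rule = rule, message = message)
  }
  if (nrow(plans) < 3) {
    add(NA_character_, "min_participants",
        sprintf("fewer than three participants (%d)", nrow(plans)))
  }
  bw <- plans$baseline_weeks
  if (nrow(plans) > 1 && !all(diff(bw) == 1L)) {
    add(NA_character_, "staggered_baselines",
        "baseline durations must increase by exactly one week per successive participant")
  }
  for (i in seq_len(nrow(plans))) {
    p <- plans[i, ]
    if (p$baseline_weeks < 3L) {
      add(p$participant_id, "min_points_baseline",
          sprintf("baseline has %d points; at least 3 required", p$baseline_weeks))
    }
    if (p$n_intervention_points < 3L) {
      add(p$participant_id, "min_points_intervention",
          sprintf("intervention has %d points; at least 3 required",
                  p$n_intervention_points))
    }
    if (p$n_followup_points < 3L) {
      add(p$participant_id, "min_points_followup",
          sprintf("follow-up has %d points; at least 3 required",
                  p$n_followup_points))
    }
  }
  if (length(v) == 0) {
    tibble::tibble(participant = character(), rule = character(),
                   message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Split a long dataset into its component series
#'
#' @param data long tibble with columns `participant`, `measure`, `side`,
#'   `week`, `phase`, `value`.
#' @return Named list of series tibbles, keyed `participant.measure.side`,
#'   in a canonical (measure, participant, side) order.
#' @export
split_series <- function(data) {
  keys <- unique(data[, c("measure", "participant", "side")])
  keys <- keys[order(keys$measure, keys$participant, keys$side), , drop = FALSE]
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    s <- data[data$participant == k$participant &
                data$measure == k$measure & data$side == k$side, , drop = FALSE]
    s[order(s$week), , drop = FALSE]
  })
  names(out) <- paste(keys$participant, keys$measure, keys$side, sep = ".")
  out
}
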