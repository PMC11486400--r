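#' Gate configuration
#'
#' Thresholds and switches for the visual-analysis gate. Defaults encode
#' the conventions of single-case research synthesis: stability when at
#' least 80% of a phase's points fall within +/-15% of the phase median;
#' low variability when at most 20% of points fall outside the
#' two-standard-deviation band; an intervention effect signalled by PEM of
#' at least 70%; zero tolerated overlap between phase ranges; consistency
#' when at least 80% of participants share the modal improvement verdict.
#'
#' @param stability_min minimum stability percentage (both analyzed phases).
#' @param stability_strict if `TRUE` require strictly greater than
#'   `stability_min` instead of `>=`. The inclusive default reflects common
#'   reporting practice, where a phase at exactly 80% counts as stable.
#' @param variability_max maximum percentage of points outside the 2-SD band.
#' @param variability_reference which values define the 2-SD band:
#'   `"own_phase"` (the phase's own mean and SD), `"whole_series"` or
#'   `"baseline"`.
#' @param overlap_max maximum tolerated percentage of intervention points
#'   inside the baseline range.
#' @param pem_min minimum percentage of intervention points exceeding the
#'   baseline median in the therapeutic direction.
#' @param consistency_min minimum share of participants agreeing with the
#'   modal improvement verdict.
#' @param band_fraction half-width of the stability / trend band as a
#'   fraction of the absolute phase median.
#' @param median_epsilon absolute fallback half-width (measure units) when
#'   the phase median is zero, so scores near zero do not produce
#'   zero-width bands.
#' @param immediacy_min_change minimum absolute level change between the
#'   last three baseline and first three intervention points; the default 0
#'   accepts any direction-consistent change.
#' @param strict_monotone_trend if `TRUE`, classify trend by strict
#'   monotonicity instead of the least-squares slope band.
#' @param enabled character vector of gate criteria to enforce.
#' @return Named list of class `gate_config`.
#' @export
gate_config <- function(stability_min = 80,
                        stability_strict = FALSE,
                        variability_max = 20,
                        variability_reference = c("own_phase", "whole_series", "baseline"),
                        overlap_max = 0,
                        pem_min = 70,
                        consistency_min = 0.8,
                        band_fraction = 0.15,
                        median_epsilon = 0.5,
                        immediacy_min_change = 0,
                        strict_monotone_trend = FALSE,
                        enabled = c("level", "trend", "stability", "variability",
                                    "overlap", "immediacy", "pem", "consistency")) {
  variability_reference <- match.arg(variability_reference)
  structure(list(stability_min = stability_min,
                 stability_strict = stability_strict,
                 variability_max = variability_max,
                 variability_reference = variability_reference,
                 overlap_max = overlap_max,
                 pem_min = pem_min,
                 consistency_min = consistency_min,
                 band_fraction = band_fraction,
                 median_epsilon = median_epsilon,
                 immediacy_min_change = immediacy_min_change,
                 strict_monotone_trend = strict_monotone_trend,
                 enabled = enabled),
            class = "gate_config")
}

#' Read a gate configuration from YAML
#'
#' Top-level keys matching [gate_config()] arguments override the
#' defaults; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return `gate_config` list.
#' @export
read_gate_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(gate_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    stop("unknown gate configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(gate_config, cfg)
}

# band half-width around a phase median; absolute fallback when median == 0
.median_band <- function(med, band_fraction, epsilon) {
  if (med == 0) epsilon else band_fraction * abs(med)
}

#' Classify the trend of a phase
#'
#' Operationalizes "monotonically increasing or decreasing" as a
#' least-squares slope classifier: the slope over the point index is
#' projected across the phase (`slope * (n - 1)`), and when the projected
#' change stays within `band_fraction` of the absolute phase median the
#' phase is called stable; otherwise the slope sign gives the direction.
#' Strict monotonicity (available via `strict_monotone`) is rarely useful
#' on noisy series, which is why the band classifier is the default.
#'
#' @param values ordered phase values (at least 3).
#' @param band_fraction stable-band half-width as fraction of |median|.
#' @param epsilon absolute fallback band when the median is zero.
#' @param strict_monotone use strict monotonicity instead of the slope band.
#' @return `"upward"`, `"downward"` or `"stable"`.
#' @examples
#' classify_trend(c(14, 13, 12, 11, 10))  # downward
#' @export
classify_trend <- function(values, band_fraction = 0.15, epsilon = 0.5,
                           strict_monotone = FALSE) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("trend classification needs at least 3 points", call. = FALSE)
  if (strict_monotone) {
    d <- diff(values)
    if (all(d > 0)) return("upward")
    if (all(d < 0)) return("downward")
    return("stable")
  }
  x <- seq_len(n)
  slope <- sum((x - mean(x)) * (values - mean(values))) / sum((x - mean(x))^2)
  projected <- slope * (n - 1)
  band <- .median_band(median(values), band_fraction, epsilon)
  if (abs(projected) <= band) "stable" else if (slope > 0) "upward" else "downward"
}

#' Within-phase stability
#'
#' Percentage of phase points falling within +/-`band_fraction` of the
#' phase median (band boundaries inclusive). The band is relative to the
#' absolute median, with an absolute fallback when the median is zero.
#'
#' @inheritParams classify_trend
#' @return Percentage in \[0, 100\], a multiple of `100 / n`.
#' @examples
#' stability_pct(c(10, 10, 10, 10, 20))  # 80
#' @export
stability_pct <- function(values, band_fraction = 0.15, epsilon = 0.5) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 1)
  med <- median(values)
  half <- .median_band(med, band_fraction, epsilon)
  100 * mean(values >= med - half & values <= med + half)
}

#' Within-phase variability (two-standard-deviation band)
#'
#' Percentage of phase points falling outside the band formed by the
#' reference mean plus/minus two reference standard deviations. By default
#' the reference is the phase itself; the gate can instead reference the
#' whole series or the baseline phase (see
#' [gate_config()]`$variability_reference`), since own-phase referencing
#' bounds the exceedance at 25% for small phases and alternative
#' references are sometimes needed to reproduce published variability
#' figures.
#'
#' A zero-spread reference cannot classify values away from its mean: when
#' the reference SD is zero and any assessed value differs from the
#' reference mean, the band is undefined and an error is raised (an
#' all-constant phase still returns 0).
#'
#' @param values phase values to assess.
#' @param reference_values values defining the band (default: the phase
#'   itself); needs at least 2 points.
#' @return Percentage in \[0, 100\].
#' @export
variability_pct <- function(values, reference_values = values) {
  values <- values[!is.na(values)]
  reference_values <- reference_values[!is.na(reference_values)]
  stopifnot(length(values) >= 1)
  if (length(reference_values) < 2) {
    stop("reference needs at least 2 points for an SD", call. = FALSE)
  }
  m <- mean(reference_values)
  s <- sd(reference_values)
  if (s == 0) {
    if (all(values == m)) return(0)
    stop("reference SD is zero: two-standard-deviation band undefined",
         call. = FALSE)
  }
  100 * mean(values < m - 2 * s | values > m + 2 * s)
}

#' Between-phase overlap
#'
#' Percentage of intervention points lying within the closed range of the
#' baseline values. Zero overlap is the strongest visual separation
#' between phases.
#'
#' @param baseline,intervention phase value vectors (non-empty).
#' @return Percentage in \[0, 100\].
#' @export
overlap_pct <- function(baseline, intervention) {
  baseline <- baseline[!is.na(baseline)]
  intervention <- intervention[!is.na(intervention)]
  stopifnot(length(baseline) >= 1, length(intervention) >= 1)
  rng <- range(baseline)
  100 * mean(intervention >= rng[1] & intervention <= rng[2])
}

#' Immediacy of effect
#'
#' Change in level between the last three baseline points and the first
#' three intervention points. The effect is immediate when the change goes
#' in the therapeutic direction and its magnitude exceeds `min_change`
#' (default 0: any direction-consistent change counts). Phases with fewer
#' than three points are compared on the available points and flagged.
#'
#' @param baseline,intervention phase value vectors (non-empty).
#' @param direction therapeutic direction, `"decrease"` or `"increase"`.
#' @param min_change minimum absolute level change.
#' @return List with `met` (logical), `magnitude` (level change), and the
#'   number of points used from each phase.
#' @export
immediacy <- function(baseline, intervention,
                      direction = c("decrease", "increase"), min_change = 0) {
  direction <- match.arg(direction)
  baseline <- baseline[!is.na(baseline)]
  intervention <- intervention[!is.na(intervention)]
  if (length(baseline) == 0 || length(intervention) == 0) {
    stop("immediacy needs non-empty baseline and intervention phases",
         call. = FALSE)
  }
  b <- tail(baseline, 3)
  i <- head(intervention, 3)
  magnitude <- mean(i) - mean(b)
  toward <- if (direction == "decrease") magnitude < 0 else magnitude > 0
  list(met = toward && abs(magnitude) > min_change,
       magnitude = magnitude,
       n_baseline_used = length(b),
       n_intervention_used = length(i),
       flagged_short = length(b) < 3 || length(i) < 3)
}

#' Percentage of data exceeding the median (PEM)
#'
#' Share of intervention points strictly better than the baseline median
#' in the therapeutic direction. Ties with the median do not count as
#' exceeding. Categories follow the usual effect bands: below 70% no
#' effect, 70-90% a moderate effect, above 90% a high effect.
#'
#' @inheritParams immediacy
#' @return List with `pct` and `category` (`"none"`, `"moderate"`,
#'   `"high"`).
#' @examples
#' pem(c(64, 64, 65), c(50, 65, 50, 50, 50), "decrease")
#' @export
pem <- function(baseline, intervention,
                direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  baseline <- baseline[!is.na(baseline)]
  intervention <- intervention[!is.na(intervention)]
  stopifnot(length(baseline) >= 1, length(intervention) >= 1)
  med <- median(baseline)
  better <- if (direction == "decrease") intervention < med else intervention > med
  pct <- 100 * mean(better)
  category <- if (pct < 70) "none" else if (pct <= 90) "moderate" else "high"
  list(pct = pct, category = category)
}

#' Consistency of improvement across participants
#'
#' In a multiple-baseline design a causal interpretation is supported when
#' the same pattern appears across participants. Consistency is the share
#' of participants whose improvement verdict (level change in the
#' therapeutic direction, yes/no) matches the modal verdict; the criterion
#' is met when that share reaches the configured threshold. With fewer
#' than two participants the criterion is not evaluable and passes
#' vacuously, flagged as such.
#'
#' @param improved logical vector, one improvement verdict per participant.
#' @param threshold minimum modal share (default 0.8).
#' @return List with `fraction`, `met`, `modal_improved` and `evaluable`.
#' @export
consistency <- function(improved, threshold = 0.8) {
  improved <- as.logical(improved)
  if (length(improved) < 2) {
    return(list(fraction = NA_real_, met = TRUE,
                modal_improved = NA, evaluable = FALSE))
  }
  share_true <- mean(improved)
  fraction <- max(share_true, 1 - share_true)
  list(fraction = fraction,
       met = fraction >= threshold,
       modal_improved = share_true >= 0.5,
       evaluable = TRUE)
}

# which trend direction counts as improving for a measure
.improving_trend <- function(direction) {
  if (direction == "decrease") "downward" else "upward"
}

#' Evaluate the visual-analysis gate for one series
#'
#' Computes the within-phase summaries (level, trend, stability,
#' variability) for every phase present and the between-phase summaries
#' (level change, overlap, immediacy, PEM) for baseline versus
#' intervention, then evaluates the enabled gate criteria:
#'
#' * `level` — the intervention level changed in the therapeutic direction;
#' * `trend` — baseline stable, and intervention trending in the improving
#'   direction or stable alongside a level change;
#' * `stability` — stability meets the threshold in both analyzed phases;
#' * `variability` — 2-SD-band exceedance at or below the threshold in
#'   both analyzed phases;
#' * `overlap` — overlap percentage at or below the threshold;
#' * `immediacy` — immediate direction-consistent level change;
#' * `pem` — PEM at or above the threshold;
#' * `consistency` — cross-participant agreement (supplied via
#'   `consistency_result` by the study-level pipeline; vacuous for an
#'   isolated series).
#'
#' The overall verdict is the conjunction of the enabled criteria and
#' controls entry to the randomization test. Follow-up summaries are
#' computed when points exist but never contribute to the verdict.
#'
#' @param series a series tibble (see [sced_series()]).
#' @param spec one-row measure registry entry (see [measure_spec()]).
#' @param config a [gate_config()].
#' @param consistency_result optional result of [consistency()] for this
#'   measure/side across participants.
#' @return Object of class `gate_decision`: list with `criteria` (named
#'   logicals), `overall`, `within` (tibble), `between` (list), `notes`.
#' @export
evaluate_gate <- function(series, spec, config = gate_config(),
                          consistency_result = NULL) {
  ok <- series_analyzable(series)
  if (!isTRUE(ok)) {
    stop("series not analyzable: ", attr(ok, "reason"), call. = FALSE)
  }
  direction <- spec$direction
  bl <- phase_values(series, "baseline")
  iv <- phase_values(series, "intervention")
  fu <- phase_values(series, "follow_up")
  all_values <- c(bl, iv, fu)

  ref_for <- function(own) {
    switch(config$variability_reference,
           own_phase = own, whole_series = all_values, baseline = bl)
  }
  within_row <- function(phase, v) {
    tibble::tibble(
      phase = phase,
      n_points = length(v),
      level = if (length(v) >= 1) mean(v) else NA_real_,
      trend = if (length(v) >= 3)
        classify_trend(v, config$band_fraction, config$median_epsilon,
                       config$strict_monotone_trend) else NA_character_,
      stability_pct = if (length(v) >= 1)
        stability_pct(v, config$band_fraction, config$median_epsilon) else NA_real_,
      variability_pct = if (length(v) >= 2 && length(ref_for(v)) >= 2)
        variability_pct(v, ref_for(v)) else NA_real_)
  }
  within <- dplyr::bind_rows(within_row("baseline", bl),
                             within_row("intervention", iv),
                             if (length(fu) > 0) within_row("follow_up", fu))

  level_change <- mean(iv) - mean(bl)
  level_improved <- if (direction == "decrease") level_change < 0 else level_change > 0
  imm <- immediacy(bl, iv, direction, config$immediacy_min_change)
  pm <- pem(bl, iv, direction)
  ovl <- overlap_pct(bl, iv)
  between <- list(level_change = level_change,
                  level_improved = level_improved,
                  overlap_pct = ovl,
                  immediacy = imm$met,
                  immediacy_magnitude = imm$magnitude,
                  pem_pct = pm$pct,
                  pem_category = pm$category)

  w <- function(phase, col) within[[col]][within$phase == phase]
  meets_stability <- function(x) {
    if (config$stability_strict) x > config$stability_min else x >= config$stability_min
  }
  trend_ok <- identical(w("baseline", "trend"), "stable") &&
    (identical(w("intervention", "trend"), .improving_trend(direction)) ||
       (identical(w("intervention", "trend"), "stable") && level_improved))
  cons <- if (is.null(consistency_result)) {
    list(met = TRUE, evaluable = FALSE, fraction = NA_real_)
  } else consistency_result

  criteria <- c(
    level = level_improved,
    trend = trend_ok,
    stability = meets_stability(w("baseline", "stability_pct")) &&
      meets_stability(w("intervention", "stability_pct")),
    variability = isTRUE(w("baseline", "variability_pct") <= config$variability_max) &&
      isTRUE(w("intervention", "variability_pct") <= config$variability_max),
    overlap = ovl <= config$overlap_max,
    immediacy = imm$met,
    pem = pm$pct >= config$pem_min,
    consistency = isTRUE(cons$met)
  )
  enabled <- intersect(config$enabled, names(criteria))
  notes <- character()
  if (!isTRUE(cons$evaluable) && "consistency" %in% enabled) {
    notes <- c(notes, "consistency not evaluable (<2 participants); passes vacuously")
  }
  if (isTRUE(imm$flagged_short)) {
    notes <- c(notes, "immediacy computed on fewer than 3 points per phase")
  }
  structure(list(criteria = criteria,
                 overall = all(criteria[enabled]),
                 enabled = enabled,
                 within = within,
                 between = between,
                 notes = notes),
            class = "gate_decision")
}

#' @export
print.gate_decision <- function(x, ...) {
  cat("Visual-analysis gate:", if (x$overall) "PASS" else "FAIL", "\n")
  flags <- ifelse(x$criteria, "pass", "fail")
  marked <- ifelse(names(x$criteria) %in% x$enabled, "", " (disabled)")
  cat(paste0("  ", format(names(x$criteria), width = 12), flags, marked,
             collapse = "\n"), "\n")
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
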