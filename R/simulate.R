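#' Generate a staggered multiple-baseline design
#'
#' Builds the participant plans of a concurrent multiple-baseline study:
#' all participants start the baseline concurrently at week 1; baseline
#' durations start at `first_baseline_weeks` and increase by one week per
#' successive participant (3-7 weeks for five participants); the
#' intervention lasts 12 weeks with five assessment points; three
#' follow-up assessments occur 4, 8 and 12 weeks after the intervention
#' ends.
#'
#' @param n_participants number of participants (default 5).
#' @param first_baseline_weeks baseline duration of the first participant.
#' @param ages participant ages in years; the default mirrors a five-woman
#'   RRMS cohort in their fifties and is recycled for other sizes.
#' @return Tibble of participant plans (see [participant_plan()]).
#' @examples
#' generate_design()$baseline_weeks  # 3 4 5 6 7
#' @export
generate_design <- function(n_participants = 5, first_baseline_weeks = 3,
                            ages = c(56, 56, 47, 52, 59)) {
  stopifnot(n_participants >= 1, first_baseline_weeks >= 1)
  ages <- rep(ages, length.out = n_participants)
  dplyr::bind_rows(lapply(seq_len(n_participants), function(i) {
    participant_plan(participant_id = LETTERS[i],
                     baseline_weeks = first_baseline_weeks + (i - 1L),
                     age = ages[i])
  }))
}

#' Assessment schedule for one participant
#'
#' Week indices (1-based, from study start) at which a participant is
#' assessed: once per baseline week; five intervention assessments at
#' intervention weeks 3-7 (weekly once intervention assessments begin);
#' follow-up assessments 4, 8 and 12 weeks after the 12-week intervention
#' ends.
#'
#' @param plan one-row participant plan.
#' @return Tibble with `week` and `phase`.
#' @export
assessment_schedule <- function(plan) {
  bw <- plan$baseline_weeks
  iv_weeks <- bw + seq(3L, length.out = plan$n_intervention_points)
  fu_weeks <- bw + plan$intervention_weeks + c(4L, 8L, 12L)[seq_len(plan$n_followup_points)]
  tibble::tibble(
    week = c(seq_len(bw), iv_weeks, fu_weeks),
    phase = as_phase(rep(.phase_levels, c(bw, length(iv_weeks), length(fu_weeks)))))
}

#' Define a simulation scenario
#'
#' A scenario fixes the generative conditions of a synthetic dataset: the
#' measure, the per-side phase levels, the noise level, an optional AR(1)
#' serial-correlation coefficient, and an optional missing-assessment
#' pattern. Values are generated as `phase level + noise`: a pure
#' step-change model at intervention onset, which is the structure the
#' visual analysis and the randomization test assume.
#'
#' @param name scenario identifier.
#' @param measure one-row measure registry entry.
#' @param levels named list of per-side numeric length-3 vectors
#'   `(baseline, intervention, follow-up)`; names are sides (`left`,
#'   `right`, or `none`).
#' @param noise_sd standard deviation of the Gaussian noise, in measure
#'   units (>= 0).
#' @param missing optional tibble with columns `participant`, `phase`,
#'   `index` marking scheduled assessments to blank out (index counted
#'   within the phase).
#' @param ar1 lag-1 autocorrelation of the noise (default 0, i.e. iid);
#'   nonzero values stress-test the exchangeability assumption of the
#'   randomization test.
#' @return List of class `scenario_spec`.
#' @export
make_scenario <- function(name, measure, levels, noise_sd, missing = NULL,
                          ar1 = 0) {
  stopifnot(is.numeric(noise_sd), noise_sd >= 0, abs(ar1) < 1)
  lv <- unlist(levels)
  if (measure$units == "%MSO" && (any(lv <= 0) || any(lv > 100))) {
    stop("%MSO levels must lie in (0, 100]", call. = FALSE)
  }
  if (measure$units == "ms" && any(lv <= 0)) {
    stop("latency levels must be strictly positive", call. = FALSE)
  }
  structure(list(name = name, measure = measure, levels = levels,
                 noise_sd = noise_sd, missing = missing, ar1 = ar1),
            class = "scenario_spec")
}

#' Built-in scenarios
#'
#' Named generative fixtures whose magnitudes mirror the group-level
#' patterns of a bilateral TMS exercise study:
#'
#' * `"rmt_effect"` — resting motor threshold with a clear bilateral
#'   step improvement (left 64 to 50 %MSO, right 62 to 52 %MSO, follow-up
#'   returning to baseline levels) and low noise (SD 0.8 %MSO); includes
#'   the participant-E missing-assessment pattern (one baseline and one
#'   intervention point missed).
#' * `"cmct_null_highvar"` — central motor conduction time with no
#'   intervention effect and noise of 15% of the level, emulating the
#'   unstable, high-variability series for which the visual analysis
#'   withholds statistical testing.
#' * `"clinical_clean"` — a unilateral clinical balance score with a
#'   noiseless step improvement and a follow-up regression toward
#'   baseline, reproducing the 100%-stability / zero-overlap pattern.
#'
#' @param name one of `"rmt_effect"`, `"cmct_null_highvar"`,
#'   `"clinical_clean"`.
#' @param registry measure registry supplying the measure definitions.
#' @return A `scenario_spec` (see [make_scenario()]).
#' @export
scenario <- function(name = c("rmt_effect", "cmct_null_highvar", "clinical_clean"),
                     registry = default_measure_registry()) {
  name <- match.arg(name)
  switch(name,
    rmt_effect = make_scenario(
      "rmt_effect",
      get_measure_spec(registry, "rmt"),
      levels = list(left = c(64, 50, 65), right = c(62, 52, 62)),
      noise_sd = 0.8,
      missing = tibble::tibble(participant = c("E", "E"),
                               phase = c("baseline", "intervention"),
                               index = c(7L, 4L))),
    cmct_null_highvar = make_scenario(
      "cmct_null_highvar",
      get_measure_spec(registry, "cmct"),
      levels = list(left = c(13, 13, 13), right = c(11, 11, 11)),
      noise_sd = 1.8),
    clinical_clean = make_scenario(
      "clinical_clean",
      get_measure_spec(registry, "minibest"),
      levels = list(none = c(20, 26, 22)),
      noise_sd = 0))
}

# one AR(1) noise path; rho = 0 reduces to iid N(0, sd^2)
.noise_path <- function(n, sd, rho) {
  if (sd == 0) return(rep(0, n))
  z <- rnorm(n, 0, sd)
  if (rho == 0) return(z)
  e <- numeric(n)
  e[1] <- z[1]
  for (t in seq_len(n)[-1]) e[t] <- rho * e[t - 1] + sqrt(1 - rho^2) * z[t]
  e
}

#' Generate a synthetic multiple-baseline dataset
#'
#' Simulates every participant x side series of a scenario on the
#' staggered schedule: each scheduled value is the scenario's phase level
#' for that side plus Gaussian noise. Identical seeds produce
#' bit-identical datasets. Missing assessments from the scenario's
#' pattern are blanked to `NA` (the schedule row is kept).
#'
#' @param scen a `scenario_spec` (see [scenario()], [make_scenario()]).
#' @param plans participant plans, default [generate_design()].
#' @param seed integer seed.
#' @return Long tibble with columns `participant`, `measure`, `side`,
#'   `week`, `phase`, `value`.
#' @examples
#' d <- generate_series(scenario("rmt_effect"), seed = 1)
#' dplyr::count(d, phase)
#' @export
generate_series <- function(scen, plans = generate_design(), seed = 1) {
  stopifnot(inherits(scen, "scenario_spec"))
  sides <- names(scen$levels)
  build <- function() {
    rows <- list()
    for (i in seq_len(nrow(plans))) {
      plan <- plans[i, ]
      sched <- assessment_schedule(plan)
      for (side in sides) {
        lv <- scen$levels[[side]]
        level <- lv[as.integer(sched$phase)]
        value <- level + .noise_path(nrow(sched), scen$noise_sd, scen$ar1)
        if (!is.null(scen$missing)) {
          mp <- scen$missing[scen$missing$participant == plan$participant_id, ,
                             drop = FALSE]
          for (j in seq_len(nrow(mp))) {
            in_phase <- which(as.character(sched$phase) == mp$phase[j])
            if (mp$index[j] <= length(in_phase)) {
              value[in_phase[mp$index[j]]] <- NA_real_
            }
          }
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          participant = plan$participant_id,
          measure = scen$measure$name,
          side = side,
          week = sched$week,
          phase = sched$phase,
          value = value)
      }
    }
    dplyr::bind_rows(rows)
  }
  withr::with_seed(as.integer(seed), build())
}

#' Generate a synthetic MEP trace
#'
#' Builds one EMG sweep for the trace-level operations: flat Gaussian
#' noise over a pre-stimulus window, then a biphasic response template
#' (one sine period of 10 ms) starting at the programmed onset latency
#' with the programmed peak-to-peak amplitude, plus additive noise
#' throughout. With zero noise, [detect_mep_onset()] recovers the onset
#' to within one sample period and [peak_to_peak_amplitude()] recovers
#' the amplitude exactly.
#'
#' @param amplitude programmed peak-to-peak amplitude in mV (>= 0; 0
#'   produces a no-response trace).
#' @param onset_latency programmed onset in ms after the stimulus.
#' @param noise_sd additive Gaussian noise SD in mV.
#' @param sampling_rate sampling rate in Hz (default 24 kHz).
#' @param pre_stimulus_ms pre-stimulus window length in ms.
#' @param duration_ms post-stimulus window length in ms.
#' @param seed optional integer seed for reproducible noise.
#' @return An [mep_trace()].
#' @export
generate_mep_trace <- function(amplitude, onset_latency, noise_sd = 0,
                               sampling_rate = 24000, pre_stimulus_ms = 20,
                               duration_ms = 80, seed = NULL) {
  stopifnot(amplitude >= 0, noise_sd >= 0)
  if (onset_latency < 0 || onset_latency >= duration_ms) {
    stop("onset latency must lie within the post-stimulus window", call. = FALSE)
  }
  n_pre <- round(pre_stimulus_ms * sampling_rate / 1000)
  n_post <- round(duration_ms * sampling_rate / 1000)
  n <- n_pre + n_post
  stim_idx <- n_pre + 1L
  build <- function() {
    samples <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else rep(0, n)
    if (amplitude > 0) {
      t_post <- (seq_len(n_post) - 1L) / sampling_rate * 1000  # ms after stimulus
      in_resp <- t_post >= onset_latency & t_post < onset_latency + 10
      wave <- 0.5 * amplitude * sin(2 * pi * (t_post[in_resp] - onset_latency) / 10)
      samples[stim_idx - 1L + which(in_resp)] <-
        samples[stim_idx - 1L + which(in_resp)] + wave
    }
    samples
  }
  samples <- if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
  mep_trace(samples, sampling_rate, stim_idx)
}
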