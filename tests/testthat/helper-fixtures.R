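# Build a series tibble from per-phase value vectors (weeks assigned
# consecutively; NA values stand for missed assessments).
mk_series <- function(baseline, intervention, follow_up = numeric(),
                      participant = "A", measure = "rmt", side = "left") {
  n <- c(length(baseline), length(intervention), length(follow_up))
  sced_series(week = seq_len(sum(n)),
              phase = rep(c("baseline", "intervention", "follow_up"), n),
              value = c(baseline, intervention, follow_up),
              participant = participant, measure = measure, side = side)
}

# Independent rank-based oracle for NAP: the tie-corrected Mann-Whitney U
# of the intervention sample over the combined midranks, divided by nA*nB.
# Shares no code with nap().
nap_rank_oracle <- function(baseline, intervention, direction) {
  r <- rank(c(baseline, intervention))
  nB <- length(intervention)
  u <- sum(r[seq(length(baseline) + 1, length(r))]) - nB * (nB + 1) / 2
  up <- u / (length(baseline) * nB)  # P(intervention > baseline) + 0.5 ties
  if (direction == "increase") up else 1 - up
}

# Independent brute-force randomization-test oracle: enumerate every
# assignment with combn and score it with the rank-based statistic above.
exact_p_oracle <- function(baseline, intervention, direction) {
  x <- c(baseline, intervention)
  nB <- length(intervention)
  idx <- combn(length(x), nB)
  stats <- apply(idx, 2, function(j) nap_rank_oracle(x[-j], x[j], direction))
  obs <- nap_rank_oracle(baseline, intervention, direction)
  mean(abs(stats - 0.5) >= abs(obs - 0.5) - 1e-12)
}
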