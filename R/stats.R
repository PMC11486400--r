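#' Nonoverlap of all pairs (NAP)
#'
#' The probability that a randomly chosen intervention point is better
#' than a randomly chosen baseline point in the therapeutic direction,
#' with ties counted as half: over all `nA x nB` cross-phase pairs,
#' `NAP = (improved pairs + 0.5 * tied pairs) / (nA * nB)`. A value of 1
#' is complete nonoverlap (every intervention point better than every
#' baseline point); 0.5 indicates chance-level separation.
#'
#' The statistic is computed by explicit enumeration of all pairs; it is
#' rank-based, so it is invariant under strictly increasing transforms of
#' the data.
#'
#' @param baseline,intervention phase value vectors (non-empty; `NA`s
#'   removed).
#' @param direction therapeutic direction: does improvement mean a
#'   `"decrease"` or an `"increase"`?
#' @return NAP in \[0, 1\].
#' @examples
#' nap(c(10, 9, 11, 10), c(9, 8, 8, 10, 7), "decrease")  # 0.875
#' @export
nap <- function(baseline, intervention,
                direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  baseline <- baseline[!is.na(baseline)]
  intervention <- intervention[!is.na(intervention)]
  if (length(baseline) == 0 || length(intervention) == 0) {
    stop("NAP needs non-empty baseline and intervention phases", call. = FALSE)
  }
  better <- if (direction == "decrease") {
    outer(intervention, baseline, `<`)
  } else {
    outer(intervention, baseline, `>`)
  }
  ties <- outer(intervention, baseline, `==`)
  (sum(better) + 0.5 * sum(ties)) / (length(baseline) * length(intervention))
}

# deterministic per-series seed derivation from a study-level seed, < 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %% 2147483629) + 1L
}

#' Randomization test for a two-phase series
#'
#' Tests exchangeability of the phase labels within one series: under the
#' null hypothesis that the intervention has no effect, the observed
#' `nA + nB` values could have fallen in either phase, so the reference
#' distribution reassigns them to phases of the observed sizes. The
#' two-sided p-value is the proportion of assignments whose statistic is
#' at least as far from its null center (0.5 for NAP, 0 for the mean
#' difference) as the observed one; the observed assignment is always part
#' of the count, so p is never zero.
#'
#' All `choose(nA + nB, nB)` assignments are enumerated exactly when their
#' number does not exceed `max_exact`; otherwise a seeded Monte-Carlo
#' sample is drawn and the observed assignment is added to both numerator
#' and denominator.
#'
#' @inheritParams nap
#' @param statistic test statistic: `"nap"` (default) or
#'   `"mean_difference"`.
#' @param max_exact largest number of assignments enumerated exactly.
#' @param n_resamples Monte-Carlo sample size when enumeration is
#'   infeasible.
#' @param seed integer seed for the Monte-Carlo scheme (ignored under
#'   exact enumeration).
#' @return List with `p_value`, `scheme` (`"exact_enumeration"` or
#'   `"monte_carlo"`), `statistic` (the observed value), `n_assignments`
#'   (denominator of the exact scheme) or `n_resamples`, and `seed`.
#' @examples
#' randomization_p(c(64, 64, 65), c(50, 50, 51, 50, 50), "decrease")
#' @export
randomization_p <- function(baseline, intervention,
                            direction = c("decrease", "increase"),
                            statistic = c("nap", "mean_difference"),
                            max_exact = 50000, n_resamples = 10000,
                            seed = NULL) {
  direction <- match.arg(direction)
  statistic <- match.arg(statistic)
  baseline <- baseline[!is.na(baseline)]
  intervention <- intervention[!is.na(intervention)]
  if (length(baseline) == 0 || length(intervention) == 0) {
    stop("randomization test needs non-empty phases", call. = FALSE)
  }
  x <- c(baseline, intervention)
  n <- length(x)
  nB <- length(intervention)
  nA <- n - nB
  center <- if (statistic == "nap") 0.5 else 0
  if (statistic == "nap") {
    # pairwise improvement matrix shared by all assignments: M[i, j] is 1
    # when value i beats value j in the therapeutic direction, 0.5 on ties
    cmp <- if (direction == "decrease") outer(x, x, `<`) else outer(x, x, `>`)
    M <- cmp + 0.5 * outer(x, x, `==`)
    row_tot <- rowSums(M)
    stat_fun <- function(idx) (sum(row_tot[idx]) - sum(M[idx, idx])) / (nA * nB)
  } else {
    stat_fun <- function(idx) mean(x[idx]) - mean(x[-idx])
  }
  obs <- stat_fun(seq(n - nB + 1L, n))
  dev_obs <- abs(obs - center)
  tol <- 1e-12
  n_assign <- choose(n, nB)

  if (n_assign <= max_exact) {
    combs <- combn(n, nB)
    devs <- vapply(seq_len(ncol(combs)),
                   function(j) abs(stat_fun(combs[, j]) - center),
                   numeric(1))
    p <- mean(devs >= dev_obs - tol)
    return(list(p_value = p, scheme = "exact_enumeration", statistic = obs,
                n_assignments = as.integer(n_assign), seed = NA_integer_))
  }

  run_mc <- function() {
    hits <- 0L
    for (b in seq_len(n_resamples)) {
      idx <- sample.int(n, nB)
      if (abs(stat_fun(idx) - center) >= dev_obs - tol) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_resamples)
  }
  p <- if (is.null(seed)) run_mc() else withr::with_seed(seed, run_mc())
  list(p_value = p, scheme = "monte_carlo", statistic = obs,
       n_resamples = as.integer(n_resamples),
       seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Multiple-baseline start-point randomization test
#'
#' Design-based alternative to the within-series label permutation: in a
#' staggered multiple-baseline design the intervention onsets were
#' assigned to participants, so under the null hypothesis any assignment
#' of the observed stagger onsets to participants was equally likely.
#' Each permutation re-splits every participant's series at the permuted
#' onset week (points before the onset count as baseline, later
#' non-follow-up points as intervention) and the combined statistic is
#' the sum over participants of the direction-adjusted improvement
#' (baseline mean minus intervention mean for `"decrease"` measures and
#' the reverse for `"increase"`). The two-sided p-value is the share of
#' assignments with `|T|` at least the observed `|T|`, observed included.
#'
#' All `n!` assignments are enumerated for up to `max_participants`
#' participants (120 permutations for five), which covers realistic
#' multiple-baseline panels.
#'
#' @param series_list list of series tibbles for one measure/side, one
#'   per participant, each with its realized staggered onset.
#' @param direction therapeutic direction of the measure.
#' @param max_participants guard on exact enumeration size.
#' @return List with `p_value`, `statistic` (observed combined
#'   improvement), `n_assignments` and `onsets` (the stagger weeks).
#' @export
mb_startpoint_p <- function(series_list,
                            direction = c("decrease", "increase"),
                            max_participants = 7) {
  direction <- match.arg(direction)
  n <- length(series_list)
  if (n < 2) stop("start-point test needs at least 2 participants", call. = FALSE)
  if (n > max_participants) {
    stop("exact start-point enumeration limited to ", max_participants,
         " participants", call. = FALSE)
  }
  onsets <- vapply(series_list, function(s) {
    min(s$week[as.character(s$phase) == "intervention"])
  }, numeric(1))
  # per-participant improvement if the onset had been at week w
  improvement_at <- function(s, w) {
    keep <- as.character(s$phase) != "follow_up" & !is.na(s$value)
    wk <- s$week[keep]; v <- s$value[keep]
    bl <- v[wk < w]; iv <- v[wk >= w]
    if (length(bl) == 0 || length(iv) == 0) return(NA_real_)
    d <- mean(iv) - mean(bl)
    if (direction == "decrease") -d else d
  }
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  all_assign <- perms(onsets)
  stats <- vapply(all_assign, function(assigned) {
    sum(vapply(seq_len(n),
               function(j) improvement_at(series_list[[j]], assigned[j]),
               numeric(1)), na.rm = TRUE)
  }, numeric(1))
  obs <- sum(vapply(seq_len(n),
                    function(j) improvement_at(series_list[[j]], onsets[j]),
                    numeric(1)), na.rm = TRUE)
  list(p_value = mean(abs(stats) >= abs(obs) - 1e-12),
       statistic = obs,
       n_assignments = length(all_assign),
       onsets = unname(onsets))
}

#' Bonferroni-corrected significance level
#'
#' `alpha / n_tests`. In the bilateral-testing convention used here,
#' `n_tests` is the number of body sides tested for the same measure
#' (0.05 / 2 = 0.025 when both upper limbs are tested).
#'
#' @param alpha nominal level in (0, 1).
#' @param n_tests number of tests performed (>= 1).
#' @return Corrected level.
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(n_tests) || length(n_tests) != 1 || n_tests < 1) {
    stop("n_tests must be a positive integer", call. = FALSE)
  }
  alpha / n_tests
}

#' Inter-assessor agreement
#'
#' Fraction of co-scored data points on which two independent assessors
#' agree to within `tolerance`. The study convention checks at least 20%
#' of the points of each condition and requires agreement of at least 0.8;
#' validating the 20% coverage is the caller's responsibility since it
#' depends on the full schedule.
#'
#' @param assessor_a,assessor_b equal-length numeric vectors of co-scored
#'   points.
#' @param tolerance maximum absolute difference still counted as
#'   agreement.
#' @param minimum pass threshold on the agreement fraction.
#' @return List with `agreement` in \[0, 1\] and `pass`.
#' @export
interassessor_agreement <- function(assessor_a, assessor_b, tolerance = 0,
                                    minimum = 0.8) {
  if (length(assessor_a) != length(assessor_b)) {
    stop("assessor score vectors must have equal length", call. = FALSE)
  }
  if (length(assessor_a) == 0) {
    stop("agreement needs at least one co-scored point", call. = FALSE)
  }
  agreement <- mean(abs(assessor_a - assessor_b) <= tolerance)
  list(agreement = agreement, pass = agreement >= minimum)
}

#' Effect estimation for one gated series
#'
#' Applies the gate verdict: a series that failed the visual analysis is
#' returned as a gated-out marker and no p-value is computed. A series
#' that passed receives the NAP effect size, a randomization-test p-value
#' and a Bonferroni-corrected significance verdict with
#' `alpha_corrected = alpha / n_tests`.
#'
#' @param series series tibble.
#' @param gate a `gate_decision` from [evaluate_gate()].
#' @param spec one-row measure registry entry.
#' @param alpha nominal significance level.
#' @param n_tests number of tests entering the Bonferroni correction
#'   (conventionally the number of sides tested for the measure).
#' @param seed seed passed to [randomization_p()].
#' @param ... further arguments to [randomization_p()].
#' @return Object of class `effect_result`. Gated-out series carry
#'   `gated_out = TRUE` and `NA` statistics.
#' @export
analyze_measure <- function(series, gate, spec, alpha = 0.05, n_tests = 1L,
                            seed = NULL, ...) {
  stopifnot(inherits(gate, "gate_decision"))
  if (!isTRUE(gate$overall)) {
    return(structure(list(gated_out = TRUE, nap = NA_real_,
                          p_value = NA_real_, alpha = alpha,
                          n_tests = as.integer(n_tests),
                          alpha_corrected = bonferroni_alpha(alpha, n_tests),
                          significant = NA, scheme = NA_character_,
                          n_baseline = length(phase_values(series, "baseline")),
                          n_intervention = length(phase_values(series, "intervention")),
                          seed = NA_integer_),
                     class = "effect_result"))
  }
  bl <- phase_values(series, "baseline")
  iv <- phase_values(series, "intervention")
  est <- nap(bl, iv, spec$direction)
  rt <- randomization_p(bl, iv, spec$direction, seed = seed, ...)
  ac <- bonferroni_alpha(alpha, n_tests)
  structure(list(gated_out = FALSE, nap = est, p_value = rt$p_value,
                 alpha = alpha, n_tests = as.integer(n_tests),
                 alpha_corrected = ac,
                 significant = rt$p_value < ac,
                 scheme = rt$scheme,
                 n_baseline = length(bl), n_intervention = length(iv),
                 seed = rt$seed),
            class = "effect_result")
}

#' @export
print.effect_result <- function(x, ...) {
  if (isTRUE(x$gated_out)) {
    cat("gated out by visual analysis: no statistical test performed\n")
    return(invisible(x))
  }
  cat(sprintf("NAP = %.3f, p = %.4f (%s), alpha_corrected = %.4f -> %s\n",
              x$nap, x$p_value, x$scheme, x$alpha_corrected,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
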