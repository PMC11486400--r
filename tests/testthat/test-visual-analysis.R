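test_that("trend classification: slope band and monotone cases", {
  expect_equal(classify_trend(c(64, 64, 64, 64)), "stable")
  expect_equal(classify_trend(c(14, 13, 12, 11, 10)), "downward")
  expect_equal(classify_trend(c(10, 10.1, 9.9, 10.0, 10.05)), "stable")
  expect_equal(classify_trend(c(1, 2, 3, 4, 5)), "upward")
  expect_error(classify_trend(c(1, 2)), "at least 3")
  # strict mode demands monotonicity
  expect_equal(classify_trend(c(5, 4, 4.5), strict_monotone = TRUE), "stable")
  expect_equal(classify_trend(c(5, 4, 3), strict_monotone = TRUE), "downward")
})

test_that("stability counts points within 15% of the phase median", {
  expect_equal(stability_pct(c(100, 100, 100, 100, 100)), 100)
  expect_equal(stability_pct(c(10, 10, 10, 10, 20)), 80)  # band [8.5, 11.5]
  # zero median falls back to the absolute epsilon band
  expect_equal(stability_pct(c(0, 0.4, -0.4, 0, 2), epsilon = 0.5), 80)
})

test_that("stability is invariant to positive rescaling", {
  withr::with_seed(31, {
    for (i in 1:25) {
      v <- rnorm(sample(4:9, 1), 50, 8)
      cc <- runif(1, 0.1, 10)
      expect_equal(stability_pct(cc * v), stability_pct(v))
    }
  })
})

test_that("variability uses the two-standard-deviation band of the reference", {
  expect_equal(variability_pct(c(7, 7, 7, 7)), 0)
  expect_error(variability_pct(c(0, 0, 0, 0, 10), reference_values = c(0, 0, 0, 0)),
               "SD is zero")
  # whole-series reference, checked by direct arithmetic
  series_vals <- c(10, 10, 10, 10, 10, 30)
  iv <- c(10, 10, 30)
  band_hi <- mean(series_vals) + 2 * sd(series_vals)
  expected <- 100 * mean(iv > band_hi | iv < mean(series_vals) - 2 * sd(series_vals))
  expect_equal(variability_pct(iv, reference_values = series_vals), expected)
  expect_equal(expected, 100 / 3)
})

test_that("overlap is the share of intervention points inside the baseline range", {
  expect_equal(overlap_pct(c(60, 62, 64), c(50, 51, 50, 52, 49)), 0)
  expect_equal(overlap_pct(c(60, 62, 64), c(61, 63, 50, 49, 48)), 40)
  expect_equal(overlap_pct(c(60, 62, 64), c(60, 62, 64, 61, 63)), 100)
})

test_that("immediacy compares last-3 baseline with first-3 intervention", {
  step <- immediacy(c(70, 64, 64, 64), c(50, 50, 50, 49, 51), "decrease")
  expect_true(step$met)
  expect_equal(step$magnitude, -14)
  flat <- immediacy(c(64, 64, 64), c(64, 64, 64), "decrease")
  expect_false(flat$met)
  expect_equal(flat$magnitude, 0)
  wrong <- immediacy(c(10, 10, 10), c(8, 8, 8), "increase")
  expect_false(wrong$met)
  expect_equal(wrong$magnitude, -2)
  expect_error(immediacy(numeric(0), c(1, 2, 3), "decrease"), "non-empty")
})

test_that("PEM counts strict exceedance of the baseline median with categories", {
  all_better <- pem(c(64, 64, 64), c(50, 50, 51, 50, 50), "decrease")
  expect_equal(all_better$pct, 100)
  expect_equal(all_better$category, "high")
  four_of_five <- pem(c(64, 64, 64), c(50, 65, 50, 50, 50), "decrease")
  expect_equal(four_of_five$pct, 80)
  expect_equal(four_of_five$category, "moderate")
  # ties with the median do not exceed it
  tied <- pem(c(64, 64, 64), c(64, 64, 64, 64, 64), "decrease")
  expect_equal(tied$pct, 0)
  expect_equal(tied$category, "none")
})

test_that("consistency measures cross-participant agreement with the modal verdict", {
  expect_equal(consistency(rep(TRUE, 5))$fraction, 1)
  expect_true(consistency(rep(TRUE, 5))$met)
  split32 <- consistency(c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(split32$fraction, 0.6)
  expect_false(split32$met)
  boundary <- consistency(c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(boundary$fraction, 0.8)
  expect_true(boundary$met)
  lone <- consistency(TRUE)
  expect_true(lone$met)
  expect_false(lone$evaluable)
})

test_that("rank-based summaries are invariant under monotone transforms", {
  withr::with_seed(41, {
    for (i in 1:40) {
      bl <- rnorm(5, 60, 5)      # odd baseline size: transform commutes with median
      iv <- rnorm(sample(3:6, 1), 52, 5)
      tr <- function(x) exp(x / 20)  # strictly increasing
      p0 <- pem(bl, iv, "decrease")$pct
      p1 <- pem(tr(bl), tr(iv), "decrease")$pct
      expect_equal(p0, p1)
      expect_equal(overlap_pct(bl, iv), overlap_pct(tr(bl), tr(iv)))
    }
  })
})

test_that("negating values and flipping direction leaves verdicts unchanged", {
  withr::with_seed(43, {
    for (i in 1:25) {
      bl <- rnorm(4, 60, 4); iv <- rnorm(5, 50, 4)
      expect_equal(pem(bl, iv, "decrease")$pct, pem(-bl, -iv, "increase")$pct)
      expect_equal(immediacy(bl, iv, "decrease")$met,
                   immediacy(-bl, -iv, "increase")$met)
      expect_equal(overlap_pct(bl, iv), overlap_pct(-bl, -iv))
      expect_equal(nap(bl, iv, "decrease"), nap(-bl, -iv, "increase"))
    }
  })
})

test_that("percentage outputs are multiples of 100/n of the relevant phase", {
  withr::with_seed(47, {
    for (i in 1:25) {
      n_b <- sample(3:7, 1); n_i <- sample(3:6, 1)
      bl <- rnorm(n_b, 60, 6); iv <- rnorm(n_i, 55, 6)
      for (p in c(pem(bl, iv, "decrease")$pct, overlap_pct(bl, iv))) {
        expect_true(p >= 0 && p <= 100)
        expect_equal(p * n_i / 100, round(p * n_i / 100))  # integer point count
      }
      s <- stability_pct(bl)
      expect_equal(s * n_b / 100, round(s * n_b / 100))
    }
  })
})

test_that("the gate passes a clean step series and pinpoints single failures", {
  registry <- default_measure_registry()
  rmt_spec <- get_measure_spec(registry, "rmt")

  clean <- mk_series(c(64, 64.5, 63.8), c(50, 50.4, 49.8, 50.1, 50))
  g <- evaluate_gate(clean, rmt_spec)
  expect_true(g$overall)
  expect_true(all(g$criteria[setdiff(names(g$criteria), "consistency")]))

  null_series <- mk_series(c(64, 64.5, 63.8), c(64.1, 63.9, 64.4, 63.7, 64.2))
  g0 <- evaluate_gate(null_series, rmt_spec)
  expect_false(g0$overall)
  expect_false(g0$criteria[["pem"]])
  expect_false(g0$criteria[["immediacy"]])

  # a lone mid-baseline outlier breaks stability (3/4 = 75%) and nothing else
  outlier <- mk_series(c(64, 90, 64, 64), c(50, 50, 51, 50, 52))
  g1 <- evaluate_gate(outlier, rmt_spec)
  expect_false(g1$overall)
  expect_false(g1$criteria[["stability"]])
  expect_true(all(g1$criteria[setdiff(names(g1$criteria), "stability")]))
})

test_that("gate configuration toggles criteria and thresholds", {
  registry <- default_measure_registry()
  rmt_spec <- get_measure_spec(registry, "rmt")
  outlier <- mk_series(c(64, 90, 64, 64), c(50, 50, 51, 50, 52))
  relaxed <- gate_config(enabled = setdiff(gate_config()$enabled, "stability"))
  expect_true(evaluate_gate(outlier, rmt_spec, relaxed)$overall)

  # strict stability turns an exactly-80% phase into a failure
  s80 <- mk_series(c(64, 64, 64, 64, 80), c(50, 50, 51, 50, 52))
  expect_true(evaluate_gate(s80, rmt_spec)$criteria[["stability"]])
  strict <- gate_config(stability_strict = TRUE)
  expect_false(evaluate_gate(s80, rmt_spec, strict)$criteria[["stability"]])
})

test_that("unanalyzable series are rejected by the gate with a reason", {
  thin <- mk_series(c(64, 65), c(50, 50, 51, 50, 50))
  expect_error(evaluate_gate(thin, get_measure_spec(default_measure_registry(), "rmt")),
               "not analyzable")
})
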