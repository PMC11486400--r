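test_that("NAP counts improved pairs with ties at half weight", {
  expect_equal(nap(c(10, 9, 11, 10), c(9, 8, 8, 10, 7), "decrease"), 0.875)
  b <- c(64, 64, 65, 64, 64, 63)
  expect_equal(nap(b, b, "decrease"), 0.5)  # identical copy: pure ties/symmetry
  expect_equal(nap(b, c(50, 51, 50, 50, 52), "decrease"), 1)
  expect_error(nap(numeric(0), c(1, 2)), "non-empty")
})

test_that("NAP complements across directions and matches the rank-sum oracle", {
  withr::with_seed(53, {
    for (i in 1:200) {
      bl <- sample(0:20, sample(3:8, 1), replace = TRUE)  # ties likely
      iv <- sample(0:20, sample(3:8, 1), replace = TRUE)
      dn <- nap(bl, iv, "decrease")
      up <- nap(bl, iv, "increase")
      expect_equal(dn + up, 1)
      expect_equal(dn, nap_rank_oracle(bl, iv, "decrease"))
      expect_equal(up, nap_rank_oracle(bl, iv, "increase"))
    }
  })
})

test_that("exact randomization p matches brute-force enumeration", {
  b <- c(64, 64, 65, 64, 64, 63)
  i <- c(50, 51, 50, 50, 52)
  rt <- randomization_p(b, i, "decrease")
  expect_equal(rt$scheme, "exact_enumeration")
  expect_equal(rt$n_assignments, choose(11, 5))
  # complete nonoverlap: one all-low and one all-high assignment are the
  # only ones at maximal distance from the 0.5 null center
  expect_equal(rt$p_value, 2 / 462)
  expect_equal(rt$p_value, exact_p_oracle(b, i, "decrease"))

  withr::with_seed(59, {
    for (k in 1:10) {
      bl <- rnorm(4, 10, 2); iv <- rnorm(4, 9, 2)
      expect_equal(randomization_p(bl, iv, "decrease")$p_value,
                   exact_p_oracle(bl, iv, "decrease"))
    }
  })
})

test_that("a no-effect copy gives p = 1 and degenerate data cannot reject", {
  b <- c(5, 6, 7)
  expect_equal(randomization_p(b, b, "decrease")$p_value, 1)
  const <- rep(4, 5)
  expect_equal(randomization_p(const, rep(4, 4), "decrease")$p_value, 1)
})

test_that("Monte-Carlo p agrees with exact enumeration within 3 standard errors", {
  withr::with_seed(61, {
    bl <- rnorm(6, 10, 2)
    iv <- rnorm(5, 7.5, 2)
  })
  exact <- randomization_p(bl, iv, "decrease")
  mc <- randomization_p(bl, iv, "decrease", max_exact = 1, n_resamples = 4000,
                        seed = 99)
  expect_equal(mc$scheme, "monte_carlo")
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 4000)
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 1 / 4000)
  # same seed reproduces the Monte-Carlo p exactly
  mc2 <- randomization_p(bl, iv, "decrease", max_exact = 1, n_resamples = 4000,
                         seed = 99)
  expect_equal(mc$p_value, mc2$p_value)
})

test_that("the NAP-statistic p-value is invariant under monotone transforms", {
  withr::with_seed(67, {
    bl <- rnorm(5, 12, 3); iv <- rnorm(5, 10, 3)
  })
  p0 <- randomization_p(bl, iv, "decrease")$p_value
  p1 <- randomization_p(exp(bl / 5), exp(iv / 5), "decrease")$p_value
  expect_equal(p0, p1)
})

test_that("the mean-difference statistic is available as an alternative", {
  rt <- randomization_p(c(10, 11, 12), c(5, 6, 7), statistic = "mean_difference")
  expect_equal(rt$scheme, "exact_enumeration")
  expect_equal(rt$p_value, 2 / choose(6, 3))  # +/- the extreme split
})

test_that("the start-point randomization test ranks the realized stagger", {
  d <- generate_series(scenario("rmt_effect"), seed = 1)
  left <- split_series(d[d$side == "left", ])
  r <- mb_startpoint_p(left, "decrease")
  expect_equal(r$n_assignments, factorial(5))
  # a clean step at every true onset makes the realized assignment the
  # unique extreme among the 120 stagger permutations
  expect_equal(r$p_value, 1 / 120)
  expect_gt(r$statistic, 0)

  null_d <- generate_series(scenario("cmct_null_highvar"), seed = 1)
  rn <- mb_startpoint_p(split_series(null_d[null_d$side == "left", ]), "decrease")
  expect_gt(rn$p_value, 0.05)

  # deterministic: exact enumeration has no randomness
  expect_equal(mb_startpoint_p(left, "decrease")$p_value, r$p_value)
  expect_error(mb_startpoint_p(left[1], "decrease"), "at least 2")
})

test_that("Bonferroni correction divides alpha by the number of tests", {
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "positive integer")
})

test_that("inter-assessor agreement is the tolerant match fraction", {
  perfect <- interassessor_agreement(1:5, 1:5)
  expect_equal(perfect$agreement, 1)
  expect_true(perfect$pass)
  offs <- interassessor_agreement(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 9))
  expect_equal(offs$agreement, 0.8)
  expect_true(offs$pass)
  tol <- interassessor_agreement(c(1, 2), c(1.4, 2.6), tolerance = 0.5)
  expect_equal(tol$agreement, 0.5)
  expect_error(interassessor_agreement(1:3, 1:4), "equal length")
  expect_error(interassessor_agreement(numeric(0), numeric(0)), "at least one")
})

test_that("analyze_measure withholds statistics from gated-out series", {
  registry <- default_measure_registry()
  rmt_spec <- get_measure_spec(registry, "rmt")
  s_fail <- mk_series(c(64, 64.2, 63.9), c(64.1, 63.8, 64.3, 64, 64.1))
  g_fail <- evaluate_gate(s_fail, rmt_spec)
  out <- analyze_measure(s_fail, g_fail, rmt_spec, n_tests = 2)
  expect_true(out$gated_out)
  expect_true(is.na(out$p_value))
  expect_true(is.na(out$nap))

  s_pass <- mk_series(c(64, 64.2, 63.9), c(50, 50.2, 49.9, 50.1, 50))
  g_pass <- evaluate_gate(s_pass, rmt_spec)
  res <- analyze_measure(s_pass, g_pass, rmt_spec, n_tests = 2)
  expect_false(res$gated_out)
  expect_equal(res$nap, 1)
  expect_equal(res$alpha_corrected, 0.025)
  expect_equal(res$significant, res$p_value < 0.025)
})
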