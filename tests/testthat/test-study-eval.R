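# Worked examples: a reading/language intervention with five primary
# outcomes (mean inter-outcome correlation ~.6), and two working-memory
# training trials evaluated with four subtests (manual correlations
# .70-.78) and twelve measure-timepoint combinations (~.8).

burgoyne_p <- c(0.002, 0.022, 0.002, 0.011, 0.062)

test_that("five-outcome example: 3 significant under MEff, 2 under Bonferroni", {
  ev <- evaluate_study(burgoyne_p, mean_r = 0.6)
  expect_equal(round_half_up(ev$alphas[["meff"]], 3), 0.014)
  expect_equal(ev$alphas[["bonferroni"]], 0.01)
  expect_equal(unname(ev$counts[c("uncorrected", "meff", "bonferroni")]),
               c(4, 3, 2))
  # the p = .011 outcome is the one MEff adds over Bonferroni
  expect_true(ev$flags[4, "meff"])
  expect_false(ev$flags[4, "bonferroni"])
  expect_false(ev$flags[5, "uncorrected"])
  expect_output(print(ev), "Adjusted alphas")
})

test_that("four-subtest example: MEff alpha .02, two outcomes significant", {
  p <- c(0.048, 0.728, 0.001, 0.005)
  ev <- evaluate_study(p, mean_r = 0.7,
                       outcome_names = c("Spatial Recall", "Listening Recall",
                                         "Dot Matrix", "Digit Recall"))
  expect_equal(round_half_up(ev$alphas[["meff"]], 3), 0.020)
  expect_equal(unname(ev$flags[, "meff"]), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(ev$flags[, "bonferroni"]), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(round_half_up(sidak_alpha(4), 3), 0.013)
})

test_that("a correlation range reports MEff alphas at both endpoints", {
  p <- c(0.048, 0.728, 0.001, 0.005)
  ev <- evaluate_study(p, mean_r = c(0.70, 0.78))
  expect_true(all(c("meff_low", "meff_high") %in% names(ev$alphas)))
  expect_false("meff" %in% names(ev$alphas))
  expect_lt(ev$alphas[["meff_low"]], ev$alphas[["meff_high"]])
  expect_equal(unname(ev$flags[, "meff_low"]), unname(ev$flags[, "meff_high"]))
  expect_equal(unname(ev$counts[["meff_low"]]), 2)
})

test_that("twelve-measure example: estimated alpha .01 at mean correlation .8", {
  expect_equal(round_half_up(alpha_from_lookup(12, 0.8), 3), 0.010)
  expect_equal(round_half_up(bonferroni_alpha(12), 3), 0.004)
})

test_that("significance sets are nested: bonferroni within meff within uncorrected", {
  set.seed(61)
  for (i in 1:25) {
    k <- sample(2:12, 1)
    p <- runif(k, 0.0005, 1)
    ev <- evaluate_study(p, mean_r = runif(1, 0, 1))
    expect_true(all(ev$flags[, "bonferroni"] <= ev$flags[, "meff"]))
    expect_true(all(ev$flags[, "meff"] <= ev$flags[, "uncorrected"]))
    expect_true(all(ev$flags[, "bonferroni"] <= ev$flags[, "sidak"]))
  }
  ev <- evaluate_study(rep(1, 4), mean_r = 0.5)
  expect_true(all(ev$counts == 0))
})

test_that("full-matrix and mean-offdiagonal evaluations nearly agree", {
  p <- c(0.005, 0.012, 0.02, 0.2, 0.4, 0.6, 0.8, 0.9)
  for (r in seq(0.2, 0.8, by = 0.1)) {
    for (k in c(4, 6, 8)) {
      m <- block_matrix(c(k / 2, k / 2), r)
      a_full <- evaluate_study(p[1:k], corr_matrix = m)$alphas[["meff"]]
      a_scalar <- evaluate_study(p[1:k],
                                 mean_r = mean_offdiag(m))$alphas[["meff"]]
      expect_lte(abs(a_full - a_scalar), 0.002)
    }
  }
})

test_that("invalid study inputs are rejected with guidance", {
  expect_error(evaluate_study(0.03, mean_r = 0.5), "single outcome")
  expect_error(evaluate_study(c(0, 0.5), mean_r = 0.5), "\\(0, 1\\]")
  expect_error(evaluate_study(c(0.5, 1.2), mean_r = 0.5), "\\(0, 1\\]")
  expect_error(evaluate_study(c(0.1, 0.2)), "exactly one")
  expect_error(evaluate_study(c(0.1, 0.2), mean_r = 0.5,
                              corr_matrix = diag(2)), "exactly one")
  expect_error(evaluate_study(c(0.1, 0.2), mean_r = c(0.1, 0.2, 0.3)),
               "length 1 or 2")
})

test_that("p-value CSV reader requires outcome and p columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("outcome,p", "a,0.01", "b,0.2"), path)
  expect_equal(read_study_pvalues(path), c(a = 0.01, b = 0.2))
  writeLines(c("name,value", "a,0.01"), path)
  expect_error(read_study_pvalues(path), "expected columns")
})
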