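test_that("multinomial chi-square matches the closed-form upper tail", {
  r <- multinomial_chisq(c(20, 20, 20, 20, 20))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)

  r <- multinomial_chisq(c(40, 20, 20, 20, 0))
  expect_equal(r$chi2, 40)
  expect_equal(r$df, 4)
  expect_equal(r$p, ref_chisq_upper_even(40, 4), tolerance = 1e-12)

  r <- multinomial_chisq(c(25, 15, 20, 20, 20))
  expect_equal(r$chi2, 2.5)
  expect_equal(r$p, ref_chisq_upper_even(2.5, 4), tolerance = 1e-12)
})

test_that("chi-square agrees with an enumeration oracle on random counts", {
  set.seed(21)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    obs <- as.vector(rmultinom(1, sample(50:400, 1), rep(1 / k, k)))
    if (sum(obs) == 0) next
    r <- multinomial_chisq(obs)
    E <- sum(obs) / k
    chi2 <- 0
    for (j in seq_len(k)) chi2 <- chi2 + (obs[j] - E)^2 / E
    expect_equal(r$chi2, chi2)
    if ((k - 1) %% 2 == 0)
      expect_equal(r$p, ref_chisq_upper_even(chi2, k - 1),
                   tolerance = 1e-10)
  }
})

test_that("chi-square degenerate inputs error as specified", {
  expect_error(multinomial_chisq(c(0, 0, 0)), "zero")
  expect_error(multinomial_chisq(5), "single bin")
  expect_error(multinomial_chisq(c(10, 10), c(0.5, 0)), "positive")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 50), 0.5)
  expect_equal(bonferroni_adjust(0.5, 10), 1.0)
  expect_equal(bonferroni_adjust(1e-6, 1000), 1e-3)
  expect_equal(bonferroni_adjust(c(0.01, 0.2), 5), c(0.05, 1))
  expect_error(bonferroni_adjust(0.1, 0), "family_size")
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "smaller")
})

test_that("unadjusted test rejects near the nominal rate on null wells", {
  set.seed(22)
  p <- replicate(2000, {
    obs <- as.vector(rmultinom(1, 500, rep(0.2, 5)))
    multinomial_chisq(obs)$p
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
  # Bonferroni at family 2000 essentially never rejects
  expect_lt(sum(bonferroni_adjust(p, 2000) < 0.05), 3)
})

test_that("stability fractions hit the stated extremes", {
  tests <- data.frame(parameter = rep(c("a", "b"), each = 4),
                      p_adj = c(rep(1, 4), rep(0.001, 4)))
  rep <- stability_fractions(tests, cutoff = 0.05,
                             parameters = c("a", "b", "c"))
  expect_equal(rep$fraction_passing[rep$parameter == "a"], 1)
  expect_equal(rep$fraction_passing[rep$parameter == "b"], 0)
  expect_true(rep$untestable[rep$parameter == "c"])
})

test_that("planted well-level drift is recovered as noisy", {
  scr <- generate_screen(small_screen_config(seed = 23,
                                             cells_per_well = 500))
  bp <- bin_profile(scr$cells)
  st <- stability(bp)
  roles <- scr$truth$parameter_roles[st$report$parameter]
  noisy <- st$report$fraction_passing[roles == "noisy"]
  stable <- st$report$fraction_passing[grepl("^stable", roles)]
  expect_lt(median(noisy), 0.5)
  expect_gt(min(stable), max(noisy))
})

test_that("the threshold ladder is the 20-step nested family", {
  scr <- generate_screen(small_screen_config(seed = 24))
  st <- stability(bin_profile(scr$cells))
  lad <- stability_ladder(st)
  expect_length(lad$thresholds, 20)
  expect_equal(lad$thresholds, seq(0.01, 0.96, by = 0.05))
  sizes <- lengths(lad$retained)
  for (i in 2:20)
    expect_true(all(lad$retained[[i]] %in% lad$retained[[i - 1]]))
  # a parameter passing everywhere survives every threshold
  always <- st$report$parameter[!st$report$untestable &
                                  st$report$fraction_passing == 1]
  expect_true(all(always %in% lad$retained[[20]]))
  # untestable parameters never enter the ladder
  un <- st$report$parameter[st$report$untestable]
  expect_false(any(un %in% lad$retained[[1]]))
})

test_that("stability selection ignores treatment labels entirely", {
  scr <- generate_screen(small_screen_config(seed = 25))
  ct <- scr$cells
  st_full <- stability(bin_profile(ct))
  drop <- ct[is.na(ct$moa) | ct$moa != "MoA02", ]
  st_drop <- stability(bin_profile(drop))
  expect_identical(st_full$report, st_drop$report)
  lad_full <- stability_ladder(st_full)
  lad_drop <- stability_ladder(st_drop)
  expect_identical(lad_full$retained, lad_drop$retained)
})

test_that("best-threshold selection respects the sparser-tie rule", {
  scr <- generate_screen(small_screen_config(seed = 26, n_parameters = 10,
                                             n_noisy = 0, n_degenerate = 0,
                                             signature_size = 2))
  bp <- bin_profile(scr$cells)
  rep <- data.frame(parameter = attr(scr$cells, "features")[1:4],
                    wells_tested = 10, wells_passing = 10,
                    fraction_passing = 1, untestable = FALSE)
  # both rungs retain the same parameters: identical accuracy, tie -> 0.9
  lad2 <- stability_ladder(rep, thresholds = c(0.5, 0.9))
  sel <- select_best_threshold(lad2, bp, mode = "all_bins")
  expect_equal(sel$threshold, 0.9)
  # single-rung ladder returns its threshold
  lad1 <- stability_ladder(rep, thresholds = 0.5)
  sel1 <- select_best_threshold(lad1, bp, mode = "all_bins")
  expect_equal(sel1$threshold, 0.5)
})
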