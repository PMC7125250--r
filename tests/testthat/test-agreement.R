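test_that("relative error ratios behave as a symmetric mean-scaled difference", {
  expect_equal(rer(0.43, 0.40), 7.2, tolerance = 0.005)
  expect_identical(round(rer(0.43, 0.40)), 7)
  expect_equal(rer(3.0, 0.25), 169.2, tolerance = 0.001)
  expect_identical(rer(2.7, 2.7), 0)
  expect_true(is.na(rer(0, 0)))
  # antisymmetry and bounds on random positive pairs
  set.seed(14)
  a <- runif(200, 0.01, 10); b <- runif(200, 0.01, 10)
  expect_equal(rer(a, b), -rer(b, a))
  expect_true(all(abs(rer(a, b)) < 200))
  expect_equal(rer(5, 0), 200)
  expect_equal(rer(0, 5), -200)
})

test_that("limits of agreement are mean +/- 2 sample SDs", {
  expect_equal(limits_of_agreement(c(4, 4, 4)), c(lower = 4, upper = 4))
  expect_equal(limits_of_agreement(c(-10, 0, 10)), c(lower = -20, upper = 20))
  set.seed(2)
  x <- rnorm(50, 3, 12)
  loa <- limits_of_agreement(x)
  expect_equal(unname(loa[2] - loa[1]), 4 * sd(x))
  expect_equal(limits_of_agreement(x + 5), loa + 5)
  expect_true(loa[1] <= mean(x) && mean(x) <= loa[2])
  expect_error(limits_of_agreement(c(1, NA)), "at least 2")
})

test_that("paired regression reproduces closed-form least squares", {
  x <- c(1, 2, 3)
  r <- agree_regression(x, x)
  expect_equal(r$slope, 1); expect_equal(r$intercept, 0); expect_equal(r$r2, 1)
  r2 <- agree_regression(x, 2 * x)
  expect_equal(r2$slope, 2); expect_equal(r2$r2, 1)
  r3 <- agree_regression(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r3$slope, 0.5)
  expect_equal(r3$intercept, 1)
  expect_equal(r3$r2, 0.25)
  # r2 does not depend on the regression orientation
  set.seed(9)
  a <- runif(30); b <- a + rnorm(30, 0, 0.2)
  expect_equal(agree_regression(a, b, "central")$r2,
               agree_regression(a, b, "local")$r2)
  expect_error(agree_regression(c(1, 1, 1), c(1, 2, 3)), "variance")
  # studentized-residual exclusion removes a gross outlier
  xx <- c(seq(1, 5, length.out = 12), 3)
  yy <- c(seq(1, 5, length.out = 12) + rnorm(12, 0, 0.01), 40)
  r4 <- agree_regression(xx, yy, outlier_threshold = 3)
  expect_equal(r4$excluded, 13L)
  expect_equal(r4$slope, 1, tolerance = 0.05)
})

test_that("the agreement summary composes RERs, quartiles, LOA and regression", {
  s <- rer_summary(c(1, 2, 3), c(1, 3, 2))
  expect_equal(s$slope, 0.5)
  expect_equal(s$r2, 0.25)
  expect_equal(s$n, 3L)
  expect_equal(s$median_rer, 0)
  ident <- rer_summary(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ident$rers, rep(0, 4))
  expect_equal(unname(ident$loa), c(0, 0))
  expect_equal(ident$slope, 1); expect_equal(ident$r2, 1)
  # an undefined (0, 0) pair is excluded and counted, others untouched
  s2 <- rer_summary(c(1, 2, 3, 0), c(1, 3, 2, 0))
  expect_equal(s2$n_excluded, 1L)
  expect_equal(s2$rers, s$rers)
  expect_true(s2$q1 <= s2$median_rer && s2$median_rer <= s2$q3)
})

test_that("profile patterns split into similar, same-trend and crossing", {
  t <- c(0, 60, 120)
  base <- c(3, 2.2, 1.8)
  expect_equal(as.character(classify_pattern(base + 0.3, base)), "SIMILAR")
  expect_equal(as.character(classify_pattern(base + 0.8, base)), "SAME_TREND")
  expect_equal(as.character(classify_pattern(base + c(0.8, -0.9, 0.1), base)),
               "DIFFERENT_TREND")
  # rescaling both profiles and the threshold together preserves the label
  for (s in c(0.5, 2, 7)) {
    expect_equal(classify_pattern(s * (base + 0.8), s * base,
                                  threshold = s * 0.5),
                 classify_pattern(base + 0.8, base, threshold = 0.5))
  }
  profiles <- list(
    list(times = t, local = base + 0.3, central = base),
    list(times = t, local = base + 0.8, central = base),
    list(times = t, local = base + c(0.8, -0.9, 0.1), central = base))
  census <- pattern_census(paired_df(profiles))
  expect_equal(census$proportion, rep(1 / 3, 3))
  expect_equal(sum(census$proportion), 1)
  all_sim <- pattern_census(paired_df(profiles[1]))
  expect_equal(all_sim$proportion[all_sim$pattern == "SIMILAR"], 1)
  # the default generator produces all three patterns
  sim <- simulate_cohort(cohort_config(n_lesions = 150, seed = 123))
  cs <- pattern_census(sim)
  expect_true(all(cs$n > 0))
})

test_that("measurability discordance counts one-sided BLQ calls", {
  fx <- blq_fixture(357, n_local_only = 14, n_central_only = 22)
  d <- measurability_discordance(fx)
  expect_equal(d$n_discordant, 36)
  expect_equal(round(d$pct_discordant, 1), 10.1)
  expect_equal(round(d$pct_central_blq, 1), 6.2)
  expect_equal(round(d$pct_local_blq, 1), 3.9)
  expect_equal(d$n_discordant, d$n_local_blq + d$n_central_blq)
  clean <- blq_fixture(50, 0, 0)
  expect_equal(measurability_discordance(clean)$pct_discordant, 0)
})

test_that("fit comparison matches per-parameter agreement summaries", {
  ebes <- data.frame(ID = 1:6,
                     ETA_TS0 = 0, ETA_KG = 0, ETA_KD = 0,
                     TS0_i = c(2.5, 3.0, 3.6, 1.9, 4.2, 2.8),
                     KG_i = c(1.1, 1.4, 0.9, 1.2, 1.0, 1.3) * 1e-3,
                     KD_i = c(6, 8, 7, 9, 5, 7.5) * 1e-3)
  mkfit <- function(theta, sigma, ebes) {
    structure(list(population = tgi_population(theta, c(0.3, 0.2, 0.4), sigma),
                   rse = NULL, ebes = ebes), class = "tgi_fit")
  }
  fl <- mkfit(tgi_params(3.1, 0.0012, 0.0077), 0.43, ebes)
  # identical fits: all parameter RERs zero, perfect EBE correlation
  same <- compare_fits(fl, fl)
  expect_equal(same$population$rer_pct, rep(0, 4))
  expect_equal(unname(vapply(same$ebe, function(s) s$r2, 0)), rep(1, 3))

  ebes2 <- ebes
  ebes2$TS0_i <- ebes$TS0_i * 1.1
  fc <- mkfit(tgi_params(2.9, 0.00091, 0.0070), 0.40, ebes2)
  cmp <- compare_fits(fl, fc)
  expect_identical(round(cmp$population$rer_pct[cmp$population$parameter == "sigma"]), 7)
  expect_equal(cmp$ebe$TS0$rers,
               rer_summary(ebes$TS0_i, ebes2$TS0_i)$rers)
  expect_equal(cmp$ebe$TS0$slope,
               rer_summary(ebes$TS0_i, ebes2$TS0_i)$slope)

  # disjoint IDs are an error; partial overlap is reported
  ebes3 <- ebes; ebes3$ID <- ebes3$ID + 100L
  expect_error(compare_fits(fl, mkfit(tgi_params(3, 0.001, 0.007), 0.4, ebes3)),
               "share no lesion IDs")
  ebes4 <- ebes; ebes4$ID <- c(1:5, 200L)
  cmp4 <- compare_fits(fl, mkfit(tgi_params(3, 0.001, 0.007), 0.4, ebes4))
  expect_equal(sort(cmp4$excluded_ids), c(6L, 200L))
  expect_equal(cmp4$n_lesions, 5L)
})

test_that("raising operator noise does not improve raw agreement", {
  med_abs_rer <- function(sig) {
    sim <- simulate_cohort(cohort_config(n_lesions = 250,
                                         operator_sigma = c(sig, sig),
                                         seed = 909))
    pairs <- tgiagree:::pair_observations(sim)
    median(abs(rer(pairs$DV_local, pairs$DV_central)), na.rm = TRUE)
  }
  m <- vapply(c(0.1, 0.43, 0.9), med_abs_rer, 0)
  expect_true(all(diff(m) >= 0))
})
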