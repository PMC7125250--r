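test_that("LLOQ substitution records half the limit and flags the value", {
  expect_equal(apply_lloq(0.4, 0.5), list(value = 0.25, blq = TRUE))
  expect_equal(apply_lloq(0.5, 0.5), list(value = 0.5, blq = FALSE))
  expect_equal(apply_lloq(2.0, 0.5), list(value = 2.0, blq = FALSE))
  out <- apply_lloq(c(0, 0.49, 0.51, 3), 0.5)
  expect_equal(out$value, c(0.25, 0.25, 0.51, 3))
  expect_equal(out$blq, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(apply_lloq(-0.1, 0.5), "non-negative")
})

test_that("simulation is reproducible under a seed and honours degenerate settings", {
  cfg <- cohort_config(n_lesions = 15, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  expect_identical(sample_individuals(cfg), sample_individuals(cfg))
  expect_identical(sample_visit_schedule(cfg), sample_visit_schedule(cfg))
  expect_equal(length(unique(a$observations$ID)), 15)

  # no inter-lesion variability, no operator noise: records equal the
  # typical profile exactly
  pop0 <- tgi_population(tgi_params(3.1, 0.0012, 0.0077),
                         omega2 = c(0, 0, 0), sigma_add = 0.43)
  cfg0 <- cohort_config(n_lesions = 8, population = pop0,
                        operator_sigma = c(0, 0), seed = 5)
  sim0 <- simulate_cohort(cfg0)
  ob <- sim0$observations
  expect_equal(ob$DV, predict_ts(tgi_params(3.1, 0.0012, 0.0077), ob$TIME))
  expect_true(all(ob$BLQ == 0L))
})

test_that("sampled random effects and visit schedules match the configured distributions", {
  cfg <- cohort_config(n_lesions = 10000, seed = 202)
  ind <- sample_individuals(cfg)
  expect_equal(var(ind$ETA_TS0), 0.31, tolerance = 0.05)
  expect_equal(var(ind$ETA_KG), 0.20, tolerance = 0.05)
  expect_equal(var(ind$ETA_KD), 0.44, tolerance = 0.05)
  expect_equal(median(ind$TS0), 3.1, tolerance = 0.05)

  sim <- simulate_cohort(cohort_config(n_lesions = 4000, seed = 303))
  per <- split(sim$truth$TIME, sim$truth$ID)
  counts <- lengths(per)
  expect_true(all(counts >= 1 & counts <= 5))
  expect_equal(mean(counts), 3, tolerance = 0.05)
  gaps <- unlist(lapply(per, diff))
  expect_true(all(gaps >= 19 & gaps <= 116))
  expect_equal(median(gaps), 59, tolerance = 0.05)
  # times strictly increasing from the baseline scan
  expect_true(all(vapply(per, function(t) t[1] == 0 && all(diff(t) > 0), TRUE)))
})

test_that("recorded values never fall below half the LLOQ and flags are consistent", {
  sim <- simulate_cohort(cohort_config(n_lesions = 400, seed = 17))
  ob <- sim$observations
  expect_true(all(ob$DV >= 0.25))
  expect_true(all(ob$DV[ob$BLQ == 1L] == 0.25))
  expect_true(all(ob$DV[ob$BLQ == 0L] >= 0.5))
  expect_gt(sum(ob$BLQ), 0)
})

test_that("datasets round-trip through the delimited dialect with validation", {
  sim <- simulate_cohort(cohort_config(n_lesions = 12, seed = 31))
  dpath <- withr::local_tempfile(fileext = ".csv")
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim, dpath, truth_path = tpath)
  back <- read_cohort(dpath, truth_path = tpath)
  expect_equal(back$observations, sim$observations)
  expect_equal(back$truth, sim$truth)

  # a DV below lloq/2 is invalid
  bad <- sim$observations
  bad$DV[3] <- 0.1
  bpath <- withr::local_tempfile(fileext = ".csv")
  write_cohort(bad, bpath)
  expect_error(read_cohort(bpath), "lloq/2")

  # non-increasing times are rejected with the offending line
  bad2 <- sim$observations
  rows <- which(bad2$ID == 1 & bad2$OPER == "LOCAL")
  if (length(rows) >= 2) {
    bad2$TIME[rows[2]] <- bad2$TIME[rows[1]]
    b2 <- withr::local_tempfile(fileext = ".csv")
    write_cohort(bad2, b2)
    expect_error(read_cohort(b2), "strictly increasing")
  }

  # header-only file: empty collection with a warning
  epath <- withr::local_tempfile(fileext = ".csv")
  writeLines("ID,PTID,OPER,TIME,DV,BLQ", epath)
  expect_warning(empty <- read_cohort(epath), "no observations")
  expect_equal(nrow(empty$observations), 0L)
})

test_that("configuration files round-trip and unknown keys are rejected", {
  cfg <- cohort_config(n_lesions = 33, operator_sigma = c(0.3, 0.5),
                       gap_sd = 12, seed = 77)
  cpath <- withr::local_tempfile(fileext = ".txt")
  write_cohort_config(cfg, cpath)
  back <- read_cohort_config(cpath)
  expect_equal(back$n_lesions, 33L)
  expect_equal(back$operator_sigma, cfg$operator_sigma)
  expect_equal(back$gap_sd, 12)
  expect_equal(back$seed, 77L)
  expect_equal(back$population$theta$ts0, 3.1)
  expect_identical(simulate_cohort(back)$observations,
                   simulate_cohort(cfg)$observations)

  writeLines(c("n_lesions = 10", "banana = 3"), cpath)
  expect_error(read_cohort_config(cpath), "unknown config key")
  writeLines(c("n_lesions = 10", "n_lesions = 12"), cpath)
  expect_error(read_cohort_config(cpath), "duplicate")
})

test_that("progression-driven dropout truncates follow-up after regrowth", {
  pop <- tgi_population(tgi_params(3, 0.02, 0.2), omega2 = c(0, 0, 0),
                        sigma_add = 0.1)
  cfg <- cohort_config(n_lesions = 60, population = pop,
                       operator_sigma = c(0, 0), dropout = TRUE, seed = 8)
  sim <- simulate_cohort(cfg)
  per <- split(sim$truth, sim$truth$ID)
  for (df in per) {
    if (nrow(df) < 3) next
    run_min <- cummin(df$TRUE_TS)
    # at most one visit beyond the first 20% regrowth above the running minimum
    prog <- which(df$TRUE_TS > 1.2 * run_min)
    if (length(prog)) expect_lte(max(seq_len(nrow(df))), prog[1])
  }
})
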