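test_that("conditional log-likelihood matches its closed form and an independent implementation", {
  th <- tgi_params(3.1, 0.0012, 0.0077)
  w2 <- c(0.31, 0.20, 0.44)
  # single observation: residual term plus the eta prior
  y <- 2.5; t <- 40; sg <- 0.43
  m <- predict_ts(th, t)
  expect_equal(conditional_loglik(t, y, th, c(0, 0, 0), c(0, 0, 0), sg),
               -0.5 * log(2 * pi * sg^2) - (y - m)^2 / (2 * sg^2))
  # dual-implementation oracle on random cases
  set.seed(21)
  for (i in 1:20) {
    times <- sort(runif(4, 0, 300))
    yy <- runif(4, 0.25, 6)
    eta <- rnorm(3, 0, 0.5)
    expect_equal(conditional_loglik(times, yy, th, eta, w2, sg),
                 naive_cll(times, yy, c(3.1, 0.0012, 0.0077), eta, w2, sg))
  }
  # zero residual SD with a nonzero residual is impossible data
  expect_identical(conditional_loglik(t, y, th, c(0, 0, 0), w2, 0), -Inf)
})

test_that("Laplace objective agrees with adaptive Gauss-Hermite quadrature", {
  sim <- simulate_cohort(cohort_config(n_lesions = 3, seed = 3))
  pop <- table1_local_population()
  lap <- laplace_ofv(sim, pop, "LOCAL")
  expect_lt(abs(lap$ofv - agq_ofv(sim, pop, "LOCAL", n_nodes = 32)), 0.5)
})

test_that("the objective is additive over lesions and collapses when variances vanish", {
  sim <- simulate_cohort(cohort_config(n_lesions = 6, seed = 12))
  pop <- table1_local_population()
  base <- laplace_ofv(sim, pop, "LOCAL")
  doubled <- sim$observations
  copy <- doubled
  copy$ID <- copy$ID + 1000L
  both <- rbind(doubled, copy)
  expect_equal(laplace_ofv(both, pop, "LOCAL")$ofv, 2 * base$ofv,
               tolerance = 1e-8)

  # omega2 = 0 pins the random effects: ofv is the fixed-effect -2 loglik
  pop0 <- tgi_population(pop$theta, omega2 = c(0, 0, 0), sigma_add = 0.43)
  d <- tgiagree:::extract_operator(sim, "LOCAL")
  ref <- -2 * sum(vapply(seq_along(d$ids), function(i)
    naive_cll(d$times[[i]], d$y[[i]], c(3.1, 0.0012, 0.0077), c(0, 0, 0),
              c(0, 0, 0), 0.43), 0))
  expect_equal(laplace_ofv(sim, pop0, "LOCAL")$ofv, ref, tolerance = 1e-8)
})

test_that("fitting is deterministic and invariant to dataset row order", {
  sim <- simulate_cohort(cohort_config(n_lesions = 40, seed = 55))
  f1 <- fit_tgi(sim, "LOCAL")
  f2 <- fit_tgi(sim, "LOCAL")
  expect_identical(fit_parameter_table(f1), fit_parameter_table(f2))
  shuffled <- sim$observations[sample(nrow(sim$observations)), ]
  f3 <- fit_tgi(shuffled, "LOCAL")
  expect_equal(fit_parameter_table(f3)$estimate,
               fit_parameter_table(f1)$estimate, tolerance = 1e-6)
})

test_that("typical values are recovered from a rich low-noise design", {
  pop <- tgi_population(tgi_params(3.1, 0.0012, 0.0077),
                        omega2 = c(0, 0, 0), sigma_add = 0.01)
  cfg <- cohort_config(n_lesions = 200, population = pop,
                       operator_sigma = c(0.01, 0.01),
                       visit_lambda = 8, seed = 404)
  sim <- simulate_cohort(cfg)
  fit <- fit_tgi(sim, "LOCAL")
  expect_true(fit$converged)
  expect_lt(abs(rer(fit$population$theta$ts0, 3.1)), 2)
  expect_lt(abs(rer(fit$population$theta$kg, 0.0012)), 2)
  expect_lt(abs(rer(fit$population$theta$kd, 0.0077)), 2)
})

test_that("empirical Bayes estimates shrink with the information content", {
  pop <- table1_local_population()
  # no data: full shrinkage to the typical values
  e0 <- ebe_single(pop, numeric(0), numeric(0))
  expect_equal(e0$eta, c(0, 0, 0))
  expect_equal(e0$params, pop$theta)

  # dense, nearly noise-free data from a known individual recovers it
  truth_eta <- c(0.3, -0.4, 0.5)
  ind <- individual_parameters(pop$theta, truth_eta)
  times <- seq(0, 360, by = 30)
  y <- predict_ts(ind, times)
  pop_tight <- tgi_population(pop$theta, omega2 = pop$omega2,
                              sigma_add = 0.005)
  e1 <- ebe_single(pop_tight, times, y)
  expect_equal(e1$params$ts0, ind$ts0, tolerance = 0.01)
  expect_equal(e1$params$kg, ind$kg, tolerance = 0.01)
  expect_equal(e1$params$kd, ind$kd, tolerance = 0.01)

  # removing observations moves the estimate toward the typical values
  norms <- vapply(c(13, 7, 3, 1), function(k) {
    e <- ebe_single(tgi_population(pop$theta, pop$omega2, 0.2),
                    times[seq_len(k)], y[seq_len(k)])
    sqrt(sum(e$eta^2))
  }, 0)
  expect_true(all(diff(norms) <= 1e-8))

  # a huge residual SD washes out the data entirely
  e2 <- ebe_single(tgi_population(pop$theta, pop$omega2, 100), times, y)
  expect_equal(e2$eta, c(0, 0, 0), tolerance = 1e-3)
})

test_that("substituted below-LLOQ records enter the likelihood as ordinary data", {
  sim <- simulate_cohort(cohort_config(n_lesions = 80, seed = 71))
  pop <- table1_local_population()
  d <- tgiagree:::extract_operator(sim, "LOCAL")
  lap <- laplace_ofv(sim, pop, "LOCAL")
  # recomputing with the recorded DVs (0.25 where BLQ) reproduces the ofv:
  # no censoring correction is applied
  again <- laplace_ofv(sim$observations, pop, "LOCAL")
  expect_identical(lap$ofv, again$ofv)
  expect_gt(sum(sim$observations$BLQ), 0)
})

test_that("the prediction-corrected VPC is coherent on its own simulations", {
  pop <- table1_local_population()
  sim <- simulate_cohort(cohort_config(n_lesions = 60, seed = 606))
  v <- prediction_corrected_vpc(pop, sim, n_sim = 100, seed = 1)
  expect_s3_class(v, "tgi_vpc")
  # percentiles ordered within every bin
  expect_true(all(v$obs_p5 <= v$obs_p50 & v$obs_p50 <= v$obs_p95))
  expect_true(all(v$sim_p5_lo <= v$sim_p5_hi))
  # degenerate model: all replicates identical, intervals have zero width
  pop0 <- tgi_population(pop$theta, omega2 = c(0, 0, 0), sigma_add = 0)
  sim0 <- simulate_cohort(cohort_config(n_lesions = 10, population = pop0,
                                        operator_sigma = c(0, 0), seed = 2))
  v0 <- prediction_corrected_vpc(pop0, sim0, n_sim = 100, seed = 3)
  expect_equal(v0$sim_p50_lo, v0$sim_p50_hi)
  expect_equal(v0$sim_p5_lo, v0$sim_p95_hi)
  # bins covering no data are dropped with a warning
  expect_warning(
    vb <- prediction_corrected_vpc(pop, sim, n_sim = 100,
                                   bins = c(0, 50, 100, 5000, 6000),
                                   seed = 4),
    "empty")
  expect_true(all(vb$n > 0))
})
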