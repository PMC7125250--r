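#' Conditional log-likelihood of one lesion's data
#'
#' Gaussian log-density of the observed diameters around the individual
#' prediction `predict_ts(individual_parameters(theta, eta), t)` with
#' additive residual SD `sigma_add`, plus the `Normal(0, omega2)` log-prior
#' of the random effects. Components with `omega2 = 0` are treated as
#' pinned at `eta = 0` and contribute no prior term. A zero residual SD
#' with any nonzero residual yields `-Inf`.
#'
#' This is the joint density whose per-lesion mode and curvature drive the
#' Laplace approximation; the reference implementation here is pure R (the
#' estimator uses a compiled equivalent).
#'
#' @param times,y Observation times (days) and recorded diameters (cm).
#' @param theta Population typical values ([tgi_params()]).
#' @param eta Length-3 random-effect vector.
#' @param omega2 Length-3 random-effect variances.
#' @param sigma_add Additive residual SD, cm.
#' @return Scalar log-likelihood.
#' @export
conditional_loglik <- function(times, y, theta, eta, omega2, sigma_add) {
  theta <- as_tgi_params(theta)
  stopifnot(length(times) == length(y), length(times) >= 1L,
            length(eta) == 3L, length(omega2) == 3L, all(omega2 >= 0),
            sigma_add >= 0)
  pred <- predict_ts(individual_parameters(theta, eta), times)
  resid <- y - pred
  if (sigma_add == 0) {
    ll <- if (any(resid != 0)) -Inf else Inf
  } else {
    ll <- sum(dnorm(y, pred, sigma_add, log = TRUE))
  }
  for (k in 1:3) {
    if (omega2[k] > 0) {
      ll <- ll + dnorm(eta[k], 0, sqrt(omega2[k]), log = TRUE)
    } else if (eta[k] != 0) {
      ll <- -Inf
    }
  }
  ll
}

extract_operator <- function(data, operator) {
  ob <- if (inherits(data, "tgi_cohort")) data$observations else data
  stopifnot(is.data.frame(ob), all(c("ID", "OPER", "TIME", "DV") %in% names(ob)))
  operator <- match.arg(toupper(operator), c("LOCAL", "CENTRAL"))
  ob <- ob[ob$OPER == operator, , drop = FALSE]
  if (nrow(ob) == 0L) stop("no observations for operator ", operator)
  ob <- ob[order(ob$ID, ob$TIME), , drop = FALSE]  # canonical row order
  ids <- sort(unique(ob$ID))
  list(ids = ids,
       times = lapply(ids, function(i) ob$TIME[ob$ID == i]),
       y = lapply(ids, function(i) ob$DV[ob$ID == i]),
       operator = operator)
}

#' Laplace approximation of the marginal likelihood
#'
#' For each lesion the conditional mode of the random effects is found by a
#' damped Newton iteration and the marginal likelihood is approximated by
#' the Laplace formula using the curvature at the mode. Values below the
#' limit of quantification enter as their substituted records, exactly as
#' they appear in the dataset.
#'
#' @param data A `tgi_cohort` or a data frame in the dataset dialect.
#' @param population A [tgi_population()].
#' @param operator Which operator's records to use, `"LOCAL"` or
#'   `"CENTRAL"`.
#' @param eta_start Optional matrix of starting random effects (one row per
#'   lesion, in lesion-ID order).
#' @param control A [tgi_control()].
#' @return A list with `ofv` (-2 times the total approximate log marginal
#'   likelihood), `etas` (conditional modes), `lesion_loglik`, `converged`
#'   (per lesion) and `ids`.
#' @export
laplace_ofv <- function(data, population, operator = "LOCAL",
                        eta_start = NULL, control = tgi_control()) {
  stopifnot(inherits(population, "tgi_population"))
  d <- extract_operator(data, operator)
  n <- length(d$ids)
  if (is.null(eta_start)) eta_start <- matrix(0, n, 3L)
  res <- cpp_laplace(d$times, d$y,
                     c(population$theta$ts0, population$theta$kg,
                       population$theta$kd),
                     as.numeric(population$omega2), population$sigma_add,
                     eta_start, control$inner_tol, control$inner_maxit)
  res$ids <- d$ids
  res
}

#' Estimation settings
#'
#' @param maxit Maximum outer quasi-Newton iterations.
#' @param rel_tol Relative objective-change convergence tolerance of the
#'   outer optimisation.
#' @param inner_tol Gradient-norm tolerance of the inner Newton search for
#'   the conditional modes.
#' @param inner_maxit Maximum inner Newton iterations.
#' @param fix_omega2 `NULL`, or length-3 numeric: fix the random-effect
#'   variances at these values instead of estimating them.
#' @param fix_sigma `NULL`, or scalar: fix the residual SD.
#' @return A list of class `tgi_control`.
#' @export
tgi_control <- function(maxit = 300L, rel_tol = 1e-6, inner_tol = 1e-8,
                        inner_maxit = 60L, fix_omega2 = NULL,
                        fix_sigma = NULL) {
  stopifnot(is.null(fix_omega2) ||
              (is.numeric(fix_omega2) && length(fix_omega2) == 3L &&
                 all(fix_omega2 >= 0)),
            is.null(fix_sigma) ||
              (is.numeric(fix_sigma) && length(fix_sigma) == 1L &&
                 fix_sigma > 0))
  structure(list(maxit = as.integer(maxit), rel_tol = rel_tol,
                 inner_tol = inner_tol, inner_maxit = as.integer(inner_maxit),
                 fix_omega2 = fix_omega2, fix_sigma = fix_sigma),
            class = "tgi_control")
}

# per-lesion least-squares fits give robust typical-value starting points
init_from_data <- function(d, fallback = tgi_params(3.1, 0.0012, 0.0077)) {
  fits <- lapply(seq_along(d$ids), function(i) {
    t <- d$times[[i]]; yy <- d$y[[i]]
    if (length(t) < 3L) return(NULL)
    ss <- function(u) {
      p <- exp(u)
      sum((yy - p[1L] * (exp(p[2L] * t) + exp(-p[3L] * t) - 1))^2)
    }
    start <- log(c(max(yy[1L], 0.3), 0.002, 0.008))
    out <- try(nlminb(start, ss, lower = log(c(1e-3, 1e-6, 1e-6)),
                      upper = log(c(100, 0.2, 0.5))), silent = TRUE)
    if (inherits(out, "try-error")) NULL else exp(out$par)
  })
  fits <- do.call(rbind, fits[!vapply(fits, is.null, TRUE)])
  if (is.null(fits) || nrow(fits) == 0L)
    return(fallback)
  tgi_params(stats::median(fits[, 1L]),
             max(stats::median(fits[, 2L]), 1e-5),
             max(stats::median(fits[, 3L]), 1e-5))
}

#' Fit the TGI model as a nonlinear mixed-effects model
#'
#' Maximises the Laplace-approximate marginal likelihood over the typical
#' values, the diagonal random-effect variances and the additive residual
#' SD, all log-transformed to enforce positivity. Relative standard errors
#' come from the inverse observed information on the transformed scale
#' (for a log-transformed parameter the standard error of the log is the
#' relative standard error of the natural parameter). Empirical Bayes
#' estimates are the conditional-mode random effects at the optimum.
#'
#' @param data A `tgi_cohort` or data frame in the dataset dialect.
#' @param operator `"LOCAL"` or `"CENTRAL"`.
#' @param init Optional [tgi_population()] of starting values. By default
#'   the typical values are initialised from the medians of per-lesion
#'   least-squares fits (lesions with at least three points), the variances
#'   at 0.3 and the residual SD at 0.4 cm.
#' @param control A [tgi_control()].
#' @return An object of class `tgi_fit` with elements `population`, `rse`
#'   (percent, `NA` for fixed components), `ofv`, `ebes` (one row per
#'   lesion: random effects and implied individual parameters),
#'   `converged`, `n_lesions`, `n_obs`, `operator`.
#' @export
fit_tgi <- function(data, operator = "LOCAL", init = NULL,
                    control = tgi_control()) {
  d <- extract_operator(data, operator)
  n <- length(d$ids)
  if (is.null(init)) {
    theta0 <- init_from_data(d)
    init <- tgi_population(theta0, omega2 = rep(0.3, 3L), sigma_add = 0.4)
  }
  stopifnot(inherits(init, "tgi_population"))

  est_omega <- is.null(control$fix_omega2)
  est_sigma <- is.null(control$fix_sigma)
  fixed_omega2 <- if (est_omega) NULL else pmax(control$fix_omega2, 1e-10)
  u0 <- c(log(c(init$theta$ts0, init$theta$kg, init$theta$kd)),
          if (est_omega) log(pmax(init$omega2, 1e-6)),
          if (est_sigma) log(init$sigma_add))
  lower <- c(rep(-12, 3L), if (est_omega) rep(log(1e-8), 3L),
             if (est_sigma) log(1e-4))
  upper <- c(rep(6, 3L), if (est_omega) rep(log(25), 3L),
             if (est_sigma) log(10))

  cache <- new.env(parent = emptyenv())
  cache$etas <- matrix(0, n, 3L)
  u0 <- unname(u0)
  unpack <- function(u) {
    theta <- unname(exp(u[1:3]))
    omega2 <- unname(if (est_omega) exp(u[4:6]) else fixed_omega2)
    sigma <- unname(if (est_sigma) exp(u[length(u)]) else control$fix_sigma)
    list(theta = theta, omega2 = omega2, sigma = sigma)
  }
  obj <- function(u) {
    p <- unpack(u)
    res <- cpp_laplace(d$times, d$y, p$theta, p$omega2, p$sigma,
                       cache$etas, control$inner_tol, control$inner_maxit)
    if (is.finite(res$ofv)) cache$etas <- res$etas
    res$ofv
  }
  # quasi-Newton rounds with fresh conditional-mode caches; restarting from
  # the previous optimum guards against premature "false convergence" on
  # stiff (low-noise) likelihood surfaces
  opt <- NULL
  settled <- FALSE
  for (round in 1:3) {
    cur <- nlminb(u0, obj, lower = lower, upper = upper,
                  control = list(iter.max = control$maxit,
                                 eval.max = 10L * control$maxit,
                                 rel.tol = control$rel_tol))
    improved <- is.null(opt) ||
      opt$objective - cur$objective > control$rel_tol * abs(opt$objective)
    if (is.null(opt) || cur$objective <= opt$objective) opt <- cur
    if (!improved) { settled <- TRUE; break }
    u0 <- opt$par
    cache$etas <- matrix(0, n, 3L)
  }
  p <- unpack(opt$par)
  final <- cpp_laplace(d$times, d$y, p$theta, p$omega2, p$sigma,
                       cache$etas, control$inner_tol, control$inner_maxit)
  population <- tgi_population(tgi_params(p$theta[1L], p$theta[2L], p$theta[3L]),
                               omega2 = p$omega2, sigma_add = p$sigma)

  par_names <- c("TS0", "Kg", "Kd",
                 if (est_omega) c("IIV_TS0", "IIV_Kg", "IIV_Kd"),
                 if (est_sigma) "sigma")
  rse <- rep(NA_real_, length(par_names))
  names(rse) <- par_names
  info <- try(stats::optimHess(opt$par, obj), silent = TRUE)
  if (!inherits(info, "try-error")) {
    cov_u <- try(2 * solve(info), silent = TRUE)  # obj is -2*loglik
    if (!inherits(cov_u, "try-error") && all(diag(cov_u) > 0))
      rse[] <- 100 * sqrt(diag(cov_u))
  }
  if (anyNA(rse))
    warning("observed information is singular or indefinite; ",
            "some RSEs unavailable")

  ebes <- data.frame(ID = d$ids,
                     ETA_TS0 = final$etas[, 1L], ETA_KG = final$etas[, 2L],
                     ETA_KD = final$etas[, 3L],
                     TS0_i = p$theta[1L] * exp(final$etas[, 1L]),
                     KG_i = p$theta[2L] * exp(final$etas[, 2L]),
                     KD_i = p$theta[3L] * exp(final$etas[, 3L]))
  structure(list(population = population, rse = rse, ofv = opt$objective,
                 ebes = ebes,
                 converged = (opt$convergence == 0 || settled) &&
                   all(final$converged),
                 n_lesions = n, n_obs = sum(lengths(d$y)),
                 operator = d$operator,
                 data = d, control = control, optim = opt),
            class = "tgi_fit")
}

#' @export
print.tgi_fit <- function(x, ...) {
  cat(sprintf("TGI mixed-effects fit (%s set): %d lesions, %d observations\n",
              x$operator, x$n_lesions, x$n_obs))
  cat(sprintf("  OFV (-2 log marginal likelihood): %.3f  [converged: %s]\n",
              x$ofv, x$converged))
  est <- c(TS0 = x$population$theta$ts0, Kg = x$population$theta$kg,
           Kd = x$population$theta$kd,
           IIV_TS0 = x$population$omega2[[1L]],
           IIV_Kg = x$population$omega2[[2L]],
           IIV_Kd = x$population$omega2[[3L]],
           sigma = x$population$sigma_add)
  rse <- x$rse[match(names(est), names(x$rse))]
  for (k in seq_along(est))
    cat(sprintf("  %-8s %-12.5g %s\n", names(est)[k], est[[k]],
                if (is.na(rse[k])) "" else sprintf("(%.0f%% RSE)", rse[k])))
  invisible(x)
}

#' Parameter table of a fit
#'
#' @param fit A `tgi_fit`.
#' @return Data frame with columns `parameter`, `estimate`, `rse_pct`.
#' @export
fit_parameter_table <- function(fit) {
  stopifnot(inherits(fit, "tgi_fit"))
  est <- c(TS0 = fit$population$theta$ts0, Kg = fit$population$theta$kg,
           Kd = fit$population$theta$kd,
           IIV_TS0 = fit$population$omega2[[1L]],
           IIV_Kg = fit$population$omega2[[2L]],
           IIV_Kd = fit$population$omega2[[3L]],
           sigma = fit$population$sigma_add)
  data.frame(parameter = names(est), estimate = unname(est),
             rse_pct = unname(fit$rse[match(names(est), names(fit$rse))]))
}

#' Empirical Bayes estimate for a single lesion
#'
#' Conditional-mode random effects of one lesion given a population model,
#' mapped to individual structural parameters. With no observations the
#' mode is zero (full shrinkage to the typical values); sparse or noisy
#' data shrink the estimate toward the typical values.
#'
#' @param population A [tgi_population()].
#' @param times,y The lesion's observation times and diameters (possibly
#'   empty).
#' @param control A [tgi_control()].
#' @return List with `eta` and `params` ([tgi_params()]).
#' @export
ebe_single <- function(population, times, y, control = tgi_control()) {
  stopifnot(inherits(population, "tgi_population"), length(times) == length(y))
  if (length(times) == 0L) {
    return(list(eta = c(0, 0, 0), params = population$theta))
  }
  res <- cpp_laplace(list(as.numeric(times)), list(as.numeric(y)),
                     c(population$theta$ts0, population$theta$kg,
                       population$theta$kd),
                     as.numeric(population$omega2), population$sigma_add,
                     matrix(0, 1L, 3L), control$inner_tol, control$inner_maxit)
  eta <- as.numeric(res$etas[1L, ])
  list(eta = eta, params = individual_parameters(population$theta, eta))
}

default_time_bins <- function(times, max_bins = 5L) {
  edges <- unique(as.numeric(stats::quantile(times,
                                             probs = seq(0, 1, length.out = max_bins + 1L),
                                             type = 7)))
  if (length(edges) < 2L) edges <- c(min(times), max(times) + 1)
  edges
}

#' Prediction-corrected visual predictive check
#'
#' Simulates replicate datasets from the fitted (or supplied) population
#' model on the observed design, corrects observed and simulated records by
#' the ratio of the bin-median population prediction to each record's own
#' population prediction, and summarises the 5th/50th/95th percentiles per
#' time bin together with the simulation interval of each percentile.
#' Simulated records are clamped at zero and passed through the same LLOQ
#' substitution as the data.
#'
#' @param object A `tgi_fit` or a [tgi_population()].
#' @param data A `tgi_cohort` or data frame in the dataset dialect (defaults
#'   to the data stored in the fit).
#' @param operator Operator records to diagnose.
#' @param n_sim Number of simulated replicates (at least 100).
#' @param bins Optional numeric vector of bin edges (days); by default
#'   quantile-based edges. Bins containing no observations are dropped with
#'   a warning.
#' @param lloq LLOQ applied to simulated records, cm.
#' @param pi Width of the simulated percentile interval (default 0.9).
#' @param seed Seed of the simulation stream.
#' @return A data frame of class `tgi_vpc`: one row per bin with observed
#'   and simulated percentile summaries; attribute `n_sim`.
#' @export
prediction_corrected_vpc <- function(object, data = NULL, operator = "LOCAL",
                                     n_sim = 200L, bins = NULL, lloq = 0.5,
                                     pi = 0.9, seed = 12345L) {
  population <- if (inherits(object, "tgi_fit")) object$population else object
  stopifnot(inherits(population, "tgi_population"), n_sim >= 100L)
  if (is.null(data)) {
    if (!inherits(object, "tgi_fit")) stop("data must be supplied")
    d <- object$data
  } else {
    d <- extract_operator(data, operator)
  }
  times <- unlist(d$times)
  yobs <- unlist(d$y)
  lesion <- rep(seq_along(d$ids), lengths(d$times))
  pred <- predict_ts(population$theta, times)

  if (is.null(bins)) bins <- default_time_bins(times)
  bin <- findInterval(times, bins, rightmost.closed = TRUE)
  bin[bin == 0L] <- 1L
  nb <- length(bins) - 1L
  counts <- tabulate(bin, nbins = nb)
  if (any(counts == 0L)) {
    warning("dropping ", sum(counts == 0L), " empty time bin(s)")
  }
  used <- which(counts > 0L)
  pc_med <- vapply(used, function(b) stats::median(pred[bin == b]), 0)
  pcorr <- numeric(length(times))
  for (k in seq_along(used)) {
    sel <- bin == used[k]
    pcorr[sel] <- pc_med[k] / pred[sel]
  }
  probs <- c(0.05, 0.5, 0.95)
  obs_pct <- t(vapply(used, function(b)
    stats::quantile(yobs[bin == b] * pcorr[bin == b], probs, names = FALSE),
    numeric(3L)))

  n_les <- length(d$ids)
  sim_pct <- with_seed(seed, {
    arr <- array(NA_real_, c(n_sim, length(used), 3L))
    w <- sqrt(as.numeric(population$omega2))
    for (s in seq_len(n_sim)) {
      eta <- matrix(rnorm(3L * n_les, 0, rep(w, each = n_les)), n_les, 3L)
      ind_pred <- population$theta$ts0 * exp(eta[lesion, 1L]) *
        (exp(population$theta$kg * exp(eta[lesion, 2L]) * times) +
           exp(-population$theta$kd * exp(eta[lesion, 3L]) * times) - 1)
      ysim <- pmax(ind_pred + rnorm(length(times), 0, population$sigma_add), 0)
      ysim <- apply_lloq(ysim, lloq)$value
      for (k in seq_along(used)) {
        sel <- bin == used[k]
        arr[s, k, ] <- stats::quantile(ysim[sel] * pcorr[sel], probs,
                                       names = FALSE)
      }
    }
    arr
  })
  qlo <- (1 - pi) / 2; qhi <- 1 - qlo
  band <- function(j, q) apply(sim_pct[, , j, drop = FALSE], 2L,
                               stats::quantile, probs = q, names = FALSE)
  out <- data.frame(bin = used,
                    t_lo = bins[used], t_hi = bins[used + 1L],
                    t_med = vapply(used, function(b) stats::median(times[bin == b]), 0),
                    n = counts[used],
                    obs_p5 = obs_pct[, 1L], obs_p50 = obs_pct[, 2L],
                    obs_p95 = obs_pct[, 3L],
                    sim_p5_lo = band(1L, qlo), sim_p5_hi = band(1L, qhi),
                    sim_p50_lo = band(2L, qlo), sim_p50_hi = band(2L, qhi),
                    sim_p95_lo = band(3L, qlo), sim_p95_hi = band(3L, qhi))
  attr(out, "n_sim") <- n_sim
  class(out) <- c("tgi_vpc", "data.frame")
  out
}
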