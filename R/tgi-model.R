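#' Structural parameters of the tumour growth inhibition model
#'
#' A lesion's longest-diameter kinetics are described by a biexponential
#' growth/decay curve with three parameters: the baseline diameter `ts0`
#' (cm), a first-order growth rate constant `kg` (per day) and a first-order
#' decay rate constant `kd` (per day) representing the drug effect.
#'
#' `kg = 0` (pure decay) and `kd = 0` (pure growth) are admitted as
#' degenerate lesions; the population estimator keeps both strictly positive
#' through its log parameterisation, but the structural model itself does
#' not require it.
#'
#' @param ts0 Baseline tumour size, cm; strictly positive.
#' @param kg Growth rate constant, per day; non-negative.
#' @param kd Decay rate constant, per day; non-negative.
#' @return An object of class `tgi_params`.
#' @examples
#' p <- tgi_params(ts0 = 3.1, kg = 0.0012, kd = 0.0077)
#' predict_ts(p, c(0, 59, 180))
#' @export
tgi_params <- function(ts0, kg, kd) {
  stopifnot(is.numeric(ts0), length(ts0) == 1L, is.finite(ts0), ts0 > 0,
            is.numeric(kg), length(kg) == 1L, is.finite(kg), kg >= 0,
            is.numeric(kd), length(kd) == 1L, is.finite(kd), kd >= 0)
  structure(list(ts0 = ts0, kg = kg, kd = kd), class = "tgi_params")
}

#' @export
print.tgi_params <- function(x, ...) {
  cat(sprintf("TGI structural parameters: TS(0) = %g cm, Kg = %g /day, Kd = %g /day\n",
              x$ts0, x$kg, x$kd))
  invisible(x)
}

as_tgi_params <- function(p) {
  if (inherits(p, "tgi_params")) return(p)
  if (is.numeric(p) && length(p) == 3L) return(tgi_params(p[[1L]], p[[2L]], p[[3L]]))
  stop("expected a 'tgi_params' object or a numeric triple (ts0, kg, kd)")
}

#' Population model: typical values, inter-individual variances, residual SD
#'
#' Bundles the fixed effects (typical structural parameters), the diagonal
#' variances of the lognormal random effects on TS(0), Kg and Kd, and the
#' additive residual standard deviation of the measurement error, in cm.
#'
#' @param theta A [tgi_params()] object (population typical values).
#' @param omega2 Numeric length-3 vector of random-effect variances for
#'   (TS0, Kg, Kd); all non-negative.
#' @param sigma_add Additive residual standard deviation, cm; non-negative.
#' @return An object of class `tgi_population`.
#' @examples
#' tgi_population(tgi_params(3.1, 0.0012, 0.0077),
#'                omega2 = c(0.31, 0.20, 0.44), sigma_add = 0.43)
#' @export
tgi_population <- function(theta, omega2, sigma_add) {
  theta <- as_tgi_params(theta)
  stopifnot(is.numeric(omega2), length(omega2) == 3L, all(is.finite(omega2)),
            all(omega2 >= 0),
            is.numeric(sigma_add), length(sigma_add) == 1L,
            is.finite(sigma_add), sigma_add >= 0)
  omega2 <- as.numeric(omega2)
  names(omega2) <- c("TS0", "Kg", "Kd")
  structure(list(theta = theta, omega2 = omega2, sigma_add = sigma_add),
            class = "tgi_population")
}

#' @export
print.tgi_population <- function(x, ...) {
  cat("TGI population model\n")
  cat(sprintf("  theta:     TS(0) = %g cm, Kg = %g /day, Kd = %g /day\n",
              x$theta$ts0, x$theta$kg, x$theta$kd))
  cat(sprintf("  omega^2:   TS0 = %g, Kg = %g, Kd = %g\n",
              x$omega2[["TS0"]], x$omega2[["Kg"]], x$omega2[["Kd"]]))
  cat(sprintf("  sigma_add: %g cm\n", x$sigma_add))
  invisible(x)
}

#' Predict tumour size under the biexponential TGI model
#'
#' Evaluates `TS(t) = TS(0) * (exp(Kg t) + exp(-Kd t) - 1)`. Since
#' `exp(Kg t) >= 1` for `t >= 0`, the prediction is strictly positive at all
#' non-negative times; the curve falls while drug-induced decay dominates
#' and rises again once regrowth takes over.
#'
#' @param p A [tgi_params()] object.
#' @param t Vector of non-negative times, days.
#' @return Numeric vector of predicted diameters, cm.
#' @export
predict_ts <- function(p, t) {
  p <- as_tgi_params(p)
  stopifnot(is.numeric(t), all(is.finite(t)))
  if (any(t < 0)) stop("negative times are not allowed")
  p$ts0 * (exp(p$kg * t) + exp(-p$kd * t) - 1)
}

#' Individual parameters from typical values and random effects
#'
#' Maps a lesion's random effects onto the structural scale through the
#' lognormal model `P_i = theta_P * exp(eta_i)`, preserving positivity.
#'
#' @param theta A [tgi_params()] object of population typical values.
#' @param eta Numeric length-3 vector of random effects for (TS0, Kg, Kd).
#' @return A [tgi_params()] object for the individual lesion.
#' @export
individual_parameters <- function(theta, eta) {
  theta <- as_tgi_params(theta)
  stopifnot(is.numeric(eta), length(eta) == 3L, all(is.finite(eta)))
  tgi_params(theta$ts0 * exp(eta[[1L]]),
             theta$kg  * exp(eta[[2L]]),
             theta$kd  * exp(eta[[3L]]))
}

#' Time of the tumour size nadir
#'
#' The biexponential profile has a unique interior minimum at
#' `t* = log(kd/kg) / (kg + kd)` provided the decay rate exceeds the growth
#' rate; otherwise the profile is non-decreasing and no interior nadir
#' exists.
#'
#' @param p A [tgi_params()] object with `kd > kg > 0`.
#' @return Nadir time in days.
#' @export
nadir_time <- function(p) {
  p <- as_tgi_params(p)
  if (p$kg <= 0 || p$kd <= 0 || p$kd <= p$kg)
    stop("no interior nadir: requires kd > kg > 0")
  log(p$kd / p$kg) / (p$kg + p$kd)
}

DAYS_PER_MONTH <- 365.25 / 12  # 30.4375; fixed so month figures are reproducible

#' Tumour size doubling time
#'
#' `log(2)/kg`, the time for the growth term to double, reported in days or
#' months. A month is fixed at 365.25/12 = 30.4375 days.
#'
#' @param kg Growth rate constant, per day; strictly positive.
#' @param unit `"days"` or `"months"`.
#' @return Doubling time in the requested unit (unrounded).
#' @export
doubling_time <- function(kg, unit = c("days", "months")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(kg), length(kg) == 1L, is.finite(kg))
  if (kg <= 0) stop("kg must be strictly positive")
  d <- log(2) / kg
  if (unit == "months") d / DAYS_PER_MONTH else d
}

#' Tumour size halving time
#'
#' `log(2)/kd`, the time for the decay term to halve, reported in days or
#' months (30.4375 days).
#'
#' @param kd Decay rate constant, per day; strictly positive.
#' @inheritParams doubling_time
#' @return Halving time in the requested unit (unrounded).
#' @export
halving_time <- function(kd, unit = c("days", "months")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(kd), length(kd) == 1L, is.finite(kd))
  if (kd <= 0) stop("kd must be strictly positive")
  d <- log(2) / kd
  if (unit == "months") d / DAYS_PER_MONTH else d
}

#' Round a kinetic time in months at reporting precision
#'
#' Values of ten months or more are rounded to the nearest integer, shorter
#' times to one decimal, the precision at which such kinetic metrics are
#' conventionally reported.
#'
#' @param months Numeric vector of times in months.
#' @return Rounded numeric vector.
#' @export
round_months <- function(months) {
  ifelse(abs(months) >= 10, round(months), round(months, 1L))
}

#' Bidimensional change equivalent of a unidimensional diameter change
#'
#' Under a spheroid assumption, a relative change `f` in a lesion's longest
#' diameter corresponds to a relative change `(1 + f)^2 - 1` in the product
#' of its two perpendicular diameters. This converts unidimensional
#' (RECIST-style) response thresholds to the bidimensional (WHO-style)
#' scale: a +20% diameter increase maps to +44% in the diameter product.
#'
#' @param f Relative diameter change (fraction, e.g. `0.20` for +20%);
#'   must exceed -1.
#' @return Relative change of the diameter product (fraction).
#' @export
who_recist_threshold <- function(f) {
  stopifnot(is.numeric(f), all(is.finite(f)))
  if (any(f <= -1)) stop("diameter change fraction must be > -1")
  (1 + f)^2 - 1
}
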