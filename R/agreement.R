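#' Relative error ratio of a paired measurement
#'
#' `RER = 100 * (local - central) / mean(local, central)`, the
#' equal-weight agreement statistic for two operators reading the same
#' scan: neither reading is treated as the reference, so the difference is
#' scaled by their mean. For strictly positive pairs the RER lies in
#' (-200, 200); it reaches +/-200 only when exactly one member is zero,
#' and is undefined (returned as `NA`) when both are zero.
#'
#' @param local,central Numeric vectors of paired values.
#' @return Numeric vector of RERs in percent; `NA` where undefined.
#' @examples
#' rer(0.43, 0.40)  # 7.2% -> prints as 7% at integer precision
#' rer(3.0, 0.25)   # 169.2%
#' @export
rer <- function(local, central) {
  stopifnot(is.numeric(local), is.numeric(central),
            length(local) == length(central))
  m <- (local + central) / 2
  out <- ifelse(m == 0, NA_real_, 100 * (local - central) / m)
  out[!is.finite(local) | !is.finite(central)] <- NA_real_
  out
}

#' Bland-Altman limits of agreement
#'
#' `mean(x) +/- 2 * sd(x)` of the agreement statistic, using the sample
#' (n-1) standard deviation. The band has width `4 * sd(x)` and is centred
#' on the mean.
#'
#' @param rers Numeric vector of defined RERs (percent); `NA`s are dropped.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
limits_of_agreement <- function(rers) {
  rers <- rers[is.finite(rers)]
  if (length(rers) < 2L) stop("need at least 2 defined values")
  m <- mean(rers); s <- stats::sd(rers)
  c(lower = m - 2 * s, upper = m + 2 * s)
}

#' Linear regression of paired operator values
#'
#' Ordinary least squares of one operator's values on the other's; `r2` is
#' the squared Pearson correlation (and hence does not depend on which set
#' is the response). Optionally flags and removes gross outliers by their
#' studentized residual before refitting.
#'
#' @param local,central Paired numeric vectors (at least 3 pairs).
#' @param response Which set is regressed on the other; default the central
#'   review is modelled as a function of the local read.
#' @param outlier_threshold `NULL` (no exclusion, the default) or a positive
#'   number: points with `|studentized residual| >` the threshold in an
#'   initial fit are excluded and reported.
#' @return List with `slope`, `intercept`, `r2`, `n`, `excluded` (indices
#'   of removed pairs).
#' @export
agree_regression <- function(local, central,
                             response = c("central", "local"),
                             outlier_threshold = NULL) {
  response <- match.arg(response)
  stopifnot(length(local) == length(central))
  keep <- is.finite(local) & is.finite(central)
  x <- if (response == "central") local[keep] else central[keep]
  y <- if (response == "central") central[keep] else local[keep]
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0) stop("zero variance in the predictor")
  idx <- which(keep)
  excluded <- integer(0L)
  fit <- stats::lm(y ~ x)
  if (!is.null(outlier_threshold)) {
    rs <- stats::rstudent(fit)
    out <- which(is.finite(rs) & abs(rs) > outlier_threshold)
    if (length(out)) {
      excluded <- idx[out]
      x <- x[-out]; y <- y[-out]
      if (length(x) < 3L) stop("outlier exclusion left fewer than 3 pairs")
      fit <- stats::lm(y ~ x)
    }
  }
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = stats::cor(x, y)^2, n = length(x), excluded = excluded)
}

#' Agreement summary of a set of paired values
#'
#' Computes the RER of every pair, drops undefined pairs (both members
#' zero; counted in `n_excluded`), and summarises the distribution
#' (mean, SD, median, quartiles, range), the Bland-Altman limits of
#' agreement and the paired linear regression. Quartiles use linear
#' interpolation between order statistics.
#'
#' @param local,central Paired numeric vectors (at least 2 defined pairs).
#' @param context Optional label describing what is being compared.
#' @inheritParams agree_regression
#' @return An object of class `agreement_summary`.
#' @export
rer_summary <- function(local, central, context = "raw observation",
                        response = "central", outlier_threshold = NULL) {
  rr <- rer(local, central)
  ok <- is.finite(rr)
  if (sum(ok) < 2L) stop("need at least 2 pairs with a defined RER")
  rv <- rr[ok]
  q <- stats::quantile(rv, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  reg <- agree_regression(local[ok], central[ok], response = response,
                          outlier_threshold = outlier_threshold)
  structure(list(context = context, rers = rv, n = sum(ok),
                 n_excluded = sum(!ok),
                 mean_rer = mean(rv), sd_rer = stats::sd(rv),
                 median_rer = q[2L], q1 = q[1L], q3 = q[3L],
                 min = min(rv), max = max(rv),
                 loa = limits_of_agreement(rv),
                 slope = reg$slope, intercept = reg$intercept, r2 = reg$r2,
                 excluded_pairs = reg$excluded),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("Agreement summary (%s): n = %d (%d excluded)\n",
              x$context, x$n, x$n_excluded))
  cat(sprintf("  RER %%: median %.1f [Q1 %.1f, Q3 %.1f], range %.1f to %.1f\n",
              x$median_rer, x$q1, x$q3, x$min, x$max))
  cat(sprintf("  LOA: %.1f to %.1f %%\n", x$loa[["lower"]], x$loa[["upper"]]))
  cat(sprintf("  regression: slope %.2f, intercept %.2f, r2 %.2f\n",
              x$slope, x$intercept, x$r2))
  invisible(x)
}

PATTERN_LEVELS <- c("SIMILAR", "SAME_TREND", "DIFFERENT_TREND")

#' Classify a lesion's paired profile pattern
#'
#' A lesion whose two operator profiles never differ by more than the
#' threshold is `SIMILAR`. Otherwise, if all nonzero differences share one
#' sign the profiles never cross and the lesion is `SAME_TREND` (different
#' but parallel in trend); a sign change marks `DIFFERENT_TREND`.
#'
#' @param local,central The lesion's paired diameters over time, cm.
#' @param threshold Absolute-difference threshold, cm; defaults to the
#'   0.5 cm limit of quantification.
#' @return A factor with levels `SIMILAR`, `SAME_TREND`, `DIFFERENT_TREND`.
#' @export
classify_pattern <- function(local, central, threshold = 0.5) {
  stopifnot(length(local) == length(central), length(local) >= 1L,
            threshold >= 0)
  d <- local - central
  label <- if (max(abs(d)) <= threshold) {
    "SIMILAR"
  } else {
    nz <- d[d != 0]
    if (all(nz > 0) || all(nz < 0)) "SAME_TREND" else "DIFFERENT_TREND"
  }
  factor(label, levels = PATTERN_LEVELS)
}

pair_observations <- function(data) {
  ob <- if (inherits(data, "tgi_cohort")) data$observations else data
  stopifnot(is.data.frame(ob),
            all(c("ID", "OPER", "TIME", "DV") %in% names(ob)))
  loc <- ob[ob$OPER == "LOCAL", , drop = FALSE]
  cen <- ob[ob$OPER == "CENTRAL", , drop = FALSE]
  key <- c("ID", "TIME")
  m <- merge(loc, cen, by = key, suffixes = c("_local", "_central"))
  m[order(m$ID, m$TIME), , drop = FALSE]
}

#' Census of paired-profile patterns over a cohort
#'
#' Applies [classify_pattern()] to every lesion with paired records and
#' tabulates the class shares.
#'
#' @param data A `tgi_cohort` or data frame in the dataset dialect.
#' @param threshold Absolute-difference threshold, cm.
#' @return Data frame with `pattern`, `n`, `proportion` (summing to 1).
#' @export
pattern_census <- function(data, threshold = 0.5) {
  pairs <- pair_observations(data)
  if (nrow(pairs) == 0L) stop("no paired observations")
  labs <- vapply(split(pairs, pairs$ID), function(df)
    as.character(classify_pattern(df$DV_local, df$DV_central, threshold)),
    "")
  tab <- table(factor(labs, levels = PATTERN_LEVELS))
  data.frame(pattern = names(tab), n = as.integer(tab),
             proportion = as.numeric(tab) / sum(tab))
}

#' Measurability discordance between operators
#'
#' Counts paired scans where exactly one operator recorded the lesion as
#' below the limit of quantification (non-measurable) while the other
#' measured it, split by which operator called it non-measurable.
#' Percentages are of all paired observations.
#'
#' @param data A `tgi_cohort` or data frame in the dataset dialect (must
#'   carry the `BLQ` flag).
#' @return List with `n_pairs`, `n_discordant`, `pct_discordant`,
#'   `n_local_blq`, `pct_local_blq`, `n_central_blq`, `pct_central_blq`.
#' @export
measurability_discordance <- function(data) {
  pairs <- pair_observations(data)
  stopifnot(all(c("BLQ_local", "BLQ_central") %in% names(pairs)))
  n <- nrow(pairs)
  if (n == 0L) stop("no paired observations")
  lb <- pairs$BLQ_local == 1L
  cb <- pairs$BLQ_central == 1L
  local_only <- sum(lb & !cb)     # local read non-measurable, central measured
  central_only <- sum(cb & !lb)
  list(n_pairs = n,
       n_discordant = local_only + central_only,
       pct_discordant = 100 * (local_only + central_only) / n,
       n_local_blq = local_only,
       pct_local_blq = 100 * local_only / n,
       n_central_blq = central_only,
       pct_central_blq = 100 * central_only / n)
}

#' Compare the local and the central population fits
#'
#' Computes the relative error ratio of every population parameter between
#' the two fits, and for each individual parameter (baseline size, growth
#' and decay rates) the full agreement summary of the paired empirical
#' Bayes estimates: regression slope/intercept/r2, RER quartiles and
#' Bland-Altman limits of agreement. Lesions present in only one fit are
#' excluded and reported.
#'
#' @param local_fit,central_fit `tgi_fit` objects for the two operators.
#' @param outlier_threshold Passed to [rer_summary()] for the EBE
#'   regressions (default no exclusion).
#' @return An object of class `tgi_fit_comparison` with elements
#'   `population` (parameter table with columns `parameter`, `local`,
#'   `central`, `rer_pct`), `ebe` (named list of `agreement_summary`),
#'   `excluded_ids`, `n_lesions`.
#' @export
compare_fits <- function(local_fit, central_fit, outlier_threshold = NULL) {
  stopifnot(inherits(local_fit, "tgi_fit") || is.list(local_fit),
            inherits(central_fit, "tgi_fit") || is.list(central_fit))
  pl <- local_fit$population; pc <- central_fit$population
  pop_local <- c(TS0 = pl$theta$ts0, Kg = pl$theta$kg, Kd = pl$theta$kd,
                 sigma = pl$sigma_add)
  pop_central <- c(TS0 = pc$theta$ts0, Kg = pc$theta$kg, Kd = pc$theta$kd,
                   sigma = pc$sigma_add)
  pop <- data.frame(parameter = names(pop_local),
                    local = unname(pop_local), central = unname(pop_central),
                    rer_pct = rer(unname(pop_local), unname(pop_central)))
  el <- local_fit$ebes; ec <- central_fit$ebes
  common <- intersect(el$ID, ec$ID)
  if (length(common) == 0L)
    stop("the two fits share no lesion IDs (local: ",
         paste(utils::head(el$ID, 5L), collapse = ","), "...; central: ",
         paste(utils::head(ec$ID, 5L), collapse = ","), "...)")
  excluded <- union(setdiff(el$ID, common), setdiff(ec$ID, common))
  el <- el[match(common, el$ID), ]; ec <- ec[match(common, ec$ID), ]
  ebe <- list(
    TS0 = rer_summary(el$TS0_i, ec$TS0_i, context = "TS0 EBE",
                      outlier_threshold = outlier_threshold),
    Kg = rer_summary(el$KG_i, ec$KG_i, context = "Kg EBE",
                     outlier_threshold = outlier_threshold),
    Kd = rer_summary(el$KD_i, ec$KD_i, context = "Kd EBE",
                     outlier_threshold = outlier_threshold))
  structure(list(population = pop, ebe = ebe, excluded_ids = excluded,
                 n_lesions = length(common)),
            class = "tgi_fit_comparison")
}

#' @export
print.tgi_fit_comparison <- function(x, ...) {
  cat("Local vs central fit comparison\n")
  cat("Population parameters (RER % rounded to integer):\n")
  tab <- x$population
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-6s local %-10.4g central %-10.4g RER %d%%\n",
                tab$parameter[i], tab$local[i], tab$central[i],
                round(tab$rer_pct[i])))
  cat(sprintf("Individual estimates (%d shared lesions):\n", x$n_lesions))
  for (nm in names(x$ebe)) {
    s <- x$ebe[[nm]]
    cat(sprintf("  %-4s slope %.2f, r2 %.2f, median RER %.1f%%, LOA %.1f to %.1f%%\n",
                nm, s$slope, s$r2, s$median_rer, s$loa[["lower"]],
                s$loa[["upper"]]))
  }
  if (length(x$excluded_ids))
    cat("  excluded lesions:", paste(x$excluded_ids, collapse = ", "), "\n")
  invisible(x)
}
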