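#' Configuration of the synthetic paired-measurement cohort
#'
#' Describes a cohort of lesions, each measured twice per CT scan (a "local"
#' hospital read and a "central" review-centre read of the same image), with
#' the sampling structure of a sparse oncology trial: 1-5 visits per lesion,
#' inter-visit gaps of several weeks, lognormal inter-lesion variability in
#' the growth/decay kinetics, additive operator measurement noise, and
#' substitution of values below the limit of quantification.
#'
#' Visit counts are drawn from a Poisson distribution truncated to
#' `visit_range`; the default rate gives a mean of about 3 visits. Gaps are
#' drawn from a normal distribution truncated to `gap_range` (default median
#' 59 days, bounds 19-116 days). Lesions are grouped into patients by the
#' `lesions_per_patient_prob` distribution (default median 2, range 1-6);
#' grouping affects only identifiers, as the analysis is lesion-level.
#'
#' @param n_lesions Number of lesions to simulate.
#' @param population A [tgi_population()] giving the true typical values,
#'   inter-lesion variances and (unused here) residual SD. The default is a
#'   typical advanced non-small-cell lung cancer profile: baseline 3.1 cm,
#'   slow regrowth (Kg = 0.0012/day) and treatment-induced decay
#'   (Kd = 0.0077/day).
#' @param operator_sigma Length-2 vector, cm: additive measurement SD of the
#'   local and the central operator.
#' @param operator_bias Length-2 multiplicative bias of each operator on the
#'   true diameter (default none); exposed for sensitivity studies.
#' @param lloq Lower limit of quantification, cm. Values strictly below it
#'   are recorded at `lloq/2` and flagged.
#' @param visit_lambda Rate of the truncated Poisson visit-count draw.
#' @param visit_range Integer bounds on visits per lesion.
#' @param gap_mean,gap_sd,gap_range Normal parameters and truncation bounds
#'   of the inter-visit gap, days.
#' @param lesions_per_patient_prob Probabilities of 1..k lesions per patient.
#' @param dropout If `TRUE`, a lesion's follow-up stops at the first visit
#'   where its true size has regrown more than 20% above its running
#'   minimum (progression-driven withdrawal); off by default.
#' @param seed Integer seed making the whole cohort reproducible, or `NULL`.
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_lesions = 10, seed = 7)
#' sim <- simulate_cohort(cfg)
#' head(sim$observations)
#' @export
cohort_config <- function(n_lesions = 120,
                          population = tgi_population(
                            tgi_params(3.1, 0.0012, 0.0077),
                            omega2 = c(0.31, 0.20, 0.44),
                            sigma_add = 0.43),
                          operator_sigma = c(local = 0.43, central = 0.43),
                          operator_bias = c(local = 1, central = 1),
                          lloq = 0.5,
                          visit_lambda = 3.35,
                          visit_range = c(1L, 5L),
                          gap_mean = 59, gap_sd = 15, gap_range = c(19, 116),
                          lesions_per_patient_prob =
                            c(0.45, 0.25, 0.15, 0.08, 0.05, 0.02),
                          dropout = FALSE,
                          seed = NULL) {
  stopifnot(is.numeric(n_lesions), length(n_lesions) == 1L,
            n_lesions == round(n_lesions),
            inherits(population, "tgi_population"),
            is.numeric(operator_sigma), length(operator_sigma) == 2L,
            all(operator_sigma >= 0),
            is.numeric(operator_bias), length(operator_bias) == 2L,
            all(operator_bias > 0),
            is.numeric(lloq), length(lloq) == 1L, lloq > 0,
            is.numeric(visit_lambda), visit_lambda > 0,
            length(visit_range) == 2L, visit_range[1L] >= 1,
            visit_range[1L] <= visit_range[2L],
            is.numeric(gap_mean), is.numeric(gap_sd), gap_sd >= 0,
            length(gap_range) == 2L, gap_range[1L] > 0,
            gap_range[1L] <= gap_range[2L],
            is.numeric(lesions_per_patient_prob),
            all(lesions_per_patient_prob >= 0),
            sum(lesions_per_patient_prob) > 0,
            is.logical(dropout), length(dropout) == 1L)
  if (n_lesions < 1) stop("n_lesions must be at least 1")
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed))
    seed <- as.integer(seed)
  }
  names(operator_sigma) <- names(operator_bias) <- c("local", "central")
  structure(list(n_lesions = as.integer(n_lesions), population = population,
                 operator_sigma = operator_sigma, operator_bias = operator_bias,
                 lloq = lloq, visit_lambda = visit_lambda,
                 visit_range = as.integer(visit_range),
                 gap_mean = gap_mean, gap_sd = gap_sd, gap_range = gap_range,
                 lesions_per_patient_prob =
                   lesions_per_patient_prob / sum(lesions_per_patient_prob),
                 dropout = dropout, seed = seed),
            class = "cohort_config")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Draw per-lesion structural parameters
#'
#' Samples one random-effect triple per lesion from independent
#' `Normal(0, omega2)` distributions and maps it through the lognormal
#' individual-parameter model.
#'
#' @param config A [cohort_config()].
#' @param n Number of lesions (defaults to `config$n_lesions`).
#' @return A data frame with columns `ID`, `ETA_TS0`, `ETA_KG`, `ETA_KD`,
#'   `TS0`, `KG`, `KD`.
#' @export
sample_individuals <- function(config, n = config$n_lesions) {
  stopifnot(inherits(config, "cohort_config"))
  pop <- config$population
  with_seed(config$seed, {
    eta <- vapply(pop$omega2, function(w2) rnorm(n, 0, sqrt(w2)),
                  numeric(n))
    eta <- matrix(eta, nrow = n)
    data.frame(ID = seq_len(n),
               ETA_TS0 = eta[, 1L], ETA_KG = eta[, 2L], ETA_KD = eta[, 3L],
               TS0 = pop$theta$ts0 * exp(eta[, 1L]),
               KG = pop$theta$kg * exp(eta[, 2L]),
               KD = pop$theta$kd * exp(eta[, 3L]))
  })
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(0L)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

rtrunc_pois <- function(n, lambda, lo, hi) {
  k <- lo:hi
  p <- dpois(k, lambda)
  k[sample.int(length(k), n, replace = TRUE, prob = p)]
}

#' Draw one lesion's visit schedule
#'
#' The first visit is the baseline scan at day 0; the visit count comes from
#' the truncated Poisson and each gap from the truncated normal of the
#' configuration.
#'
#' @param config A [cohort_config()].
#' @return Strictly increasing numeric vector of times (days) starting at 0.
#' @export
sample_visit_schedule <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, sample_schedule_impl(config))
}

sample_schedule_impl <- function(config) {
  nv <- rtrunc_pois(1L, config$visit_lambda,
                    config$visit_range[1L], config$visit_range[2L])
  if (nv == 1L) return(0)
  gaps <- rtrunc_norm(nv - 1L, config$gap_mean, config$gap_sd,
                      config$gap_range[1L], config$gap_range[2L])
  cumsum(c(0, gaps))
}

#' Record a measurement subject to the lower limit of quantification
#'
#' Values strictly below `lloq` are non-measurable: they are recorded at
#' half the limit and flagged as below the limit of quantification (BLQ).
#' Values at the limit are kept.
#'
#' @param value Non-negative measured diameters, cm.
#' @param lloq Lower limit of quantification, cm.
#' @return A list with components `value` (recorded diameters) and `blq`
#'   (logical flags).
#' @export
apply_lloq <- function(value, lloq) {
  stopifnot(is.numeric(value), all(is.finite(value)),
            is.numeric(lloq), length(lloq) == 1L, lloq > 0)
  if (any(value < 0)) stop("measured values must be non-negative")
  blq <- value < lloq
  list(value = ifelse(blq, lloq / 2, value), blq = blq)
}

#' Simulate a paired local/central lesion cohort
#'
#' For each lesion one true biexponential profile is drawn (lognormal
#' inter-lesion variability), then each operator's record at each visit is
#' truth times operator bias plus independent additive Gaussian noise,
#' clamped at zero and passed through the LLOQ rule. Both operators read
#' the same scan, so they share the visit schedule and the true profile.
#'
#' @param config A [cohort_config()].
#' @return An object of class `tgi_cohort`: a list with
#'   \describe{
#'     \item{observations}{data frame `ID`, `PTID`, `OPER` (LOCAL/CENTRAL),
#'       `TIME` (days), `DV` (recorded diameter, cm), `BLQ` (0/1).}
#'     \item{truth}{noise-free sidecar: `ID`, `TS0`, `KG`, `KD`, `TIME`,
#'       `TRUE_TS`.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_lesions
    # patient grouping: draw lesions-per-patient counts until n is covered
    kmax <- length(config$lesions_per_patient_prob)
    ptid <- integer(0L); pt <- 0L
    while (length(ptid) < n) {
      pt <- pt + 1L
      k <- sample.int(kmax, 1L, prob = config$lesions_per_patient_prob)
      ptid <- c(ptid, rep(pt, k))
    }
    ptid <- ptid[seq_len(n)]

    pop <- config$population
    eta <- cbind(rnorm(n, 0, sqrt(pop$omega2[[1L]])),
                 rnorm(n, 0, sqrt(pop$omega2[[2L]])),
                 rnorm(n, 0, sqrt(pop$omega2[[3L]])))
    obs <- vector("list", n); tru <- vector("list", n)
    for (i in seq_len(n)) {
      p_i <- individual_parameters(pop$theta, eta[i, ])
      times <- sample_schedule_impl(config)
      ts_true <- predict_ts(p_i, times)
      if (config$dropout && length(times) > 1L) {
        run_min <- cummin(ts_true)
        prog <- ts_true > 1.2 * run_min & seq_along(times) > 1L
        if (any(prog)) {           # keep visits up to and including progression
          keep <- seq_len(which(prog)[1L])
          times <- times[keep]; ts_true <- ts_true[keep]
        }
      }
      rec <- lapply(c(local = 1L, central = 2L), function(opi) {
        y <- pmax(ts_true * config$operator_bias[[opi]] +
                    rnorm(length(times), 0, config$operator_sigma[[opi]]), 0)
        apply_lloq(y, config$lloq)
      })
      obs[[i]] <- data.frame(
        ID = i, PTID = ptid[i],
        OPER = rep(c("LOCAL", "CENTRAL"), each = length(times)),
        TIME = rep(times, 2L),
        DV = c(rec$local$value, rec$central$value),
        BLQ = as.integer(c(rec$local$blq, rec$central$blq)))
      tru[[i]] <- data.frame(ID = i, TS0 = p_i$ts0, KG = p_i$kg, KD = p_i$kd,
                             TIME = times, TRUE_TS = ts_true)
    }
    structure(list(observations = do.call(rbind, obs),
                   truth = do.call(rbind, tru),
                   config = config),
              class = "tgi_cohort")
  })
}

#' @export
print.tgi_cohort <- function(x, ...) {
  ob <- x$observations
  cat(sprintf("Paired lesion cohort: %d lesions, %d patients, %d observations (%d paired scans)\n",
              length(unique(ob$ID)), length(unique(ob$PTID)), nrow(ob),
              nrow(ob[ob$OPER == "LOCAL", , drop = FALSE])))
  cat(sprintf("  BLQ records: %d (%.1f%%)\n", sum(ob$BLQ),
              100 * mean(ob$BLQ)))
  invisible(x)
}

COHORT_COLUMNS <- c("ID", "PTID", "OPER", "TIME", "DV", "BLQ")

#' Write / read a paired lesion dataset
#'
#' The dataset dialect is a comma-delimited table with header columns `ID`,
#' `PTID`, `OPER` (`LOCAL`/`CENTRAL`), `TIME` (days), `DV` (cm) and `BLQ`
#' (0/1), one row per operator per visit. The optional noise-free truth
#' sidecar holds `ID`, `TS0`, `KG`, `KD`, `TIME`, `TRUE_TS`.
#'
#' @param cohort A `tgi_cohort` (or a data frame in the dataset dialect).
#' @param path File to write the observation table to.
#' @param truth_path Optional file for the truth sidecar.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `tgi_cohort` (with `truth = NULL` unless a sidecar is supplied).
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  ob <- if (inherits(cohort, "tgi_cohort")) cohort$observations else cohort
  stopifnot(is.data.frame(ob), all(COHORT_COLUMNS %in% names(ob)))
  utils::write.csv(ob[, COHORT_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(truth_path) && inherits(cohort, "tgi_cohort") &&
      !is.null(cohort$truth))
    utils::write.csv(cohort$truth, truth_path, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param lloq Lower limit of quantification used to validate recorded
#'   values (no value may fall below `lloq/2`).
#' @export
read_cohort <- function(path, truth_path = NULL, lloq = 0.5) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    warning("dataset file ", path, " contains no observations")
    ob <- data.frame(ID = integer(0L), PTID = integer(0L),
                     OPER = character(0L), TIME = numeric(0L),
                     DV = numeric(0L), BLQ = integer(0L))
    return(structure(list(observations = ob, truth = NULL, config = NULL),
                     class = "tgi_cohort"))
  }
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("dataset is missing column(s): ", paste(missing_cols, collapse = ", "))
  ob <- raw[, COHORT_COLUMNS]
  line <- seq_len(nrow(ob)) + 1L   # header is line 1
  bad <- which(!ob$OPER %in% c("LOCAL", "CENTRAL") |
                 !is.finite(ob$TIME) | ob$TIME < 0 |
                 !is.finite(ob$DV) | !ob$BLQ %in% c(0L, 1L))
  if (length(bad))
    stop("malformed dataset row(s) at line(s) ",
         paste(utils::head(line[bad], 10L), collapse = ", "))
  low <- which(ob$DV < lloq / 2)
  if (length(low))
    stop("DV below lloq/2 (", lloq / 2, " cm) at line(s) ",
         paste(utils::head(line[low], 10L), collapse = ", "))
  for (key in split(seq_len(nrow(ob)), paste(ob$ID, ob$OPER))) {
    tt <- ob$TIME[key]
    if (any(diff(tt) <= 0))
      stop("times not strictly increasing for lesion ", ob$ID[key[1L]],
           " (", ob$OPER[key[1L]], ") at line(s) ",
           paste(line[key][which(diff(tt) <= 0) + 1L], collapse = ", "))
  }
  truth <- NULL
  if (!is.null(truth_path)) {
    truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
    need <- c("ID", "TS0", "KG", "KD", "TIME", "TRUE_TS")
    if (!all(need %in% names(truth)))
      stop("truth sidecar is missing column(s): ",
           paste(setdiff(need, names(truth)), collapse = ", "))
  }
  structure(list(observations = ob, truth = truth, config = NULL),
            class = "tgi_cohort")
}

config_keys <- function() {
  c("n_lesions", "theta_ts0", "theta_kg", "theta_kd",
    "omega2_ts0", "omega2_kg", "omega2_kd", "sigma_add",
    "sigma_local", "sigma_central", "bias_local", "bias_central",
    "lloq", "visit_lambda", "visit_min", "visit_max",
    "gap_mean", "gap_sd", "gap_min", "gap_max",
    "lesions_per_patient_prob", "dropout", "seed")
}

#' Write / read a cohort configuration as a flat key-value file
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are
#' rejected. `lesions_per_patient_prob` is a comma-separated list.
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @return `read_cohort_config` returns a [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  pop <- config$population
  kv <- c(
    n_lesions = config$n_lesions,
    theta_ts0 = pop$theta$ts0, theta_kg = pop$theta$kg,
    theta_kd = pop$theta$kd,
    omega2_ts0 = pop$omega2[[1L]], omega2_kg = pop$omega2[[2L]],
    omega2_kd = pop$omega2[[3L]], sigma_add = pop$sigma_add,
    sigma_local = config$operator_sigma[[1L]],
    sigma_central = config$operator_sigma[[2L]],
    bias_local = config$operator_bias[[1L]],
    bias_central = config$operator_bias[[2L]],
    lloq = config$lloq, visit_lambda = config$visit_lambda,
    visit_min = config$visit_range[1L], visit_max = config$visit_range[2L],
    gap_mean = config$gap_mean, gap_sd = config$gap_sd,
    gap_min = config$gap_range[1L], gap_max = config$gap_range[2L],
    lesions_per_patient_prob =
      paste(config$lesions_per_patient_prob, collapse = ","),
    dropout = as.integer(config$dropout))
  if (!is.null(config$seed)) kv <- c(kv, seed = config$seed)
  writeLines(paste(names(kv), kv, sep = " = "), path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  unknown <- setdiff(keys, config_keys())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicate config key(s): ", paste(keys[duplicated(keys)], collapse = ", "))
  g <- function(key, default) if (key %in% keys) vals[keys == key] else default
  num <- function(key, default) as.numeric(g(key, default))
  cohort_config(
    n_lesions = num("n_lesions", 120),
    population = tgi_population(
      tgi_params(num("theta_ts0", 3.1), num("theta_kg", 0.0012),
                 num("theta_kd", 0.0077)),
      omega2 = c(num("omega2_ts0", 0.31), num("omega2_kg", 0.20),
                 num("omega2_kd", 0.44)),
      sigma_add = num("sigma_add", 0.43)),
    operator_sigma = c(num("sigma_local", 0.43), num("sigma_central", 0.43)),
    operator_bias = c(num("bias_local", 1), num("bias_central", 1)),
    lloq = num("lloq", 0.5),
    visit_lambda = num("visit_lambda", 3.35),
    visit_range = c(num("visit_min", 1), num("visit_max", 5)),
    gap_mean = num("gap_mean", 59), gap_sd = num("gap_sd", 15),
    gap_range = c(num("gap_min", 19), num("gap_max", 116)),
    lesions_per_patient_prob =
      as.numeric(strsplit(g("lesions_per_patient_prob",
                            "0.45,0.25,0.15,0.08,0.05,0.02"), ",")[[1L]]),
    dropout = num("dropout", 0) != 0,
    seed = if ("seed" %in% keys) num("seed", NA) else NULL)
}
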