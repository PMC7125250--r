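#' Write / read a fit's output tables
#'
#' A fit is persisted as two delimited tables: the parameter table
#' (`parameter`, `estimate`, `rse_pct`) and the empirical Bayes table
#' (`ID`, `ETA_TS0`, `ETA_KG`, `ETA_KD`, `TS0_i`, `KG_i`, `KD_i`).
#' `read_fit` rebuilds a minimal `tgi_fit`-compatible object sufficient for
#' [compare_fits()] and reporting.
#'
#' @param fit A `tgi_fit`.
#' @param params_path,ebes_path File paths of the two tables.
#' @return `read_fit` returns a list of class `tgi_fit` with `population`,
#'   `rse` and `ebes`.
#' @export
write_fit <- function(fit, params_path, ebes_path) {
  stopifnot(inherits(fit, "tgi_fit"))
  utils::write.csv(fit_parameter_table(fit), params_path, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(fit$ebes, ebes_path, row.names = FALSE, quote = FALSE)
  invisible(params_path)
}

#' @rdname write_fit
#' @export
read_fit <- function(params_path, ebes_path) {
  par <- utils::read.csv(params_path, stringsAsFactors = FALSE)
  need <- c("TS0", "Kg", "Kd", "IIV_TS0", "IIV_Kg", "IIV_Kd", "sigma")
  if (!all(need %in% par$parameter))
    stop("parameter table ", params_path, " is missing rows: ",
         paste(setdiff(need, par$parameter), collapse = ", "))
  g <- function(nm) unname(par$estimate[match(nm, par$parameter)])
  ebes <- utils::read.csv(ebes_path, stringsAsFactors = FALSE)
  ecols <- c("ID", "ETA_TS0", "ETA_KG", "ETA_KD", "TS0_i", "KG_i", "KD_i")
  if (!all(ecols %in% names(ebes)))
    stop("EBE table ", ebes_path, " is missing column(s): ",
         paste(setdiff(ecols, names(ebes)), collapse = ", "))
  structure(list(
    population = tgi_population(tgi_params(g("TS0"), g("Kg"), g("Kd")),
                                omega2 = c(g("IIV_TS0"), g("IIV_Kg"),
                                           g("IIV_Kd")),
                                sigma_add = g("sigma")),
    rse = stats::setNames(par$rse_pct, par$parameter),
    ebes = ebes, converged = NA), class = "tgi_fit")
}

#' Write the agreement report of a pipeline run
#'
#' One block per comparison (raw paired observations and each individual
#' parameter), with the distribution, limits of agreement and regression
#' summaries, plus the population-parameter RER table, the pattern census
#' and the measurability-discordance table.
#'
#' @param comparison A `tgi_fit_comparison`.
#' @param raw An `agreement_summary` of the raw paired observations.
#' @param census A [pattern_census()] table.
#' @param discordance A [measurability_discordance()] list.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_agreement_report <- function(comparison, raw, census, discordance, dir) {
  sum_row <- function(s) data.frame(
    comparison = s$context, n = s$n, n_excluded = s$n_excluded,
    median_rer = s$median_rer, q1 = s$q1, q3 = s$q3,
    min = s$min, max = s$max,
    loa_lower = s$loa[["lower"]], loa_upper = s$loa[["upper"]],
    slope = s$slope, intercept = s$intercept, r2 = s$r2)
  blocks <- rbind(sum_row(raw), do.call(rbind, lapply(comparison$ebe, sum_row)))
  paths <- file.path(dir, c("agreement_summary.csv", "population_rer.csv",
                            "pattern_census.csv", "discordance.csv"))
  utils::write.csv(blocks, paths[1L], row.names = FALSE, quote = FALSE)
  utils::write.csv(comparison$population, paths[2L], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(census, paths[3L], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(
    quantity = c("paired_scans", "discordant", "local_blq_only",
                 "central_blq_only"),
    n = c(discordance$n_pairs, discordance$n_discordant,
          discordance$n_local_blq, discordance$n_central_blq),
    pct = c(100, discordance$pct_discordant, discordance$pct_local_blq,
            discordance$pct_central_blq)),
    paths[4L], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Run the full simulate-fit-compare pipeline
#'
#' Executes the analysis end to end: simulate a paired cohort, fit the TGI
#' mixed-effects model to the local and the central records separately,
#' and compare raw measurements and model outputs. Each stage writes its
#' outputs under `out_dir` and a JSON run manifest records the
#' configuration snapshot, per-stage status, outputs and record counts. A
#' stage failure halts the run with the manifest recording the partial
#' completion. Reruns with the same configuration and seed reproduce all
#' outputs.
#'
#' The single configured seed fans out into deterministic per-stage
#' substreams so stages can be rerun independently.
#'
#' @param config A [cohort_config()] or the path of a key-value config file.
#' @param out_dir Output directory (created if needed).
#' @param vpc If `TRUE`, also run a prediction-corrected visual predictive
#'   check on each fit.
#' @param n_sim Number of VPC replicates.
#' @param control A [tgi_control()] passed to both fits.
#' @return The run manifest (a list), invisibly.
#' @export
run_pipeline <- function(config, out_dir, vpc = FALSE, n_sim = 200L,
                         control = tgi_control()) {
  if (is.character(config)) config <- read_cohort_config(config)
  stopifnot(inherits(config, "cohort_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  seed <- if (is.null(config$seed)) 12345L else config$seed
  stage_seed <- function(k) (seed + 1000L * k) %% .Machine$integer.max

  manifest <- list(
    package = "tgiagree",
    version = as.character(utils::packageVersion("tgiagree")),
    seed = seed,
    config = file.path(out_dir, "config_used.txt"),
    stages = list())
  write_cohort_config(config, manifest$config)
  manifest_path <- file.path(out_dir, "manifest.json")
  flush_manifest <- function()
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  record <- function(name, status, outputs = character(0L), n_records = NA,
                     note = "") {
    manifest$stages[[name]] <<- list(status = status,
                                     outputs = as.list(outputs),
                                     n_records = n_records, note = note)
    flush_manifest()
  }
  run_stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e) e)
    if (inherits(out, "error")) {
      record(name, "failed", note = conditionMessage(out))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(out),
           call. = FALSE)
    }
    out
  }

  # stage 1: simulate
  cohort <- run_stage("simulate", function() {
    cfg <- config; cfg$seed <- stage_seed(1L)
    sim <- simulate_cohort(cfg)
    write_cohort(sim, file.path(out_dir, "dataset.csv"),
                 truth_path = file.path(out_dir, "truth.csv"))
    record("simulate", "completed",
           file.path(out_dir, c("dataset.csv", "truth.csv")),
           nrow(sim$observations))
    sim
  })

  # stages 2-3: fit each operator
  fits <- list()
  for (op in c("LOCAL", "CENTRAL")) {
    nm <- paste0("fit_", tolower(op))
    fits[[op]] <- run_stage(nm, function() {
      fit <- fit_tgi(cohort, operator = op, control = control)
      pp <- file.path(out_dir, sprintf("params_%s.csv", tolower(op)))
      ep <- file.path(out_dir, sprintf("ebes_%s.csv", tolower(op)))
      write_fit(fit, pp, ep)
      if (!fit$converged)
        warning("fit for operator ", op, " did not fully converge")
      record(nm, "completed", c(pp, ep), fit$n_obs,
             note = sprintf("ofv=%.3f converged=%s", fit$ofv, fit$converged))
      fit
    })
  }

  # stage 4: agreement
  run_stage("compare", function() {
    pairs <- pair_observations(cohort)
    raw <- rer_summary(pairs$DV_local, pairs$DV_central,
                       context = "raw observation")
    comparison <- compare_fits(fits$LOCAL, fits$CENTRAL)
    census <- pattern_census(cohort, threshold = config$lloq)
    disc <- measurability_discordance(cohort)
    paths <- write_agreement_report(comparison, raw, census, disc, out_dir)
    record("compare", "completed", paths, nrow(pairs))
    NULL
  })

  if (vpc) {
    run_stage("vpc", function() {
      paths <- character(0L)
      for (op in c("LOCAL", "CENTRAL")) {
        v <- prediction_corrected_vpc(fits[[op]], n_sim = n_sim,
                                      lloq = config$lloq,
                                      seed = stage_seed(4L))
        p <- file.path(out_dir, sprintf("vpc_%s.csv", tolower(op)))
        utils::write.csv(as.data.frame(v), p, row.names = FALSE, quote = FALSE)
        paths <- c(paths, p)
      }
      record("vpc", "completed", paths, n_sim)
      NULL
    })
  }
  invisible(manifest)
}
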