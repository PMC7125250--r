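# tgiagree

Inter-operator variability in tumour size measurement, and how far it
propagates into model-based drug-effect evaluation.

In oncology trials the longest diameter of each target lesion is often
measured twice from the same CT scan — once at the treating hospital
("local") and once at a centralised review centre ("central"). The two
reads disagree, and the disagreement matters because both response
categorisation (WHO/RECIST) and longitudinal tumour growth inhibition (TGI)
modelling are driven by these measurements. `tgiagree` provides a complete,
tested pipeline to study this question on simulated paired data:

1. **Structural model.** Lesion diameter follows the biexponential TGI
   model
   `TS(t) = TS(0) · (exp(Kg·t) + exp(−Kd·t) − 1)`,
   with baseline size `TS(0)` (cm), growth rate constant `Kg` (/day) and
   decay (drug-effect) rate constant `Kd` (/day). Individual lesions vary
   lognormally around the typical values, `P_i = θ_P · exp(η_i)`,
   `η ~ N(0, ω²)`, with an additive residual error (SD `σ`, cm).
2. **Synthetic paired cohorts.** A generator draws lesions, sparse visit
   schedules (1–5 visits, gaps 19–116 days), and two operator records per
   scan sharing one true profile, with per-operator additive noise and
   substitution of values below the 0.5 cm limit of quantification by
   0.25 cm (flagged BLQ).
3. **Nonlinear mixed-effects estimation.** The marginal likelihood is
   approximated per lesion by a Laplace approximation at the conditional
   mode of `η` (damped Newton inner iterations, analytic derivatives,
   compiled in C++) and maximised over `θ`, `ω²` and `σ` on the log scale.
   The fit reports estimates, % relative standard errors, empirical Bayes
   individual estimates, and prediction-corrected visual predictive checks.
4. **Agreement analysis.** Paired raw measurements and paired model
   outputs are compared by relative error ratios
   `RER = 100·(local − central)/mean`, Bland–Altman limits of agreement
   `mean ± 2·SD`, linear regression (slope, r²), a three-way profile
   pattern classification (similar / same trend / different trend), and
   measurability-discordance counts (one operator calls the lesion
   non-measurable while the other measures it).

## Worked example

```r
library(tgiagree)

cfg <- cohort_config(n_lesions = 120, seed = 42)  # defaults: see below
sim <- simulate_cohort(cfg)
print(sim)
#> Paired lesion cohort: 120 lesions, 47 patients, 672 observations (336 paired scans)
#>   BLQ records: 31 (4.6%)

fit_local   <- fit_tgi(sim, "LOCAL")
fit_central <- fit_tgi(sim, "CENTRAL")
print(fit_local)
#> TGI mixed-effects fit (LOCAL set): 120 lesions, 336 observations
#>   OFV (-2 log marginal likelihood): 864.833  [converged: TRUE]
#>   TS0      2.9551       (5% RSE)
#>   Kg       0.0012031    (13% RSE)
#>   Kd       0.0075523    (9% RSE)
#>   IIV_TS0  0.30653      (14% RSE)
#>   IIV_Kg   0.17906      (47% RSE)
#>   IIV_Kd   0.24288      (34% RSE)
#>   sigma    0.37856      (7% RSE)
```

The cohort was generated with typical values TS(0) = 3.1 cm,
Kg = 0.0012/day, Kd = 0.0077/day, variances (0.31, 0.20, 0.44) and operator
SD 0.43 cm, so the fit recovers the truth closely; `Kg` is the
least-identified parameter because regrowth is usually seen on few visits.
`round(doubling_time(fit_local$population$theta$kg, "months"))` gives
`19` months for this fit.

```r
compare_fits(fit_local, fit_central)
#> Local vs central fit comparison
#> Population parameters (RER % rounded to integer):
#>   TS0    local 2.955      central 2.986      RER -1%
#>   Kg     local 0.001203   central 0.001173   RER 2%
#>   Kd     local 0.007552   central 0.007974   RER -5%
#>   sigma  local 0.3786     central 0.5229     RER -32%
#> Individual estimates (120 shared lesions):
#>   TS0  slope 0.98, r2 0.92, median RER -2.1%, LOA -39.9 to 35.3%
#>   Kg   slope 0.67, r2 0.59, median RER 2.5%, LOA -24.9 to 30.0%
#>   Kd   slope 0.60, r2 0.25, median RER -5.4%, LOA -69.6 to 58.2%
```

The population-level estimates of the two operators agree to within a few
percent, while the individual (empirical Bayes) drug-effect estimates
correlate poorly (r² = 0.25 here) — the central finding this package lets
you reproduce and probe: operator noise washes out individual drug-effect
estimates long before it affects the study-level ones.

One call runs everything and writes delimited tables plus a JSON manifest:

```r
run_pipeline(cohort_config(n_lesions = 120, seed = 42), "out/")
```

or, from a shell, `Rscript inst/cli/tgi-pipeline.R run --config cfg.txt
--out out/` (subcommands `simulate`, `fit`, `agree`, `vpc`, `defaults`).

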