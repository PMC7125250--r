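---
title: "Methods: the TGI model, its estimation, and the paired-operator agreement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the TGI model, its estimation, and the paired-operator agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgiagree)
```

## The scientific problem

Two radiologists reading the same CT scan will not report the same longest
diameter for a lesion. `tgiagree` studies how that inter-operator
variability propagates through a model-based analysis of tumour kinetics:
does it merely add noise to individual profiles, or does it distort the
study-level characterisation of drug effect? The package simulates paired
local/central measurement series with a known truth, fits each operator's
series separately with a nonlinear mixed-effects tumour growth inhibition
(TGI) model, and quantifies agreement between the two sets of raw data,
individual estimates and population estimates.

## Structural model and statistical assumptions

A lesion's longest diameter (cm) over time $t$ (days) is

$$\mathrm{TS}(t) = \mathrm{TS}(0)\left(e^{K_g t} + e^{-K_d t} - 1\right),$$

the sum of an exponentially growing (untreated, resistant) and an
exponentially shrinking (drug-sensitive) component. Since
$e^{K_g t} \ge 1$ for $t \ge 0$, the prediction is strictly positive:
lesions shrink toward — but never mathematically reach — zero, then
regrow. When $K_d > K_g > 0$ the profile has a unique nadir at
$t^\* = \log(K_d/K_g)/(K_g+K_d)$ (`nadir_time()`). Degenerate lesions with
$K_g = 0$ (pure decay) or $K_d = 0$ (pure growth) are admitted by the
structural functions; the estimator itself keeps all three parameters
strictly positive through its log parameterisation.

Individual lesions vary lognormally around the typical values,
$P_i = \theta_P\, e^{\eta_i}$ with $\eta_i \sim N(0, \omega_P^2)$
independently per parameter and per lesion (diagonal $\omega$; no
correlations are estimated). Measurements carry additive Gaussian
residual error with SD $\sigma$ (cm). Analysis is at the lesion level
(individual longest diameter); patients only group lesion IDs and carry no
random effect of their own.

Derived kinetic metrics use a month of 365.25/12 = 30.4375 days, fixed so
that reported month-scale doubling times ($\log 2 / K_g$) and halving
times ($\log 2 / K_d$) are exactly reproducible; `round_months()`
implements the reporting convention of one decimal below ten months and
integer precision above. `who_recist_threshold()` converts a relative
change $f$ in a diameter into the $(1+f)^2 - 1$ change of the product of
perpendicular diameters implied by a spheroid lesion — the bridge between
unidimensional (RECIST-style) and bidimensional (WHO-style) response
thresholds, under which +20% in diameter equals +44% in diameter product.

## The synthetic cohort generator

The generator (`cohort_config()`, `simulate_cohort()`) emulates a sparse
late-phase oncology sampling design. Defaults, with the reasoning behind
each:

| quantity | default | rationale |
|---|---|---|
| lesions | 120 | a realistic paired-read subset of a phase III trial |
| typical values $\theta$ | 3.1 cm, 0.0012/d, 0.0077/d | advanced NSCLC-like kinetics: ~19-month doubling, ~3-month halving |
| variances $\omega^2$ | 0.31, 0.20, 0.44 | moderate inter-lesion spread, largest on drug effect |
| operator SD | 0.43 cm each | sub-centimetre read error of manual callipers on CT |
| lesions/patient | median 2, range 1–6 | drawn from a fixed categorical distribution |
| visits/lesion | truncated Poisson(3.35) on 1..5 | mean ≈ 3 visits; singleton lesions occur and are retained |
| inter-visit gap | Normal(59, 15²) truncated to [19, 116] d | median ≈ 59 days, clinic-scheduling spread |
| LLOQ | 0.5 cm | conventional limit for measurable disease |

Both operators read the same scan: they share the visit schedule and the
true profile, and differ only through independent additive noise (and an
optional multiplicative per-operator bias, default 1, for sensitivity
studies). Noisy draws are clamped at zero before LLOQ processing; values
strictly *below* the LLOQ are recorded as half the limit (0.25 cm) and
flagged BLQ, values at the limit are kept. The per-operator SDs default to
equal values because nothing in a paired design identifies which operator
is noisier a priori; both are configurable.

The visit-count and gap distributions are parametric stand-ins chosen to
match the stated median/range targets; only their summaries, not their
shapes, are calibrated. An optional progression-driven dropout rule
(`dropout = TRUE`, off by default) ends follow-up once the true profile
has regrown more than 20% above its running minimum, mimicking treatment
withdrawal at progression; it deliberately reproduces the weakness that
regrowth is then observed on very few points.

What the generator does **not** emulate: imaging physics, intra-operator
(repeat-read) variability, site effects, informative visit timing, and the
heavy dispersion of real baseline diameters — real cohorts include
baseline reads down to the substitution value 0.25 cm, which a lognormal
baseline with $\omega^2 \approx 0.3$ cannot produce. One visible
consequence is that the simulated share of below-LLOQ records sits below
the share typically seen in real paired trial data. Passing tests
therefore demonstrate correctness of the pipeline under the stated
generative assumptions, not fidelity to any particular trial.

## Estimation: per-lesion Laplace approximation

The marginal likelihood of lesion $i$ integrates the conditional Gaussian
likelihood over its random effects:

$$L_i(\theta,\omega^2,\sigma) = \int
p(y_i \mid \eta)\, p(\eta \mid \omega^2)\, d\eta .$$

We approximate each integral by the Laplace method at the conditional mode
$\hat\eta_i$: the objective function value is
$-2\sum_i \left[ \ell_i(\hat\eta_i) + \tfrac{d}{2}\log 2\pi -
\tfrac12 \log\det(-\ell_i''(\hat\eta_i)) \right]$, with $d$ the number of
free random effects. This is the closest transparent analogue of
first-order conditional estimation for an additive-error model (with
additive error, there is no $\eta$–$\varepsilon$ interaction to model);
an exact FOCE linearisation is deliberately out of scope. The test suite
verifies the approximation directly against 64-node adaptive
Gauss–Hermite quadrature on small instances (agreement well within 0.5 on
the $-2\log L$ scale).

Numerical choices:

* **Inner problem.** The conditional mode is found by damped Newton
  iterations with analytic gradient and Hessian (compiled C++), started at
  the previous outer iteration's mode, with backtracking line search and
  ridge-repaired curvature; the stopping rule is a gradient norm below
  `inner_tol` scaled by the objective magnitude. If a warm start ends
  unconverged, the search restarts from the prior mean $\eta = 0$ and the
  better of the two results is kept. Variance components below $10^{-10}$
  pin their random effect at zero and drop out of the integral.
* **Outer problem.** `nlminb` quasi-Newton iterations on
  $(\log\theta, \log\omega^2, \log\sigma)$, which enforces positivity,
  with box bounds wide enough to be inert in regular problems
  ($\omega^2 \in [10^{-8}, 25]$, $\sigma \in [10^{-4}, 10]$ cm).
  Convergence is a relative objective change below $10^{-6}$; the
  optimisation is re-run (fresh mode caches, up to three rounds) until a
  round finds no further improvement, which guards against premature
  "false convergence" on the stiff surfaces that arise with very small
  residual noise. A fit is reported `converged` only if the final round
  settles and every lesion's inner search converged.
* **Initial values.** $\theta$ from the medians of per-lesion
  least-squares fits over lesions with at least three points (falling back
  to the default typical values otherwise); $\omega^2 = 0.3$;
  $\sigma = 0.4$ cm. `tgi_control()` can fix $\omega^2$ and/or $\sigma$
  instead of estimating them — used, for instance, to isolate the typical
  values in noise-free identity checks, where free variance estimation
  would sit on its lower bound.
* **Uncertainty.** Relative standard errors are
  $100 \cdot \mathrm{SE}(\log\hat P)$, i.e. the delta-method RSE of the
  natural parameter, from the inverse observed information of the
  objective on the transformed scale (central finite differences). A
  singular information matrix flags the RSEs unavailable rather than
  failing the fit.
* **BLQ records** enter the likelihood as their substituted values
  (0.25 cm), matching the substitution convention of the data dialect; a
  censored-likelihood (M3) treatment is explicitly a non-goal.
* **Empirical Bayes estimates** are the conditional modes at the optimum.
  Their shrinkage toward $\theta$ is monotone in the information removed,
  which the test suite checks on nested designs.

The prediction-corrected VPC simulates `n_sim` replicates on the observed
design (including clamping and LLOQ substitution), corrects observed and
simulated values by the bin-median population prediction, and reports
5/50/95th percentiles per time bin with simulation intervals. Default
bins are quantile-based; user bins that cover no data are dropped with a
warning. The simulation seed defaults to 12345 and is exposed.

## Agreement conventions

Several conventions in the agreement module were genuinely open choices;
they are fixed as follows and config-exposed where meaningful:

* **RER orientation and domain.** `rer()` is antisymmetric, lies in
  (−200, 200) for positive pairs, hits ±200 exactly when one member is
  zero, and is undefined (excluded and counted, never imputed) when both
  are. Zero–zero pairs occur in principle only for paired BLQ records if
  raw zeros are compared; with substituted records they do not arise.
* **Limits of agreement** use the sample (n−1) SD:
  $\mathrm{mean} \pm 2\,\mathrm{SD}$ of the RER distribution, so the band
  width is exactly $4\,\mathrm{SD}$.
* **Regression orientation.** By default the central review is regressed
  on the local read; $r^2$ is the squared Pearson correlation and hence
  orientation-invariant, and the orientation can be swapped. An optional
  outlier rule (|studentized residual| > threshold, off by default)
  supports excluding single gross outliers from EBE regressions.
* **Quartiles** use linear interpolation between order statistics
  (R type 7).
* **Pattern classification.** "Similar" means the two profiles never
  differ by more than the threshold (default: the 0.5 cm LLOQ). The
  informal notion of "different but following the same trend" is
  operationalised as *non-crossing*: all nonzero differences share one
  sign. A sign change anywhere marks "different trend". The rule is
  scale-equivariant when the threshold is rescaled with the data.
* **Measurability discordance** counts paired scans where exactly one
  operator recorded BLQ, split by which operator, as percentages of all
  paired scans.
* **Reporting precision.** Percentages to one decimal; population
  parameter RERs to the nearest integer.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → fit(local) → fit(central) → compare,
writing delimited tables with headers that round-trip through the
package's own readers, plus a JSON manifest of configuration, stages,
outputs and record counts. The single configured seed fans out into
deterministic per-stage substreams so stages can be rerun independently;
identical configuration and seed reproduce all outputs bit for bit. The
command-line front end (`inst/cli/tgi-pipeline.R`) is a thin wrapper over
these functions with distinct exit codes for configuration, I/O and
convergence failures.

## Problem sizes used by the test suite

The suite exercises the estimator at the scales the method is designed
for while staying quick: Monte-Carlo distribution checks use $10^4$
sampled lesions; oracle (quadrature) comparisons use 3-lesion instances;
parameter-recovery checks fit 120-lesion cohorts across five replicate
seeds, plus one 200-lesion rich-design, low-noise cohort where the typical
values must be recovered within 2%. A full 120-lesion fit takes well under
two seconds on one core, which is what makes replicate fitting practical.

## Known limitations

* $K_g$ is weakly identified by design-realistic data — regrowth is
  typically seen on the last one or two visits — so its recovery
  tolerance is wider, and its estimates are the most operator-sensitive;
  treat individual $K_g$ (and $K_d$) EBEs with caution when measurement
  noise approaches half a centimetre.
* The two operator fits are wholly separate; a joint model with shared
  random effects (which could *estimate* operator variance components) is
  out of scope, as are covariate and exposure–response submodels,
  censored-likelihood BLQ handling, SAEM-type estimators, and sum-of-
  longest-diameters (multi-lesion) endpoints.
* Laplace approximation error grows for lesions with one observation and
  large variances; the quadrature cross-check bounds it on small
  instances but no interior error estimate is reported per fit.
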