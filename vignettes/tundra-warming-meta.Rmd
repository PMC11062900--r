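---
title: "Methods: multilevel meta-analysis and spatial upscaling of warming effects on tundra ecosystem respiration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilevel meta-analysis and spatial upscaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tundresp)
```

## The scientific problem

Passive open-top chambers (OTCs) warm tundra vegetation and topsoil by
roughly 1-2 degrees C. Dozens of such experiments, re-measured over up to
two and a half decades, allow a synthesis question: how much does
experimental warming increase growing-season ecosystem respiration (ER),
how persistent is the response, and which site conditions modulate it?
`tundresp` implements the full analysis chain for such a synthesis: from
plot-level daily flux records to standardized effect sizes, a multilevel
meta-analytic model, moderator metaregressions, and a Monte Carlo
upscaling of the fitted soil-driver relationship over gridded soil data.

The unit of analysis is the *dataset*: one experiment in one ER
measurement year. Datasets are nested in experiments, experiments in
sites, and repeated measurement years within an experiment are serially
correlated — the hierarchy the random-effects structure must represent.

## Effect sizes

Daily plot fluxes are first standardized to gCO2 m^-2 d^-1 (molar masses
44.009 for CO2 and 12.011 g/mol for C; 86 400 s/d). Within each dataset,
daily values outside mean +/- 3 sd (treatments pooled, sample sd) are
removed in a *single pass*; the filter is deliberately not iterated, and
the pipeline refuses to apply it twice. Growing-season means are then
taken per plot (plots — not plot-days — are the replication unit, which
avoids pseudo-replication from temporally autocorrelated daily values),
converted to grams of carbon, and summarized per treatment.

Three effect sizes are supported per dataset, with their large-sample
sampling variances:

* **Hedges' g (SMD)** — `(m_w - m_c)/s_p` with the (n-1)-weighted pooled
  sd and small-sample correction `J = 1 - 3/(4m - 1)`, `m = n_w + n_c - 2`;
  variance `J^2 [(n_w+n_c)/(n_w n_c) + d^2/(2(n_w+n_c))]`.
* **lnROM** — `log(m_w/m_c)`, variance `s_w^2/(n_w m_w^2) + s_c^2/(n_c m_c^2)`;
  back-transformed to percent change as `100 (exp(ROM) - 1)`.
* **raw mean difference** — for drivers whose absolute change is the
  interpretable quantity (e.g. warming in degrees C).

The growing season defaults to June-August; sites are individually
configurable (a southern-hemisphere site uses October-February).

## The multilevel CAR meta-model

Per-dataset effects `y_i` with known sampling variances `v_i` follow

```
y_i = x_i' beta + u_exp(i) + u_ds(i) + c_exp(i)(year_i) + e_i
```

with independent experiment intercepts (`sigma2_exp`), dataset intercepts
(`sigma2_dataset`), and a continuous-time AR(1) process `c` of *true*
effects over years within experiment: variance `tau2_car`, correlation
`rho_car^|year_i - year_j|`. The marginal covariance is block-diagonal by
experiment, which the fitting exploits: each likelihood evaluation runs
block-wise Cholesky factorizations rather than one dense `k x k` solve.

Estimation is REML. The restricted log-likelihood is reported in the
`-1/2 [(k-p) log 2pi + log|V| + log|X'V^-1 X| + r'V^-1 r]` form; note that
the error-contrast form differs by the constant `1/2 log|X'X|` (metafor
reports the latter — the difference matters only when comparing absolute
log-likelihood values across software). Optimization searches
log-variances and logit(rho) (upper bound `1 - 1e-6`) with `nlminb` from
four deterministic starts: near-zero components, a DerSimonian-Laird-type
moment estimate split evenly, and inflated/deflated perturbations of it —
REML surfaces here can be multimodal in `rho`. A restart at the best
optimum must fail to improve the objective by `1e-6` before the fit is
flagged converged; this is robust to the "false convergence" reports
optimizers produce on boundary ridges (e.g. `rho -> 1`, where the CAR term
becomes exchangeable and trades off against the experiment intercept).
Variance components below `1e-7` are flagged as boundary estimates rather
than silently zeroed. Weak identification of `sigma2_dataset` against the
CAR term is expected with few repeated years; both are retained, as the
model is written, with boundary flags.

Wald machinery supplies coefficient CIs and three test statistics:
Cochran's `Q` from the intercept-only inverse-variance fit (`w_i = 1/v_i`),
residual heterogeneity `QE` of the fixed-effect moderator fit, and the
omnibus moderator chi-square `Qm` on the non-intercept coefficients.
Model comparison (e.g. with vs without the CAR term) uses AIC from ML
refits, since REML likelihoods are not comparable across fixed-effect
structures; McFadden pseudo-R^2 likewise compares ML fits of the moderator
model and the intercept-only null on the identical complete-case subset.
No Knapp-Hartung adjustment or robust variance is applied.

## Moderator analyses

Metaregressions are single-factor by design: driver coverage is uneven
across datasets, and multifactor models would shrink the usable sample.
Each model keeps its own complete cases and reports its own `n`; nothing
is imputed. Continuous moderators enter unstandardized so slopes stay on
the driver scale; categorical moderators are dummy-coded against the
first level. A pairwise correlation screen is exported for collinearity
inspection but performs no automatic exclusion, and no multiplicity
correction is applied across the single-factor family (the family size is
visible in the output).

Temporal structure is analysed through warming duration (measurement year
minus treatment start year; 0 means the first summer) and four age
classes with closed integer bounds 0-4, 5-9, 10-14, 15+ — the only
reading under which the classes partition the durations. Per-class mean
effects, per-class duration slopes (requiring at least 3 datasets and a
duration contrast within the class) and an overall duration slope are
reported.

## Spatial upscaling with Monte Carlo uncertainty

The upscaling propagates a fitted two-factor lnROM model on mineral-soil
total nitrogen (TN, % by mass) and C:N across a soil grid:

1. **Mineral layer.** Depth intervals are classified mineral iff
   TN <= 0.01 g/g, SOC <= 0.1 g/g and bulk density >= 1 g/cm^3 within
   0-60 cm; organic horizons are carbon- and nitrogen-rich and light, so
   the thresholds act as upper, upper and lower bounds respectively (the
   directions are configurable). Mineral TN and SOC are thickness-weighted
   means over those intervals; cells with no mineral interval are nodata.
2. **Per-cell spread.** `sd = (q95 - q05)/(2 qnorm(0.95))` from the
   percentile rasters.
3. **Correlated truncated sampling.** Each cell draws `mc_draws`
   (default 100) TN-SOC pairs. Marginals are normals truncated below at
   5% of the target mean (no negative concentrations), with locations
   adjusted by root-finding on the truncated-normal mean identity so the
   truncated mean equals the target. The two marginals are coupled by a
   Gaussian copula at correlation 0.8273. The copula is a deliberate
   choice: rectangle truncation of a joint normal attenuates the realized
   correlation of the retained draws substantially (to about 0.76 under
   heavy truncation at these parameter values), whereas the copula
   coupling preserves the exact truncated marginals — hence the mean
   adjustment — and realizes the stated correlation to within about 0.01.
   Cells where the adjustment cannot be solved (sd far exceeding the
   mean) fall back to floor-clipped untruncated draws and are flagged.
4. **C:N bias.** Grid C:N must be derived as SOC/TN, a biased proxy for
   measured C:N; a set of 100 bootstrap linear regressions of reported on
   computed C:N calibrates it, one regression per Monte Carlo iteration.
5. **Combination.** Each draw yields a prediction mean and SE on the
   lnROM scale; draws are combined with the equal-weight mixture sd,
   `sqrt(mean(MEAN^2 + SE^2) - mean(MEAN)^2)`, *on the lnROM scale* —
   predictions and their SEs are native there — and only then transformed
   to percent change (delta method for the sd). The coefficient of
   variation uses `|mean|` with an NA guard below `1e-6` to avoid
   zero-crossing blowups.
6. **Uncertainty decomposition.** The propagation is run twice on the
   *identical* soil-draw substream: once with the full coefficient
   covariance and once with parameters fixed at their means. The ratio
   input-only sd / combined sd lies in (0, 1] by construction (the two
   runs share draws, so Monte Carlo noise cannot push it above 1).
7. **Regional totals.** Area-weighted sums against a baseline annual
   respiration raster, in PgC/yr. Cells are treated as independent when
   aggregating the sd — per-cell soil percentiles carry no spatial
   error correlation — which understates regional uncertainty if errors
   are spatially correlated; this assumption is flagged in the output
   documentation.

All randomness descends from one root seed through fixed per-stage
substreams (`substream_seed`), so identical seeds reproduce results bit
for bit and the decomposition can replay its draws exactly.

## The synthetic-data generator

`simulate_database()` emulates the synthesis structure end to end: 28
sites hosting 56 experiments contributing 136 dataset-years (1-13
consecutive years per experiment), 3-8 plots per treatment, per-dataset
true effects `mu + u_exp + u_ds + CAR(year)` with defaults
`mu = 0.57`, `sigma2_exp = 0.1`, `sigma2_dataset = 0.05`,
`tau2_car = 0.05`, `rho_car = 0.6`, and positive, right-skewed daily
fluxes: lognormal multiplicative noise (sd 0.35 on the log scale) around
plot-level means, about 16 measurement days per plot per season, and a
median control flux of 3 gCO2 m^-2 d^-1 — magnitudes and sampling
frequency chosen to be tundra-plausible. The warmed-plot offset is
calibrated analytically (a short fixed-point iteration, since the offset
feeds back into the pooled sd) so the *computed* Hedges' g is unbiased
for each dataset's true effect. Driver tables carry control-plot
conditions (TN, C:N, soil moisture) and full treatment/control blocks for
warming-induced changes (air +1.4 C, soil +0.4 C, moisture -1.6 in the
defaults), with a configurable correlation (default -0.43) between the
control TN level and the warming-induced TN change. Per-driver
missingness fractions exercise the complete-case discipline.
`simulate_rasters()` produces smooth TN/SOC/BD fields on a two-interval
depth profile with percentile bands generated from known sds (so the
sd-from-percentiles identity is exactly invertible), configurable
fractions of organic-top and fully organic cells, and a positive baseline
respiration field.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: instrument-level measurement error
structure, gap patterns and diurnal sampling bias, spatially correlated
soil errors, non-Gaussian true-effect distributions, or publication-type
selection. It is a validation harness, not a data emulator.

## Validation design and known limitations

The test suite validates the engine against independent oracles: a dense
error-contrast restricted-likelihood oracle (and metafor's `rma.mv` with
the same nested + CAR structure as an external cross-check), closed-form
inverse-variance estimators with variance components pinned to zero,
Gauss-Hermite quadrature of the truncated-copula sampling law for the
upscaling expectation, and brute-force mixture sampling for the mixture
sd. Recovery simulations run the generator through the full pipeline at
the study hierarchy (problem sizes: 200 replicate databases for pooled
recovery; 1000 replicates at k = 50 for the size of the omnibus test;
10^5-10^6 draws for the sampling checks — sizes chosen to make Monte
Carlo error small relative to the tolerances tested).

One limitation surfaced by that design is worth stating plainly: with
3-8 plots per treatment, the Hedges' g sampling variance — which contains
the `d^2` term — is strongly correlated with the observed effect, so
inverse-variance weighting systematically downweights large observed
effects. Per-dataset effects are unbiased, but the *weighted pooled
estimate* of a positive mean effect is attenuated by roughly 0.05-0.08
standardized units under these conditions, and Wald CIs centred on it
undercover the truth accordingly. This is a structural property of
SMD synthesis with estimated weights at small replication, not an
implementation artifact (the unweighted mean of the same computed effects
matches the realized truth, and the effect-level recovery test with fixed
known variances is unbiased). Real syntheses with comparable replication
should expect the same attenuation.
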