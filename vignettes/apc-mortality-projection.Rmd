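---
title: "Bayesian age-period-cohort projection of mortality by socio-economic position"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian age-period-cohort projection of mortality by socio-economic position}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cause-specific mortality evolves along three entangled time scales: the age of
the deceased, the calendar period of death (contemporary influences such as
health-care changes or economic shocks), and the birth cohort (early-life
influences that a generation carries through life). Ischaemic heart disease
(IHD) in rapidly developing populations is a canonical case: generations that
grew up during an economic transition can carry a different lifetime risk than
their predecessors, and the social gradient of the disease can reverse as the
epidemic matures. `apcmort` implements the full analysis chain for such a
study: tabulating individual death records and population denominators onto a
sex- and income-stratified Lexis grid, fitting a Bayesian Poisson
age-period-cohort (APC) model per stratum, comparing submodels by DIC,
projecting age-standardized rates (ASRs) three five-year periods ahead, and
locating changes in the estimated effect trends by joinpoint regression.

The default grid has ten 5-year age groups (30-34 to 75+) and six 5-year
periods (1976-1980 to 2001-2005). Because birth cohort = period − age, cohorts
run along the grid's anti-diagonals: `cohort_index(a, p) = n_age - a + p`,
giving 15 overlapping 10-year cohorts centred at 5-year intervals from 1901 to
1971. Ages below 30 are excluded (IHD deaths are rare before 30) but counted
and reported, never silently dropped.

## Income stratification

Neighbourhood (TPU) median household income per capita is split at the median
across TPUs *within each census year*: strictly below the cutoff is
"low-income", equal or above is "high-income". With an even number of TPUs the
cutoff is the lower of the two middle order statistics, so at least one TPU
sits exactly at the cutoff and the "equal to or above" clause is never
vacuous. The classification is relative (a different cut point each year),
hence invariant to rescaling a year's incomes. Deaths and population are
linked to the census year nearest their own year, ties resolving to the
earlier census; this linkage rule is a declared convention of the package, as
inter-census linkage is rarely reported in source studies.

## The model

For stratum cells with deaths $D_{ap}$ and person-years $N_{ap}$,

$$D_{ap} \sim \text{Poisson}(N_{ap}\,e^{\eta_{ap}}), \qquad
\eta_{ap} = \mu + \alpha_a + \beta_p + \gamma_{c(a,p)},$$

with second-order random-walk (RW2) priors on each effect vector: every
element from the third onward is normal around the linear extrapolation of
its two predecessors, $x_k \sim N(2x_{k-1} - x_{k-2}, \sigma^2)$, flat on the
first two elements. The RW2 prior penalizes only second differences, which is
exactly the feature of APC effects that remains interpretable under the
aliasing $c = A - a + p$: levels and one common linear trend are not
identified, only curvature is. Each RW2 precision $1/\sigma^2$ carries a
Gamma(0.001, 0.001) hyperprior (the classical diffuse choice for this model
family; both parameters are exposed in `apc_model_spec()`), and the intercept
a $N(0, 10^6)$ prior.

### Identifiability constraints

Identifiable estimates are produced by fixing the second and penultimate
period effects and the central (8th) cohort effect to zero. Those three
constraints remove the period level, the shared linear trend, and the cohort
level; one flat direction remains (age level against the intercept), so
`apply_constraints()` additionally centres the age effects at mean zero,
absorbing the level into $\mu$. The transform is the unique affine map with
these properties, built on the identity $p = c - A + a$, and it leaves every
fitted log rate unchanged to machine precision — that invariance is asserted
on random states in the test suite. Constraints are applied after every MCMC
iteration as a deterministic projection rather than by conditioning the
kernel: the RW2 priors depend only on second differences, which the
projection preserves, so the projected chain targets the constrained
posterior exactly (up to the intercept's practically-flat prior).

### Sampling

`sample_posterior()` runs an adaptive single-site Metropolis-within-Gibbs
sampler (in compiled code): random-walk Metropolis on the intercept and each
effect coordinate with per-coordinate proposal scales adapted toward a 0.44
acceptance rate during burn-in and frozen afterwards, and conjugate Gibbs
draws for the RW2 precisions. Defaults mirror the study conditions: 5 chains
from over-dispersed starts, 40,000 retained draws in total, burn-in extended
until the split-chain Gelman-Rubin $\hat R$ of every monitored parameter
falls below 1.05 (the threshold is configurable; 1.05 is the declared
default since source analyses typically report "on the basis of R-hat"
without a number). If the criterion is still unmet at `max_burn_in`, the
result is returned flagged `converged = FALSE` with full diagnostics, and the
pipeline command refuses to continue — never a silent return. Identical seeds
give bit-identical chains; all randomness flows through R's RNG.

Correctness of the sampler is established against independent oracles rather
than against another Bayesian engine: with per-cell person-years of $10^8$
the posterior mean log rates must agree with the constrained Poisson GLM
(IRLS) fit within 1%, and on simulated data the known generating effects must
be recovered (coverage and inflection location, below).

### DIC

`dic()` uses the deviance $-2\sum_{ap}\bigl(D\log(N\lambda) - N\lambda\bigr)$,
omitting the $\log D!$ data constant and the saturated term consistently
across the seven `{age, period, cohort}` submodels, so DIC *differences* on
the same data are unaffected while absolute values are not comparable with
outputs of other software (which may include those constants);
`compare_models()` tabulates Dbar, pD and DIC across all submodels.

## Standardization

Age-standardized rates use the WHO World Standard age weights, embedded as
constants (the 85-89/90-94/95-99/100+ tail collapsed to a single 85+ entry),
restricted to the grid's 30+ range and renormalized. Reported ASRs are
therefore 30+ standardized rates; no back-extrapolation below age 30 is
attempted, and output files flag the convention. Posterior ASR summaries are
the mean and the equal-tailed 95% interval (2.5%/97.5% empirical quantiles,
linear-interpolation definition).

## Projection

`extend_effects()` draws three future period and cohort effects per retained
posterior draw from the RW2 predictive distribution: linear extrapolation of
the last two values plus a Gaussian innovation with *that draw's* variance,
so hyperparameter uncertainty propagates and the projection bands are genuine
predictive intervals (with all variances forced to zero the projection
reduces exactly to linear extrapolation). The youngest age group in the last
projected period reaches cohort $A + P + 2 = 18$, consuming all three
extrapolated cohort effects; an off-by-one there is guarded by an explicit
error. Projected ASRs need no population forecasts, being functions of rates
only; projected death counts are out of scope.

One behaviour deserves emphasis: projected rates are log-normal-like, and
three RW2 steps can accumulate substantial variance when the fitted effects
have large curvature (which inflates the posterior of $\sigma^2$). The
posterior *mean* of a far-horizon ASR is then dominated by a few extreme
draws and is Monte-Carlo unstable, while the median and the interval are
stable. The ASR series therefore carries both `asr` (mean, the conventional
summary) and `asr_med`; read the median for point projections at the horizon.

## Joinpoint analysis

Trend changes in the estimated effect series (posterior-mean log relative
risks against cohort or period centre years) are located by continuous
piecewise-linear regression on the broken-line basis
$\{1, x, (x-\tau_j)_+\}$, fitted by exact least squares, with breakpoints
searched exhaustively over the interior observed x-values (at least
`min_obs = 2` observations per segment) and the number of breakpoints chosen
by $\text{BIC}_k = n\ln(\text{SSE}_k/n) + (2+2k)\ln n$, counting each
joinpoint's position as a free parameter; ties go to the smaller $k$, and
exact fits (SSE at rounding-error level) map to $-\infty$ so the smallest
exactly-fitting model wins. Fits are unweighted on the log-RR scale.

A measured limitation: at series length 15 this BIC variant over-selects
spurious joinpoints on flat noise in roughly 15% of series (the acceptance
script recomputes this rate), which is why the NCI tool's documentation
prefers permutation tests for formal inference; permutation testing is out of
scope here, so treat a single selected joinpoint on a short series as
suggestive rather than confirmatory, and keep `max_k` small.

## The synthetic-data generator

No registry or census microdata are publicly deposited for studies of this
design, so `default_scenario()` defines a fully documented generating truth
per sex-income stratum and `simulate_grid_counts()` / `simulate_records()`
emulate the study inputs at grid and record level (the record expansion
round-trips exactly through classification and aggregation, and generates
era-appropriate ICD-8/9/10 codes). The scenario encodes the qualitative
structure such analyses report:

* age effects rising with a slope jump at 50-54;
* a low-income-only period dip in the early 1990s and late-1990s upturn, with
  only minor period structure in high-income strata;
* declining cohort effects — the dominant driver — with a marked male-only
  upturn at the cohort centred on 1946 (larger for low-income men, with a
  slight steepening of the decline just before it, so the upturn's second
  difference concentrates at one cohort), a female downturn around the
  early-1920s cohorts, and a slight upturn near 1941 for high-income women.

The intercept is calibrated so the first-period 30+ ASR hits the stratum
anchor (33.3 per 100,000 for low-income women, 55.5 for low-income men — the
documented endpoints for such a population — and 38/76 for the high-income
strata), and the base cohort slope is solved so the deterministic truth
extension hits the end-of-projection anchor (19.7, 34.2, 13 and 23
respectively), which reproduces the reversal of the social gradient within
the observed window. Person-years are 0.3-0.9 million per cell (mid-year
population 150,000 at the youngest group, declining 10% per age group,
growing 4% per period), magnitudes comparable to a metropolitan income
stratum. This scale was chosen, together with the upturn's shape, by a design
power analysis so that the generating truth is actually recoverable by the
model — the package's recovery tests are only meaningful if the scenario is
identifiable; at an order of magnitude fewer person-years the upturn location
is unrecoverable even by maximum likelihood.

What passing these tests does *not* show about real data: the generator has
no ICD-revision discontinuities, no migration, no TPU boundary changes or
merging, no overdispersion beyond Poisson, and no dependence between strata;
real registry analyses must confront all of these.

## Numerical choices and problem sizes

* Cohort centre years are (period centre) − (age centre) rounded half-up to
  the nearest year, with the open 75+ group assigned nominal centre 77.5;
  period centres are the middle calendar year (1978, ..., 2018). Projected
  cohort labels derive as 1976/1981/1986 under this convention.
* Even-count medians take the lower middle order statistic (SEP module);
  quantiles elsewhere are the linear-interpolation (type 7) definition.
* The constraint transform and RW2 density are validated to 1e-10 or better;
  projection linearity at zero variance to 1e-12.
* Test and acceptance runs use reduced MCMC budgets (2 chains × 2,000-4,000
  retained draws, burn-in 1,200-2,000, extended automatically until
  $\hat R < 1.05$) — chosen as the smallest budgets at which the convergence
  criterion is reliably met on the default scenario; production analyses
  should use the 5 × 8,000 default.
* Degenerate inputs error early: non-positive person-years, zero innovation
  variance in the prior density, out-of-range reference indices, duplicate
  joinpoint positions, unparseable ICD codes (flagged `NA`, never `FALSE`).

## Limitations

Only rectangular A×P tabulations are supported (no Lexis triangles or exact
birth dates); the APC identifiability problem is handled by reference
constraints, not resolved — effect levels and common trends are conventions,
and only second-order features should be interpreted; DIC values are not
comparable across software; joinpoint inference is BIC-based model selection
without permutation error control; projections inherit every assumption of
the RW2 extrapolation and say nothing about structural breaks after the
observed window.
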