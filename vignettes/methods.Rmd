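---
title: "Population PK/PD modelling of ACE inhibition through the angiotensin II/I ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK/PD modelling of ACE inhibition through the angiotensin II/I ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ratiopkpd` implements a population pharmacokinetic/pharmacodynamic analysis
of the ACE inhibitor metabolite enalaprilat and its effect on the angiotensin
II/angiotensin I ratio, a dimensionless readout of in-vivo ACE activity:
enalaprilat blocks the conversion of angiotensin I to angiotensin II, so the
ratio falls from its baseline as drug reaches the effect site. The package
covers two study settings with different information content: a rich
single-dose study in healthy adults (joint PK/PD modelling) and a sparse
repeated-dose study in infants with heart failure treated with enalapril
orodispersible minitablets (PD modelling with measured concentrations as
input). Because the underlying clinical datasets are not public, the package
ships seeded synthetic-study generators that reproduce both designs, and its
calibration rests on (a) exact reproduction of the studies' data accounting
and (b) recovery of the published parameter tables from data generated at
those values.

## Structural models

**Absorption.** Enalapril is an oral prodrug hydrolysed to enalaprilat, so
the appearance of enalaprilat in serum is delayed and gradual. The default
absorption model is a continuous transit chain: drug flows into the
absorption compartment at rate

$$r(t) = D\,k_{tr}\,\frac{(k_{tr}t)^{n}e^{-k_{tr}t}}{\Gamma(n+1)},
\qquad n = k_{tr}\,\mathrm{Mtt} - 1,$$

a gamma-density-shaped input with unit mass whose mode sits at $n/k_{tr}$.
`Mtt` (h) is the mean transit time and `k_tr` (1/h) the transit rate
constant; `k_a` (1/h) then moves drug from the absorption compartment into
the central compartment. Published transit parameterisations differ by one
stage in the $n \leftrightarrow (k_{tr}, \mathrm{Mtt})$ mapping, so both
conventions (`mtt_minus_one`, the default, and `mtt`) are selectable; a
lag-time and a plain first-order variant are available for model comparison.
The contract of `transit_input_rate()` requires $k_{tr}\mathrm{Mtt} > 1$
(positive shape); inside the estimation machinery the shape is floored at a
tiny positive value instead, because the $n \to 0$ limit is a well-defined
exponential input and Markov-chain proposals must never abort.

**Disposition.** Two-compartment linear kinetics with apparent parameters
(CL/F, V1/F, Q/F, V2/F; bioavailability is not identifiable from oral data
alone). The solver is semi-analytic: the disposition impulse response is an
exponential mixture obtained by partial fractions, and its convolution with
the gamma-shaped input has a closed form through the regularised incomplete
gamma function. Exponential terms whose decay rate approaches or exceeds
$k_{tr}$ (where that closed form degenerates) are integrated on a 40-node
Gauss-Legendre grid over the exponential boundary layer. The solver is exact
to machine precision against a fine-step Runge-Kutta reference, deterministic
and fast enough for stochastic-EM inner loops; repeated doses superpose.

**Effect link and PD.** A first-order effect compartment
$dC_e/dt = k_{e0}(C - C_e)$ explains the clockwise hysteresis seen in the
adult concentration-effect data (a given concentration late in the profile
produces a lower ratio than the same concentration early on). The ratio
follows a sigmoid Imax model,

$$\mathrm{ratio} = E_0\left(1 - \frac{I_{max} C_e^{\gamma}}
{C_e^{\gamma} + IC_{50}^{\gamma}}\right),$$

with full inhibition ($I_{max} = 1$) by default and a partial-inhibition
variant available. The paediatric model is the direct ($k_{e0} \to \infty$),
$\gamma = 1$ special case with measured concentrations in place of a PK
model; the numerical equivalence of that limit is covered by tests.

## Statistical layer

Inter-individual variability is lognormal,
$\theta_i = \theta_{pop}\,e^{\eta_i}$, reported as CV% through the exact
transform $\mathrm{CV} = 100\sqrt{e^{\omega^2}-1}$ (at the largest reported
variability, 141.9% CV, the approximation $\mathrm{CV}\% \approx 100\,\omega$
would be off by a third, which is why the exact transform is used). Random
effects may be correlated; the assembled covariance matrix is validated for
positive definiteness on construction. Continuous covariates enter as power
links scaled by a reference value (the observation-count-weighted mean by
default; the weighting is a package choice since several conventions exist),
categorical covariates exponentially.

Residual error is proportional or combined; combined error is
$sd = a + b\,f$ (the "combined1" convention of mainstream population PK
software, which the reported additive/proportional coefficient pairs
follow), with $\sqrt{a^2 + (bf)^2}$ selectable for sensitivity checks. Concentrations below the lower limit of quantification (LLOQ) are
interval-censored: they contribute the unconditional interval probability
$\Phi\{(\mathrm{LLOQ}-f)/sd\} - \Phi\{(0-f)/sd\}$ on $[0, \mathrm{LLOQ}]$
rather than a point density. Adult ratios more than 24 h post dose are
excluded (the ratio rebounds above baseline there and 24 h is the maximum
therapeutic dosing interval), predose adult PK samples are excluded, and the
paediatric exclusion categories (angiotensin I above its calibration range,
therapy interruptions, unclear stop times, both angiotensins below LLOQ,
records more than 24 h after the last dose) are applied by tag.

## Estimation

`fit_population()` chooses among three maximum-likelihood routes:

- **SAEM** (stochastic approximation EM) for the general case. All
  structural parameters ride in the individual log-parameter vector; the
  Markov kernel on individual parameters mixes an independence proposal from
  the population prior, an adaptive joint random walk and an adaptive
  componentwise random walk. Parameters without modelled IIV receive an
  artificial variance that decays geometrically across the exploratory phase
  (simulated annealing), so their population values are updated by the same
  sufficient-statistic averages as everything else and collapse onto point
  estimates; `art_v0` may be set per parameter, and the staged adult
  workflow uses a wide setting for the PD link parameters (which start far
  from their final values) and a narrow one for PK parameters pre-estimated
  in stage 1. Estimated variances are floored at 95% of their previous value
  per exploratory iteration so the chain cannot collapse early. Residual
  error coefficients are re-optimised each iteration from cached
  predictions.
- **Gauss-Hermite maximum likelihood** for the paediatric direct Imax model
  (one random effect): with a non-adaptive 41-node rule the random effect
  takes identical node values for every subject, so the marginal likelihood
  vectorises over all observations and the fit is deterministic and takes
  seconds.
- **Direct ML** when no parameter carries IIV (used by the test suite's
  least-squares cross-checks).

The objective function value (OFV, $-2\log$ marginal likelihood) is exact
for 0- and 1-dimensional random effects and otherwise estimated by
importance sampling with a defensive-mixture proposal: 85% from a Laplace
approximation of each subject's random-effect posterior (numerical Hessian
at the empirical Bayes mode, eigenvalue-clipped, inflated 1.2-fold) and 15%
from the population prior to guard the tails. A proposal this narrow matters:
with rich designs the conditional posterior is far tighter than the prior,
and naive prior-scaled proposals degenerate to a handful of effective draws.
Monte-Carlo standard errors are reported alongside.

Relative standard errors come from the exact Hessian of the marginal
log-likelihood (deterministic marginals) or a BHHH score cross-product with
common random numbers, with a case-resampling bootstrap as the reference
method. Positive parameters are profiled on the log scale throughout; the
sigmoidicity factor is bounded below at 0.1.

## Covariate search

The search is a documented simplification of correlation-guided stepwise
selection. Candidate (parameter, covariate) pairs are screened by the
correlation between empirical Bayes estimates and covariates; the strongest
pair per covariate is then tested by a profile likelihood-ratio test at the
$\chi^2_1$ thresholds (6.635 at the default forward/backward p = 0.01). The
test re-profiles the linked parameter's population intercept *and* its own
variance under both hypotheses - as a full refit would - while all other
parameters stay at the base estimates, and it evaluates both hypotheses on
one cached set of per-subject importance-sampling draws so Monte-Carlo noise
cancels exactly in the objective-function difference. Full stochastic refits
proved unusable for this decision: the objective-function noise of two
independently run stochastic fits is an order of magnitude larger than the
6.635 threshold at these study sizes. Known limitation: because each
covariate is tested on its best-correlated parameter, the familywise
false-selection rate of a whole search exceeds the nominal per-test 1% (a
permutation check at the 9-subject design puts it near 15-20% per dataset);
this is a property of screen-then-test stepwise procedures generally, not of
the threshold. The effect does not vanish with study size: the chance
correlation needed to cross the threshold shrinks as $1/\sqrt{n}$ while the
likelihood-ratio statistic scales with $n$, so the maximum over screened
pairs keeps its median just below the 6.635 cutoff (measured on 40-subject
covariate-free replicates: forward $\Delta$OFV maxima between 3 and 10, and
one spurious link retained in roughly one dataset in four). A search run on
one dataset therefore retains a chance covariate noticeably more often than
the nominal 1% per test; users should treat single-dataset stepwise
selections as hypotheses, not findings.

## Synthetic-study generators

The generators are first-class, tested code; they define the conditions
under which the package's calibration claims hold.

**Adult design.** 20 mg enalapril maleate (20,000 ug) at $t = 0$ in 9
subjects; 34 scheduled PK samples per subject *including* predose. The
sampling grid (every 10 min to 3 h, every 20 min to 6 h, every 30 min to
8 h, then 24/48/72 h) naturally enumerates to 35 including predose, while
the study's own accounting (9 x 34 scheduled, minus 9 missing samples in 2
subjects, minus 9 predose = 288 analysed concentrations) requires 34; the
generator therefore trims the 7.5 h sample, the only reading consistent with
the printed arithmetic. Which samples are missing is random (the study
states only the 5 + 4 split default here); 13 ratio samples per subject at
predose, 0.5-8 h, 24/48/72 h. IIV, the V1-CL random-effect correlation and
both residual-error models follow the packaged final adult parameter table.
Concentrations below 0.70 ug/L are interval-censored; with the published
parameters about 17% of included concentrations end up censored, close to
the study's reported fraction. Negative proportional-error draws for the
strictly positive ratio are resampled.

**Paediatric design.** 27 ACE-inhibitor-naive infants (age 0.07-2.24 y,
weight 3.2-13 kg, Ross score 0-9, mostly congenital heart disease), initial
dose 0.03-0.08 mg/kg maleate, once- or twice-daily maintenance dosing up to
roughly a year with full dosing diaries; a predose + 4 h profile at the
first dose and sparse later visits. Default instant counts reproduce the
published data accounting exactly (87 observation instants; 54 included
after the exclusion rules, split 16 predose-first / 12 post-first / 26
post-repeated; exclusion categories 10/10/8/2/1/2), and scale
proportionally for other study sizes. Enalaprilat concentrations are
generated from a seeded lognormal level (median 3 ug/L, geometric SD 2.5,
truncated at the study's maximum of 18.3 ug/L) shaped by a unimodal
time-since-dose template peaking near 3.5 h - deliberately *not* from a
fitted PK model, since the paediatric analysis treats concentrations as
input data. Sparse-visit sampling times are uniform over the dosing
interval; the real distribution is unknown (sampling times were at the
investigators' discretion), and this default is flagged as arbitrary.

**Raw angiotensins and the substitution rule.** Each instant carries raw
ANG I and ANG II values alongside the ratio so the below-LLOQ machinery is
exercised end to end: ANG II below its LLOQ (22.3 pg/mL) marks the instant
as LLOQ/2-substituted, both-below-LLOQ instants are excluded. ANG I is drawn
lognormally with median 300 pg/mL and geometric SD 1.6, calibrated
prospectively against two published observables - roughly half of included
ratios have ANG II below the LLOQ, and ANG I stays almost entirely within
its 25.4-1594.2 pg/mL calibration range (with the tagged
above-range-category instants forced above it). By default the fitted ratio
stream carries the *generated* ratio (`ratio_dv = "generated"`): the package
treats generator/model consistency - fitting the generating model to its own
large-n output must recover the truth - as a design requirement of its
calibration suite. The `"substituted"` variant, in which the fitted values
are recomputed from the raw analytes with ANG II replaced by LLOQ/2, is kept
available because it reproduces the measurement-side distortion of heavily
censored ANG II; under that variant the recovered IC50 is biased upward by
roughly a third and the IIV is inflated, since substituted ratios form a
concentration-independent floor near (LLOQ/2)/ANG I. Real paediatric data
carry exactly this distortion, so calibration statements made under the
default generator do not extend to it.

## Diagnostics

`vpc()` simulates replicate studies on the original design (default 500) and
compares observed 10/50/90th percentiles per time bin with the 90%
prediction intervals of the simulated percentiles; concentrations below the
LLOQ enter percentile computation at LLOQ/2 on both sides. Rich designs bin
on the shared nominal times, sparse designs on quantiles of time since last
dose (default 8 bins); bins with fewer than 3 observations merge leftward
and the merges are logged. Percentiles are linear-interpolation (type 7)
quantiles - recorded in the result because percentile conventions move band
edges. `gof()` returns the standard four surfaces as data, with censored
records kept out of the residual table. `hysteresis_metric()` closes the
(concentration, effect) polygon from the last point back to the first and
reports the shoelace signed area (negative = clockwise; the "none" label
uses a tolerance of 1e-9 times the product of the coordinate ranges).
`percent_change_4h()` computes the per-subject percent fall of the ratio
from predose to 4 h. `comparison_overlay()` re-indexes paediatric
observations to time since last dose under the adult VPC bands, with each
point tagged by dose class and substitution status; predose-first-dose
records are placed at $t = 0$ with their own tag, since a
time-since-last-dose axis has no natural position for them.

## Calibration experiments and problem sizes

`adult_recovery()` simulates a 40-subject adult study at the packaged final
adult table and reproduces the staged analysis blind from generic
round-number initial values: a PK-only SAEM fit (150 exploratory / 60
smoothing iterations), then the simultaneous PK/PD fit initialised from the
PK estimates (200/80 iterations). `paediatric_recovery()` simulates 200
sparse subjects and fits the direct Imax model by quadrature.
`recovery_median()` reports the median over 10 derived seeds. These sizes
are the package's calibration choices: 40 adult subjects give single-seed
standard errors comfortably inside the recovery tolerances for all fixed
effects except the baseline ratio E0, whose 141.9% CV makes even a
40-subject mean noisy (hence the median over seeds); 200 paediatric subjects
pin E0 and IC50 to a few percent. `scripts/acceptance.R` reruns both
experiments from a command-line seed and writes the recovered values as
JSON.

## Known limitations

- Estimates from short SAEM runs carry stochastic convergence error of a few
  percent on top of statistical error; the iteration counts above were
  chosen so that this is small against the recovery tolerances, not so that
  it vanishes.
- The covariate search's familywise false-selection rate exceeds the nominal
  per-test level, as discussed above.
- The paediatric concentration generator spans the observed concentration
  range but is not a pharmacokinetic model; nothing simulated here says
  anything about paediatric enalaprilat kinetics.
- Passing recovery tests under the default generator demonstrates internal
  consistency of model + estimator + design, not correctness on real data:
  real studies add the LLOQ/2 substitution distortion (see above), assay
  drift, site effects and dosing-history errors that the generators do not
  emulate.
- No inter-occasion variability; no mechanistic renin-angiotensin turnover
  model; the prodrug enalapril itself is not modelled.
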