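---
title: "Methods: twin modelling of infant looking preferences"
author: "twingaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin modelling of infant looking preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twingaze)
```

## The scientific problem

When a 5-month-old infant is shown a display containing one face and four
non-face objects, where they look is one of the first behaviours by which
they select their own perceptual environment. `twingaze` implements the
full analysis chain for asking how much of the individual variation in
three such looking phenotypes is genetic versus environmental, using the
classical twin design:

* **face orienting** — the proportion of valid trials on which the face is
  the first object looked at;
* **face preference** — looking time on the face divided by looking time
  on all five objects, averaged over valid trials;
* **efficiency of visual exploration** — the number of distinct objects
  looked at in the first 10 s of a trial, averaged over valid trials.

Because comparable raw infant gaze data cannot generally be shared, the
package includes a first-class synthetic-data generator that emulates the
whole measurement chain — twin pedigree, latent biometric structure, raw
120 Hz gaze streams, missing data — so every downstream stage is testable
end to end without any external data. Real gaze tables with the same
column contract enter through `read_gaze_csv()`.

## The biometric model

For a pair of twins the phenotype vector stacks twin 1's traits over twin
2's. The classical decomposition writes each trait as a sum of additive
genetic (A), shared-environment (C), optionally dominance (D), and
non-shared environment (E) influences, each parameterised by a
lower-triangular Cholesky factor (`A = L_A L_A'`, and so on), which
guarantees positive semi-definite component matrices and, for two traits,
partitions the second trait's variance into a portion *shared with* and a
portion *unique from* the first trait. The implied pair covariance is

* within-twin block: `A + C + D + E`,
* cross-twin block: `A + C + D` for MZ pairs and `0.5 A + C + 0.25 D` for
  DZ pairs,

reflecting that monozygotic co-twins share all segregating genetic
material while dizygotic co-twins share half of it on average (a quarter
for dominance deviations). C and D are not jointly identifiable from
MZ/DZ data and cannot be combined in one model; E is mandatory so the
likelihood is proper.

Fitting is by full-information maximum likelihood: each pair contributes
the multivariate-normal deviance over its *observed* entries, so pairs
with an absent co-twin are retained by marginalisation (row/column
deletion in the implied moments). Age (z-scaled days) and sex (0/1) enter
the mean model only, equated across twins and zygosity. Optimisation is
multi-start BFGS (5 restarts by default, jittered from moment-based start
values under a private RNG stream so fits are deterministic); a fit is
flagged non-converged unless at least two restarts agree within 1e-4 in
deviance.

Reporting conventions, applied to every fit: `df = (number of non-missing
observed data values) − (free parameters)` and `AIC = −2LL − 2·df`
(lower is better). Nested models are compared by `Δχ² = −2LL(nested) −
−2LL(full)` on `Δdf` degrees of freedom; `select_best()` keeps, among
nested models with p ≥ 0.05, the one with the lowest AIC, breaking exact
AIC ties by fewest parameters, and falls back to the full model when all
nested models are rejected.

Saturated models free the means, standard deviations and correlations of
the pair vector per zygosity (and twin order); equality-constraint sets
(`means_order`, `vars_zyg`, `corrs_order`, ...) reduce them, and
comparing constrained against free fits tests the twin-design
assumptions. Twin and cross-trait cross-twin (CTCT) correlations are read
off the constrained saturated model in which means and variances are
equated across order and zygosity and correlations across twin
order/direction, with zygosity-specific correlations retained.

Confidence intervals are likelihood-based: the 95% interval for a
standardized component is the set of values whose constrained refit
raises the deviance by at most 3.841, computed by an exact substitution
reparameterisation (the constrained Cholesky entries are expressed
through the component value, so the profile is one-dimensional), with
bounds clipped to [0, 1]. At boundary values (a component truly 0) the
naive χ² reference is used rather than a 50:50 mixture — the standard
convention in the twin literature, noted as a mild conservatism
limitation.

## What the synthetic generator emulates

`simulate_twin_phenotypes()` realises the latent traits through the
factor structure above (MZ pairs share A factor scores exactly, DZ with
correlation 0.5, C shared, E independent), with pair-shared sex and age
(age in days ~ Normal(168, 9) truncated to [145, 203], matching a 5-month
assessment window). Incomplete pairs drop one twin at random at a
configurable rate (default 12% in the pipeline, mirroring a cohort of 285
pairs of which 251 were complete).

`simulate_gaze_cohort()` renders latent traits as raw gaze samples. The
generative law is deliberately minimal — the goal is separable control of
the two phenotypes, not oculomotor realism:

* latency to the first AOI look is lognormal (median 0.4 s);
* the first look lands on the face with a per-infant probability tied to
  the latent orienting trait (equivalent to a softmax over the five
  objects with a face bonus);
* subsequent looks follow a continuous-time Markov chain that jumps
  uniformly among the other AOIs, with exponential dwells whose face mean
  is scaled so the stationary face occupancy equals the infant's dwell-share
  parameter. After a short orienting glance the chain is started from its
  stationary distribution; because exponential dwells are memoryless this
  makes the expected face share of the trial exactly the dwell-share
  parameter rather than biased by the transient;
* missingness is i.i.d. per-sample dropout plus geometric blink bursts
  (mean 12 samples), each mechanism at rate `1 − sqrt(1 − r)` so their
  union realises the per-infant rate `r`, drawn from a Beta distribution
  with mean 0.28 and s.d. 0.13.

Latent standardized traits map to unit-interval parameters through a
probit link calibrated by numerical integration
(`calibrate_probit_link()`): face dwell-share mean 0.44 / s.d. 0.14 and
first-look probability mean 0.30 / s.d. 0.10. The orienting s.d. is set
below the observed s.d. of the 6-trial proportion (0.19) deliberately:
the observed measure adds trial-level binomial noise on top of the
between-infant spread, so a parameter-scale s.d. near 0.19 would
overshoot the observed dispersion. The non-face dwell mean (1.5 s) was
chosen so the mean number of objects explored in 10 s is about 3.6.

What the generator does *not* emulate: saccade kinematics, pupil
dynamics, calibration drift, systematic position biases, and the
heavier-tailed attrition of real infant testing (rendered cohorts lose
almost no trials to the validity filter, whereas real cohorts lose
several percent of infants). Passing the end-to-end tests therefore shows
that the *pipeline* is correct and unbiased under a plausible generative
law — not that the generative law captures real infant gaze.

A deterministic rendering mode (`dwell_noise = "none"`) realises each
infant's dwell-share exactly and is used for round-trip tests: phenotypes
extracted from a noise-free render match the generating parameters to
sample-quantisation error.

One consequence of simulating the whole measurement chain deserves
emphasis: the generating ACE structure applies to the *latent* traits,
and the rendered trials add measurement noise that loads onto E of the
*observed* phenotypes. Twin correlations and heritabilities estimated
from a rendered cohort are therefore attenuated relative to the
generating latent values — exactly as test-retest unreliability
attenuates them in real data. Recovery checks that target the fitting
engine itself (the acceptance checks) simulate at the phenotype level,
where the generating components are the observed-scale truth.

## Gaze processing choices

AOI containment is half-open (`[x0, x1) × [y0, y1)`), so adjacent
rectangles never double-assign a sample. A *look* is a maximal run of at
least 3 consecutive same-AOI samples (~25 ms at 120 Hz); a single invalid
sample inside a run is bridged when both neighbours agree
(interpolation-lite), while valid off-AOI samples always break runs. Both
constants are arguments (`min_samples`, `max_gap`), since minimal look
duration conventions vary across labs.

Trial validity requires all of: valid-sample proportion ≥ 0.25, *summed
valid-sample time* ≥ 5 s, and at least one AOI look. The duration
criterion is interpreted as summed valid time, not elapsed time — elapsed
time is always 20 s, so an elapsed-time reading would be vacuous.
Participants need at least 4 valid trials; measures are unweighted means
over valid trials. The exploration window (10 s) and the target AOI
(face) are configuration constants: any AOI can be designated the target,
which is how sensitivity analyses on, say, the most salient non-social
object are run.

Gaze-quality control follows a screen-then-residualise rule: each
phenotype is tested against the two quality covariates (mean proportion
of missing samples, number of valid trials) with a pair-clustered linear
estimating equation; if either is significant at 0.05 the phenotype is
replaced by residuals *plus the grand mean*, so chance-level comparisons
(against 0.2 for five objects) remain interpretable after adjustment.

## Association statistics

Tests against chance select the procedure by a Shapiro–Wilk normality
test at α = 0.05 (t-test when normality is not rejected, Wilcoxon
signed-rank otherwise, dropping values exactly at chance), with effect
size `d = (mean − chance)/s.d.` in either case. Longitudinal associations
use independence-working linear estimating equations — point estimates
equal least squares — with cluster-robust (per-pair) sandwich standard
errors, no small-sample adjustment, so singleton clusters reduce exactly
to HC0. Outcome and continuous predictors are z-scaled (binary 0/1
columns are not), all predictors entered together. Since estimating
equations have no canonical R², the effect size ΔR² uses the squared
correlation between fitted and observed outcome, full model versus
covariate-only null. Multiplicity over analyses sharing an outcome is
handled by the Benjamini–Hochberg step-up rule at q = 0.05.

## Numerical choices and degenerate inputs

* Deviance evaluations returning non-finite values (non-PD restricted
  covariance during optimisation) are replaced by a large penalty; the
  exported `fiml_minus2ll()` instead errors, naming the offending pair.
* Cholesky sign indeterminacy is resolved by flipping factor columns so
  diagonal paths are non-negative; standardized components are reported
  from squared paths.
* Saturated-model correlations are parameterised on the atanh scale;
  non-PD proposals are penalised rather than transformed away.
* Profile bounds: a component profiled to 0 (or 1) without crossing the
  3.841 threshold reports the boundary itself.
* Degenerate inputs error early with informative messages: all-equal
  values in chance tests, zero variance in skewness, collinear design
  columns in `gee_fit()` (named), overlapping AOIs, non-monotone time
  stamps, missing columns on file input (named).

## Problem sizes used by the test suite

Analytic identities run at toy sizes. Stochastic recovery checks use the
sizes at which their tolerances are meaningful: 4,000 + 4,000 pairs for
univariate heritability (±0.03) and the bivariate shared/unique split
(±0.04) — at this size the Monte-Carlo s.d. of the split is about 0.02,
so these checks remain genuinely stochastic — and 10,000 pairs for the
association slope (±0.02), with CI coverage assessed over 200 replicates
of 1,000 pairs. The full pipeline demonstration below uses a reduced
cohort; the defaults reproduce the full study dimensions.

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 1, out_dir = "pipeline_out")
res <- run_pipeline(cfg)   # ~2 min for the full 155 + 130 pair cohort
res$bivariate$selected$label
res$bivariate$decomposition
```

## Known limitations

* Chi-squared reference at boundary components is unmixed (conservative).
* No sex-limitation, moderation (G×E), or ordinal liability models.
* The gaze generative law is a minimal mechanism; see above for what it
  omits.
* The AOI layout is a stand-in ring layout (five 320 px boxes around the
  screen centre, face position counterbalanced across stimuli); real
  display layouts should be supplied as scene YAML when scoring real
  data.
* Phenotypes are modelled on their raw proportion scale, matching how
  such measures are usually described; a pre-standardisation step is
  available for simulation studies via the generating spec.
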