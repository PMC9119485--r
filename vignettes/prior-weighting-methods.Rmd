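---
title: "Models and methods: precision-weighted performance estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: precision-weighted performance estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorweight)
```

## The scientific problem

In an effort-based visuomotor task, a participant presses a force sensor to
launch a ball toward a target; the relative force determines where the ball
stops. On most trials the outcome is shown (basic trials). On interleaved
*estimation* trials the trajectory is hidden and the participant reports
where they believe the ball stopped, on a 12-option response grid whose
veridical option is centred on the true final position. The quantity of
interest is **prior weighting**: how strongly the participant's belief about
the outcome is pulled toward the target (their prior) relative to sensory
evidence about where the ball actually went. Reduced prior weighting has
been linked to apathy, and its pharmacological modulation by the
noradrenaline reuptake inhibitor atomoxetine to the structural integrity of
the locus coeruleus, measured as a contrast-to-noise ratio (CNR) on
neuromelanin-sensitive MRI.

All positions in this package are fractions of screen width in $[0, 1]$;
pixels appear only at I/O (`frac_to_px()`, default display 1920 px wide).

## The observer model

On estimation trial $n$ the observer combines a Gaussian prior centred on
the target $x_\mathrm{target}$ (sd $\sigma_p$) with Gaussian sensory
evidence centred on the final ball position $x_\mathrm{ball}$
(sd $\sigma_e$), possibly shifted by a constant $x_\mathrm{shift}$. The
posterior is Gaussian with mean

$$\hat{x} = w\, x_\mathrm{target} + (1 - w)\,(x_\mathrm{ball} + x_\mathrm{shift}),
\qquad w = \frac{\sigma_e^2}{\sigma_e^2 + \sigma_p^2},$$

and variance $\sigma_{\hat{x}}^2 = \sigma_e^2 \sigma_p^2 / (\sigma_e^2 +
\sigma_p^2)$. Responses are modelled as samples from this posterior.
Subtracting $x_\mathrm{ball}$ gives the estimator's working identity: the
regression slope of estimation error on performance error is $-w$.

The simulator (`simulate_session()`) draws responses from
$N(\hat{x}, \sigma_{\hat{x}}^2)$ *conditional on the realized ball
position*, exactly matching the likelihood of the hierarchical model below.
A stricter reading of cue combination would first draw an explicit noisy
evidence sample; that mode is available (`evidence_noise = TRUE`) but is not
the default, because the default keeps generator and inference model
coherent and matches the conditional-distribution invariant the test suite
asserts. The force-to-velocity-to-position physics is not simulated: the
final ball position is drawn directly as
$x_\mathrm{target} + N(0, \sigma_m^2)$ with motor noise
$\sigma_m = 0.068$ screen widths, chosen so the interquartile range of force
error is about 9.2 percentage points, the value observed in the placebo
condition of the study population this package emulates.

## Slope-based estimation of prior weighting

`estimate_prior_weighting()` uses only estimation trials. Errors are
z-scored per session (population-sd denominator, fixed for
reproducibility), and a no-intercept model is fitted — either independent
per-session least squares, or one restricted-maximum-likelihood mixed model
with a random slope per session and no intercepts (`method = "mixed"`,
mirroring the study's estimator; flat pooling across all sessions, with
per-participant nesting intentionally not applied because the study
specified one slope per testing session).

Because both variables are standardized, the fitted slope equals the
Pearson correlation of the two error series. This has a consequence worth
stating plainly: the standardized estimator recovers the generating $w$
exactly when the estimation-error variance equals the performance-error
variance, i.e. $\mathrm{Var}(y) = w^2\sigma_m^2 + \sigma^2_\mathrm{resid} =
\sigma_m^2$. A noiseless session is perfectly correlated and yields
$\hat{w} = 1$ regardless of the generating slope. The package therefore
also provides `standardize = FALSE`, which regresses the raw errors in
common screen-fraction units and recovers the slope without that caveat; it
serves as a transparent oracle in the tests. Estimates are never clipped to
$[0, 1]$; out-of-range values are flagged (`out_of_range`), since clipping
would bias the recovery study.

`run_parameter_recovery()` maps each generating $w$ to observer parameters
through the variance-matching condition:
$\sigma_e^2 = (1 + w)\,\sigma_m^2$ and
$\sigma_p^2 = \sigma_e^2 (1 - w)/w$. In this regime the two error
variabilities coincide — as they do, to good approximation, in the
empirical data the task design comes from (both about 6.8% of screen
width) — and the recovery study reproduces the identity-line property: over
a grid $w \in \{0.1, \dots, 0.9\}$ with the default design (40 estimation
trials) and 2000 simulated sessions per point, the median estimate deviates
from the generating value by less than 0.05 everywhere, with the 12-option
discretization switched on. Discretization and edge clamping contribute a
small attenuation (about 0.02–0.03 at mid-range $w$) that the harness
quantifies rather than assumes away.

## Trial-sequence generation

Each session has 4 blocks of 30 trials (20 basic + 10 estimation, one block
per effort-by-reward combination), the first 3 trials of every block basic,
and no two consecutive estimation trials. Valid estimation-slot
arrangements are sampled *exactly uniformly* by the gap bijection (choose
$k$ of $m - k + 1$ virtual slots and spread), rather than by rejection
sampling over permutations: the result is provably uniform over admissible
sequences and runs in linear time, which matters when the recovery study
simulates tens of thousands of sessions (rejection sampling accepts only
about 0.5% of permutations at the default design).

## The hierarchical Bayesian decomposition

A change in prior weighting can come from a change in prior precision, in
evidence precision, or both. The hierarchical model
(`build_generative_model()`, `fit_hierarchical()`) separates these by
modelling the full response distribution of the drug-manipulated group
(both sessions of each participant; control sessions are not fitted):

* per trial: $x_\mathrm{estimate} \sim N(\hat{x}, \sigma_{\hat{x}}^2)$ with
  session-specific sds;
* per participant: $\sigma_{p}^{(j)} = \sigma_p + \Delta_p\,[j =
  \text{atomoxetine}]$ and likewise $\sigma_e^{(j)}$; a shared evidence
  shift $x_\mathrm{shift}$;
* per group: $\sigma_p, \sigma_e \sim N^+(\mu, \tau^2)$ (positive-truncated),
  $\Delta_p, \Delta_e, x_\mathrm{shift} \sim N(\mu, \tau^2)$.

Responses enter in screen-fraction units, not z-scored: the model's
location and scale parameters stay physically interpretable, and the
z-scoring convention belongs to the regression estimator, not the
generative model. Responses recorded on the discrete grid are treated as
continuous Gaussians, as in the source analysis; a discretized likelihood
is out of scope.

**Hyperpriors.** Weakly informative, in screen-fraction units, all
overridable via `hyper_prior_spec()`: group means of the sd parameters
$\sim N^+(0, 0.2^2)$; group sds $\sim$ half-$N(0, 0.1^2)$; the delta and
shift group means are centred at zero ($N(0, 0.1^2)$) — a conservative
prior of no drug effect. The scales are sized to the data range (responses
live in $[0,1]$, sds around 0.05–0.1).

**Variants.** `full`, `prior_delta_only`, `evidence_delta_only`,
`no_delta` fix the omitted $\Delta$ parameters at zero structurally.
`compare_models()` ranks them by WAIC and PSIS-LOO computed from the
pointwise log-likelihood (deviance scale, pairwise difference SEs computed
pointwise). Pareto-smoothed importance sampling uses the Zhang–Stephens
posterior-mean generalized-Pareto fit with the usual weak prior on the
shape, tail smoothing for shapes below 0.7, and truncation at the raw
maximum weight.

**Sampler.** The joint posterior is sampled with adaptive
Metropolis-within-Gibbs over the package's own joint log density. Three
structural choices make this mix well where a naive random walk does not:

1. participant blocks are proposed in per-session coordinates
   $(\mathrm{logit}\, w, \log \sigma_{\hat{x}})$ — the quantities the data
   constrain nearly independently — with exact change-of-variables terms
   back to the natural parameters;
2. proposal covariances are adapted during warm-up only (empirical
   covariance with a Robbins–Monro global scale targeting 28% acceptance;
   the first half of warm-up is discarded from the adaptation history);
3. every iteration interleaves two whole-family moves per parameter family
   (a rescale of all participant deviations together with the group sd, log
   Jacobian $n c$; and a joint location shift with the group mean), which
   traverse the hierarchical funnel that otherwise freezes the group-sd
   parameters.

Positive parameters are sampled on the log scale. Convergence is assessed
with rank-normalized split R-hat and bulk effective sample size; a fit
reports a `converged` flag (all R-hat < 1.01) and warns rather than errors.
The reference budget mirrors the study (8 chains × 4000 iterations, 2000
warm-up); the simulation studies in the test suite use 4 chains × 15,000
iterations with 5,000 warm-up (thinned), which reaches R-hat < 1.01 on a
17-participant cohort in a few minutes, and the model-selection experiment
uses 2 chains × 6,000 per variant. Likelihood evaluations reduce to
per-session Gaussian sufficient statistics, so sampling cost is independent
of trial count.

**Posterior summaries.** Participant-level estimates are posterior medians;
derived prior weightings are computed per draw and then medianed (median of
the derived quantity, not the derived quantity of medians). Posterior
predictive checks simulate replicated responses per retained draw and
summarize per-participant mean predictive error; under the well-specified
model these are centred on zero, and a deliberately misspecified fit (a
large unmodelled evidence shift with the shift clamped at zero) displaces
them, which the tests use as a misfit probe.

## The synthetic cohort

`simulate_cohort()` emulates the study design: 17 Parkinson's participants
tested twice in a counterbalanced placebo/atomoxetine crossover
(drug order permuted in blocks of six, three per order), 20 controls tested
once; Apathy Scale scores as rounded Gaussians clipped to the instrument
range 0–42 with the reported group means and sds; LC CNR, LEDD and UPDRS-III
covariates at plausible values. All randomness flows from one master seed
through per-session derived streams recorded in the output.

Two generative couplings give the group analyses something to detect, with
defaults equal to the study's standardized effects: apathy against prior
weighting (−0.35) and LC CNR against the drug-induced change in prior
weighting (−0.59). When a coupling is zero the corresponding parameters are
drawn *directly from the group-level distributions* — the exact hierarchy
the inference model assumes, which is what a calibration or
coverage experiment needs. When a coupling is non-zero, prior weighting is
targeted on the scale of the reported group summaries
(placebo mean 0.45, sd 0.26; drug-change sd 0.27) and the sds are
back-solved; bounding $w$ to $(0.03, 0.97)$ attenuates the realized
correlations slightly (the drug coupling by roughly 0.05), which the tests
measure rather than hide. Responses at the grid edge are flagged
(`grid_clamped`) and kept by all downstream analyses.

What the generator deliberately does not emulate: reward-feedback effects
on behaviour, pharmacokinetics, learning across trials, and the
force-to-position physics. Passing tests on this synthetic cohort show that
the estimators recover the generative structure they assume; they cannot
show that real estimation behaviour is Gaussian, stationary, or free of
lapses.

## Group-level inference

All continuous variables are z-scored and categorical predictors
sum-to-zero coded, so reported coefficients are standardized betas;
tests are two-sided at $\alpha = 0.05$ and uncorrected (a Holm option
exists on the user's side via `p.adjust`). The procedures:

* `regress_apathy()`: OLS of prior weighting on apathy × group with the
  performance-error IQR as nuisance covariate (residual df 32 at the study's
  37 sessions).
* `fit_drug_cnr_model()`: linear mixed model (random participant
  intercept) of prior weighting on drug × LC CNR plus the IQR covariate,
  with Satterthwaite denominator df substituting for Kenward–Rogers — on
  this balanced crossover they coincide for the tested contrasts. The IQR
  covariate enters at participant level (session mean): that is the only
  specification consistent with the printed degrees of freedom
  (within-participant effects on $n-2 = 15$ df, the between-participant CNR
  effect on $n-3 = 14$).
* `pitman_test()`: Pitman–Morgan equality of variances for paired samples
  via the sum–difference correlation, $t = r\sqrt{n-2}/\sqrt{1-r^2}$.
* `johnson_neyman()`: closed-form thresholds where a moderated slope
  crosses the two-sided significance boundary (a quadratic in the
  moderator); an empty discriminant yields "all" or "none" depending on the
  quadratic's sign, not an error.
* `jzs_bayes_factor()`: default-prior Bayes factors — Cauchy
  ($\sqrt{2}/2$) effect-size prior for t tests via adaptive integration
  over the prior variance mixture; uniform (stretched-beta $\kappa = 1$)
  prior on the correlation via the integral form of the exact sampling
  density of $r$.
* `precision_term_ancova()`: repeated-measures ANCOVA testing whether the
  drug effect on prior weighting relates differently to the drug effects on
  the two precision terms; the interaction F (1, $n-2$ df) is algebraically
  the squared t of regressing the within-participant difference on the
  covariate. The two delta-sd variables are standardized by default before
  the within-subject contrast (both modes available; the unstandardized
  mode is the algebraic-identity oracle in the tests).
* `plausible_values()`: per-posterior-draw correlations between the drawn
  drug effects and the observed change in prior weighting, propagating
  parameter uncertainty into the correlation scale.
* Inclusion Bayes factors by model averaging are out of scope;
  `bic_inclusion_bf()` offers a coarse BIC-difference approximation and
  labels itself as such.

## Locus coeruleus contrast

`compute_cnr_map()` implements voxelwise
$(x - \mu_\mathrm{ref})/\sigma_\mathrm{ref}$ against a reference-region
mask ($n-1$ sd denominator, fixed by convention here since the source is
silent); `compute_contrast_ratio_map()` divides by the reference mean
instead. CNR is affine-invariant and CR scale- but not offset-invariant;
both facts are asserted numerically. `generate_phantom()` builds a
synthetic test volume whose blob elevation is specified in reference-sd
units, so the recovered mean CNR is unbiased for the requested effect at
any noise level. Atlas construction, bias-field correction and
coregistration are upstream of this package; masks carry their
probability-threshold provenance only as metadata. NIfTI I/O is available
when RNifti is installed.

## Reproducibility plumbing

`run_pipeline()` chains simulate → estimate → fit → group statistics with
stage toggles, per-stage derived seeds, CSV outputs and a JSON manifest.
Identical seeds give byte-identical simulated artefacts. The package has no
shell entry point by design: it is an analysis library, and the functions
plus this vignette are its interface.

## Known limitations

* The Gaussian continuous likelihood ignores the 12-option discretization
  of real responses; the recovery harness bounds the resulting bias instead
  of removing it.
* The mixed-model prior-weighting estimator pools flatly across sessions;
  participant-level nesting is not implemented as a default because the
  source analysis specified one slope per session.
* The Metropolis-within-Gibbs sampler needs tens of thousands of cheap
  iterations where a gradient-based sampler would need hundreds; budgets
  below a few thousand iterations per chain are useful only for smoke
  tests.
* Couplings in the synthetic cohort are calibrated on the correlation scale
  only approximately (bounding of $w$ attenuates them by up to ~0.05).
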