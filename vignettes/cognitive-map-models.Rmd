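---
title: "Modeling reward generalization over spatial and predictive cognitive maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling reward generalization over spatial and predictive cognitive maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewardmaps)
```

## The scientific problem

When an agent learns rewards for a handful of stimuli and must value
stimuli it has never sampled, it needs a *map*: some notion of which
stimuli are similar, so that value can generalize. `rewardmaps` models two
candidate maps for stimuli encountered in a spatial environment:

* a **spatial map** — stimuli close together in the arena have similar
  values — formalized as a Gaussian (RBF) kernel over Euclidean distances
  between stimulus locations;
* a **predictive map** — stimuli that tend to follow each other during
  exploration have similar values — formalized as a diffusion kernel over
  the stimulus transition graph recovered from a temporal-difference
  learned successor representation (SR).

Both maps plug into Gaussian-process (GP) regression over stimulus
rewards. A **compositional** model averages the two kernels; a **mean
tracker** (identity kernel) learns each stimulus independently and serves
as the no-generalization baseline. The pipeline fits all four models to
trial-level choices, compares them by random-effects Bayesian model
selection, decomposes each participant's behavior into spatial and
predictive effect magnitudes, tracks how the balance ("spatial weight")
moves across trials, derives trial-wise regressors for neuroimaging GLMs,
and supplies a bootstrap mediation analysis for per-participant summaries.

## The generative world the synthetic cohort emulates

Because the original behavioral data cannot be bundled, the package ships
a first-class synthetic world whose defaults mirror the study conditions:

* a circular arena of radius 15 virtual meters (vm) holding 12 stimuli at
  least 3 vm apart, each revealed within a 3-vm visibility radius;
* exploration by one of four policies seen in free navigation —
  stereotyped stimulus tours, border circling, top-to-bottom lawnmower
  scans, or a correlated random walk with reflective walls. Movement is
  discrete steps of fixed length (default 0.5 vm; the source studies do
  not report step sizes or sampling rates, so these are free parameters,
  not estimates). Tour agents dwell briefly at each stimulus, as
  participants do when a hidden stimulus reveals itself;
* two reward contexts with integer values in 0–100, generated under three
  constraints that are re-tested rather than trusted: pooled pairwise
  value differences uncorrelated with pairwise spatial distance (Pearson
  p > 0.05), similar total value across contexts, and four inference
  stimuli that never appear in choices, with true values 71/3 (context 1)
  and 72/13 (context 2);
* 100 choice trials in alternating context blocks of 10, generated by GP
  agents that compute posterior means under a designated kernel and choose
  by a softmax with temperature 5 reward points (the studies fit logistic
  slopes rather than specifying an agent noise model, so a single softmax
  temperature is the simplest defensible choice).

By default every agent follows its own seeded random tour. This is the one
place the generator deliberately goes beyond the minimal reading of the
task: with a shared, spatially convenient tour, the predictive kernel
nearly duplicates the spatial kernel and no analysis could tell the maps
apart. Randomized tours play the same role for transition structure that
the decorrelated value assignment plays for rewards. Even so the kernels
remain substantially correlated (around r = 0.7 in the shipped cohort),
which is why the effect decomposition below never interprets a single
joint fit.

What the generator does **not** emulate: first-person rendering, landmark
geometry, object-location memory feedback loops, reaction times, and any
within-session drift in exploration style. Passing tests therefore show
that the *pipeline* recovers what it should from data with this
statistical structure, not that human data behave this way.

## Maps from behavior

**Path integration.** Stimulus locations are estimated per participant by
re-integrating displacements with Gaussian noise (sd 0.001 vm) added to
the location estimate at each time step, then averaging the integrated
positions recorded within 3 vm of each stimulus. The noise injection is
implemented literally as stated by its source and exposed as
`noise_sigma`; at these magnitudes the estimator's error is dominated not
by noise but by chord bias — grazing pass-bys pull the position average
toward the path. With dwelling tour agents the per-stimulus error stays
under half the visibility radius. Stimuli never approached are flagged and
(by default) fall back to their true coordinates with a warning.

**Spatial kernel.** `K[i, j] = sigma_f2 * exp(-d_ij^2 / (2 lambda^2))`,
with the signal variance fixed at 1: no fitted value is reported for it
anywhere, and with a logistic link downstream it trades off against the
regression slope, so freeing it would only deidentify the slope. The
lengthscale `lambda` is grid-searched (default grid 0.5–16 vm, roughly
log-spaced around the 3-vm stimulus separation).

**Successor representation and diffusion kernel.** Visits are extracted
from the trajectory with per-stimulus debouncing (one visit per contiguous
in-disc interval — visit granularity is otherwise undefined). The SR is
TD-learned in experiential order from zero initialization (single pass;
both exposed as configuration), with discount `gamma = 0.9` and
grid-searched learning rate `eta`. The transition matrix is recovered as
`T = (M^-1 - I) / (-gamma)`; small negative entries from finite-sample M
are clipped to zero so that `L = I - T` stays a proper Laplacian; symmetry
is enforced by the pairwise maximum of the triangles; and rows are
renormalized (pairwise max breaks stochasticity; renormalization preserves
the normalized-Laplacian reading — both behaviors sit behind a flag,
default renormalize). Renormalization can leave slight asymmetry, so the
Laplacian uses the symmetric part. The diffusion kernel
`K = expm(-lambda L)` is computed by symmetric eigendecomposition rather
than scaling-and-squaring: exactness and positive semi-definiteness come
for free, and the scaling-and-squaring route serves as the independent
oracle in the tests. Its lengthscale is fixed at 1, the discount at 0.9. A
count-based transition estimator is provided as the fallback for
ill-conditioned successor matrices (condition number above 1e10 raises an
error naming it).

## GP prediction and choice modeling

Sequential predictions condition each context's GP strictly on that
context's past rewards (a "context firewall" the tests enforce by
permutation). Rewards are mean-centered per context by the running mean of
observations so far (whether centering was per context or global is not
derivable from the sources; a flag offers both, and on the very first
trial of a context there is nothing to center by, so the prediction is the
zero prior). Observation noise is fixed at `sigma2 = 0.01`. Repeated
observations enter as separate rows; the noise term handles duplicates.
The per-trial solve grows a bordered inverse of the observation
covariance, so a 100-trial run costs O(sum t^2); the tests pin it to
from-scratch batch refits at 1e-8.

Choices are modeled as
`P(choose a) = plogis(beta0 + (beta1 + b_p) (m_a - m_b))` with a fixed
intercept absorbing side bias and participant-specific random slopes.
Predictors are z-scored within participant, with scales stored. Two
estimation engines exist deliberately:

* `engine = "glmer"` (lme4), the reference engine for one-off fits;
* `engine = "two_stage"`, the package's empirical-Bayes hierarchical
  logistic: penalized per-participant Newton fits shrunk toward the
  population slope, with moment/EM updates of the population parameters.

The two agree closely on simulated data (the tests require slope
agreement and r > 0.9 across participant slopes). The two-stage engine
exists because the inner loops are brutal for any general GLMM optimizer:
hyperparameter grids evaluate up to 36 kernel configurations, and
leave-one-trial-out CV refits the regression once per trial (2,400 refits
per model on a 24 x 100 cohort). Grid search therefore scores candidates
by the pooled logistic likelihood (hyperparameter selection only needs an
ordering), and LOO-CV refits the held-out participant's coefficients while
holding the population shrinkage target at its full-data value — one trial
among thousands moves the pooled stage negligibly. GP predictions are
never recomputed inside LOO: they depend on experienced rewards, not on
the held-out choice label. Grid ties break toward smaller `lambda`, then
smaller `eta`, deterministically.

Per-participant model evidence is the sum of that participant's held-out
log-likelihoods — random-effects model selection needs subject-level
evidences, and summed LOO scores are the natural cross-validated choice.
The BMS itself is the standard variational Dirichlet scheme (uniform prior
alpha0 = 1) with exceedance probabilities from 1e5 seeded Dirichlet draws.

## Effects, weights, and dynamics

Because the spatial and predictive predictors correlate, per-participant
effects come from two reparameterized models — spatial as main predictor
with (predictive - spatial) second, and the reverse — whose implied
coefficients on each predictor are algebraically recoverable from either
parameterization. The package averages the *absolute* implied coefficients
across the two models (the aggregation rule is ambiguous in prose form;
average-of-absolutes is implemented and flagged here), and the spatial
weight is `spatial / (spatial + predictive)`, defined as 0.5 with a flag
if both vanish. Trial-wise weights add predictor-by-trial interactions
(trial z-scored), making the implied coefficients linear in trial; the
same average-then-ratio aggregation is used so that with null interactions
the trial-wise weights reduce *exactly* to the static ones — the nesting
the tests assert. Weight time-series are summarized by a quasi-binomial
logistic slope per participant (exact zero for constant series). A
map-evidence probe, `map_posterior_probability()`, compares GP marginal
likelihoods of the rewards observed through trial t under the two kernels
with a uniform prior; its discriminability grows with the spatial
correlation structure of the rewards, not with trial count, once every
stimulus value is pinned down.

Value ratings are modeled with the same logic in the linear domain
(closed-form empirical-Bayes ridge per participant, per-rating LOO, BMS),
with a baseline model that predicts every rating by the mean of the mean
tracker's predictions for non-inference stimuli.

## Regressors and mediation

The neuroimaging hand-off constructs, without fitting any GLM: adaptation
regressors (spatial and predictive distance to the preceding stimulus,
z-scored per block — per block rather than per session by default, the
finer and safer choice — excluding block-initial events, immediate
repeats, and post-choice events); chosen/unchosen value modulators
(demeaned, never orthogonalized); compositional reward prediction errors
(observed minus predicted-before-feedback, centering re-added); the
spatial-weight update `w_t - w_{t-1}` (demeaned, telescoping to
`w_T - w_1`); and relative map accuracy `|RPE_pred| - |RPE_spatial|`, with
positive values meaning the outcome was more consistent with the spatial
map (the sign convention is recorded in the table's metadata). "Distance
according to a kernel" defaults to the kernel-induced metric
`sqrt(K_ii + K_jj - 2 K_ij)` — for the Gaussian kernel this is monotone in
Euclidean distance — with `1 - K` behind a flag.

Mediation is single-level OLS: a from M ~ X, b and c' from Y ~ M + X, c
from Y ~ X, ab = a*b, so ab + c' = c holds to machine precision; inference
is a percentile bootstrap over participants (default 10,000 resamples,
seeded) with two-tailed p-values read off the bootstrap distribution.
Variables are z-scored by default (the reported path units in the source
analyses do not state standardization; both modes ship).

## Problem sizes and numerical choices

The shipped validation experiments use: 100 random 12-state reversible
chains for the SR round trip (max error < 1e-8 asserted, observed ~1e-15);
20 synthetic datasets for sequential-vs-batch GP equivalence (1e-8
asserted, observed ~1e-11); a 4 x 4 model-recovery confusion with 24
participants x 100 trials x 10 seeds (the generating model wins the BMS
frequency in over 70% of cohorts; identity and a near-zero-lengthscale
spatial kernel are structurally confusable, so a perfect diagonal is not
attainable even in principle); 20 switch-agent cohorts of 12 participants
for weight dynamics (sign tests at p < 0.05); 10 cohorts of 8 for the
regressor checks; and 500 null replicates (n = 48, 1,000 bootsamples each)
for mediation calibration — the full 10,000-resample default is for
analyses, not for calibration loops, where it would add nothing but
runtime. Degenerate inputs are handled explicitly: constant predictors
warn and pin slopes at zero, constant z-score columns are zeroed with a
warning, rank-deficient mediation regressions drop the collinear column's
contribution, and unvisited stimuli are flagged.

## Known limitations

The two-stage engine approximates the GLMM; its shrinkage constants come
from moment/EM updates, not a marginal likelihood, and extreme separation
is handled by the prior rather than detected formally. The effect
decomposition's aggregation rule and the trial-wise weight construction
are documented interpretations of ambiguous prose, not guaranteed
reproductions. The synthetic world's exploration policies are stylized;
none of the validation results certify behavior on human data, and the
reproduction of the published four-model frequencies requires the deposited
behavioral dataset, which must be supplied externally
(`data-raw/deposited/`) — offline, that check reports its absence rather
than silently passing.
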