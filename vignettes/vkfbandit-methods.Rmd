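---
title: "Modelling adaptive learning under uncertainty in restless bandits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adaptive learning under uncertainty in restless bandits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vkfbandit)
```

## The scientific problem

In a restless multi-armed bandit, each option's reward probability drifts
over time, so a decision maker can never stop learning: good behaviour
requires tracking both the *value* of each option and how *uncertain* and
*volatile* the environment currently is. Two people can look identical on
surface measures (accuracy, win-stay/lose-shift) while differing sharply in
the latent computations behind their choices — one reduces uncertainty with
experience and settles into efficient learning, the other keeps treating the
world as volatile and never lets its learning rate decay. `vkfbandit`
implements the full analysis chain for studying exactly this kind of
dissociation in two-group designs (for instance chronic-pain patients versus
healthy controls): task simulation, latent-state learning models,
hierarchical model fitting and comparison, trajectory characterization, and
the mediation analysis linking uncertainty adaptation to questionnaire
outcomes such as apathy.

Because no participant-level dataset ships with the package, a first-class
synthetic-data module generates cohorts with the statistical structure the
analysis assumes; every pipeline stage is exercised end-to-end on those
cohorts.

## The task model

`generate_reward_schedule()` draws the hidden environment: each of
`n_arms` (default 3) reward probabilities performs an independent step
random walk over `n_trials` (default 200). On every trial each arm has a
10% chance (`step_prob = 0.1`) of proposing a step of ±0.1
(`step_size = 0.1`), bounded in [0.1, 0.9]. A proposed step that would
leave the bounds is *rejected* (the value holds) rather than clipped, which
keeps the consecutive-difference invariant exactly {0, ±`step_size`} and
makes the walk testable. Initial probabilities are drawn uniformly from the
step grid inside the bounds, so every simulated subject faces a different
environment.

Two conventions deserve a note. First, the step size: a 0.1 step is the
only choice consistent with probabilities bounded in [0.1, 0.9]; it is
configurable. Second, the trial count defaults to 200 — the trial range the
exponential trajectory analysis is defined on (x = 1..200) — and the
drift is applied on every trial rather than only on rewarded trials; a
reward-conditioned drift variant is available via
`simulate_agent(drift_on_reward = TRUE)` for users who prefer that reading
of the task.

Responses slower than 5 s (or missing) are invalid; invalid trials carry no
outcome and are skipped by every model without a state update.

## Learning models

Four trial-by-trial models are implemented (`model_ids()`), all sharing the
initial mean `m0 = 0.5` (the probability midpoint):

* **rw1** — Rescorla–Wagner delta rule, `v' = v + α (R − v)`, one learning
  rate `α`, softmax with weight `β_V` on the raw values.
* **rw2** — the same with separate learning rates for positive
  (`α_pos`) and negative (`α_neg`) feedback.
* **kf** — Kalman filter with constant process noise `v` and observation
  noise `σ²`: gain `k = (w+v)/(w+v+σ²)`, mean `m' = m + k (O − m)`,
  posterior variance `w' = (1−k)(w+v)`. Unchosen arms keep their mean but
  diffuse, `w ← w + v`, because their hidden probabilities keep drifting
  while unobserved.
* **vkf** — the binary volatile Kalman filter: the process-noise variance
  (volatility) `v` is itself learned at rate `λ` from the realized squared
  belief change,
  `v' = v + λ ((m'−m)² + w + w' − 2 w_cov − v)` with
  `w_cov = (1−k) w`. Volatility is tracked per arm; only the chosen arm's
  `v` updates, and unchosen arms diffuse by their own current volatility.
  `vkf_rv` is the value-only softmax variant.

One dynamical property of this filter deserves emphasis. Because unchosen
arms accumulate diffusion, a revisited stale arm contributes a large
`w − v` term to the volatility update, so the *volatility series itself
drifts upward* over a long session — the per-arm filter interprets the
staleness of rarely-sampled options as environmental change. The
decision-relevant latents are better behaved: the chosen arm's posterior
variance (the package's "uncertainty" series) and its gain (the
"learning rate") start at the level set by the initial volatility `v0`
and decay towards an operating level whenever `v0` starts above it. This
asymmetry is why, in the synthetic cohorts below, adaptive agents are
realized through a high `v0` (uncertainty visibly resolves with
experience) and impaired-adaptation agents through a low `v0` with a high
`λ` (uncertainty starts at its operating level and never visibly falls).
An alternative formulation that runs each arm's filter in its own event
time (no diffusion of unchosen arms) avoids the volatility drift, but it
also drains the choice likelihood of almost all information about `λ` and
the uncertainty weight — relative uncertainty then barely varies — and
with it any prospect of recovering those parameters from 200-trial
sessions; the diffusion form is the one this analysis chain is built on.

The observation update operates directly on the probability scale with the
binary-noise parameter `σ²` in the gain (a sigmoid-linked variant is a
deliberate non-goal here: the linear form is the form the pipeline is
designed around, and the λ = 0 reduction to the constant-volatility Kalman
filter — which the test suite asserts at machine tolerance — only holds
exactly for the linear form). The posterior-variance update uses the
standard predict-then-update form `w' = (1−k)(w+v)`; since the gain's
numerator is the prior variance `w+v`, the posterior must use it too.

For the Kalman-family models the softmax operates on *relative* quantities:
each arm's share of the summed means (relative value, RV) and of the summed
posterior variances (relative uncertainty, RU),

\[ P_i \propto \exp(\beta_V\, RV_i + \beta_U\, RU_i). \]

RV/RU are defined per chosen option in the underlying construct; the
softmax needs a value per option, so each arm's share is used, which
reduces to the construct at the chosen arm. The Rescorla–Wagner models use
raw values, matching their standard formulation.

The trial-wise "learning rate" reported by the package is the Kalman gain
`k` of the chosen arm; "uncertainty" is the chosen arm's posterior variance
`w` (an arm-averaged option exists). Filtering is strictly causal: the
choice probability at trial *t* uses the pre-choice (prior) latent state.

`negative_log_likelihood()` evaluates the same filter in compiled code
(~0.2 ms per 200-trial evaluation); the R implementation `run_model()` is
the reference, and the suite asserts their agreement to 1e−10 as well as
bit-identity between an agent's internal states and re-filtering its own
data.

## Hierarchical fitting and model comparison

Parameters are fit in an unconstrained space — sigmoid transform for
unit-range parameters, exponential for positive ones — with the wide
initial prior N(0, 6.25) on every coordinate, so the prior barely
constrains plausible native values. `map_fit_subject()` maximizes the log
joint with multi-start BFGS (10 starts: the prior mean plus prior draws)
and computes the Laplace approximation to the model evidence
(`log joint at the mode + d/2·log 2π − ½·log det H`).

`hbi_fit()` is a self-contained hierarchical empirical-Bayes scheme with
the contract of the random-effects toolboxes used in this literature:

1. every subject × model is fit under the 0/6.25 prior;
2. per-subject model responsibilities are computed from the Laplace
   evidences;
3. each model's group-level Gaussian prior is re-estimated from the
   subject optima, responsibility-weighted — the variance update adds each
   subject's Laplace posterior variance (diagonal of the inverse Hessian)
   to the spread of the optima, without which the empirical prior collapses
   and over-shrinks weakly identified parameters;
4. subjects are refit under the empirical priors (deterministically: warm
   start from the previous optimum plus the group-mean start, so the outer
   loop converges rather than jittering), and the loop repeats until the
   transformed group means change by less than `tol = 1e−3` (cap 50
   iterations; non-convergence returns the best iterate, flagged).

Model comparison uses random-effects Bayesian model selection: a
variational Dirichlet estimate of population model frequencies followed by
a Monte-Carlo estimate (10⁵ draws, seeded) of each model's exceedance
probability — the probability that it is the most frequent model in the
population.

## Parameter recovery and the v0 control

`parameter_recovery()` validates the pipeline: per replicate, 30 artificial
subjects are simulated from the binary VKF with the two-term softmax, fit
hierarchically, and the Pearson correlation between true and recovered
native parameters is computed across subjects; the reported value is the
per-parameter median over replicates (20 at full scale; the acceptance
script uses 5 replicates and the test suite similar reduced sizes to keep
runtimes in minutes — these are the package's chosen desk-scale settings.
The replicate-to-replicate spread at that scale is roughly ±0.05 for the
well-identified parameters and ±0.2 for the observation-noise and
initial-volatility parameters, whose recovery is intrinsically
seed-sensitive here).

The true-parameter distributions are the one genuinely open design choice,
and achievable recovery levels depend on them. The package draws each
parameter from a normal in transformed space
(`agent_param_dist()`): λ ~ logit-N(logit 0.2, 0.9), v0 ~ log-N(log 0.5,
1.3), σ² ~ log-N(0, 1.5), β_V ~ log-N(log 2.2, 1.0) and
β_U ~ log-N(log 2.2, 0.5). Three considerations fix the locations and
scales:

* **Identifiability of σ².** The gain `k = (w+v)/(w+v+σ²)` is the only
  channel through which σ² reaches behaviour. If v0 (and hence the early
  `w+v`) is large relative to σ², the gain saturates near 1 and the
  likelihood is nearly flat in σ² — no fitting procedure can then recover
  it, and strong σ² recovery in this model family implies a
  generative regime where σ² is comparable to `w+v`. Hence the small v0
  location.
* **Dispersion relative to estimation noise.** A recovery correlation is
  signal variance over total variance; with 200 binary trials per subject
  the per-subject posterior on log σ² has a standard deviation of order
  0.5–1, so the true dispersion must be of order 1–2 in log space for
  correlations near 0.9. The β_V and σ² scales reflect that.
* **The two decision weights are not symmetric.** Relative uncertainty has
  a narrower behavioural dynamic range than relative value, and the
  uncertainty weight is the second-weakest recovered parameter in this
  model family's published recovery analyses; drawing β_U with a tighter
  dispersion than β_V reproduces that asymmetry.

Two parameters recover markedly worse than the rest under any regime we
examined: v0, which only influences the first few tens of trials before
the learned volatility forgets its initial value, and σ², which shares
the gain with the volatility so that 200 binary trials mainly express
their ratio. The weakness of v0 is precisely why the accompanying control
analysis (`fixed_v0_sensitivity()`) clamps it at {1, 3, 5, 7, 9} and
verifies that recovery of λ, σ² and the decision weights is insensitive
to the clamp.

## Trajectory analysis and the adaptation index

For each subject the fitted model is run over the observed choices and a
latent series (default: chosen-arm posterior variance, i.e. uncertainty) is
characterized two ways: an OLS slope with its two-sided p-value, and a
nonlinear least-squares exponential `f(x) = a·e^{bx}` over trial numbers
(multi-start across both signs of `b`, plus a log-linear initialization
when the series is positive). For decaying fits the time constant
`τ = −1/b` is the number of trials to fall to 1/e (≈37%) of the initial
value. Trajectories are classified `decay` (b < 0, adaptive), `growth`
(b > 0, maladaptive) or `flat`; by default significance is not required
for a non-flat class — the sign rule is the primary classification — and a
significance-augmented rule (p < 0.05) is available.

Group contrasts use pooled-variance two-sample t-tests on the per-subject
slopes and rates (the pooled form gives the conventional
`n1 + n2 − 2` degrees of freedom) and Fisher's exact test on decay-vs-not counts.

When the pipeline contrasts groups it refits the winning model *within
each group* before extracting trajectories
(`pipeline_config(per_group_fit = TRUE)`, the default). The reason is
shrinkage: a pooled hierarchical fit pulls every subject's weakly
identified parameters (the initial volatility above all) towards one
population mean, which can erase a genuine between-group difference in
exactly those parameters. Per-group empirical priors shrink within, not
across, groups; model *comparison* still uses the pooled fit, where
pooling is appropriate.

The **uncertainty-adaptation index** — the mediator in the clinical
analysis, whose exact operationalization the construct leaves open — is
defined as the sign-flipped OLS slope of the subject's uncertainty series:
positive means uncertainty was reduced over the task. The sign-flipped
exponential rate `−b` is available as an alternative (`method = "decay"`).

## Clinical statistics

`mediation()` implements single-mediator OLS mediation: `a` from `M ~ X`,
`b` and `c'` from `Y ~ X + M`, total effect `c` from `Y ~ X`, indirect
effect `ab` (identically `c − c'` for linear models — asserted to 1e−10),
with a percentile bootstrap CI from 5000 case-resampled replicates of whole
subjects; case resampling and the percentile interval are the natural
choices when the indirect-effect distribution is asymmetric.
Pooled-variance t-tests and Pearson control correlations (GCPS severity
against the adaptation index and questionnaire battery) round out the
module. Missing data are handled complete-case per analysis.

## What the synthetic cohorts do and do not emulate

`simulate_cohort()` draws, per subject, a fresh schedule and a binary-VKF
agent, plus questionnaire scores from a linear structural model: apathy =
base + group effect + loading × (standardized true adaptation index) +
Gaussian noise, with plausibly scaled VAS/PHQ-9/PCS/EQ-5D scores and a
GCPS grade distribution matching a mild-to-moderate chronic-pain sample.
The default design (`default_groups()`) has 39 control-like and 26
patient-like subjects; the control-like group starts with initial
volatility far above its operating level (high `v0`, low `λ`) and so
reduces uncertainty with experience, while the patient-like group draws
higher volatility learning rates with initial volatility at the operating
level, yielding flat uncertainty trajectories. Because the group difference enters apathy
both directly and through the adaptation index, the generated cohorts
realize partial mediation mechanistically rather than by construction of
the outcome alone.

What passing tests on these cohorts shows: the pipeline recovers the
structures it assumes — generating parameters, group trajectory
differences, mediation paths — at realistic sample sizes. What it cannot
show: anything about real patients. The generator's agents are exactly the
fitted model family (no model mismatch), response times are decorative,
questionnaire noise is Gaussian and independent across instruments, and
no exclusion/outlier structure is simulated. Empirical effect sizes from
any real two-group study are therefore outside what these simulations can
certify.

## Numerical choices and limitations

* Softmax is computed with max-subtraction; normalization is exact to
  1e−12 and shift-invariance holds by construction.
* Posterior variances, volatilities and the policy's relative inputs are
  floored at 1e−12: agents at the edge of the parameter space (gain
  numerically 0 or 1) otherwise drive means or variances into
  multiplicative underflow over a few hundred trials.
* Hessians are numerical (`optimHess`); non-positive-definite curvature is
  ridged until Cholesky succeeds and the fit flagged as not cleanly
  converged.
* The exceedance-probability Monte Carlo uses a fixed seed; XPs sum to 1
  up to sampling error (~1e−3 at the default 10⁵ draws).
* Exponential fits on near-flat series can put `b` on either side of 0
  with large uncertainty; classification of such series is genuinely
  unstable and the significance-augmented rule is the conservative option.
* `hbi_fit` treats group variances as diagonal (no parameter covariance at
  the group level), and model responsibilities use Laplace evidences, so
  pathologically multimodal subject posteriors are beyond its reach.
* The middle/late phase windows of the binned dynamics (51–100, 151–200)
  leave trials 101–150 unassigned by design, matching the convention the
  analysis follows; `binned_dynamics()` accepts custom windows.
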