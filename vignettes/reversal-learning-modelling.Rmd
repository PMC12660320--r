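---
title: "Modelling probabilistic reversal learning with prlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling probabilistic reversal learning with prlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prlearn)
```

## The task and what the generator emulates

`prlearn` models a three-symbol probabilistic reversal-learning task. Each
block introduces three fresh abstract symbols; one is rewarded with
probability 0.70 and the other two with 0.30. On every trial two of the
three symbols appear, in the fixed cyclic pair order AB, BC, CA, with
left/right placement randomised; the participant picks one and receives a
binary outcome (reward / non-reward). After every 25 trials within a block
the high reward probability is covertly reassigned to one of the other two
symbols (a *reversal*), forcing continual re-learning. The default session
is four blocks of 100, 100, 60 and 60 trials — 320 trials, 12 symbols. A
response deadline (1.25 s) produces occasional *lost* trials with no choice
and no feedback.

`build_schedule()` materialises the whole design up front, including a
pre-drawn Bernoulli outcome for **each of the three symbols on each trial**.
Pre-drawing makes any chosen symbol's outcome schedule-determined, so a
simulated run, a re-fit, and the simulation-based likelihood all see the
same world; the marginal reward probabilities are unaffected. Design points
the task description leaves open were fixed as follows:

- at a reversal the new high-probability symbol is drawn uniformly from the
  two currently low-probability symbols (guarantees a change);
- each block starts with a uniformly drawn high-probability symbol;
- 60-trial blocks reverse after trials 25 and 50, leaving a truncated final
  period of 10 trials, which the analyses treat like any other period;
- trials, blocks and symbols are numbered from 1, the R convention, both
  internally and in outputs. The schedule export columns `draw_sym0/1/2`
  name the block's first/second/third symbol.

## The learning models

Each option A carries an expected value $V_A$, updated only when A is
chosen, via the prediction error $\delta(t) = r(t) - V_A(t)$:

$$V_A(t+1) = V_A(t) + \alpha\,\delta(t), \qquad
P_A(t) = \sigma\!\big(\beta\,(V_A(t)-V_B(t))\big)$$

with $\sigma(z) = 1/(1+e^{-z})$. `rw1` uses one learning rate $\alpha$;
`rw2` uses $\alpha^{+}$ after reward and $\alpha^{-}$ after non-reward,
capturing the asymmetry with which positive and negative feedback shape
behaviour. `rw2` with equal rates is *bitwise* identical to `rw1` (a tested
invariant). Non-reward is coded 0, so $\alpha^{-}$ applies when $r = 0$.

Assumptions and initialisation:

- values start at $v_0 = 0.5$, the uninformative midpoint of binary
  outcomes, and reset to $v_0$ at block boundaries (new symbols make this
  mandatory); values are carried *across* reversal boundaries, which are
  covert;
- unchosen and unshown symbols are never updated;
- lost trials trigger no update and contribute nothing to any likelihood.

## Fitting

`rw_fit()` estimates parameters per session (by default per
subject × block × condition via `fit_sessions()`; a pooled
subject × condition mode is available) under the constraints $\beta > 0$
and $0.1 < \alpha < 0.9$:

1. an exhaustive **grid search** (17 learning-rate points strictly inside
   (0.1, 0.9), 20 log-spaced $\beta$ points in [0.1, 20]) finds a good
   start. Because the value trajectory does not depend on $\beta$, each
   learning-rate cell is propagated once and all $\beta$ values are scored
   analytically; ties break toward the smallest rates, then the smallest
   $\beta$;
2. a **Nelder–Mead simplex** refines the start in a smoothly
   reparameterised space (logit for the rates into the open constraint
   interval, log for $\beta$), so the optimiser is unconstrained and the
   estimates can pin at, but never leave, the box. Tolerance `reltol =
   1e-6`, iteration cap 2000; non-convergence is flagged, returning the
   best point found. The refined log-likelihood can never fall below the
   grid start.

Two likelihoods are available. The default **observed-choice** likelihood
is the sum of log SoftMax probabilities of the recorded choices, computed
on the observed history — fast and deterministic. The **simulation-based**
likelihood reproduces the predicted-choice-probability procedure: 1000
forward simulations per parameter set, in which the model's own choices
drive the value updates and outcomes come from the schedule's pre-drawn
table; each trial's predicted probability of the observed choice is the
mean across simulations of the probability each simulation assigns to it.
Degenerate identities pin the two together ($\beta = 0$ gives
$m\,\ln 0.5$ exactly; $\alpha = 0$ makes them equal), and their Monte-Carlo
noise shrinks as $1/\sqrt{n_\text{sims}}$. Trials lost in the observed
session are skipped in the simulations too, keeping histories aligned.
During simplex refinement in simulated mode the same seed is reused for
every evaluation (common random numbers), so the objective is
deterministic. One known property: at extreme $\beta$ the simulated
likelihood is flatter than the observed one, because disagreement between
simulations caps the mean predicted probability of any single choice; the
two surfaces agree in rank over the moderate region where the models are
identified.

Numerical safety: choice probabilities are floored at $10^{-12}$ before
logs. Model comparison sums per-session $\mathrm{BIC} = -2\log L +
d\log n$ (with $d = 2$ or 3 free parameters and $n$ the non-lost trial
count) across subjects; `compare_models()` reports an exact tie explicitly.
After model selection, `latents_from_fit()` re-enters *all* fitted
parameters of the winning model into the learning rule, driven by the
observed choices, to produce the trial-wise values and prediction errors
consumed by the model-based analyses (and usable as fMRI-regressor
material).

## The synthetic cohorts

`simulate_cohort()` emulates a within-subject stimulation design: every
subject performs the task once per condition (default labels NAcc, dACC,
Sham), each session on a freshly built schedule with seeds spawned from one
master seed, with condition order counterbalanced by rotation and lost
trials injected i.i.d. (default rate 2%; participants' true lost-trial
rates are not characterised in the source material, and 2% is a
conservative guess). Condition effects are additive shifts on the
generating parameters, checked against the legal ranges before any
simulation.

The default generating agent is the symmetric-rate `rw2` with
$\alpha^{+} = \alpha^{-} = 0.2$, $\beta = 5$, values well inside the range
reported for human reversal-learning fits. The base was deliberately
calibrated so that the package's reference injected effect — a
$+0.15$ shift of $\alpha^{+}$ in one condition, emulating the direction in
which stimulation of reward circuitry has been reported to act — is
reliably detectable by the win–stay analysis at the reference cohort size
of 26 subjects, as the corresponding empirical effect was. The marginal
behavioural impact of an $\alpha^{+}$ shift shrinks as the base rate grows
(the win–stay probability saturates), so a generator parked at high base
rates would inject effects the analyses cannot see at realistic sample
sizes; that would test nothing.

What the generator does **not** emulate: subject-level parameter
heterogeneity (all subjects share the generating parameters, so
between-subject variance is pure trial noise and paired tests enjoy no
extra advantage), reaction times, session-order or fatigue effects, and any
actual stimulation physiology. Passing the statistical suites therefore
shows that the analyses are calibrated and sensitive under clean
conditions; it does not certify them for the messier covariance structure
of real cohorts.

## The behavioural analyses

**Win–stay regression.** For each consecutive within-block pair of
non-lost trials, `WinStay(t+1)` is +1 if the trial-$t$ choice was rewarded
and repeated, −1 if rewarded, shown again, and abandoned, and 0 otherwise —
including unrewarded trials and the one third of pairs where the rotation
removes the previous choice from the screen. OLS per
subject × condition × block on `Reward(t)`, `choiceStickiness(t)` (choice
repeats the previous choice; 0 on a block's first trial) and
`isHPScreen(t+1)` yields coefficients that are averaged over blocks and
submitted to a one-way condition ANOVA with all pairwise paired t-tests,
Bonferroni-corrected over the three pairs, plus the paired Cohen's D (mean
difference over the SD of the differences). The model-based variant
replaces `Reward(t)` with the fitted prediction error $\delta(t)$.
Block-wise paired contrasts between two conditions are deliberately
uncorrected: they chart the effect's time course under predefined
hypotheses.

**Learning curves.** Trials are aligned by position within a contingency
period; the high-probability-choice indicator (or, model-based, the
expected value of the high-probability symbol) is averaged across periods
and subjects and smoothed with a centred 5-trial running average, truncated
at the period edges — the truncation, not the averaging, is why the
apparent reversal point shifts slightly earlier than the true one. The
trial-level condition contrast uses a linear mixed model with a per-subject
random intercept (REML via `lme4`); fixed-effect p values use the normal
approximation on t, which is accurate at the trial-level sample sizes this
contrast is built for (residual dfs in the thousands).

**Maladaptive win–stay.** Win–stay is usually adaptive, but repeating a
rewarded *low*-probability choice when the high-probability symbol is
available is not. On trials where both shown symbols are low-probability
and the choice was rewarded, the analysis asks whether the same symbol is
chosen again at the next trial where it appears alongside the current
high-probability symbol (stay +1 / switch −1), tests per-subject rates
against zero within each condition, and compares conditions by ANOVA.

**Exploratory metrics.** Post-learning accuracy (high-probability choice
rate over the last 10 trials of each period), perseveration errors (rate of
choosing the immediately previous high-probability symbol, when shown, in
the first 5 trials after a reversal) and post-error adjustment (switch rate
after non-reward, among pairs where the previous choice is available). The
10- and 5-trial windows are package choices; the metrics are named but not
operationalised in the source literature. Short periods truncate the
window with a warning.

**Rank test.** `rank_test_groups()` wraps the two-sided Mann–Whitney U for
independent groups (e.g. a patient cohort against healthy controls): exact
enumeration when both groups have at most 8 observations, otherwise the
normal approximation with tie correction.

## Reproducibility, problem sizes and limitations

Every stochastic stage takes an explicit seed, and `run_pipeline()` spawns
per-stage and per-session seeds from one master seed, so identical
configurations reproduce every output bit for bit (the manifest records an
MD5 checksum per artefact). The test suite exercises the pipeline at the
sizes the properties are stated for: schedule calibration on at least
100,000 pre-drawn outcomes per probability class; parameter recovery on 50
asymmetric agents at 320 trials; model recovery on 20 cohort replicates of
26 subjects per generating model; ANOVA type-I calibration on 1000 null
cohorts and power on 20 injected-effect cohorts of 26 subjects. These
choices keep each property estimate's Monte-Carlo error well below the
margins being asserted.

Known limitations: no hierarchical (shrinkage) estimation — each session
is fitted independently, so single-session estimates of $\beta$ are noisy
at 320 trials; no eligibility traces, forgetting, or counterfactual
updating; the simulated likelihood is substantially more expensive than
the analytic one and is provided for procedural fidelity rather than
routine use; and the mixed-model p values rely on the normal approximation,
which should not be trusted for small subject counts.
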