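# prlearn

Behavioural modelling toolkit for **probabilistic reversal learning**, the
task family used to probe reward-guided learning in human neuromodulation
studies (transcranial ultrasound stimulation, deep brain stimulation) and in
lesion work on the ventral striatum.

In the task, each block introduces three novel symbols; one carries a 70%
reward probability and the other two 30%. Two symbols are shown per trial in
the fixed pair rotation AB → BC → CA (sides randomised), and after every 25
trials the high reward probability covertly moves to a different symbol, so
participants must keep re-learning the cue–reward contingencies. The default
session is four blocks of 100/100/60/60 trials — 320 trials and 12 symbols.

`prlearn` provides, end to end:

- a **task generator** (`task_config()`, `build_schedule()`) with pre-drawn
  per-symbol outcomes, so every run is reproducible from a seed;
- **Rescorla–Wagner agents** for simulation (`simulate_agent()`,
  `simulate_cohort()`), including multi-subject cohorts with injected
  condition effects emulating within-subject stimulation designs;
- **model fitting** (`rw_fit()`) by grid search plus Nelder–Mead simplex,
  with BIC model comparison (`compare_models()`);
- the **behavioural statistics** used around such models: win–stay
  regression and condition ANOVA, block-wise contrasts, smoothed learning
  curves, mixed-model contrasts on high-probability choice, maladaptive
  win–stay, exploratory performance metrics, and a Mann–Whitney rank test.

## The models

Each choice option A holds an expected value `V_A`, updated after feedback
by the delta rule

    V_A(t+1) = V_A(t) + α · δ(t),        δ(t) = r(t) − V_A(t)

with outcome `r ∈ {0, 1}` and learning rate `α`. Only the chosen symbol is
updated; unchosen and unshown symbols keep their values. Choices follow a
SoftMax (logistic) rule over the two shown symbols,

    P(A) = σ( β · (V_A − V_B) ),         σ(z) = 1 / (1 + e^(−z))

with inverse temperature `β` governing exploration versus exploitation.
Two variants are fitted: `rw1` with a single learning rate, and the
asymmetric `rw2` with separate rates `α⁺` (after reward) and `α⁻` (after
non-reward). `rw2` with `α⁺ = α⁻` reproduces `rw1` exactly.

Fitting maximises the log-likelihood of the observed choices under the
constraints `β > 0`, `0.1 < α < 0.9` — a coarse grid search first, then a
simplex refinement in a smoothly reparameterised (logit/log) space. A
simulation-based alternative likelihood (`likelihood = "simulated"`)
predicts each observed choice from 1000 forward simulations in which the
model's own choices drive the value updates. Models are compared by the sum
of per-session `BIC = −2 log L + d log n` (lower is better).

## Worked example

```r
library(prlearn)

sched  <- build_schedule(task_config(), seed = 1)
agent  <- agent_params("rw2", alpha_pos = 0.35, alpha_neg = 0.2, beta = 5)
trials <- simulate_agent(agent, sched, lost_rate = 0.02, seed = 2)

fit <- rw_fit(trials, model = "rw2")
fit
#> Rescorla-Wagner fit (rw2, observed likelihood)
#> alpha_pos alpha_neg      beta
#>    0.3596    0.1935    4.6110
#> logLik -167.3342 on 314 non-lost trials; BIC 351.9166; converged
```

The fitted learning rates and inverse temperature sit close to the
generating values (0.35, 0.2, 5); 6 of the 320 trials were lost to the
response deadline and are excluded from the likelihood. On this single
session the simpler `rw1` wins the complexity trade-off (BIC 348.91 vs
351.92) — with one session and similar rates, the extra rate is not worth
`log n`; across a cohort generated with distinct `α⁺`/`α⁻` the summed BIC
favours `rw2` (see the model-recovery tests).

A synthetic 26-subject cohort with a reward-learning-rate shift of +0.15 in
the "NAcc" condition, run through the win–stay analysis:

```r
cohort <- simulate_cohort(
  cohort_spec(condition_effects = list(NAcc = c(alpha_pos = 0.15))),
  seed = 3)
betas <- winstay_regression(code_winstay(cohort))
condition_anova(betas)
#> One-way condition ANOVA on `beta_reward` (n = 26 subjects)
#>   F(2,75) = 9.936, p = 0.0001487
#> Paired post-hoc t-tests (Bonferroni corrected):
#>          pair t_stat df    p_raw p_bonferroni cohens_d
#>  NAcc vs dACC  4.259 25 0.000254    0.0007619   0.8353
#>  NAcc vs Sham  2.919 25 0.007333    0.0220002   0.5724
#>  dACC vs Sham -1.246 25 0.224280    0.6728408  -0.2444
```

The injected effect surfaces as a stronger reward → win-stay relationship
in the shifted condition, with the two control conditions indistinguishable
— the signature the analysis is designed to detect.

`run_pipeline(run_config(...))` chains simulate → fit → analyse → report and
writes all tables, a report and a checksummed manifest under an output
directory; `read_run_config()` loads the same configuration from YAML.

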