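# twostepr

Simulation, hierarchical model fitting and group-level analyses for the
two-step sequential decision task, built for studies that relate the
balance of model-free versus model-based control to individual-difference
measures — here, blatant and subtle prejudice questionnaire scores.

## Who this is for

Researchers in computational psychiatry and cognitive modeling who want a
tested, end-to-end pipeline for the classic two-step paradigm: simulate
task behavior from a generative agent, fit the agent hierarchically to
trial-level choice data, score the questionnaire, and run the standard
inferential analyses — all validated on synthetic cohorts where the ground
truth is known.

## The model

Each trial has two stages. A stage-1 choice `a` leads to its "common"
second-stage state with probability 0.7 (rare otherwise); a stage-2 choice
is rewarded according to slowly drifting probabilities (reflecting Gaussian
random walks in \[0.25, 0.75\], step SD 0.025, over 201 trials). The
seven-parameter hybrid agent mixes two controllers:

- model-free SARSA(λ):
  `δ1 = Q2(s2, c2) − Q1(s1, c1)`, `Q1 += α1 δ1`;
  `δ2 = r − Q2(s2, c2)`, `Q2 += α2 δ2`, `Q1 += α1 λ δ2`
- model-based planning:
  `Q_MB(a) = 0.7 · max_b Q2(common(a), b) + 0.3 · max_b Q2(other, b)`
- mixture and choice:
  `Q_net = ω Q_MB + (1 − ω) Q_MF`, softmax with inverse temperature β1 and
  a perseveration bonus ρ for repeating the previous stage-1 choice; plain
  softmax with β2 at stage 2.

ω is the quantity of interest: 0 = purely model-free (habitual),
1 = purely model-based (deliberative). Fitting is per-subject MAP in an
unconstrained space (sigmoid/exp/identity transforms) under a group-level
Gaussian prior re-estimated by empirical-Bayes EM with Laplace
approximation; models are compared by integrated BIC.

The questionnaire module scores the 20-item blatant/subtle prejudice scale
(4-level Likert responses rescaled 1/2/4/5; two 10-item scales, sums in
10–50). The analysis module implements the three inferential analyses:

1. stay/switch mixed-effects logistic regression
   (`stay ~ transition × outcome × log prejudice + covariates`, random
   within-subject intercept, main effects and interaction),
2. second-stage RT linear mixed model (250 ms exclusion, raw ms),
3. regressions of z-scaled RL parameters (α1, α2, ω, λ) on log prejudice,
   Bonferroni α = 0.0125,

plus VIF/outlier diagnostics and semipartial R²β effect sizes.

## Worked example

Generate a 30-subject synthetic cohort with the planted negative
ω–prejudice coupling, fit the hybrid model, and run the three analyses:

```r
library(twostepr)
gen    <- generate_cohort(cohort_spec(n_subjects = 30, seed = 42))
scores <- score_items_table(gen$items)
set.seed(7)
fit  <- em_fit(gen$cohort, settings = fit_settings(n_starts = 2, em_max_iter = 30))
stay <- fit_stay_glmm(build_stay_table(gen$cohort, scores, "blatant"), nAGQ = 0)
rt   <- fit_rt_model(build_rt_table(gen$cohort, scores, "blatant"))
preg <- fit_param_regressions(fits_to_df(fit), scores, gen$covariates, "blatant")
rep  <- recovery_report(gen$truth, fit, list(stay = stay, rt = rt, param = preg))
print(rep$param_recovery, digits = 2)
print(rep$effects, digits = 3)
```

Output (as printed by the code above):

```
<model_fit_result> hybrid - 30 subjects, 18 EM iterations
   param pearson spearman
1 alpha1    0.50     0.47
2 alpha2    0.93     0.93
3  beta1    0.51     0.38
4  beta2    0.92     0.84
5    lam    0.64     0.64
6      w    0.70     0.72
7    rho    0.94     0.97
      analysis                                       term estimate        p
1    stay_glmm prev_transition:prev_outcome:prejudice_log   -0.703 1.19e-01
2     rt_model                   transition:prejudice_log  137.098 1.34e-08
3 w_regression                              prejudice_log   -1.614 1.73e-03
signs agree with planted coupling: TRUE
```

Reading the numbers: parameter recovery correlations show ω is recovered
at r = 0.70 even at n = 30; all three analyses return the planted
direction — a negative three-way stay interaction (higher prejudice, less
model-based choice signature), a positive transition × prejudice RT
interaction (higher prejudice, less rare-trial slowing), and a negative ω
regression slope. At this reduced n only the latter two reach
significance; the full 127-subject pipeline is exercised by the test
suite.

One command reproduces the whole synthetic study (simulate → score → fit →
analyze → recover) with a hashed artifact manifest:

```r
run_all("out", cohort_spec(seed = 1))
```

## Vignette

`vignettes/two-step-methods.Rmd` documents the model and its assumptions,
the fitting machinery and its numerical choices, what the synthetic cohort
does and does not emulate, and known limitations.
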