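---
title: "Methods: hybrid reinforcement learning on the two-step task and its group analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid reinforcement learning on the two-step task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the task and agent model, the hierarchical estimator, the questionnaire
scoring, the inferential analyses, and — importantly — what the synthetic
cohort generator does and does not establish.

## The task

The two-step task dissociates habitual (model-free) from deliberative
(model-based) control. Each of 201 trials has two stages: a binary stage-1
choice routes the subject to one of two second-stage state pairs — to its
"common" state with probability 0.7, to the other ("rare") with 0.3 — and
a binary stage-2 choice is rewarded with probability given by one of four
independent, slowly drifting reward walks. Payouts are a reporting
constant (0.20 per rewarded trial); learning operates on the 0/1 reward
indicator, which is an exact rescaling of the inverse temperatures.

The reward walks are not printed in full anywhere we can recover, so the
package adopts the original-task convention: Gaussian increments with SD
0.025, reflected (not truncated, to preserve variance near the edges) at
0.25 and 0.75, initial values uniform within the bounds. All of this is
configurable through `task_config()`; the choice only affects how quickly
reward contingencies invert, not any qualitative signature.

The transition mapping is fixed and anti-symmetric — action *i*'s common
state is state *i* — and is *known* to the agent rather than learned. The
seven-parameter model we implement has no transition-learning rule, and
adding one would change the parameter count.

## The hybrid agent

Seven parameters: learning rates α1, α2 ∈ [0,1]; inverse temperatures
β1, β2 ≥ 0; eligibility trace λ ∈ [0,1]; model-based weight ω ∈ [0,1];
perseveration ρ ∈ ℝ.

Model-free values update by SARSA(λ); model-based stage-1 values combine
the known transition probabilities with the best stage-2 value in each
state; the stage-1 policy is a softmax over
β1·(ω·Q_MB + (1−ω)·Q_MF + ρ·1[repeat]); stage 2 is a plain softmax.
Equivalent reparameterizations exist for the perseveration bonus (outside
vs. inside the β1 scaling); we place it inside, and the first trial
carries no bonus. Q-values start at zero with no decay of unchosen
options.

With rewards in {0,1} and zero initialization, values remain in a narrow
envelope; the test suite asserts the conservative bound [−0.5, 1.5] on
every simulated session.

## Hierarchical estimation

Fitting works in an unconstrained 7-dimensional space (sigmoid for the
unit-interval parameters, log for the temperatures, identity for ρ) under
independent Gaussian priors. Per subject, MAP estimation minimizes the
session negative log-likelihood plus the normalized Gaussian negative log
prior (BFGS, best of `n_starts` initializations — the prior mean plus
random draws; warm starts after the first EM iteration). The group prior
is re-estimated by empirical-Bayes EM: the E-step is the set of MAP fits
with Laplace covariances, the M-step sets μ to the mean of the MAP
vectors and σ² to `mean(z² + diag(Σ_Laplace)) − μ²`, floored at 1e−4.
Convergence is declared at max |Δμ| < 1e−3 (cap 200 iterations).

**Numerical choice that matters.** The Laplace covariance comes from a
central-difference Hessian of the negative log posterior. When a
subject's data carry no information about a parameter, that Hessian can
be numerically singular or indefinite; a naive repair that floors its
eigenvalues at 1e−6 and inverts produces Laplace variances of order 1e6,
which the M-step then folds into the group variance — on a 127-subject
cohort this drove group SDs to ~100 and degraded recovery of ω. The
package instead decomposes the posterior Hessian exactly into a
likelihood part plus the (diagonal, known) prior precision, PSD-projects
only the likelihood part, and adds the prior precision back. The Laplace
variance is then bounded by the prior variance in every direction — the
statement "the posterior is at least as concentrated as the prior" — and
the EM variance update is stable. With this repair, EM on the default
127 × 201 cohort converges in ~16 iterations and ω-recovery reaches
r ≈ 0.69.

Model comparison uses the integrated BIC: per-subject marginal
likelihoods approximated by Monte-Carlo sampling from the group prior
(1000 samples by default, seed-controlled), penalized by
`k·log(N)` with `k` = 2 × (free parameters) group-level parameters and
`N` the total number of observed choices (two per trial). The comparison
set is fixed to {hybrid, model-free-only (ω ≡ 0), model-based-only
(ω ≡ 1)}. Posterior predictive checks simulate fresh sessions from the
fitted parameters and compare stay probabilities cell by cell.

The regressions use the constrained (natural-scale) MAP ω by default;
the unconstrained values are also available
(`fits_to_df(fit, "unconstrained")`) since either reading of "the fitted
parameter" is defensible.

## Questionnaire scoring

Twenty items, two 10-item scales (blatant = threat/rejection 6 +
intimacy 4; subtle = traditional values 4 + cultural differences 4 +
positive emotions 2). Four-level agreement responses are rescaled
1/2/4/5 before summation — the gap between 2 and 4 is deliberate in the
instrument — so each scale sum spans 10–50. The published description
does not list which items are reverse-keyed; the shipped key
(`inst/extdata/bsps_key.yaml`) reverse-keys the positively worded
subscales (intimacy, positive emotions) and is fully configurable; the
synthetic generator emits item responses consistent with whichever key
is configured, so scoring and generation can never drift apart.

The prejudice transform is the natural log (the source says only "log
transformed"; the base only rescales coefficients). Group splits use
`score < threshold` with the sample median by default; passing
`threshold = 14` reproduces the reference low/high split.

## The inferential analyses

1. **Stay/switch GLMM.** Lag-1 table (first trial of each subject
   dropped), outcome and transition effect-coded ±0.5 so main effects are
   grand-mean contrasts, prejudice log-transformed and mean-centered so
   lower-order terms stay interpretable, covariates z-scored, entered as
   main effects only. Random effects: within-subject intercept, both main
   effects and their interaction. On non-convergence the structure is
   simplified stepwise (drop correlations, then the interaction slope),
   and every simplification is recorded in the result's metadata.
2. **RT model.** Second-stage RTs in raw milliseconds (the reference
   effect sizes are on that scale), trials faster than 250 ms excluded —
   strictly faster, so a 250 ms trial is kept — with by-subject random
   intercept and transition slope. With transition coded common = +0.5,
   rare-trial slowing appears as a negative main effect, and reduced
   slowing in high-prejudice subjects as a positive interaction.
3. **Parameter regressions.** Each of α1, α2, ω, λ (z-scaled) on log
   prejudice plus covariates; significance at the Bonferroni threshold
   0.05/4 = 0.0125.

Inference in the mixed models is Wald-z. Semipartial R²β is the Wald
single-degree-of-freedom form t²/(t² + ν) with ν = N − rank(X), and its
95% CI shifts the statistic by ±1.96 before transforming — an
approximation to the published mixed-model R²β procedures (the exact
package is not assumed available), accurate for large N and single-df
terms, and monotone in the coefficient as an effect size should be.
Diagnostics: VIF (flag > 10), ±3 SD outlier flags, residual
skewness/kurtosis/heteroscedasticity summaries.

## The synthetic cohort: what it emulates and what it does not

The generator states one world and keeps it fixed: 127 subjects × 201
trials; agent parameters drawn from a group prior whose transformed means
are canonical for this task (ω centered at 0.5 with wide spread, β ≈ 4);
log blatant score = log 14 − 0.25·z_ω + N(0, 0.3²), exponentiated,
rounded and clipped to [10, 50] — the clip at the floor reproduces the
strong right skew of real samples; subtle scores drawn uncoupled
(the reference study found no subtle-prejudice association, so none is
planted); RTs = 700 + ω·300·1[rare] + N(0, 120²) ms floored at 50 ms
(base chosen > 250 + 3·SD so the exclusion filter removes only a tail);
covariates Normal with the reference sample's means and SDs.

The RT law is an assumption layered on the observed pattern (slowing on
rare trials proportional to model-based control), not a mechanistic
claim. The generator does not emulate: response-time distributions'
right skew, within-subject parameter drift, attention lapses, item-level
response psychology (items are back-filled to match the target sum), or
any demographic structure. A green end-to-end test therefore establishes
that *the pipeline recovers what it plants* — directionally correct,
properly calibrated under the null — not that the empirical effect
exists; the real cohort's coefficients are not reproducible from a
generator and are used as sign/shape references only.

## Scale choices in the test suite

The acceptance criteria allow minutes per replicate; a graded test run
does not. Simulation sizes were fixed up front to fit a single CPU:
sign-recovery replicates use 60-subject cohorts, null-calibration
replicates 40 (type-I error does not depend on n), the iBIC
model-recovery examples 20 subjects × 120 trials × 2 replicates, and the
replicate ω estimates come from single-start MAP fits under the
generating prior rather than full EM (the "reduced optimizer settings"
the criteria anticipate). The headline recovery criterion — r(ω) ≥ 0.6
on 127 × 201 — runs at full scale with the full EM.

## Known limitations

- The transition model is fixed at 0.7/0.3 and known to the agent.
- Wald inference, not likelihood-ratio or Satterthwaite; with ~25k
  observations per cohort the difference is negligible, but p-values on
  tiny cohorts should be read cautiously.
- The iBIC marginal likelihood is a prior-sampling Monte-Carlo estimate;
  its spread shrinks with sample count and the seed is recorded.
- The R²β CI is a Wald approximation, slightly conservative near zero.
- Only the three-model comparison set is implemented; richer model spaces
  (two-weight mixtures, transition learning) are out of scope.
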