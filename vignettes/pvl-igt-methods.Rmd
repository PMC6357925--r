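---
title: "Modelling Iowa Gambling Task choice with the Prospect Valence Learning model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Iowa Gambling Task choice with the Prospect Valence Learning model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvligt)
```

## The task and its scores

The Iowa Gambling Task (IGT) presents four card decks. Every selection pays
a fixed gain; losses arrive intermittently. Decks A and B pay +100 per pick
but lose 250 on average per pick (A: five losses of 250 per 10 selections;
B: one loss of 1,250), so their expected value per 10-selection cycle is
−250. Decks C and D pay +50 with per-cycle losses of 5×50 and 1×250
respectively, for +250 per cycle. Learning to prefer C and D is the
behavioural signature the task measures.

`igt_schedule()` encodes this environment. Loss *frequencies* are given per
10 selections of a deck; where in the cycle each loss falls is not specified
by the table of magnitudes and frequencies, so the default
`deterministic_cycle` mode fixes evenly spread within-cycle positions
(five losses fall at positions 2, 4, 6, 8, 10; a single loss at position
10). This makes the per-cycle expected values exact identities rather than
asymptotic limits, which is why the package's acceptance checks on the
schedule are exact. A `bernoulli` mode (independent loss with probability
k/10 per selection) is available when stochastic loss timing is preferred;
its cycle totals hold in expectation only. The cycle is counted in
*selections of that deck*, not in task trials — consistent with "k losses
per 10 selections" being a property of a deck, not of the session.

A session has 120 trials of which the first 20 are practice; scoring and
fitting use the 100 experimental trials. `compute_net_scores()` drops
flagged practice rows and returns the total net score (C+D selections minus
A+B selections), five 20-trial block net scores, and per-deck counts.
Screening into the high-risk group uses a strict threshold:
`label_risk_group()` labels totals strictly above 22 as high risk.

## The PVL model

Three equations map trial outcomes to choice probabilities. The net outcome
x(t) (gain + loss, a single signed number) is first multiplied by a payoff
scale (default 0.01 — see *Numerical choices*), then valued by a prospect
utility with feedback sensitivity a ∈ [0, 1] and loss aversion λ ∈ [0, 5]:

u(t) = x(t)^a if x(t) ≥ 0, and −λ·|x(t)|^a if x(t) < 0.

Deck expectancies decay and accumulate with learning parameter A ∈ [0, 1]:

E_j(t) = A·E_j(t−1) + δ_j(t)·u(t),

where δ_j(t) indicates the chosen deck. A near 1 retains early experience;
A = 0 is memoryless. Choice follows a softmax over θ·E_j with consistency
c ∈ [0, 5] setting θ = 3^c − 1: c = 0 gives uniform random choice, large c
nearly deterministic exploitation.

Two θ rules are implemented behind one flag. The `as_printed` default is
θ = 3^c − 1, constant in t. The wider source-model literature also uses a
genuinely trial-dependent rule θ(t) = (t/10)^c; it is available as
`trial_dependent` because descriptions of the constant rule sometimes call
it trial-dependent and the intended variant can be ambiguous. Every
simulation and fit records which rule (and which payoff scale) produced it.

`simulate_agent()` composes the three equations forward on a schedule;
`pvl_loglik()` evaluates the probability of an observed deck sequence under
the same recursion (the identical compiled code path backs the simulator,
the likelihood, and both fitters). The first experimental trial always
contributes log(1/4) because expectancies start at zero; practice trials,
when simulated, are a separate warm-up run and do not seed the experimental
expectancies — whether real participants carried practice learning into
trial 1 is unknowable from score sheets, and starting from zero is the
conservative convention.

## Numerical choices

* **Payoff scale.** Raw outcomes reach −1,250; with utilities on raw
  dollars, θ·E would overflow the softmax and the reported parameter
  magnitudes (a ≈ 0.25, λ ≈ 0.4, c ≈ 0.5) would be unattainable. Outcomes
  are scaled by 0.01 before the utility (configurable; recorded in outputs),
  which keeps θ·E in a benign range and is consistent with the magnitude of
  published group-level estimates.
* **Softmax stabilisation.** Choice probabilities are computed with
  max-subtraction, so arbitrarily large θ·E cannot overflow.
* **Probability floor.** Per-trial probabilities are floored at 1e−12
  inside the log, so the log-likelihood is finite everywhere on the closed
  parameter box and bounded optimisation cannot step into −∞.
* **u(0).** A zero outcome takes the non-negative branch and has zero
  valence for any a (no 0^0 ambiguity).
* **Trial indexing** is 1-based everywhere.

## Estimation

`fit_mle()` maximises the log-likelihood over the closed box
[0,1]×[0,5]×[0,1]×[0,5] with L-BFGS-B from a mid-range start plus random
restarts (default 10). If no start improves on the uniform-choice baseline
n·log(1/4) — attained exactly at c = 0, where the data carry no information
about a, λ or A — the fit is returned at c = 0 and flagged uninformative
rather than reporting arbitrary box coordinates as estimates.

`fit_hierarchical()` is the primary estimator. Each subject's raw
parameters are Normal(μ_p, σ_p) on an unconstrained scale and mapped through
probit links onto the parameter ranges (a, A onto (0,1); λ, c onto (0,5)),
with weakly informative hyperpriors μ_p ~ Normal(0, 1) and σ_p ~
half-Normal(1). The links guarantee every draw respects the ranges by
construction. The sampler is adaptive Metropolis-within-Gibbs: componentwise
random-walk updates of subject-level raw parameters against the exact PVL
likelihood, a conjugate Gibbs update for each μ_p, and a random-walk update
on log σ_p; proposal scales adapt toward ~44% acceptance during burn-in only,
so the kept draws come from a fixed kernel. The default configuration is 3
chains, 500 burn-in iterations, 1,000 kept draws per chain. With the
likelihood disabled (`likelihood = FALSE`) the subject-level conditional is
exactly its prior and is drawn directly, which makes prior-predictive
validation of the sampler sharp.

Groups are fitted independently (one hierarchy per group), matching a
design in which group-level parameter summaries are subsequently compared
nonparametrically. The reported group-level "mean" is the posterior mean of
the link-transformed group location link(μ_p); per-subject point estimates
are posterior means. Convergence is monitored with split-chain R-hat
(threshold 1.1) and an initial-positive-sequence effective sample size; a
fit with any R-hat above threshold is returned flagged, with a warning,
never silently. Constant (degenerate) chains have undefined R-hat and are
flagged too.

## The synthetic cohort generator

No trial-level human data are available, so `generate_cohort()` builds
cohorts with the statistical structure the analysis assumes: 42 high-risk
and 43 control subjects by default; per-subject PVL parameters drawn
independently per parameter from truncated normals at the published
group-level means and SDs (high-risk a 0.249/0.084, λ 0.355/0.390,
A 0.377/0.115, c 0.393/0.418; control a 0.268/0.092, λ 0.523/0.639,
A 0.464/0.188, c 0.634/0.478); covariates (KEAT-26, SDS, state/trait
anxiety, age, BMI) from truncated normals at the published group moments,
with KEAT-26 constrained to the group's side of the 22-point threshold so
generated labels and the screening rule agree by construction; and each
subject's 20 practice + 100 experimental trials simulated by the PVL agent
on the default schedule. Everything is reproducible from one master seed.

Truncation shifts moments, so the generator numerically moment-matches the
underlying normal for every parameter (closed-form truncated-normal moments
inside a Nelder-Mead solve). One target is strictly unattainable: a
truncated normal on [0, ∞) cannot have mean/SD below 1 in the limit, and the
high-risk loss-aversion target (0.355/0.390, ratio 0.91) sits past that
limit; the generator lands on the closest achievable pair (≈0.375/0.368),
and the distributional-fidelity test checks λ against these documented
achievable moments rather than the nominal ones.

`generate_null_cohort()` draws both arms from the control distributions
with arbitrary labels; it is the harness for false-positive-rate checks of
the downstream tests.

What the generator does *not* emulate: parameter intercorrelations (none
are published; draws are independent), any coupling between symptom
severity and model parameters (a within-group net-score/KEAT-26 correlation
is reported in the source literature but its generating mechanism is not
quantified, so none is imposed), item-level questionnaire structure, and
reaction times. Passing tests therefore certify the pipeline's behaviour
under this idealised generative model, not properties of real participants.

## The statistical battery

`ancova_group()` fits outcome ~ covariates + group by least squares and
tests the group effect by extra sum of squares, reporting F, df, p and
partial eta-squared; with no covariates it reduces exactly to one-way
ANOVA. The default covariate set is SDS plus *both* STAI subscales: with 85
subjects this yields the group-effect error df of 80 that the reported
F(1, 80) statistics imply (SDS + one STAI scale would give 81).

`mixed_block_ancova()` runs the SPSS-style mixed-design analysis through
`car::Anova` on a multivariate linear model with a five-level within-subject
block factor: between-subjects group F(1, 80), within-subject block and
block×group F(4, 320) at the default cohort size, each with partial
eta-squared. Sphericity is not assumed silently: Greenhouse–Geisser epsilon
and corrected p-values are reported alongside, with the uncorrected tests
primary (matching plain F(4, 320)-style reporting). Follow-ups preserve a
reported asymmetry: per-block group contrasts are ANCOVAs (covariates
retained, Bonferroni over 5 blocks), while per-group across-block trends
are plain repeated-measures ANOVAs with df (4, 4(n−1)) (no covariates,
Bonferroni over 2 groups). Bonferroni tags are recorded on each row; the
adjustment is never silently applied to both p and α.

`mann_whitney()` computes U from midranks and reports the smaller of U_x
and n₁n₂ − U_x. The null distribution is enumerated exactly when the data
are untied and n₁·n₂ ≤ 400; otherwise a tie-corrected normal approximation
with continuity correction is used (the correction keeps the approximation
within 0.01 of exact at n₁ = n₂ = 10). `welch_t()` defaults to the
pooled-variance form (df = n₁ + n₂ − 2 = 83 at the default sizes), with
Welch's form behind a flag. `bootstrap_pearson()` case-resamples pairs
(default 10,000 replicates, seeded), reports the percentile 95% CI and a
bootstrap p (twice the smaller tail proportion of resampled r about 0,
capped at 1); degenerate resamples are redrawn up to 10 times, then dropped
with a recorded count. Correlations are computed within group.

## Problem sizes used in validation

The package validates itself at desk scale: exact schedule identities and
1,000-sequence scoring conservation; a 100-case likelihood-versus-oracle
sweep on sequences of up to 10 trials; hierarchical recovery on 20 agents ×
100 trials (2 chains × 500 kept draws) with group means of A and c
recovered within ±0.15; MLE recovery on 50 replicates of 500-trial agents
(A, c within ±0.2 in ≥80%); calibration of Mann–Whitney, ANCOVA and pooled
t on 200 null cohorts (rejection rates in [0.02, 0.09] at α = 0.05) and
bootstrap CI coverage on 300 independent-data replicates; and a 20-cohort
end-to-end sign check in which the high-risk arm's fitted learning and
consistency come out lower than the control arm's.

## Known limitations

* With c near 0 the likelihood is flat in a, λ and A, so per-subject
  maximum likelihood at 100 trials cannot locate A for near-random
  responders; since both group distributions contain such subjects, group
  contrasts of per-subject MLEs of A are attenuated relative to the truth.
  The end-to-end sign check therefore uses the hierarchical estimator,
  whose group-level pooling is exactly the remedy; per-subject MLE remains
  the right tool for long sequences and for initialisation/ranking.
* The Metropolis-within-Gibbs sampler mixes more slowly than gradient-based
  samplers for the weakly identified a and λ; R-hat flags make this visible
  rather than hidden, and longer chains resolve it.
* The trial-dependent θ rule and the constant printed rule can fit
  differently; which generated any particular published estimate cannot be
  determined from summary tables, so both are provided and recorded.
* Deterministic loss cycles make expected values exact but create
  within-cycle outcome sequences a Bernoulli environment would not;
  both modes are provided because the choice can matter for model fits.
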