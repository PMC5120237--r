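---
title: "Methods: rating-driven message tailoring, its evaluation, and the trial simulator"
author: "perspectr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rating-driven message tailoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perspectr)
```

This vignette documents the models and procedures implemented in
`perspectr`, the assumptions behind them, the defaults and why they were
chosen, and what the synthetic-data experiments in the test suite do and do
not demonstrate.

## The tailoring problem

A computer-tailored health communication (CTHC) system holds a library of
motivational messages — here modelled on a smoking-cessation library of 261
messages, written by experts and by peers, each coded for the
readiness-to-quit stages it suits and for open-vocabulary content tags
(about 40% motivational content, 53% behavioural-treatment information).
Each day one unseen message is emailed to each participant, who rates on a
five-point Likert scale how strongly the message influences them to quit.
The rule-based standard approach picks any stage-matched message; the
recommender approach ranks the stage-matched candidates by a predicted
rating learned from all prior participants' ratings plus the participant's
own ratings so far, and sends the best.

## The rating model

The deployed predictor is Bayesian probabilistic matrix factorization: with
ratings centred by the training mean $\mu$ (the global offset),

$$r_{um}-\mu \sim N(u^\top v_m,\ \alpha^{-1}), \qquad
u \sim N(\mu_U, \Lambda_U^{-1}), \quad v \sim N(\mu_V, \Lambda_V^{-1}),$$

with conjugate Normal–Wishart hyperpriors
$(\mu_\bullet,\Lambda_\bullet)\sim \mathrm{NW}(\mu_0,\beta_0,W_0,\nu_0)$ on
each side. Inference is blocked Gibbs sampling: hyperparameter draws, then
conditional Gaussian draws of every user factor given the item factors, then
the symmetric item update. Defaults are $D=10$, $\alpha=2$, $\mu_0=0$,
$\beta_0=2$, $W_0=I$, $\nu_0=D$, 50 burn-in sweeps and 200 retained samples
— the standard settings for this model family, all overridable. Ratings are
treated as real-valued (the analyses that consume them average them);
ordinal likelihoods are deliberately out of scope. Predictions are the
posterior-mean inner product plus offset, clipped to $[1,5]$; clipping and
deterministic tie-breaking (lowest message id) are implementation decisions
because a ranking consumer needs a total order.

Mean-centring before factorization keeps the global level out of the
factors, so that the mean baselines are a fair floor: a factor model that
merely rediscovered the grand mean would otherwise look better than it is.

**Cold start.** A user absent from training is handled in the
strong-generalization spirit: all non-user parameters stay frozen, and for
each posterior sample $s$ the new user's factor is the exact conditional
posterior mean
$\hat u_s = (\Lambda_U^{(s)} + \alpha V_o^{(s)\top}V_o^{(s)})^{-1}
(\Lambda_U^{(s)}\mu_U^{(s)} + \alpha V_o^{(s)\top} y)$ — a ridge regression
whose prior precision is that sample's population precision. With no
observed ratings the factor falls back to zero so the prediction is exactly
the global offset; the sampled population mean would equal that only in
expectation, and a deterministic fallback makes the empty-profile behaviour
testable.

**Comparators.** MAP probabilistic matrix factorization is fitted by exact
alternating ridge least squares (deterministic and tolerance-controlled:
relative objective change below $10^{-6}$, at most 500 alternations; the
objective is monotone non-increasing by construction), rather than
stochastic gradient. User-based K-NN uses Pearson similarity over co-rated
messages with a minimum overlap (default 3), mean-centred weighted
averaging over the $K$ most similar raters, ties among equally similar
neighbours broken by lower user index, and a fallback chain (message mean,
then global mean) so it is total. Mean baselines (global/message/user) are
the reference floor.

## Evaluation protocol

Algorithm selection uses strong generalization: test users are entirely
absent from training. Users are split into 5 folds (sizes differing by at
most one; 846 users give 170/169/169/169/169). Per test fold, 3 repeats
refit with repeat-specific seeds; a held-out 20% of train users per repeat
stands ready as a validation set for hyperparameter selection, since the
original validation sizes are not part of the protocol definition. Each
test user's ratings are split into 5 folds of exactly 4 test ratings;
observed budgets of 5, 10 and 16 ratings are drawn (nested) from the
remainder, so the 16-budget is exactly the complement of the test fold and
observed and test sets never intersect.

Metrics per cell (algorithm × fold × repeat × budget): pooled RMSE over all
scored ratings; Kendall tau-b and NDCG computed per 4-item test list and
averaged, dropping lists on which they are undefined. Conventions chosen
where several exist: tau-b with full tie correction, returning NA when a
vector is entirely tied; NDCG with exponential gain $(2^{rel}-1)$ and
$\log_2(\mathrm{rank}+1)$ discount, depth = full test list, and pessimistic
tie handling (tied predicted scores are ordered worst-relevance-first), so
reported NDCG never benefits from ties. Paired two-sided t tests compare a
reference algorithm against each competitor over matched cells with
Bonferroni adjustment by the number of competitors; zero-variance
differences are reported as undefined rather than as an arbitrary
statistic, except for exactly identical vectors (t = 0, p = 1). Grid search
is exhaustive with boundary extension: if a selected value sits at the end
of its range, the range grows one step in that direction and the search
repeats (capped, with a recorded warning), so selected hyperparameters are
interior points whenever the cap allows.

## The synthetic world

The generator produces the data structure every other module assumes, with
known ground truth returned alongside:

* **Library**: ids, synthetic text, expert/peer source (50/50), stages coded
  independently per ladder level with probability 0.4 (empty sets repaired
  to a random single stage), and tag counts that hit `round(p × n)` exactly
  (102/261 and 139/261 at the defaults).
* **Ratings**: user and item factors with i.i.d. $N(0, 0.8^2)$ entries in
  $D=2$ dimensions; continuous score = inner product + offset (default 3) +
  $N(0, 0.5^2)$ noise; ordinal rating = score rounded and clipped to 1..5.
  Each user rates a uniform sample of distinct messages (846 users × 20
  ratings by default, the pilot shape). Round-and-clip was chosen over a
  threshold model because it is simple, monotone, and the downstream
  analyses treat ratings numerically. The scale 0.8 spreads ratings over
  the full scale with modest boundary clipping; the latent dimension 2 is
  the smallest that makes ranking nontrivial.
* **Cohort**: block randomization in blocks of 7 intervention : 3 comparison
  (the realized 74:46 split of the motivating trial is not exactly
  reproducible by any fixed composition of 10 at a 2:1 target, so the
  composition is a parameter, not a constant); baseline stages from a
  configurable five-level distribution (default 0.15/0.45/0.20/0.10/0.10,
  a cohort mostly thinking about quitting); independent marginal
  demographics; and a latent preference vector per participant.
* **Follow-up**: completion is Bernoulli (default 0.79); one-day-quit and
  ladder-up indicators are Bernoulli with comparison-arm base rates 0.32 and
  0.30 and a log-odds shift `armEffect` in the intervention arm; influence
  responses are rounded Gaussians with a half-`armEffect` latent shift.
  Setting `armEffect = 0` therefore gives an exact null for the follow-up
  contingency tests even while the recommender still improves ratings.

The single `armEffect` knob doubles as an additive shift of intervention
participants' continuous rating scores; the pipeline's demonstration world
raises the global offset to 3.9 so that daily means hover around the
agreement threshold of 4, which is what makes the days-agreed proportion an
informative outcome (as it was in the motivating trial, whose daily means
sat near 4).

What the generator does **not** emulate: real rating distributions are
skewed and user-specific in variance; real message effects drift over time;
attrition correlates with dissatisfaction; demographics correlate with
preferences. Passing tests on this world show the machinery is correct and
the policies behave as designed, not that the effect sizes transfer to real
cohorts.

### The ordinal noise floor

One consequence of round-and-clip deserves emphasis because it bounds every
recovery experiment in the test suite. Even a predictor that knows the true
continuous score $m$ cannot predict `round(clip(m + ε))` better than its
conditional mean: rounding alone contributes roughly $1/12$ of additional
error variance on top of the Gaussian noise. With noise SD 0.5 the floor is
about $\sqrt{0.25 + 1/12} \approx 0.577$ before any estimation error, and
cold-start inference from 5–16 observed ratings adds posterior variance on
top (a true-factor oracle on the benchmark sits at RMSE 0.60–0.69 across
budgets). The BPMF benchmark in the acceptance suite lands at ≈ 0.66 —
close to that oracle and far below the global-mean baseline (≈ 0.97) — so
the informative comparison is against the baseline and the oracle, not
against the Gaussian noise SD itself.

## The scheduler

Both arms draw from the same library and the same stage filter; they differ
only in how a candidate is chosen, mirroring the design intent of isolating
the selection mechanism. The recommender policy ranks candidates by
predicted rating and re-infers the user's factor from all of their ratings
after every new rating — full re-inference is exact and cheap at $D \le 10$
and 30 ratings, so no incremental approximation is used. The rule-based
comparator draws uniformly (seeded, without replacement) among stage-matched
unsent messages; how the original rule-based system ordered equally eligible
messages is not part of the record, so a neutral reproducible draw is the
central comparator assumption. Its stream depends only on its seed and the
day, never on ratings. When the stage-matched candidates are exhausted the
filter relaxes outward over adjacent ladder levels before admitting all
unsent messages; "day" is the message ordinal, not calendar time. The
recommender updates only the active user's parameters during a trial — the
pilot model is not refit with accumulating trial ratings.

## Trial analysis

The primary outcome summary is the per-arm daily rating (mean over the
arm's ratings at each message ordinal) and the days-agreed count (days with
daily mean ≥ 4, the agree/strongly-agree threshold). All dichotomized
comparisons use the Pearson chi-square on 2×2 tables with df = 1 and **no
continuity correction** — this is the variant that reproduces, to two
decimals, the five published p-values of the motivating trial from its
printed count tables (.02 days agreed, .07 quit-smoking influence, .09
nicotine-replacement influence, .70 one-day quit, .60 ladder movement);
Yates-corrected values do not. Three further published influence rows
(.35/.96/.42) are not reproduced by any 2×2 Pearson computation on their
printed counts and are excluded from the reproduction set rather than
guessed at. Windowed comparisons of daily means use the pooled-variance
two-sample t test over the day window, excluding pairwise any day on which
either arm has no rater and reporting the effective n; each arm is
summarized by the mean and the standard error of its daily-mean series.
Ladder movement is strict ascent on the five-level ordering. Percentages in
displays are rounded half away from zero.

## Pipeline, seeds and problem sizes

`runPipeline()` executes simulate → fit → sessions → follow-up → analyze.
One run seed fans out to per-stage seeds by fixed offsets, so stages are
reproducible independently; every run writes its resolved configuration and
a manifest with the seed and a configuration hash, and stages can be rerun
individually from the artifacts on disk. The demonstration configuration —
a 300-user pilot, a $D=2$, 20+30-sweep sampler, and the 120-participant
7:3-blocked cohort rating 30 messages — was sized so that a full simulated
trial completes in a few seconds and repeated-seed operating
characteristics (the win rate of the intervention arm's days-agreed
proportion, and the size of the null follow-up test) are cheap to estimate;
the same machinery scales to the 846-user pilot shape unchanged.

## Numerical choices and degenerate inputs

* Predictions and simulated ratings are clipped to $[1,5]$; selection ties
  break on lowest message id, K-NN similarity ties on lowest user index,
  grid-search ties on the first (smallest) combination.
* Kendall tau-b and NDCG signal undefined inputs (entirely tied vector;
  all-zero relevance) as `NA` with a warning instead of fabricating a value.
* Degenerate t tests: identical inputs give t = 0, p = 1; constant unequal
  series give an infinite statistic and p = 0; zero-variance paired
  differences are reported undefined.
* The Gibbs sampler and all generators restore the caller's RNG state and
  are deterministic per seed; derived seeds stay within 32-bit range.
* Libraries reject duplicate ids, empty texts and empty stage sets at
  construction; rating datasets reject duplicate (user, message) pairs and
  out-of-range ratings; fitting refuses datasets whose index contains
  unrated users or messages and points to the cold-start path instead.

## Known limitations

* Explicit ratings only: implicit feedback (e.g. website returns) and
  message-metadata regression are out of scope by design.
* Real-valued treatment of ordinal ratings bounds achievable RMSE (see the
  noise-floor note) and ignores rater-specific scale use.
* The comparator's uniform draw is an assumption, not a reconstruction, of
  the original rule-based scheduler.
* The trial simulator draws demographics independently of preferences, so
  it cannot exhibit the stratified effects a real cohort might.
* Multi-stage message coding is allowed throughout; if the original system
  coded each message for a single stage, its candidate sets were smaller
  than the ones simulated here.
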