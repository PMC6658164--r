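---
title: "Methods: Q-learning analysis of dynamic two-armed-bandit behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Q-learning analysis of dynamic two-armed-bandit behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(banditfit)
```

## The scientific problem

Value-based decision making decomposes into two steps: learning the value of
each available action from outcomes, and selecting actions as a function of
those values. Striatal circuit manipulations can dissociate the two: silencing
one population of dorsal striatal neurons makes choices *more random* without
slowing learning (a gain change in action selection), while silencing another
slows *value updating* without degrading selection. `banditfit` implements the
complete analysis chain needed to detect such a double dissociation from
trial-by-trial choice data in a dynamic two-armed-bandit (TAB) task, and a
synthetic-cohort generator that makes every stage testable without animal
data.

## Tasks

**Dynamic TAB.** Each session has four blocks of 35, 40, 45 or 50 trials
(drawn uniformly). Within a block one side rewards with probability 0.72 and
the other with 0.12; the assignment reverses at every block transition, with
no sensory cue. The richer side of block 1 is random. Because transitions are
uncued, a memoryless learner cannot anticipate them —
`pre_transition_choice_profile()` checks exactly this signature.

**Progressive reversal.** Five stages of daily sessions: stage 1 rewards one
fixed side (60 trials/day, 3 days); stage 2 the opposite side (4 days);
stage 3 flips the rewarded side across sessions (4 days); stage 4 adds one
within-session reversal taking effect at trial 31; stage 5 runs 90-trial
sessions with reversals at trials 31 and 61. The rewarded side pays with
probability 1.

## The model family

Action values update only for the chosen action $a$:

$$Q_a \leftarrow (1-\alpha_{pos})\,Q_a + \alpha_{pos} R - \gamma_{win}
\quad (R = 1), \qquad
Q_a \leftarrow (1-\alpha_{neg})\,Q_a + \alpha_{neg} R - \gamma_{lose}
\quad (R = 0),$$

with the unchosen action's value unchanged. Choice follows a softmax of the
value difference:

$$P_L = \frac{1}{1 + \exp\!\big(-\beta\,(Q_L - Q_R) + b\big)}.$$

Note the sign convention: the bias $b$ enters with a *plus* inside the
exponent, so positive $b$ disfavors the left target. This convention is kept
verbatim for comparability; `left_bias()` returns $-b$, the left-favoring
bias, for interpretation.

Six variants (`model_spec(1)` … `model_spec(6)`) free progressively more
parameters: (1) $\alpha, \beta$; (2) $+b$; (3) split
$\alpha_{pos}/\alpha_{neg}$; (4) $+\gamma_{win}, \gamma_{lose}$ with tied
learning rates; (5) all six; (6) adds uncertainty-based exploration
($\epsilon, \rho$): each action carries an accumulator that grows by
$\epsilon$ per trial it is unchosen, resets to zero when chosen, and
contributes $\rho\,(U_L - U_R)$ to the softmax argument. The exploration
variant is a documented default behind a model-variant interface — other
formulations of uncertainty bonuses can be substituted without touching the
fitting machinery.

Interpretation of the two headline parameters: $\beta$ (inverse temperature)
is the *gain* of value-dependent action selection — small $\beta$ means
random choice; $\alpha$ is the gain of reward-prediction-error-driven
learning, since the update can be written
$Q_a \leftarrow Q_a + \alpha\,(R - Q_a)$.

### Numerical choices

* Q-values initialize to 0/0 at each session start and are **not** reset at
  block transitions (the animal receives no transition cue). The
  initialization is configurable (`q_init`, e.g. 0.5/0.5).
* Likelihood evaluation floors each predicted choice probability at $10^{-12}$
  before the log, so degenerate-looking histories give finite, reproducible
  likelihoods.
* The softmax is evaluated with an overflow-safe logistic; extreme
  $\beta \Delta Q$ saturates to 0/1 without numerical exceptions.
* The per-trial likelihood loop is compiled (Rcpp); `value_trajectory()` and
  the exported single-step operations (`update_values()`,
  `choice_prob_left()`) are plain R and the test suite cross-validates the
  two paths against an independent trial-by-trial recomputation.

## Maximum-likelihood fitting

`fit_mle()` pools all sessions of one animal in one condition (values
re-initialized at each session boundary) and minimizes the negative
log-likelihood with bounded quasi-Newton optimization (`optim`,
`L-BFGS-B`) from Latin-hypercube multi-starts (default 20) plus one fixed
mid-range start. Two boxes matter and are deliberately different:

* **Bounds** (the feasible region): $\alpha \in [0,1]$, $\beta \in [0,50]$,
  $b, \gamma \in [-5,5]$, $\epsilon \in [0,5]$, $\rho \in [-10,10]$.
* **Start box** (where restarts are drawn): $\beta \in [0.1, 8]$,
  $\gamma \in [-1,1]$, $\rho \in [-3,3]$, etc. The likelihood is nearly flat
  at extreme inverse temperatures, and a start placed there stalls on a
  vanishing numerical gradient; drawing starts from the plausible region
  while letting the optimizer roam the full bounds removed every nesting
  violation we could provoke (a larger model fitting worse than a model
  nested inside it).

$\alpha$ is fitted on its natural $[0,1]$ scale (box constraints, no logit
transform) so estimates are directly comparable across animals and
conditions. Fits report the recomputed negative log-likelihood, AIC
($2k + 2\,\mathrm{nll}$), BIC ($k \ln n + 2\,\mathrm{nll}$), per-restart
objective values, a convergence flag and per-parameter at-bound flags
(within $10^{-3}$ of a bound, as a fraction of its range).
`compare_models()` fits the whole family per animal × condition, tabulates
AIC/BIC and win counts, and treats nesting violations as optimization
failures, refitting with doubled restarts.

Degenerate inputs are contracts, not errors: an animal that chose one side on
every trial drives bias/β to a bound (flagged); a β = 0 generating agent
leaves α unidentified, and the suite asserts only the chance-level likelihood
$N \log 0.5$, never α recovery.

## Dynamic and steady states

Per block, the indicator of choosing the currently richer side is smoothed
with a 7-trial moving average. With $M$ the block maximum of the smoothed
series, the *dynamic state* runs from the block start until (not including)
the first trial strictly exceeding $0.70\,M$, and the *steady state* from the
first trial strictly exceeding $0.90\,M$ to the block end; trials between the
two thresholds belong to neither state.

Alignment was genuinely open: the smoothing window is **centered**
(±3 trials, truncated at block edges) by default, because trailing smoothing
systematically lags the detected end of the dynamic state; `align =
"trailing"` is provided for sensitivity analyses. "Exceeds" is strict (>),
which makes the zero-max block well-defined: a block with no high-side choice
has $M = 0$, nothing exceeds $0.70 \cdot 0$, and the whole block is dynamic.
Smoothing never crosses block boundaries.

## Choice metrics and preprocessing

`compute_choice_metrics()` returns P(R) (rewarded trials), P(H) (higher-
probability-side choices), P(WS) (stay after a rewarded predecessor) and
P(LS) (switch after an unrewarded predecessor), each with numerator and
denominator. The predecessor is always the *actual* preceding trial of the
session, even when scoping to dynamic- or steady-state trials — stay/switch
is defined by consecutive behavior, not by consecutive in-scope trials — and
never crosses session boundaries. Zero-denominator metrics are `NA`
(undefined, distinct from 0) and are excluded from within-animal averages.

Two preprocessing stages mirror the study's session handling:

* `exclude_duration_outliers()` drops, in a single pass, sessions whose mean
  trial duration exceeds their population mean by more than 3 sample SDs
  (both computed including the candidates). Populations — (line, treatment)
  for TAB; (line, treatment, stage) for reversal — are never pooled.
* `match_durations()` equalizes mean durations between CNO and DMSO session
  lists by greedily removing the longest remaining CNO session or the
  shortest remaining DMSO session, whichever single removal shrinks the gap
  more, until the gap is within `tolerance` (default 0.5 s) or a removal
  budget (default 20% of sessions) is spent. The stopping rule is
  artifact-defined (the study states only which tail of which group was
  deleted); every removal is logged and the log replays to the matched sets.

## Group-level inference

The animal is always the statistical unit: session-level values are averaged
within animal before any test. `mixed_anova_2x2()` performs the classical
mixed-design decomposition (one between factor: line; one within factor:
drug) through `aov` with an `Error(subject)` stratum — with two within
levels, sphericity is trivial. `between_anova_2x3()` (line × treatment group
for the reversal task) uses Type-II sums of squares for mildly unbalanced
cells. Exactly additive or constant data are handled explicitly: sums of
squares below numerical noise are zeroed, and constant data return `NA`
F-statistics rather than 0/0 artifacts.

Bonferroni post-hoc tests multiply raw p-values by the family size and cap at
1; the family is the set of simple-effect contrasts actually tested per
measure (CNO vs DMSO within each line → m = 2; three-group contrasts per
line → m = 3). Drug contrasts are paired, group contrasts unpaired.

The **permutation control** guards the headline count of significant
line × drug interactions: animals are reassigned to two pseudo-lines of the
original sizes (without replacement), the eight ANOVAs (four measures × two
states) are rerun, and the count of interactions with p < 0.05 is recorded
per permutation (default 100). The observed count with true labels is
reported alongside the number of permutations reaching ≥ 3.

## The synthetic cohort generator

`generate_cohort()` draws, per animal, a baseline model-1 parameter set with
$\alpha \sim U(0.15, 0.35)$ and $\beta \sim U(1.5, 3)$, and forms the
animal's CNO parameters by multiplying $\beta$ by 0.6 (line D1R) or both
learning rates by 0.5 (line D2R). The default cohort is 20 D1R + 19 D2R
animals with 10 CNO and 10 DMSO sessions each on alternating days,
first-day drug counterbalanced across animals. Trial durations are
log-normal with a session-level random effect and a ×1.3 CNO slowdown, so
the exclusion and matching stages operate on realistic right-skewed data
with occasional outlier sessions. All randomness derives from one master
seed (R's Mersenne-Twister); callers' RNG state is never disturbed.

The baseline ranges were calibrated once against the realized statistics the
study reports for its animals: with these ranges the generator's mean
dynamic-state length is ≈ 8 trials (animals: ≈ 7.5–8.5) and session-level
P(H) is ≈ 0.65–0.70. Two realized features of animal behavior are **not**
reproduced, and this is important for interpreting test outcomes:

* Real steady states are short (≈ 10 trials); single-timescale Q-agents
  cross $0.9\,M$ earlier and give steady states of ≥ 20 trials across the
  entire plausible (α, β) range we scanned.
* Real dynamic-state lengths are essentially unchanged by inactivation
  (≈ 8.4 vs 8.5 trials), whereas halving α in a pure agent lengthens the
  dynamic state (≈ 4.6 → 6.9 trials) instead of lowering within-state
  accuracy.

The study's realized mean block length (38.8 trials) also sits below the
uniform-{35,40,45,50} mean of 42.5, implying unmodeled session truncation;
the generator draws uniformly and does not attempt to match 38.8.

### What passing tests do and do not show

The generator validates the *pipeline*, not the biology. The double
dissociation on fitted parameters (interaction on $\beta$ localized to line
1, on $\alpha$ to line 2) is recovered essentially always at the study's
data size, and steady-state P(H)/P(WS) drop under a β reduction exactly as
in the animals. But three real-animal signatures are *not* implied by the
model that is fitted:

* Steady-state P(LS) **rises** when β falls in a pure softmax agent (every
  outcome-conditional probability is pulled toward 0.5, and baseline P(LS)
  is below 0.5); the animals' observed P(LS) *decrease* must reflect
  strategy components outside the value model.
* Dynamic-state P(R) is insensitive to halving α, because the dynamic state
  is defined adaptively (until smoothed P(H) reaches 70% of its block
  maximum): slower learning lengthens the window rather than lowering
  within-window accuracy.
* Dynamic-state fitted $Q_{high}$ is not lower under a pure α reduction:
  with slower forgetting, the previously rich side's value decays more
  slowly, so $Q_{high}$ starts each block from a higher floor, offsetting
  its slower rise.

These divergences are asserted honestly in the acceptance suite (the
corresponding expectations fail) and are, in our view, informative: they
quantify exactly which behavioral signatures require mechanisms beyond the
fitted Q-learning family.

## Problem sizes used in the shipped checks

The test suite simulates five full cohorts (39 animals × 20 sessions each)
for the dissociation checks, 50 agents × 10 sessions for parameter recovery,
200 sessions for Monte-Carlo behavioral checks, 500 replicates for null
calibration of the mixed ANOVA, and 20 × 100 permutations for the
permutation-control envelope. These sizes were chosen to keep Monte-Carlo
error well below every asserted margin while remaining comfortable to run
routinely.

## Known limitations

* No hierarchical/Bayesian estimation, no standard errors or profile
  intervals — point estimates per animal × condition only.
* The exploration variant (model 6) is a documented default, not a claim
  about any particular published formulation.
* The generator omits motivation/satiety drift, inter-trial-interval
  dynamics, session truncation, and any strategy component (e.g. explicit
  win-stay/lose-switch rules) beyond the value model — see above for the
  behavioral signatures this excludes.
* `between_anova_2x3()` assumes one value per animal; repeated-measures
  three-group designs are out of scope.
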