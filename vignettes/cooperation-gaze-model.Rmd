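---
title: "Modelling cooperation and gaze in one-shot Prisoner's Dilemma games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cooperation and gaze in one-shot Prisoner's Dilemma games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopgaze)
```

## The problem

In a one-shot Prisoner's Dilemma, defection is the dominant strategy, yet
people cooperate at substantial rates that depend on the payoff values, on
individual social preferences, and — the motivating phenomenon for this
package — on *where people look*. Manipulating the on-screen position of the
cooperation option changes which payoffs are sampled first and in what
order, and those gaze sequences in turn predict trial-by-trial cooperation.
`coopgaze` implements the computational core needed to study this loop:
task-design generation, a utility model of cooperation, a synthetic cohort
and gaze generator, gaze-sequence feature extraction, and out-of-sample
classification of choices from gaze.

## Task design

Payoffs T (temptation), R (reward), P (punishment) and S (sucker's) live on
the grid {0, 5, ..., 40} and must satisfy T > R > P > S, T > S and
2R > T + S. Enumerating the grid yields exactly 96 games
(`enumerate_games()`); `game_id` follows (T, R, P, S) lexicographic order as
a fixed convention. A session (`build_session()`) plays each game twice — two
blocks of 96, independently shuffled — with the four option-position
conditions (cooperate-left/right × cooperate-up/down) exactly
counterbalanced at 24 trials per combination per block. Exact rather than
random counterbalancing makes every structural test deterministic.

Screen columns encode the participant's own action (the response keys select
a column) and rows the opponent's action. The screen (1920×1080, origin
top-left) is tiled by four equal cells; within each cell the participant's
payoff occupies the left slot and the opponent's the right slot, and each
payoff AOI is an inset rectangle of its slot, half-open `[x0,x1)×[y0,y1)`,
so edge points belong to at most one AOI and inter-AOI gaps map to none. Only
the 8 payoff AOIs are modelled; the task's remaining non-payoff AOIs carry
no payoff information and are out of scope.

## The utility model and its variants

The full model (`M0_full`) has four parameters:

| parameter | meaning | bounds |
|---|---|---|
| `alpha` | other-regarding preference: weight on the opponent's payoff in the unequal outcomes | [0, 1] |
| `p` | fixed belief that the opponent cooperates | [0, 1] |
| `rho` | risk curvature of the power utility `x^rho` | (0.05, 2] |
| `beta` | softmax inverse temperature | [0, 20] |

with `U(C) = p·R^ρ + (1−p)((1−α)S^ρ + αT^ρ)`,
`U(D) = p((1−α)T^ρ + αS^ρ) + (1−p)P^ρ` and
`P(C) = logistic(β·ΔU)`. `0^ρ` evaluates to 0 on the whole `rho` range and
`beta = 0` yields exactly 0.5. The ten alternatives follow the field's usual
specifications; where a formula is not standard we fixed one and isolated it
so it can be swapped:

* `M1_risk_after_orp` applies the curvature *after* the α-mixing,
  e.g. `U(C) = p·R^ρ + (1−p)·((1−α)S + αT)^ρ`.
* `M2_bias` / `M5_selfish_bias` add a constant `c ∈ [−20, 20]` to `ΔU`
  (folded into `U(C)` so the `ΔU` identity is exact).
* `M3_selfish` pins `alpha = 0`; `M4_risk_neutral` pins `rho = 1`;
  `M8_rho_1.1` pins `rho = 1.1` (constant risk seeking).
* `M6_cara` replaces the power transform by CARA
  `u(x) = (1 − e^{−ax})/a`, with the linear limit used for `|a| < 1e−8`.
* `M7_crra` uses CRRA evaluated on `x + 1` so the zero payoff stays finite:
  `u(x) = (x+1)^{1−r}/(1−r)`, `ln(x+1)` at `r = 1`. The unit shift is a
  documented choice; additive constants cancel in `ΔU`.
* `M9_charness_rabin` weights the opponent's payoff piecewise per outcome
  cell: `lam_behind` when the agent's own payoff is at least the opponent's
  (the opponent is behind), `lam_ahead` otherwise.
* `M10_belief_RP` lets the belief vary with the reward–punishment gap,
  `p_t = logistic(γ0 + γ1·(R_t − P_t))`; its free parameters are
  `{alpha, rho, beta, gamma0, gamma1}`, so `k = 5`.

The free-parameter ledger `{4, 4, 5, 3, 3, 4, 4, 4, 3, 5, 5}` is pinned in
code and asserted by a test.

## Fitting

`fit_mle()` is a random multistart: `n_starts` uniform draws inside the
bounds (default 200; the test suite uses 8–50, which suffices at n = 192),
each refined by bounded L-BFGS-B on the negative log-likelihood, keeping the
best refined solution. The likelihood is smooth in all parameters, so a
quasi-Newton bounded optimiser is appropriate; probabilities are clipped to
`[1e−12, 1 − 1e−12]` so extreme `beta` cannot produce infinite negative
log-likelihoods. Everything is deterministic given the seed. Participants
with fewer than two cooperation or two defection trials are excluded before
fitting (`eligible_for_fit()`); their data cannot constrain the model.
`compare_models()` fits any subset of the 11 variants and reports BIC
(`k·ln n − 2·loglik`) with differences to the best variant.

Two identifiability facts matter when interpreting comparisons at n = 192
trials. First, `rho` and `beta` trade off (scaling utilities is nearly
equivalent to rescaling the temperature), so their individual recovery is
noisy even when `alpha` and `p` recover well. Second, for moderate curvature
the risk-neutral restriction fits almost as well as the full model, and BIC
prefers it — the model-selection test therefore simulates strongly
risk-averse, near-deterministic agents (`rho` ~ U(0.08, 0.15), `beta` ~
U(10, 18)), a regime in which curvature is genuinely identified and in which
the zero-payoff step of the power utility also separates it from the
shifted CRRA variant. `recovery_study()` exposes the recovery machinery for
arbitrary grids.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without any
external data. It emulates four features of the real task's data:

1. **Payoff-dependent cooperation** — choices are Bernoulli draws from the
   utility model; gaze and choices are conditionally independent given the
   agent parameters (permuting gaze cannot change choices).
2. **First-fixation biases** — the first fixated AOI follows a softmax over
   the 8 payoff slots with logit
   `b_row·[top] + b_col·[left] + b_self·[own] + b_val·payoff/40 +
   coupling·α·[other]`.
3. **Reading-order transitions** — subsequent fixations follow a move-type
   kernel over {lateral, vertical, diagonal within-person; within-cell
   person switch; diagonal between-person} with configurable weights
   (defaults 0.30/0.30/0.10/0.20/0.10, favouring the lateral/vertical
   within-person moves typical of left-to-right readers). Every move type is
   an involution on the slot grid, so the kernel's stationary distribution
   is uniform — a useful property when reasoning about how quickly
   first-fixation biases wash out.
4. **Preference–gaze coupling** — the `alpha_gaze_coupling` shift (default
   3.0) makes agents with higher other-regarding preference look more at
   the opponent's payoffs, producing a positive cross-participant
   correlation between α and relative dwell on "other" AOIs of r ≈ 0.4–0.6,
   the qualitative relation observed in real cohorts.

Fixation counts are geometric (minimum 1, mean 6); durations are log-normal
(median 250 ms, σ_log 0.4) truncated above the 100 ms keep threshold, with a
10% admixture of 30–100 ms noise events so the filtering stage has work to
do. The response time is the summed fixation time plus a 300 ms motor
constant — a denominator for relative dwell, not a cognitive RT model.

**Calibration.** The agent-parameter distributions (α ~ Beta(5, 25),
p ~ Beta(2, 4), ρ ~ truncated-Normal(1, 0.15) on [0.5, 1.5],
β ~ log-Normal(−1.05, 0.3)) and the gaze logit constants (`b_row = 0.84`,
`b_col = 0.41`, `b_self = 1.54`, `b_val = 0.8`) were chosen once, by coarse
grid search over the generator itself, so that a default cohort reproduces
the study-scale aggregates: ~23% mean cooperation (88 participants × 192
trials) and first-fixation marginals of ~68% top row, ~59% left column,
~72% own payoffs, measured — as in the analysis pipeline — on the first
fixation kept by the >100 ms filter. The constants live in
`inst/extdata/cohort_defaults.yaml`, not in code. Two calibration notes:
belief is weakly identified by the base rate because most grid games have
R + P ≈ T + S, which cancels `p` from `ΔU`, so the base rate was calibrated
mainly through the α distribution; and α heterogeneity was kept moderate
(SD ≈ 0.06) so that an 88-agent cohort mean is a stable statistic (SD ≈
1.3 percentage points) — real cohorts show wider individual differences
(documented limitation below).

**Stress modes**, both off by default: `gaze_causal_bonus` adds
`bonus × (dwell share on other AOIs)` to `ΔU`, making aggregate dwell
genuinely causal; `gaze_seq_bonus` adds a bonus when the opponent's reward
is the *second* payoff sampled — a timing signal that slot-sequence features
encode exactly but aggregate dwell only blurs, mirroring the empirical
finding that sampling the other's reward second is the gaze signature of
cooperation. The classifier ordering tests use the sequence mode, because
under the dwell mode dwell-only features contain the causal variable itself
and trivially win.

## Gaze features

`filter_fixations()` keeps events strictly longer than 100 ms ("longer
than" read strictly; configurable) inside the choice phase.
`summarize_gaze()` computes per-trial relative dwell (summed kept duration /
response time) per AOI, the AOIs of fixation slots 1–5, and the last kept
fixation; `last` duplicates an earlier slot when five or fewer fixations
were kept, and unfixated slots stay empty — encoded as all-zero feature
columns, letting the tree split on absence. `build_features()` produces the
dummy encoding (8 indicators × slots; 4 slots give the canonical 32
columns), the payoff-valued encoding (the displayed payoff when fixated,
else 0), and two baselines (8 dwell columns; the 4 raw payoffs). Column
order is fixed: slots in the given order, AOIs in
`T_Y, R_Y, P_Y, S_Y, T_O, R_O, P_O, S_O` order. `dwell_aggregates()` and
`dyad_stats()` provide the participant/trial dwell summaries and the
first-two-fixation dyad frequency tables (frequencies sum to one within each
option-position stratum; cooperation per dyad averages participant-level
rates).

## Classification and the permutation chance level

`train_tree()` grows a single fully grown CART-style tree (Gini impurity,
`min_leaf = 1`, no depth cap) via the randomForest engine with one tree and
all features available at every split; exact split ties are broken by the
seeded scan order, so everything is deterministic given the seed. A fully
grown tree is the behaviour of the standard single-tree routines this
emulates, and it is essential for the permutation null: on label-shuffled
training data a *pruned* tree predicts the majority class almost everywhere,
collapsing the "chance" cooperation rate to ~0, whereas a fully grown tree
reproduces labels at the training base rate wherever feature rows are
unique. With ~2/3 unique rows at desk scale, the measured chance level lands
at ~0.85 of the base rate — about 0.2 at a 23% base rate — which is exactly
why a permutation null, not 0.5, is the right baseline for an imbalanced
outcome. Predictions aggregate as hard 0/1 labels by default;
`predict_type = "prob"` substitutes leaf-probability averaging (leaf
probabilities are recovered by routing rows through the tree and averaging
training labels), which is the right choice for pruned trees
(`min_leaf = 50`) whose game-level rates would otherwise be degenerate 0/1
values — the configuration used for the payoffs-only baseline comparison.

`loso_predict()` implements leave-one-subject-out folds (a participant's
trials are never in their own training set — asserted by a corruption test),
`aggregate_and_score()` averages predictions across games per participant or
across participants per game and scores both against the true rates by MSE,
and `chance_level()` shuffles training labels 50 times per fold.

## Problem sizes

The test suite and the acceptance script use: 10,000 trials for the
first-fixation marginals; an 88 × 192 cohort for the base rate; three
replicate 20 × 192 cohorts (50 shuffles per fold) for the chance level —
replication because a single 20-agent draw leaves ~2 percentage points of
Monte-Carlo error on a ~20% quantity; 20 replicate mini-cohorts for the
model-selection and recovery properties. These sizes make every statistic's
Monte-Carlo error small relative to its tolerance while keeping a full run
in minutes on one CPU.

## What passing tests do and do not show

The generator reproduces the aggregate structure the analysis relies on —
base rate, first-fixation marginals, reading-order transitions, the α–dwell
coupling — so green tests show the *machinery* is correct: enumeration,
counterbalancing, likelihoods, BIC bookkeeping, leakage-free
cross-validation, permutation nulls. They do not show that real data meet
the generator's assumptions: real cohorts have wider individual differences
(cooperation rates from 0% to 100%), richer saccade dynamics than a
five-move kernel, value- and position-dependent fixation durations, and
gaze–choice dependencies beyond a shared latent α. Known limitations, by
construction: no saccade kinematics, blinks or pupil data; no trial-level
belief updating (beliefs are fixed; no feedback is given); event-level
fixation input only (no raw-sample event detection); only the 8 payoff AOIs;
and the response time is a bookkeeping quantity, not a process model.
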