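---
title: "Counting episodes in absorbing Markov chains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting episodes in absorbing Markov chains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcepisodes)
```

## The problem

Multistate Markov models answer "how long?" questions about health: how
many of the next ten years will a patient spend with normal liver
function, how many months will an older person live without disability.
But the expected time in a state says nothing about the *dynamics* of
that time — whether it accrues in one long spell or in many short,
recurrent episodes. Two treatments can deliver the same expected healthy
time while one prevents relapse and the other merely speeds recovery.
`mcepisodes` computes, in closed form, the expected **number of
episodes** of a state (or set of states) and their **average length**
for any discrete-time homogeneous absorbing Markov chain, together with
the supporting machinery: occupancy times, rate-to-probability
conversion, panel estimation, and bootstrap uncertainty.

## Model and notation

A chain moves at times $t = 0, 1, 2, \dots$ over $m$ labelled states, $n$
transient and $q \ge 1$ absorbing (e.g. dead). Transitions follow the
row-stochastic matrix $P = [p_{ij}]$ in row-to-column orientation:
$p_{ij} = \Pr(Z_{t+1} = s_j \mid Z_t = s_i)$. The package stores states
canonically (transient first), so the transient-to-transient block $U$
is always the leading $n \times n$ block and the selector
$Z = (I_n \mid 0)$ is a plain column subset.

**Occupancy.** The fundamental matrix
$$N = [n_{ij}] = (I_n - U)^{-1}$$
gives in $n_{ij}$ the expected number of steps spent in transient state
$s_j$ starting from $s_i$, counting the starting step; row sums are
remaining life expectancies in steps.

**Rewards.** Attaching a reward $r_{ij}$ to each transition and
collecting them in $R$, the expected accumulated reward per starting
state is
$$e = N Z (P \circ R)\, 1_m ,$$
with $\circ$ the elementwise product. (Several classical treatments
write the transposed, column-to-row form of this identity.)

**Episodes.** Setting $r_{ij} = 1$ exactly when $s_i \notin S^*$ and
$s_j \in S^*$ makes $e$ the expected number of *entries into* the target
set $S^*$ — the number of episodes. The average episode length is the
ratio
$$a_{ij} = n_{ij} / e_i ,$$
a ratio of expectations (total time over total entries). We implement
this identity literally and verify it against simulation as
$E[\text{time}]/E[\text{entries}]$; the per-trajectory "average length
conditional on at least one episode" interpretation is *not* asserted,
and when $e_i = 0$ the length is reported as `NA` (undefined) with a
warning rather than 0 or $\infty$, so batch and bootstrap runs never
abort on a degenerate start.

Replacing $R$ by its transpose counts *exits* from $S^*$; zeroing the
absorbing destinations first counts recoveries only. At an infinite
horizon entries balance exits-including-absorption for starts outside
$S^*$ and fall one short for starts inside it — both identities are
enforced by tests. On chains where the target can only be left through
absorption, $e_i$ is a first-passage probability and lies in $[0,1]$.

```{r worked}
P <- rbind(H = c(0.6, 0.3, 0.1), I = c(0.2, 0.5, 0.3), D = c(0, 0, 1))
colnames(P) <- rownames(P)
chain <- markov_chain(P, absorbing = "D")
fundamental_matrix(chain)$N
episode_summary(chain, target = "I")
```

## Finite horizons

Published analyses often restrict to a window — ten years of daily
steps, sixty months. The sources rarely state the truncation formula, so
we fix one convention and use it everywhere: the fundamental matrix is
replaced by the partial sum
$$N_T = \sum_{t=0}^{T-1} U^{\,t},$$
which counts the state at $t = 0$ and reduces to $I_n$ at $T = 1$;
rewards are then collected on the first $T$ transitions. Occupancies and
episode counts are non-decreasing in $T$ and converge to the
infinite-horizon values. A 10-year horizon of daily steps is taken as
$T = 3650$ (no leap-day correction); 60 months as $T = 60$.

## From rates to probabilities

Occurrence-exposure rates (events divided by person-time) are the usual
estimation currency. With the generator convention — non-negative
off-diagonal rates $q_{ij}$, diagonal $-\sum_{j \ne i} q_{ij}$, absorbing
rows zero — we convert to one-step probabilities with the rational
(Padé) approximation of the matrix exponential,
$$P = \left(I + \tfrac12 Q\right)\left(I - \tfrac12 Q\right)^{-1}.$$
Rows sum to one exactly; entries agree with $\exp(Q)$ to second order
(tested against `Matrix::expm()`). Some sources print this formula with
the sign convention $B = -Q$ (positive diagonal); with non-negative
off-diagonal rates only the variant above yields valid probabilities,
which is the one we implement. Rates too large for the step size push
entries outside $[0,1]$ and are rejected with advice to shrink the step.
The degenerate all-zero rate matrix maps to the identity with a warning,
since such a chain never absorbs.

## Estimation from panels

Long-format panels (`id`, `time`, `state`; equally spaced waves) are
grouped into one block per individual. Counting adjacent same-individual
pairs gives $c_{ij}$ and $c_i = \sum_j c_{ij}$; the MLE is
$\hat p_{ij} = c_{ij}/c_i$, and occurrence-exposure rates divide
occurrences by origin-state exposure (one step per observed transition —
the origin-state convention; irregular visit spacing is out of scope, and
missing waves are skipped, never imputed, under `allow_gaps = TRUE`).
Absorbing rows are never estimated: they are identity rows by
construction.

## Sampling uncertainty

Episode counts are strongly non-linear in $\hat P$, so we bootstrap.

* **Model-based (multinomial)**: each transient count row is redrawn as
  $\text{Multinomial}(c_i, \hat p_{i\cdot})$. Valid only if transitions
  are row-wise i.i.d. — i.e. the Markov property holds in the data.
* **Block bootstrap**: whole individuals are resampled with replacement
  (all or none of an individual's transitions enter a resample), which
  preserves within-individual correlation.

Both return the empirical variance of the replicates and percentile
confidence intervals; the quantile rule is pinned to linear
interpolation (`stats::quantile()` type 7) and tested exactly
(`percentile_ci(1:1000, 0.95)` is `(25.975, 975.025)`). Replicates on
which the statistic is not computable (a resample losing all
observations of a state) are skipped and counted, with a hard 10%
failure ceiling; each replicate runs under its own pre-drawn seed, so
results are bit-reproducible.

## What the synthetic generators emulate

`generate_panel()` draws i.i.d. trajectories from one chain — the
textbook data-generating process under which both bootstraps are
consistent. `generate_heterogeneous_panel()` gives every individual a
*private* transition matrix (finite mixture by default, for
interpretability; a logit-normal row perturbation is also offered), so
repeated transitions of one individual are correlated through the shared
private matrix and the pooled panel violates the row-wise i.i.d.
assumption, while each individual's matrix remains a valid absorbing
chain (zero patterns are preserved, so reachability survives the
perturbation).

The frozen calibration scenarios (`default_bias_scenarios()`) use a
monthly illness-death chain with recovery, panels of 150 individuals
followed for 60 monthly steps from the healthy state — sizes typical of
disability cohort analyses — and, as statistic, the expected number of
illness episodes over a 60-month horizon. The choices are deliberate:

* the 60-month horizon matches the observation window and keeps the
  statistic well-conditioned (infinite-horizon episode counts of
  long-lived chains are so non-linear in $\hat P$ that the bootstrap
  itself becomes biased, which would confound the comparison);
* the heterogeneous variant is a 50/50 mixture differing **only in
  illness incidence** ($p(\text{healthy}\to\text{ill}) = 0.04$ vs
  $0.16$, identical recovery and mortality), a plausible "robust vs
  vulnerable sub-population" structure that injects a between-individual
  variance component invisible to the multinomial model.

Under this violation the model-based bootstrap *underestimates* the
sampling variance (the across-dataset variance acquires a mixing
component the multinomial model cannot see), while the block bootstrap
stays approximately unbiased; the harness reports signed relative
biases, and the tests assert only that the block bootstrap's absolute
relative bias is the smaller one. These panels are still a simplified
world: no covariates, no censoring other than death, no observation
error, equally spaced waves. Passing tests therefore demonstrate
correctness of the machinery and the direction of the bootstrap
comparison, not performance on any particular real cohort.

```{r harness, eval = FALSE}
scen <- default_bias_scenarios()
variance_bias_harness(scen, n_datasets = 200, n_replicates = 500, seed = 1)
```

## Case-study recipes

`case_study_cirrhosis()` reproduces the classical prednisone trial
analysis: a reversible illness-death model of liver functioning (normal
/ low prothrombin index / dead), day-to-day probabilities estimated from
occurrence-exposure rates over a 3650-day horizon starting from low
functioning, with patient-level block-bootstrap intervals. The records
are user-supplied (e.g. `mstate::prothr`), never bundled. One
data-layout subtlety is handled deliberately: in transition-structured
(`msdata`-style) records each at-risk interval appears once per
competing transition, and the recipe sums exposure over *all* rows —
each interval counts once per possible destination. This is the
convention under which the published 10-year durations of the trial
reproduce to printed precision; dividing instead by naive person-time
roughly halves the implied survival.

`case_study_frailty()` is the aggregated-rates recipe: a four-state
disability model (none / mild / severe / dead) on monthly steps,
episodes of the subset {mild, severe} from the no-disability state over
60 months. It deliberately offers no resampling — an aggregated rate
table carries no individual blocks to resample. The published rate
tables it was designed for must be supplied by the user; the test suite
exercises the recipe on clearly labelled synthetic rates.

## Numerical choices and edge cases

* Row-sum tolerance $10^{-10}$; deviations below $10^{-8}$ are treated
  as float noise and renormalized, larger ones rejected as data errors.
* Validation errors name the offending state (non-stochastic row,
  non-identity absorbing row, absorbing state unreachable — checked by
  backward reachability).
* $(I - U)$ is non-singular for every validated absorbing chain; the
  solver failure is still trapped defensively.
* Finite-horizon powers use repeated squaring:
  $N_T = (I-U)^{-1}(I - U^T)$.
* Monte-Carlo oracles run until absorption with an explicit step cap and
  a truncation flag; padded (post-absorption) observations never affect
  episode counts because absorbing states cannot belong to a target set
  in practice.
* Problem sizes in the shipped validation: 50 random chains × 100,000
  trajectories for the oracle comparison (3 Monte-Carlo standard
  errors), 5,000 × 50 and 10,000 × 150 panels for parameter recovery, and
  200 datasets × 500 replicates per bootstrap scenario — chosen as the
  smallest sizes at which the Monte-Carlo noise is clearly below the
  effects being measured.

## Limitations

* Chains are homogeneous in time. Age- or duration-dependence must be
  encoded by expanding the state space (e.g. "age 70 & disabled",
  "age 71 & disabled"); the package does not automate this.
* Panels must be equally spaced; no interval-censoring corrections or
  embedded-chain estimation for coarse observation grids. If the step is
  coarse relative to the true dynamics, episode counts are
  underestimated (brief excursions between waves are invisible) even
  when occupancy times remain accurate.
* Only means of rewards are computed — no higher moments, and no
  distribution of the episode count.
* Percentile intervals only; no BCa or studentized variants. With few
  individuals (the harness flags fewer than 50 blocks) any resampling
  interval is unreliable.
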