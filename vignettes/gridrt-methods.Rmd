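---
title: "Modelling response times as first passage through entropic barriers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling response times as first passage through entropic barriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridrt)
```

## The models

gridrt treats a single decision among many alternatives as a stochastic
search: a walker explores a discretized solution space until it first
reaches an absorbing boundary, and the number of iterations times a fixed
time-per-step is the response time (RT). Two generative models share this
first-passage skeleton and differ in what shapes the walk.

**Obstacles model.** A walker starts at the origin of a square lattice.
Nodes with Euclidean distance $\ge R$ from the origin are absorbing; the
interior nodes (distance $< R$) are independently *reflecting obstacles*
with probability $q$ — entropic barriers representing branches of the
decision tree that are pruned or dead-end. Each iteration draws one of
the four lattice directions uniformly; a move into an obstacle returns
the walker (the probability current into an obstacle is zero, so the
walker stays put and the iteration still counts); a move to distance
$\ge R$ absorbs. Parameters: radius $R$ (search depth, grid steps),
obstacle fraction $q$ (pruning intensity), time per step $\Delta t$ (ms).
Two dimensions is the minimal dimensionality in which obstacles need not
disconnect the space.

**Grid DDM.** The classical drift-diffusion picture on the same lattice:
proposals are uniform over the four directions, but a proposal is
*accepted* with probability $e^{-C/\epsilon}$, where the cost of a step
$\hat z_p$ from displacement $\hat z$ is

$$C = \tfrac12\,(1 - \hat z \cdot \hat z_p) \in [0, 1],$$

so radially outward moves are free and inward moves maximally costly.
Rejected proposals leave the walker in place. Parameters: $R$,
acceptance noise $\epsilon$, and $\Delta t$. As
$\epsilon \to \infty$ every proposal is accepted and the unbiased
($q = 0$) walk is recovered — a property the test suite checks with a
two-sample KS test.

The qualitative difference between the models is in the RT tail: the
outward-biased DDM produces a comparatively light tail, while quenched
obstacles trap the walker in pockets and fatten the tail — this is what
lets the obstacles model reproduce empirical RT distributions that
neither a bounded 1-D diffusion (exponential tail) nor a free one
(power-law $t^{-3/2}$ tail) matches. The `analytic` functions
(`fpt_density_infinite()`, `fpt_density_bounded()`) implement those two
1-D limits exactly and are used as references, not as fitted models.

### Conventions that matter

* **Obstacle fraction, not smoothness.** The literature parameter
  "smoothness $\rho$" appears with both orientations (sometimes
  $p(\text{obstacle}) = 1 - \rho$, sometimes $\rho$ *is* the obstacle
  share). gridrt stores only the unambiguous obstacle fraction
  `density` ($q$, the expected share of non-origin interior nodes that
  are obstacles). Under the convention "$\rho = 0.45$ means 45% of grid
  points are obstacles", $q = \rho$; under the complementary one,
  $q = 1 - \rho$. Getting this wrong silently flips the expertise
  result, which is why a single canonical parameter is enforced.
* **The origin is never an obstacle**, and absorption is tested as
  $x^2 + y^2 \ge R^2$ on integer coordinates.
* **Disorder is annealed by default**: each simulated decision draws a
  fresh obstacle realization, because aggregated RT distributions
  average over decision problems. A quenched mode (one realization per
  batch, or a user-fixed grid) exists and is what the exact
  Markov-chain oracle validates against.
* **Disconnected realizations are resampled** (default budget $10^4$
  per draw) rather than producing censored infinite walks, so the FPT
  distribution stays normalized. At high $q$ this is the dominant cost:
  near $q = 0.65$ most realizations seal the origin in.
* **Rejected DDM proposals consume one iteration** (hesitation costs
  time). The alternative — free resampling — is available via
  `count_rejected_ddm = FALSE`; nothing in the RT data distinguishes
  the two conventions except through $\Delta t$, so one had to be fixed.
* **The first DDM step from the origin is always accepted**: the
  displacement direction is undefined there.

## Exact references

Because no closed form exists for 2-D first passage with obstacles, the
simulators are validated against exact computations:

* `exact_fpt_markov()` builds the absorbing Markov chain on the open
  interior nodes of any fixed grid and iterates it to the exact pmf of
  the absorption step count (truncation when residual transient mass
  $< 10^{-10}$). The test suite requires the quenched simulator to be
  within total variation 0.02 of this pmf at 50,000 walks, and checks
  the chain itself against brute-force path enumeration on small grids
  and a hand-computed 3-state corridor chain.
* `exact_mean_exit_steps()` solves the discrete exit-time system
  $(I - T)h = \mathbf 1$; obstacle-free simulated means must agree
  within 2 standard errors for $R = 2..6$ (and scale as $R^2$).
* The 1-D densities use the Lévy–Smirnov closed form (infinite domain)
  and a reflecting/absorbing eigenfunction series that switches to a
  method-of-images sum below $t = 0.05\,L^2$ (both forms agree to
  $10^{-8}$ at the switch; series truncation at term sup-norm
  $10^{-10}$, well below the $10^{-6}$ acceptance tolerances).

## Fitting by Jensen–Shannon divergence

RT samples are binned into half-open 0.1 s bins over $[0, 300)$ s
(3000 bins, matching a 300 s clock budget; everything at or beyond the
cap pools into the last bin). A parameter point is scored by simulating
decisions, binning them on the target's edges, and computing

$$\mathrm{JSD}(P, Q) = \tfrac12 D(P\|M) + \tfrac12 D(Q\|M), \qquad
  M = \tfrac12 (P + Q),$$

in nats ($\le \ln 2$). JSD is used both as the fitting objective and for
model comparison. No pseudo-count smoothing is applied: the mixture
$M$ is positive wherever either histogram is, so the divergence is
always finite, and `kl_divergence()` is only ever called against
mixtures inside `jsd()`.

`fit_model()` searches the radius axis exhaustively ($R = 1..10$ by
default) and the two continuous parameters inside their boxes
($q \in [0.2, 0.65]$ or $\epsilon \in [0.001, 0.25]$, and
$\Delta t \in [10, 150]$ ms).

Three numerical choices deserve explanation:

* **Deterministic evaluation seeds.** Each objective evaluation derives
  its simulation seed from the base seed and the parameter point
  (`derive_eval_seed()`), so re-evaluating a point replays the same
  simulations and the optimizer sees a deterministic surface. Without
  this, Nelder–Mead convergence is noise-dominated.
* **Coarse scan before simplex refinement.** When the target is itself
  lattice-valued (every simulated RT is a multiple of the generating
  $\Delta t$), the objective along $\Delta t$ is *combed*: it dips
  sharply wherever the model's time lattice aligns with the target's,
  superimposed on a smooth large-scale valley. A generic simplex with
  magnitude-derived step sizes either misses the dip or collapses the
  poorly scaled $\epsilon$ axis (span 0.25 against a $\Delta t$ span of
  140). `fit_model()` therefore first scans a deterministic grid
  (3 continuous values × a 10 ms $\Delta t$ grid) and then runs a
  Nelder–Mead with explicit per-dimension initial steps from the best
  scan point, the box centre, and further distinct scan points.
  Proposals outside the box are clamped with a quadratic penalty, so
  the returned optimum is always inside the space. Real RT data are
  not lattice-valued, so for them the coarse scan is merely a cheap
  global-search stage.
* **Failed evaluations score $\ln 2$.** In nearly sealed corners of the
  box (large $R$, $q$ near 0.65) the connectivity budget can be
  exhausted; the evaluation then scores the maximal JSD instead of
  aborting the whole fit. A fit fails only if every evaluation at some
  radius fails.

Walks that would outlast the histogram's overflow bin are censored into
it (`absorb_cap_steps`), which leaves the binned objective unchanged
while bounding the cost of deep-tail parameter points. Because every
walk has its own RNG substream, censoring one walk cannot perturb the
others — a property the test suite asserts bitwise.

## What the synthetic cohort emulates — and what it does not

`gen_cohort()` produces desk-scale move tables with the structure the
population analyses need: players with uniform ratings on
$[1000, 2000]$, affine rating→parameter maps clipped to the search box
(defaults: obstacle fraction rising 0.30→0.60 across the rating range,
radius falling 6→3, $\Delta t$ flat at 90 ms — the expertise structure
in which stronger players prune more aggressively and search to a
shorter effective depth at an unchanged per-step cost), 300 s budgets,
and games that end when a drawn RT would overrun the clock (that draw
is dropped and logged). Ground-truth parameters live in a separate
`truth` table so recovery tests cannot leak them.

It deliberately does **not** emulate: chess semantics (openings,
opponent adaptation, position-dependent difficulty), rating dynamics
(ratings are static covariates), instant-dependent parameters within
the middle game, or the $15 \times 10^6$-game scale of the corpora the
method was developed on. A green cohort test therefore establishes that
the pipeline recovers planted population structure at desk scale — not
that any particular empirical population has that structure.

## Population analyses

* `filter_middle_game()` keeps decisions with remaining-time fraction
  in the closed interval $[0.1, 0.9]$ (for 300 s: between 270 s and
  30 s on the clock), excluding standardized openings and endgame time
  pressure. "Between" is read as closed because the source convention
  is unstated; the difference is a measure-zero set of records.
* `fit_per_instant()` fits each remaining-time bin independently;
  undersized bins (default < 500 records) are skipped and reported
  rather than pooled, because desk-scale corpora cannot populate 0.1 s
  instants.
* `quintile_analysis()` sorts records by rating and cuts them into
  groups of equal *record* counts (sizes differ by at most one; the
  equal-games convention, not equal-players). It fits the obstacles
  model per group and reports Pearson correlations of each fitted
  parameter with group mean rating, with raw two-sided p-values (no
  multiple-testing correction, mirroring standard practice for three
  planned comparisons). With all ratings equal the correlation is
  reported as `NA` rather than an error.
* `similarity_rank_correlation()` asks, for each player, whether
  ranking the other players by JSD to the player's *real* histogram and
  to the player's *fitted* histogram gives the same ordering
  (Spearman, average ranks on ties).

## Tunable parameters at a glance

| parameter | meaning | default | range |
|---|---|---|---|
| `radius` ($R$) | absorbing-boundary radius, grid steps | — | 1..10 searched |
| `density` ($q$) | obstacle fraction of interior nodes | — | [0.2, 0.65] searched |
| `epsilon` ($\epsilon$) | DDM acceptance noise | — | [0.001, 0.25] searched |
| `dt_ms` ($\Delta t$) | milliseconds per iteration | — | [10, 150] searched |
| `sims_per_eval` | simulated decisions per objective evaluation | 75,000 | ≥ 5,000 for recovery |
| `bin_width`, `cap` | RT histogram convention (s) | 0.1, 300 | configurable |
| `max_retries` | connectivity resampling budget | $10^4$ ($10^3$ in fits) | — |
| `step_cap` | runaway-walk guard | $10^7$ | error, never truncation |

The $\epsilon$ lower bound is clipped to $10^{-3}$: at $\epsilon = 0$
the acceptance rule is degenerate off-axis (every non-outward proposal
has probability $e^{-C/\epsilon} \to 0$), and the printed lower bound 0
cannot have been meant literally.

## Known limitations

* $\epsilon$ is weakly identified near the top of its box: around the
  representative DDM triple the JSD differences across
  $\epsilon \in [0.15, 0.25]$ are of order $10^{-4}$ nats, so recovery
  of $\epsilon$ needs large per-evaluation budgets (the recovery
  experiment uses 75,000) and still carries ~0.02 spread across seeds.
* Annealed batches at $q \gtrsim 0.6$ and large $R$ spend most of their
  time resampling sealed realizations; the fitting path caps that cost
  by scoring such points $\ln 2$ after 1,000 retries.
* The per-instant and per-player analyses assume enough records per
  unit (defaults: 500 per instant bin, 20,000 games per player) —
  thresholds inherited from a corpus four orders of magnitude larger
  than anything generated here; desk-scale runs must lower them.
* No comb-geometry analytic solution and no 2-D analytic FPT with
  obstacles are provided (none exists); the tail-slope diagnostic
  `tail_log_slope()` stands in for tail-class comparisons.
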