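# gridrt

Lattice diffusion models of response times with entropic barriers.

## The problem

Classical models of simple two-choice decisions describe response times
(RT) as the first-passage time (FPT) of a noisy evidence accumulator —
a drift-diffusion process run to a threshold. Real decisions among many
alternatives (a chess move, a product choice) are instead a search
through a branching space in which most paths are pruned or dead-end.
Their RT distributions carry a signature of that search: tails that are
neither the exponential of a bounded diffusion nor the
$t^{-3/2}$ power law of a free one.

gridrt implements two generative models of such RTs as random walks on
a 2-D lattice with a circular absorbing boundary of radius $R$ (grid
steps), each iteration costing $\Delta t$ milliseconds:

* **obstacles model** — an unbiased walker among reflecting nodes
  ("entropic barriers") scattered with density $q$; a blocked move
  leaves the walker in place and still costs $\Delta t$.
  Parameters $(R, q, \Delta t)$.
* **grid DDM** — an obstacle-free walker whose proposed step $\hat z_p$
  at displacement $\hat z$ is accepted with probability
  $e^{-C/\epsilon}$, $C = (1 - \hat z\cdot\hat z_p)/2$ — a biased walk
  to a threshold. Parameters $(R, \epsilon, \Delta t)$.

Fitting minimizes the Jensen–Shannon divergence between the binned
target RT distribution and a simulated model distribution
(0.1 s bins over a 300 s budget, 75,000 simulated decisions per
parameter point by default), with exhaustive search over the radius and
Nelder–Mead refinement over the continuous parameters under common
random numbers. The package also ships exact validation oracles
(absorbing-Markov-chain FPT distributions, discrete exit times, 1-D
closed forms), cross-validated model comparison, population analyses
(per-instant fits, per-player fits, similarity rankings, rating-quintile
parameter correlations), a synthetic RT-corpus generator, and a CLI.

It is aimed at researchers in computational cognitive science who want
to fit or compare first-passage models of RT distributions, or to test
analysis pipelines for large behavioral corpora at desk scale.

## Worked example

Simulate 75,000 decisions at the representative mid-game obstacles
triple (R = 4, q = 0.45, dt = 90 ms), then recover the parameters by
JSD minimization from the binned sample alone:

```r
library(gridrt)

truth  <- representative_fits()$obstacles
target <- bin_rt(gen_rt_sample(truth, 75000, seed = 101))
fit    <- fit_model("obstacles", target,
                    fit_space(sims_per_eval = 5000), base_seed = 102)
fit
#> <fit_result> obstacles model: R = 4, q = 0.433, dt = 90.0 ms | JSD = 0.0113 nats, KS D = 0.023 (1562 evals, 65.8 s)
```

The fit searched radii 1..10 exhaustively and recovered the generating
triple: radius exactly, obstacle density within 0.02, time-per-step
exactly. The JSD of ~0.01 nats is the Monte-Carlo floor of comparing
two finite histograms (75,000 target vs 5,000 per-evaluation samples);
the KS statistic says the fitted and target distribution functions
never differ by more than ~2%.

Population-level expertise analysis on a synthetic cohort whose
generator plants rising obstacle density and falling radius in rating:

```r
cohort <- gen_cohort(cohort_config(seed = 3))
mid    <- filter_middle_game(cohort$moves)
qa     <- quintile_analysis(mid, n_groups = 5,
                            space = fit_space(radius_values = 2:8,
                                              sims_per_eval = 1500),
                            base_seed = 11,
                            control = fit_control(n_starts = 2, maxit = 20,
                                                  coarse_dt_ms = 20))
qa$correlations
#>  parameter   estimate    p_value
#>    density  0.9496178 0.01347224
#>      dt_ms -0.1744915 0.77896315
#>     radius -0.9255933 0.02409040
```

The quintile fits recover the planted signs: obstacle density rises
with rating (r = 0.95), radius falls (r = −0.93), time per step shows
no trend — stronger players prune more and search a shorter effective
depth at an unchanged per-step cost.

A command-line interface mirrors the R API
(`simulate`, `fit`, `compare`, `cohort`, `synth`):

```sh
Rscript inst/cli/gridrt.R simulate --model obstacles --radius 4 \
  --density 0.45 --dt 90 --n 75000 --seed 1 --out rt.csv
Rscript inst/cli/gridrt.R fit --target rt.csv --model obstacles \
  --seed 2 --out fit.json
```

## Package layout

* `R/`, `src/` — parameter/grid types, Rcpp walkers, exact references,
  distribution statistics, fitting, cohort analyses, synthetic data, CLI.
* `tests/testthat/` — unit + property tests per module and
  `test-acceptance.R` with the acceptance criteria.
* `vignettes/gridrt-methods.Rmd` — the models, numerical choices, and
  what the synthetic data does and does not establish.
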