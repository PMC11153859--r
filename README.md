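# valuelink

Hierarchical modelling of value learning and value-driven visual search.

`valuelink` is for researchers in decision neuroscience and cognitive aging
who study how monetary value, once associated with neutral stimuli (e.g.,
faces), changes later attention to those stimuli — and how the underlying
computational parameters differ between young and older adults. It
implements the full analysis chain for a two-task design:

1. **Associative learning task** — 300 trials of paired choices over three
   face pairs (reward, punishment, zero-outcome conditions) with an 80/20
   feedback contingency, modelled by a dual-learning-rate Rescorla–Wagner
   rule with softmax choice:

   EV ← EV + η·(outcome − EV),  P(choose a) = e^{τ·EV_a} / (e^{τ·EV_a} + e^{τ·EV_b}),

   with separate learning rates η_r, η_p and inverse temperatures τ_r, τ_p
   for reward and punishment.

2. **Visual search task** — 192 trials (target-present/absent) whose
   target-present response times are modelled as a Wiener diffusion process
   with condition-specific boundary separation α and drift rate ν, shared
   non-decision time t0, and start point fixed at z = 0.5. The likelihood is
   the first-passage-time density, evaluated by adaptive small-time /
   large-time series expansions.

3. **Hierarchical Bayesian estimation** of both models
   (Metropolis-within-Gibbs with slice-sampled scales and interweaving
   moves; split R-hat diagnostics; posterior predictive checks), and

4. **Cross-model linking** — per-individual posterior modes (KDE argmax),
   Spearman rank correlations between the two parameter sets with the
   conservative |r| > 0.30 flag, young-vs-old group contrast posteriors,
   and block-wise learning curves.

Because the original participant data are not redistributable, the package
ships a first-class synthetic-cohort generator
(`population_hyper()`, `generate_study()`) with known ground truth, so each
inference stage is validated by parameter recovery. See the methods
vignette (`vignettes/valuelink-methods.Rmd`) for the models, priors,
samplers and design decisions.

## Worked example

```r
library(valuelink)

# synthetic study: 12 young + 12 older participants
cfg <- study_config(n_young = 12L, n_old = 12L)
study <- generate_study(cfg, seed = 20)

# learning curves for the young group, 20-trial bins
lc <- learning_curves(study$learning[study$learning$group == "young", ],
                      block_size = 20L)
print(subset(lc, condition == "reward"), row.names = FALSE)
#>  condition bin proportion          se n_participants
#>     reward   1  0.7333333 0.061030709             12
#>     reward   2  0.9208333 0.034519611             12
#>     reward   3  0.9791667 0.009649802             12
#>     reward   4  0.9958333 0.004166667             12
#>     reward   5  0.9958333 0.004166667             12
```

The proportion of target choices in the reward condition climbs from 0.73
in the first 20 trials to over 0.99 by the last bin: the simulated cohort
learns the contingency. Fitting the learning model:

```r
young <- study$learning[study$learning$group == "young", ]
fit <- fit_rl(young, mcmc_config(600, 600, 4, seed = 3))
print(fit)
#> Hierarchical dual-learning-rate RW model fit
#>   participants: 12   chains: 4   kept iterations: 600
#>   convergence: all R-hat <= 1.05 (max split R-hat = 1.026)
#>
#> Group-level posterior (natural scale):
#>  parameter   mean   mode           95% CI  rhat
#>      eta_r  0.039  0.033   [0.016, 0.075] 1.018
#>      eta_p  0.143  0.131   [0.071, 0.237] 1.008
#>      tau_r 10.661  9.313  [6.943, 19.253] 1.019
#>      tau_p  5.025  4.718   [3.227, 7.524] 1.008
#>   eta_diff -0.104 -0.089 [-0.200, -0.023] 1.016
#>   tau_diff  5.636  4.539  [1.005, 14.373] 1.026
```

The group-level posterior recovers the generating regime (the young preset
centres η_r at 0.05, η_p at 0.12, τ_r at 7.98, τ_p at 4.50): the punishment
learning rate exceeds the reward learning rate (`eta_diff` credibly below
zero) while the reward inverse temperature exceeds the punishment one. The
generator's ground truth lets you score recovery directly:

```r
est <- coef(fit)   # posterior means of individual parameters
truth <- study$truth[study$truth$group == "young", ]
cor(truth$eta_r, est[, "eta_r"])
#> recovery cor (eta_r): 0.64
```

The diffusion model fits the young group's target-present search trials:

```r
present <- study$search[study$search$group == "young" &
                          study$search$target_present == 1, ]
dfit <- fit_ddm(present, mcmc_config(600, 600, 4, seed = 4))
print(dfit)
#> Hierarchical Wiener diffusion model fit (z fixed at 0.5)
#>   participants: 12   chains: 4   kept iterations: 600
#>   convergence: all R-hat <= 1.05 (max split R-hat = 1.019)
#>
#> Group-level posterior:
#>         parameter  mean  mode         95% CI  rhat
#>      alpha_reward 1.654 1.649 [1.449, 1.877] 1.000
#>  alpha_punishment 1.810 1.800 [1.660, 1.972] 1.002
#>        alpha_zero 1.548 1.530 [1.397, 1.726] 1.003
#>         nu_reward 1.344 1.296 [0.916, 1.784] 1.000
#>     nu_punishment 1.545 1.538 [1.318, 1.778] 1.008
#>           nu_zero 1.507 1.519 [1.224, 1.815] 1.007
#>                t0 0.337 0.338 [0.329, 0.344] 1.014
```

t0 lands on the generating non-decision time (0.36 s preset, with the
population parameter tracking the cohort's faster tail), and the α and ν
posteriors bracket their generating values. Finally, the linking table:

```r
ct <- correlation_table(individual_modes(fit), individual_modes(dfit))
print(ct)
#> Spearman rank correlations between posterior modes (* = |r| > 0.30):
#>                  eta_r  eta_p  tau_r  tau_p
#> alpha_reward     +0.15  -0.18  +0.01  -0.34*
#> alpha_punishment +0.33* -0.15  +0.06  +0.08
#> alpha_zero       +0.21  -0.04  +0.06  -0.29
#> nu_reward        +0.38* -0.49* +0.38* -0.55*
#> nu_punishment    -0.34* +0.24  -0.37* +0.33*
#> nu_zero          +0.31* -0.04  +0.14  +0.06
```

In this cohort the generator couples nothing across the two tasks, so
flagged cells at n = 12 illustrate exactly why the |r| > 0.30 criterion
needs cautious reading at small samples — the null distribution of |r| is
wide. The test suite quantifies both sides: planted couplings are detected,
and the false-flag behaviour of independent parameters matches the
permutation null.

`run_pipeline()` chains all of the above (simulate or ingest CSVs → fit
both models per group → posterior predictive checks → contrasts → linking
table → recovery scorecard) into one seeded, manifest-tracked run, and
`report_run()` renders a markdown report. A thin command-line wrapper lives
at `inst/scripts/valuelink.R`.

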