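# nmfdl

Vague-to-crisp mixture-model estimation with neural modeling fields and
dynamic logic.

Perception-like inference problems — finding a handful of structured
events in a sea of noise, or a handful of meaningful object combinations
among random co-occurrences — are combinatorially hard if every
data-to-model assignment must be enumerated.  Dynamic logic avoids the
enumeration: a small set of parametric *concept models* starts maximally
vague, competes for evidence through soft association variables, and
sharpens ("crispens") only as its parameter estimates improve.  `nmfdl`
implements this estimation engine for R, for researchers in computational
cognitive modeling and for anyone who needs annealed mixture fitting with
data-driven model activation, merging and pruning.

## The model

The engine maximizes the total similarity between top-down model
predictions and bottom-up signals,

```
log L = sum_n log sum_m r(m) l(n|m),
```

with conditional similarities `l(n|m)` (Gaussian or Bernoulli densities),
association variables

```
f(m|n) = r(m) l(n|m) / sum_m' r(m') l(n|m'),
```

f-weighted maximum-likelihood parameter updates (the fixed point of the
dynamic-logic parameter flow), closed-form rate updates
`r(m) = sum_n f(m|n)/N`, and a skeptic penalty `log L - kappa * k` (k =
total free parameters) that governs model activation, merging and
pruning.  Every iteration is an EM step, so the log-similarity trace is
non-decreasing.

Three model families ship with the engine:

* **Phase cones** — expanding or contracting Gaussian-profile rings
  `a exp(-(rho - R(t))^2 / 2w^2)` on a sensor array, fitted in heavy
  noise next to a background clutter component (the simulated-EEG event
  detection demonstration);
* **Situations** — Bernoulli object-presence vectors learned from binary
  situation-by-object matrices, where half the rows are pure clutter;
* **Dual language/cognition models** — paired Bernoulli channels sharing
  one association variable, used to show that a clean ("ready-made")
  language channel crispens first and rescues concept learning when the
  cognitive channel is too noisy on its own.

## Worked example

Simulate the three-event sensor-array scene (64 x 64 sensors, 40 time
steps of 5 ms, two expanding and one contracting cone, per-sample SNR 1)
and recover the events:

```r
library(nmfdl)

gen <- generate_phase_cones(figure_scene(seed = 1))
fit <- fit_cones(gen$data, n_models = 8, seed = 1)
classify_events(fit)
#>   expanding contracting
#>           2           1
recovery_metrics(fit, gen$truth)$matches[, c("center_error", "t0_error", "v_error")]
#>   center_error  t0_error     v_error
#> 1   0.04108631 0.1107426 0.005381690
#> 2   0.09928623 0.1710771 0.008986264
#> 3   0.06691633 0.0000000 0.004994480
first_matched_iteration(fit, gen$truth)
#> [1] 4
```

All three events are found — centers within 0.1 sensor units, speeds
within 0.01 sensor-units/step, onsets within 0.2 steps — by the fourth
outer iteration, out of a search space that a direct assignment
enumeration could never cover.

Learning situations from binary co-occurrence data (16,000 situations,
1,000 objects, half clutter, 20 initial models):

```r
g <- generate_situations(situation_gen_config(seed = 1))
fit <- fit_situations(g$data, n_models = 20, seed = 1)
sets <- relevant_object_sets(fit, 10)
all(sapply(g$truth$relevant_sets,
           function(ts) any(sapply(sets, identical, ts))))
#> [1] TRUE
head(recovery_error_trace(fit, g$truth), 5)
#>   iteration       error
#> 1         0 0.019770978
#> 2         1 0.018223694
#> 3         2 0.012354840
#> 4         3 0.007865025
#> 5         4 0.005941458
```

All ten planted relevant-object sets are read off exactly, and the
recovery error collapses to its plateau within three iterations (it stays
slightly above zero because probabilities are clamped away from 0 and 1).

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/nmfdl.R", package="nmfdl"))')" \
    simulate-cones --seed 7 --out-dir out
```

Subcommands: `simulate-cones`, `fit-cones`, `evaluate-cones`,
`simulate-situations`, `fit-situations`, `evaluate-situations`,
`simulate-dual`, `fit-dual`, `dual-advantage`.  `--seed` is mandatory for
every stochastic subcommand; bad inputs exit with status 2.

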