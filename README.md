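# nticell

Information-theoretic analysis of individuality in small clonal
communities of motile cells.

## What this package is for

When a single ciliate founder divides synchronously to the eight-cell
stage inside a sealed microchamber, every cell can be tracked
continuously and reduced to one dynamical observable, the
kinetic-energy proxy `KE(t) = 0.5 v(t)^2`.  Each cell k also lives
inside a sibling mean-field `C_t = mean of the other cells' KE`.
`nticell` asks where the predictive structure of each cell's future
resides, using **non-trivial information closure**:

```
NTIC = I(X_{t+1}; X_t) - I(X_{t+1}; X_t | C_t)
     = I(X_{t+1}; C_t) - TE(C -> X)
```

the portion of a cell's self-predictive information that is redundant
with its collective context.  Cells are classified per life-history
phase against their own 50-permutation surrogate null:

| MI(X′;C) significant | NTIC vs surrogate band | category |
|---|---|---|
| yes | above | coupled |
| yes | within | information-closed |
| yes | below | synergistic |
| no  | within | independent |
| no  | outside | anomalous (excluded) |

On top of the classifier the package provides the minimal-MI partial
information decomposition fingerprint (`Rdn = min(I(X;X'), I(C;X'))`,
`Syn = Rdn − NTIC`), Jensen–Shannon inheritance-fidelity statistics
across parent–daughter pairs (Kruskal–Wallis, Mann–Whitney with
Bonferroni correction and rank-biserial effect sizes), temporal
coarse-graining robustness sweeps, and a synthetic binary-fission
community generator with controllable ground-truth regimes used by the
whole test suite.  Estimators are Kraskov k-nearest-neighbour MI and
Frenzel–Pompe conditional MI (k = 8, bits, Theiler exclusion window for
serially correlated series), implemented in C++.

It is aimed at quantitative biologists analysing single-cell tracking
of interacting communities, and at anyone needing a tested NTIC /
transfer-entropy / surrogate-classification pipeline for short
univariate time series with a collective context.

## Worked example

Simulate a four-generation lineage whose first two generations are
coupled and whose last two are information-closed, then classify the
eight-cell stage in the middle phase:

```r
library(nticell)

lin <- simulate_lineage(generations = 3, frames_per_generation = 45000,
                        seed = 3)
specs <- list(`0` = regime_spec("coupled"),
              `1` = regime_spec("coupled"),
              `2` = regime_spec("information_closed"),
              `3` = regime_spec("information_closed"))
bun <- simulate_community(lin, specs, seed = 3)
bun
#> <series_bundle> 15 cells, 4 generations, seed 3
#>   regimes by generation:  coupled / coupled / information_closed / information_closed

cls <- classify_bundle(bun, estimator_config(), phases = "middle",
                       generations = 3, seed = 3)
cls[1:4, c("cell_id", "mi_self", "mi_ctx", "ntic", "mi_threshold",
           "ntic_lower", "ntic_upper", "category")]
#>   cell_id mi_self mi_ctx     ntic mi_threshold ntic_lower ntic_upper            category
#> 1       7   0.761 0.0394  0.03312       0.0188   -0.01267     0.0213             coupled
#> 2       8   0.833 0.0336 -0.00328       0.0200   -0.01942     0.0155 information_closure
#> 3       9   0.731 0.0575  0.01099       0.0162   -0.01529     0.0154 information_closure
#> 4      10   0.851 0.0353  0.02006       0.0213   -0.00768     0.0240 information_closure
```

Every cell shares information with its siblings (`mi_ctx` above its own
threshold) while self-prediction dominates (`mi_self` an order of
magnitude larger), and NTIC sits inside or near its surrogate band — the
closure signature.  Aggregating:

```r
phase_regime_table(cls)
#>   phase  category            n_cells fraction
#> 1 middle coupled                   1    0.125
#> 2 middle information_closure       6    0.75
#> 3 middle synergistic               1    0.125
#> 4 middle independent               0    0
#> 5 middle anomalous                 0    0
```

The modal category recovers the designed regime; the synergistic
minority reflects per-cell estimator scatter around a band whose width
is itself estimated from 50 permutations (see the vignette for why
single-cell assignments are noisier than community-level ones).
Inheritance fidelity across the generation transitions:

```r
dists <- bundle_distributions(bun)
pairs <- fidelity_pairs(lin, dists)
dplyr::group_by(pairs, transition) |>
  dplyr::summarise(mean_jsd = mean(jsd))
#>   transition mean_jsd
#> 1 gen0->1      0.112
#> 2 gen1->2      0.0770
#> 3 gen2->3      0.0576
```

Lower Jensen–Shannon divergence means a daughter preserved its parent's
kinetic-energy distribution more faithfully.  The information-closed
generations (2 and 3) were generated with a wider heritable
perturbation, and `fidelity_by_regime()` tests exactly that contrast on
classified daughters.

A configuration-driven runner ties the stages together and writes CSV /
JSON artifacts plus run manifests:

```r
cfg <- pipeline_config(seed = 1, out_dir = "run1")
run_pipeline(cfg, "simulate")
run_pipeline(cfg, "classify")
run_pipeline(cfg, "inherit")
run_pipeline(cfg, "sweep")
run_pipeline(cfg, "report")
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/nticell-pipeline.R`:

```sh
Rscript inst/scripts/nticell-pipeline.R simulate --config run.yaml
```

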