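# radflux

Generalized radiation models for predicting human mobility fluxes between
locations — for epidemiologists, transport modellers and urban scientists who
need an origin–destination (OD) trip matrix from population and distance data
alone, or who want to fit and validate a mobility model against an observed
OD network.

## The model

The radiation model predicts the flux from location *i* to location *j* from
three quantities only: the origin population *m_i*, the destination
population *n_j*, and the intervening population *s_ij* — the total
population strictly inside the circle of radius *d_ij* centred at the origin.
The original, parameter-free transition probability is

```
p_ij = m_i n_j / ((m_i + s_ij) (m_i + n_j + s_ij))
```

`radflux` implements the generalized family built on two modelling choices:

* **Searching direction** — *intervention-based* (opportunities are judged
  from the origin; kernel `p_ij`, circle centred at *i*) or
  *competition-based* (origins compete for demand emitted by the
  destination; kernel `q_ij = n_j m_i / ((n_j + s_ji)(n_j + m_i + s_ji))`,
  circle centred at *j*).
* **Trip OD constraint** — *production-constrained* (predicted outflows match
  observed `T_i`) or *attraction-constrained* (predicted inflows match
  observed `T_j`).

The four combinations are the PIR, PCR, AIR and ACR variants. Each raises
its kernel to a system-specific scaling exponent **λ** before normalization,

```
PIR:  T_ij = κ T_i p_ij^λ / Σ_{k≠i} p_ik^λ        (similarly PCR/AIR/ACR)
```

and rescales by a normalization factor **κ** so total predicted flux matches
total observed flux on a chosen OD-pair support (by default the observed
pairs, because empirical OD networks are sparse). λ is estimated by grid
search (default `λ = 0, 0.1, …, 1`) maximizing the Sørensen–Dice flux
similarity

```
SSI = 2 Σ_ij min(T_ij^model, T_ij^data) / (Σ_ij T_ij^model + Σ_ij T_ij^data),
```

1 for a complete match and 0 for disjoint supports. The validation battery
adds the Pearson correlation on observed pairs, trip-distance and
trip-population distributions with two-sample Kolmogorov–Smirnov tests,
binned flux coverage, and a phase-space error grid over (distance,
destination population).

## Worked example

The package ships a synthetic fixture: 60 locations with lognormal
populations on a 100 km square, an observed network sampled multinomially
from a PIR ground truth with λ\* = 0.5 (20,000 trips per origin), then
sparsified to the top 20 % of OD pairs by flux.

```r
library(radflux)
system   <- read_locations(system.file("extdata", "synth60_locations.csv",
                                       package = "radflux"))
observed <- read_flows(system.file("extdata", "synth60_flows_top20.csv",
                                   package = "radflux"), system)
d   <- pairwise_distances(system)
s   <- intervening_population(system, d)

sel <- select_best_model(system, s, observed)
for (f in sel$all_fits) print(f)
#> <fit_result> PIR: best lambda = 0.6 (Sorensen = 0.8241, kappa = 1.2438)
#> <fit_result> PCR: best lambda = 0.6 (Sorensen = 0.5987, kappa = 1.3570)
#> <fit_result> AIR: best lambda = 0.7 (Sorensen = 0.8029, kappa = 1.1554)
#> <fit_result> ACR: best lambda = 0.6 (Sorensen = 0.5722, kappa = 1.2950)

pred <- predict_generalized(system, s,
          model_spec(sel$variant, sel$fit$best_lambda, sel$fit$best_kappa),
          observed)
print(evaluate_model(pred, observed, system, d))
#> <eval_report> Sorensen = 0.8241, PCC = 0.9962
#>   KS distance:   D = 0.1313, p = 0.9786 (same)
#>   KS population: D = 0.0194, p = 1.0000 (same)
#>   flux bins covered: 6 / 6
```

The winning variant is the true generating family (PIR). The fitted
λ̂ = 0.6 sits one grid step above the ground truth λ\* = 0.5: keeping only
the strongest 20 % of pairs biases the observed network toward concentrated
flows, which a slightly larger exponent mimics — on the unsparsified network
the fit recovers λ\* to within one grid step (see the test suite). κ > 1
compensates for the flux removed by sparsification, and κ decreases as λ
grows (the κ–λ anticorrelation). The KS tests accept both the distance and
the population distribution at the 5 % level, and the prediction's 5th–95th
percentile band covers the diagonal in every observed-flux bin.

## Command line

```sh
radflux simulate --n 60 --lambda 0.5 --trips 20000 --seed 7 --out data/
radflux fit      --locations data/locations.csv --flows data/flows.csv \
                 --variant PIR --out results/
radflux evaluate --locations data/locations.csv --flows data/flows.csv \
                 --predicted results/prediction.csv --out results/
```

(`inst/exec/radflux` is the launcher; equivalently call
`radflux::radflux_cli(c("fit", ...))`.)

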