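---
title: "Generalized radiation models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized radiation models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radflux)
```

## The model family

The radiation model explains commuting as a two-step opportunity search: an
individual at origin *i* evaluates opportunities proportional to population
and accepts the closest one whose benefit beats the best available at home.
Integrating over the benefit distribution gives the transition probability

$$p_{ij} = \frac{m_i\,n_j}{(m_i + s_{ij})(m_i + n_j + s_{ij})},$$

where $m_i$, $n_j$ are origin and destination populations and $s_{ij}$ is
the *intervening population*: the total population of third locations
strictly inside the circle of radius $d_{ij}$ centred at the origin,
excluding origin and destination. Distance enters only through the ranking
of opportunities, which is what distinguishes radiation from gravity models.

`radflux` generalizes this in three directions:

1. **Scaling exponent $\lambda$.** The kernel is raised to a power
   $\lambda \ge 0$ before normalization. $\lambda$ absorbs
   system-specific distance-decay behaviour: $\lambda = 1$ recovers the
   original ranking sensitivity, $\lambda = 0$ allocates uniformly over all
   partners with positive kernel, and intermediate values interpolate.
   Intra-urban systems typically need $\lambda < 1$.
2. **Searching direction.** The *intervention* kernel $p_{ij}$ evaluates
   destinations from the origin's viewpoint. The *competition* kernel
   $$q_{ij} = \frac{n_j\,m_i}{(n_j + s_{ji})(n_j + m_i + s_{ji})}$$
   reverses the search: demand is emitted by the destination and origins
   compete for it, so the circle is centred at the destination ($s_{ji}$).
3. **Trip OD constraint.** Production-constrained variants allocate each
   origin's observed outflow $T_i$ across destinations
   ($T_{ij} = \kappa T_i w_{ij}/\sum_{k \ne i} w_{ik}$ with
   $w = p^\lambda$ or $q^\lambda$); attraction-constrained variants allocate
   each destination's observed inflow $T_j$ across origins (column
   normalization). The four combinations are PIR, PCR, AIR and ACR.

The original model assumes an infinite system in which
$\sum_j p_{ij} = 1$. In a finite system with distinct distances the sum
telescopes to $1 - m_i/M$ (with $M$ the total population), so unconstrained
predictions leak flux; moreover observed OD networks are sparse, so summing
predictions over all pairs understates what the observed pairs carry. Both
finite-size and sparsity corrections are folded into the **normalization
factor** $\kappa$ = (total observed flux) / (total unscaled predicted flux
over a support). The default support is the observed pairs; with
`kappa_support = "all_pairs"` and $\lambda = 1$, PIR reproduces the
finite-size-normalized original model exactly (the row normalization is then
precisely $1 - m_i/M$), a property the test suite asserts numerically.

## Fitting

$\lambda$ is estimated by explicit grid search (default
$\lambda = 0, 0.1, \ldots, 1$) maximizing the Sørensen–Dice flux similarity

$$\mathrm{SSI} = \frac{2\sum_{ij}\min(T^{\mathrm{model}}_{ij},
T^{\mathrm{data}}_{ij})}{\sum_{ij} T^{\mathrm{model}}_{ij} +
\sum_{ij} T^{\mathrm{data}}_{ij}},$$

summed over the union of OD pairs. The Pearson correlation on observed
pairs is recorded along the grid for reporting, but never drives selection:
empirically it is high and flat in $\lambda$, with no usable peak, whereas
the Sørensen curve peaks cleanly. Ties break toward the smaller $\lambda$
(parsimony). $\kappa$ is derived per grid point, not searched. Variant
selection compares the per-variant best Sørensen values, with deterministic
tie-breaking in the order PIR, PCR, AIR, ACR. No continuous optimizer is
offered: the grid *is* the procedure, and users can refine it via `grid=`.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `lambda` grid | 0–1 by 0.1 | — | canonical search range; coarse enough to be honest about resolution |
| `kappa_support` | `observed_pairs` | — | observed networks are sparse; all-pairs deflates predictions on them |
| `tie_policy` | `strict` | — | "inside the circle" read as $d < d_{ij}$; keeps $s = 0$ for nearest neighbours, matching the standard construction |
| `marginal_source` | `population` | persons | kernel masses are census populations; `trips` substitutes observed marginals where populations are unavailable |
| Earth radius | 6371.0 | km | fixed so geographic distances are bit-reproducible |
| distance bins | 30 log-spaced | km | heavy-tailed trip lengths |
| population bins | decades | persons | heavy-tailed populations |
| phase grid | 20 × 20 log-spaced | km × persons | resolution of the error map |
| `alpha` | 0.05 | — | KS significance level |

## Numerical choices

* $s_{ij}$ is computed per origin by sorting the distance row once and
  accumulating population over tie groups — $O(N^2 \log N)$ overall — and is
  tested for exact equality against an $O(N^3)$ brute-force enumeration.
  The diagonal is `NA` by construction and never read; no variant emits
  intrazonal flux, and intrazonal observed flows are dropped on ingest with
  a message.
* $p^\lambda$ is evaluated as $\exp(\lambda \log p)$ with a $p = 0 \to 0$
  shortcut, so $\lambda = 0$ yields a uniform allocation over the partners
  with positive kernel rather than resurrecting impossible pairs.
* Kernels return 0 whenever the numerator vanishes, including the all-zero
  corner (documented convention, not an error). An origin (destination)
  whose whole allocation row (column) is zero while its constrained marginal
  is positive raises a classed error instead of silently dropping flux.
* Percentiles in the flux-coverage table use linear interpolation between
  order statistics (R quantile type 7). A bin is "covered" when the 5th–95th
  band of predictions overlaps the bin's observed-flux interval — i.e. the
  band straddles the diagonal somewhere in the bin. (An alternative reading,
  covering the bin's geometric midpoint, fails the obvious sanity case of an
  unbiased prediction band around observations at a bin edge.)

## The Kolmogorov–Smirnov convention

The validation battery compares *trip-weighted* distance and population
distributions. A literal two-sample KS test needs sample sizes; using raw
trip counts (order $10^5$–$10^7$) as $n$ would reject essentially always, at
which point the test is useless for model comparison. `radflux` instead
treats each nonempty bin as one observation:
$n_\mathrm{eff} = B_a B_b/(B_a + B_b)$ with $B$ the number of nonempty bins,
and the p-value from the asymptotic Kolmogorov distribution. This is a
deliberate, documented convention — p-values are comparable across models
and systems analysed with the same bin scheme, but are not reproducible
bit-for-bit against analyses using a different sample construction, and the
binned statistic slightly understates the true sup-distance.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` states one world: locations uniform on a 100 km planar
square; lognormal populations (meanlog 10, sdlog 1 — median ≈ 22,000
persons, a census-tract/ward scale, heavy-tailed like empirical settlement
sizes); trips sampled *multinomially* per constrained margin from a known
variant and $\lambda^*$ (20,000 trips per origin, a realistic commuter count
for such zones); optional sparsification, either the top fraction of pairs
by flux (emulating thresholded OD data products) or Bernoulli pair dropout.
Multinomial rather than Poisson sampling makes the constrained marginals
hold exactly in the sample, so conservation tests are sharp.

Real systems differ in ways the generator deliberately ignores: spatial
autocorrelation of population (cities cluster), zone-size heterogeneity,
road-network rather than crow-flight distances, distance-dependent
observation bias, and temporal structure. A green recovery test therefore
establishes that the estimator recovers $\lambda^*$ under the model's own
assumptions — not that any empirical system satisfies them.

The bundled fixture (`synth60_*`, seed 42) is this world with PIR,
$\lambda^* = 0.5$, sparsified to the top 20 % of pairs. On it the fitted
$\hat\lambda$ is 0.6: retaining only the strongest flows is itself a
concentration filter that a slightly larger exponent imitates. On the
unsparsified network $\hat\lambda$ falls within one grid step of
$\lambda^*$ in ≥ 95 % of seeded replicates for
$\lambda^* \in \{0.2, 0.5, 0.8\}$ (test suite, criterion 6). The same
fixture exhibits the negative Spearman correlation between $\lambda$ and
$\kappa(\lambda)$: as $\lambda$ concentrates predictions onto the strong —
hence observed — pairs, the observed-support denominator grows and $\kappa$
falls.

## Open design points, resolved

* **Competition-kernel normalization (PCR).** The PCR denominator sums
  $q_{ik}$ over candidate destinations $k \ne i$ with the circle centred at
  each candidate ($s_{ki}$), exactly as the kernel's definition implies; the
  numerator uses $s_{ji}$. A unit test pins the 4-location line fixture
  values so this reading is explicit and revisable.
* **Tie handling.** Equidistant third locations are excluded by the default
  strict policy; an inclusive policy is provided, and both are oracle-tested.
* **Distance mode.** Both planar (km) and geographic (haversine) inputs are
  supported, since empirical datasets come in both flavours; no map
  projections.
* **Gravity baseline.** A minimal production-constrained power-law form
  ($T_{ij} \propto T_i n_j r_{ij}^{-\beta}$) is included purely as a
  conventional comparison point and clearly flagged as such; it is not part
  of the radiation family and no fitting machinery is attached to $\beta$.

## Limitations

Predictions are singly constrained: PIR/PCR conserve outflows but not
inflows (and vice versa) — the trip-population distribution plus KS test
exists precisely to monitor the unconstrained margin. No
doubly-constrained (IPF/Furness) balancing, no intervening-opportunities or
population-weighted-opportunities baselines, no community-structure
comparison, and no figure rendering: the tabular data behind the standard
diagnostic figures (fit curves, distributions, coverage, phase grid) is
emitted as CSV/JSON instead.
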