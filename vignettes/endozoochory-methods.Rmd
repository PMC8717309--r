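---
title: "Models and methods: seed traits, phylogenetic mixed models, and moving-window connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: seed traits, phylogenetic mixed models, and moving-window connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endolink)
```

endolink analyses endozoochorous seed dispersal by a medium-sized
mammalian herbivore from three data sources: a per-species seed trait and
germination table from a controlled feeding experiment, a phylogeny of
the fed plant species, and hourly GPS tracks over a polygonal land-use
map. This vignette explains the models and the numerical and design
choices behind each stage; it states no result that the package's tests
or acceptance script do not themselves compute.

## Seed trait indices

For seed dimensions length $l$, width $w$, height $h$ (mm), mass $m$ and
volume $V$ (mm³), the package computes

* eccentricity $EI = l/w$ (elongation),
* flatness $FI = (l + w) / (2h)$,
* density $m/V$,
* dimensional shape variance
  $V_s = \frac{1}{3}\sum_i (x_i - \bar{x})^2$ with
  $x = (1,\, w/l,\, h/l)$ — zero for a sphere.

Mass is treated as an opaque unit: the packaged feeding-trial table
prints masses whose absolute scale is not internally resolvable, and all
derived ratios (density, area/mass) reproduce the printed columns from
the printed inputs without any unit conversion.

**Surface area.** Seeds below a shape-variance threshold are treated as
ellipsoids with semi-axes $(l/2, w/2, h/2)$; seeds above it as cylinders
of radius $(w+h)/4$ and length $l$. Two points deserve care:

* When $l$ is the longest dimension, $V_s \le 2/9 \approx 0.22$ (the
  maximum is attained as $w, h \to 0$). A threshold of 1 — the
  conventional phrasing of the rule — therefore never routes a seed to
  the cylinder branch. The threshold is exposed as `vs_threshold`
  (default 1, the literal convention) and the dead branch triggers a
  one-shot warning of class `endolink_dead_branch`; a reachable
  alternative (e.g. 0.1) is a documented option. Which convention
  produced any given published area column is generally not recoverable,
  so the branch actually taken is recorded per row in `area_branch`.
* No single "ellipsoid surface area formula" exists in closed form. The
  default is the Thomsen approximation
  $S \approx 4\pi \left( \frac{a^p b^p + a^p c^p + b^p c^p}{3}
  \right)^{1/p}$ with $p = 1.6075$ (max error ≈ 1.1%); `method =
  "quadrature"` integrates the exact surface integral numerically and is
  used as the cross-check oracle in the tests. The method used is
  recorded in the result's `method` attribute.

**Standardized germination success.** With $g_f$ seedlings from feces,
$n$ seeds fed and control germination capacity $c$ (%),
$$\mathrm{SGS} = 100 \cdot \frac{g_f}{(c/100)\, n}.$$
SGS is linear in $g_f$, equals 100 when feces germination matches the
expected germinable count, and can exceed 100 when gut passage stimulates
germination (the packaged table's maximum is 218.98% for *Poa annua*).
Species with $c = 0$ cannot be standardized; they are excluded from
modelling but can be counted as SGS = 0 in group summaries
(`zero_capacity = "zero"`), which is required to reproduce the printed
neophyte contrast.

The packaged table does not print feces seedling counts; `hare_seed_traits()`
recovers them by inverting the SGS formula and rounding to the nearest
integer. Every inversion lands within 0.05 of an integer and the counts
total 177, matching the experiment's reported total.

## Predictor screening

`screen_collinearity()` drops one member of every predictor pair with
$|r| >$ 0.7 (Pearson, on log-transformed predictors by default),
iterating greedily in matrix order and always discarding the
lower-priority member; the priority list defaults to the order given.
The result is independent of row order. On the packaged table with
priority (density, EI, area), flatness, mass and volume are dropped for
their correlation with area ($|r| = 0.98, 0.83, 0.93$ on the log scale);
the area/mass ratio never exceeds the threshold against any retained
predictor ($\max |r| = 0.68$, against mass) and is therefore retained by
the rule even though an investigator may still set it aside by choice.
`trait_pca()` is exploratory only: standardized PCA whose eigenvalues sum
to the number of predictors, used to inspect loadings before model
selection, never as a modelling step.

## The phylogenetic mixed model

The germination model is a Gaussian animal model on transformed scales:
$$y = X\beta + a + e, \qquad a \sim N(0, \sigma^2_p R), \qquad
  e \sim N(0, \sigma^2_e I),$$
with $y = \log(\mathrm{SGS} + 1)$ (zeros are data, not missingness),
$X$ an intercept plus log-transformed seed traits, and $R$ the
phylogenetic correlation matrix: the Brownian covariance $C$ (shared
root-to-tip path lengths, `phylo_vcv()`) standardized to unit diagonal
(`vcv_to_correlation()`). Correlation standardization is the default
because the source trees are maximum-likelihood trees in substitution
units, not ultrametric ones; raw $C$ can be supplied instead. Zero-length
terminal branches are nudged by $10^{-8} \times$ tree depth to keep $R$
invertible. Tip matching against the trait table is case-insensitive
with spaces and underscores unified — never fuzzy; mismatches are errors.
Pruning a tree to the modelled species keeps the path between the old
root and the retained clade's ancestor as a root edge, so pruning and
covariance computation commute exactly.

**Sampler.** `pmm_fit()` is a blocked Gibbs sampler with a flat prior on
$\beta$ and inverse-gamma(0.001, 0.001) priors on both variances
(configurable; the hyperparameters are deliberately weak). All updates
are performed in the eigenbasis of $R$: writing $R = U D U^\top$ and
$y^* = U^\top y$, both covariance structures become diagonal, so each
sweep costs $O(n)$ after one $O(n^3)$ eigendecomposition. The fixed
effects are drawn with the random effects integrated out
($\beta \mid \sigma^2$, a GLS draw under
$\Sigma = \sigma^2_p D + \sigma^2_e I$), then $a^* \mid \beta$, then the
two variances from conjugate inverse-gamma conditionals. The blocked
$\beta$ update avoids the poor mixing of the naive
$\beta \mid a$ / $a \mid \beta$ alternation when $\sigma^2_p$ is small.
Chains are deterministic given the seed; two chains are run by default
and effective sample sizes (initial positive sequence estimator) and
split-$\hat{R}$ are reported.

**Heritability.** Lynch's phylogenetic heritability is computed per draw,
$h^2 = \sigma^2_p / (\sigma^2_p + \sigma^2_e)$, and summarized by its
posterior mean and the narrowest interval containing 95% of the sorted
draws (HPD). For a model without the phylogenetic term $h^2 = 0$ by
construction.

**DIC.** The deviance uses the *marginal* Gaussian likelihood
$y \sim N(X\beta,\; \sigma^2_p R + \sigma^2_e I)$ — the random effects
are integrated out analytically — because the conditional deviance makes
the effective parameter count $p_D$ unstable for hierarchical models.
This differs from some mixed-model software, so published DIC values
from other implementations are comparable only qualitatively.
$\mathrm{DIC} = \bar{D} + p_D$ with
$p_D = \bar{D} - D(\bar{\theta})$. `pmm_dredge()` enumerates all $2^k$
predictor subsets (intercept-only included), ranks by DIC, breaks ties
by parameter count then predictor names, and flags models within 2 DIC
units of the best as competing; failed subsets are reported, not dropped.

**Chain lengths.** The package default (50,000 iterations, 5,000 burn-in,
thin 10) is a conservative desk-scale setting. The simulation studies in
the test suite use 4,000–10,000 iterations with 1–2 chains: the sampler
is conjugate and mixes within a few hundred sweeps at $n = 100$, and the
studies assert coverage and rank statistics, not tail quantiles. The
original field analysis's 5,000,000-iteration settings remain available
through the same arguments.

## Moving-window connectivity

Tracks are first reduced to hourly resolution: for each whole hour the
fix nearest the hour mark within ±10 min is kept, gaps are preserved,
nothing is interpolated. Fixes are then assigned to land-use patches by
point-in-polygon; fixes outside every patch belong to the agricultural
"matrix" and are excluded from connectivity counts (but kept for travel
distance). A fix on a shared boundary goes to the lexicographically
smallest patch id — an arbitrary but deterministic inclusive-edge rule.
Overlapping patches are a data error, reported with the offending ids.

A retention window of duration $T$ (5.6, 7, 8.4 h: the gut retention
mean ± CI of the hare) starting at fix $t_0$ contains the maximal run of
consecutive fixes in the closed interval $[t_0, t_0 + T]$, truncated at
any gap longer than the fix interval. With hourly fixes a fractional $T$
cannot align with the sampling grid; the closed-interval rule resolves
this deterministically ($T = 5.6$ h admits $\lfloor 5.6 \rfloor + 1 = 6$
fixes). Per window the package counts distinct land-use types and
distinct patches per type, and sums consecutive-step Euclidean lengths
(cumulative path length by default; net displacement via
`travel_mode = "net"` — published "distance traveled" figures are
ambiguous between the two, so both are first-class).

`connectivity_summary()` averages these quantities over *full-span*
windows per individual and retention time, then across individuals
(mean ± SD). Windows truncated by the track end or by gaps hold fewer
fixes and would bias per-window counts downward, so they are excluded
whenever at least one full window exists. "Connections" between patches
are operationalized as consecutive-fix transitions between different
patches (self-transitions and matrix fixes excluded), summarized as
percentage composition over unordered land-use type pairs — one
reasonable reading of a quantity that field studies rarely define
operationally; composition percentages from real data should therefore
not be compared against other operationalizations. Individuals tracked
less than 10 days (the field inclusion rule, configurable) are excluded.

## Synthetic data

The simulators generate data with exactly the structure the analysis
assumes, which is what makes the test suite's parameter-recovery claims
meaningful:

* `sim_yule_tree()`: forward pure-birth simulation (exponential waiting
  times, uniformly chosen splitting lineage), ultrametric by
  construction, expected origin-to-tip depth
  $\sum_{k=1}^{n-1} \frac{1}{\lambda k} + \frac{1}{\lambda n}$.
* `sim_bm_traits()`: tip values drawn exactly as
  $N(\mu \mathbf{1},\, \sigma^2 C)$ via Cholesky — no per-branch
  simulation error.
* `sim_germination()`: traits evolve by Brownian motion on the log
  scale; the linear predictor $\eta = X\beta + a + e$ is formed from the
  model above and back-transformed, $\mathrm{SGS} = \max(e^\eta - 1, 0)$,
  so the fitted model is correctly specified by construction up to two
  deliberate granularities: seedling counts are integers (nearest-integer
  inversion by default, binomial as a misspecification stress test), and
  SGS clips at zero. The defaults (intercept 2.5, trait effects
  0.1/0.2/−0.1, Brownian rate 0.1, $\sigma^2_p = 0.2$,
  $\sigma^2_e = 0.3$) keep the linear predictor far enough from zero
  that clipping affects under ~1% of species, and encode a true
  heritability of $0.2/(0.2+0.3) = 0.4$ — the recovery condition the
  acceptance suite checks (true $h^2$ inside the 95% HPD in at least
  18 of 20 seeded replicates at $n = 100$ tips). The count layer leaves
  a mild upward distortion of posterior mean $h^2$ relative to the
  purely Gaussian case; the sampler itself is checked separately against
  the analytic conjugate posterior.
* `sim_landscape()`: a jittered rectangular grid rather than a Voronoi
  mosaic — exact tiling of the extent and exact control of mean patch
  area (extent / cell count), at the price of unrealistically rectilinear
  boundaries. The two study conditions are mean patch sizes of 27.5 ha
  ("simple") and 2.9 ha ("complex") over a 3 × 3 km extent.
* `sim_track()`: hourly correlated random walk with gamma step lengths
  (defaults shape 2, scale 90 m: mean 180 m/h, the magnitude of
  free-ranging hare movement of roughly 1.3 km per 7 h), wrapped-Cauchy
  turning angles (ρ = 0.6), border reflection, and optional grassland
  bias via weighted candidate headings.

What the simulators do *not* emulate: behavioral states and day–night
activity cycles, GPS measurement error, irregular fix schedules, curved
or nested patch geometry, and seed-trait distributions matched to real
databases. Passing tests therefore demonstrate the correctness of the
estimators and counting rules under the stated models, not the field
accuracy of any particular published estimate.

## Degenerate inputs and numerical conventions

* Dimensions, masses, volumes must be positive; missing seed heights are
  flagged, never imputed.
* Constant predictor columns make correlations undefined and are errors.
* Non-positive-definite phylogenetic correlations (eigenvalue
  $\le 10^{-10} \lambda_{max}$) are rejected before sampling.
* All randomness flows from user-supplied integer seeds; identical seed
  and settings give bit-identical retained draws, tracks, landscapes and
  output files.
* Timestamps are ISO 8601 UTC; coordinates must be projected meters —
  degree-range inputs are rejected rather than reprojected. Numeric I/O
  is point-decimal with a grouping mark chosen so comma-decimal cells
  fail loudly.
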