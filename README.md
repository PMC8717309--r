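# endolink

Quantifying endozoochorous seed dispersal by the European brown hare
(*Lepus europaeus*) — a "mobile linker" that ingests seeds while foraging
and deposits them, hours later, in other habitat patches.

The package implements the full analysis pipeline around a controlled
feeding experiment and GPS tracking study in agricultural landscapes, for
ecologists working on seed dispersal syndromes and functional habitat
connectivity:

1. **Seed trait indices** (`seed_eccentricity()`, `seed_flatness()`,
   `seed_density()`, `seed_shape_variance()`, `seed_surface_area()`,
   `derive_seed_traits()`): the morphological dispersal-syndrome
   descriptors — eccentricity EI = length/width, flatness
   FI = (length + width)/(2·height), density = mass/volume, dimensional
   shape variance V<sub>s</sub>, and a shape-dependent surface-area
   approximation — plus **standardized germination success**

   SGS = 100 · n<sub>feces</sub> / ((capacity/100) · n<sub>fed</sub>),

   the germination rate after gut passage relative to each species'
   control germination capacity.

2. **A Bayesian phylogenetic mixed model** (`pmm_fit()`), written as a
   blocked Gibbs sampler for

   y = Xβ + a + e,  a ~ N(0, σ²ₚ R),  e ~ N(0, σ²ₑ I),

   with R the correlation implied by a phylogeny (`read_newick()`,
   `phylo_vcv()`, `vcv_to_correlation()`), response log(SGS + 1) and
   log-transformed seed traits as fixed effects. It reports Lynch's
   phylogenetic heritability h² = σ²ₚ/(σ²ₚ + σ²ₑ) with HPD intervals
   (`pmm_heritability()`), a marginal-deviance DIC (`pmm_dic()`), and
   all-subsets DIC model selection (`pmm_dredge()`). Fitted objects have
   `tidy()`, `glance()` and `autoplot()` methods.

3. **Moving-window habitat connectivity** (`connectivity_summary()`):
   hourly-resampled GPS tracks are assigned to land-use patches, windows
   of length equal to the hare's gut retention time (5.6 / 7 / 8.4 h) are
   slid along each track, and the connected land-use types, unique patches
   per type, and travel distances per window are averaged per individual
   and landscape.

4. **Simulators** (`sim_yule_tree()`, `sim_bm_traits()`,
   `sim_germination()`, `sim_landscape()`, `sim_track()`) that generate
   trees, phylogenetically structured germination tables, mosaic
   landscapes of configurable mean patch size, and correlated-random-walk
   tracks — so every stage of the pipeline is testable without the
   original field data.

The 44-species feeding-trial table ships with the package
(`hare_seed_traits()`).

## Worked example

```r
library(endolink)

traits <- hare_seed_traits()
sum(traits$seeds_fed)                      # 34710 seeds fed
sum(traits$feces_germ)                     # 177 seedlings from feces
round(100 * sum(traits$feces_germ) / sum(traits$seeds_fed), 2)  # 0.51 (%)

germination_by_group(traits, "neophyte", exclude = "poa_annua")
#> # A tibble: 2 × 4
#>   group    level     n mean_sgs
#> 1 neophyte FALSE    34    1.27
#> 2 neophyte TRUE      9    0.419
```

Non-neophytes germinate three times better after gut passage (1.27% vs
0.42% mean SGS). Fitting the phylogenetic mixed model on a simulated
feeding trial with known heritability 0.4:

```r
tree <- sim_yule_tree(100, birth_rate = 1, seed = 1001)
sim  <- sim_germination(tree, seed = 2001)          # defaults encode h2 = 0.4
R    <- vcv_to_correlation(phylo_vcv(tree))
des  <- pmm_design(sim, c("density", "ei", "area"))
fit  <- pmm_fit(des$y, des$X, R, iterations = 10000, burnin = 1000,
                thin = 5, seed = 1)
pmm_heritability(fit)
#> # A tibble: 1 × 4
#>    mean hpd_lower hpd_upper  prob
#> 1 0.456     0.228     0.686  0.95
```

The posterior mean sits near the generating value and the 95% HPD covers
it. `pmm_dredge(sim, c("density", "ei", "area"), R = R)` ranks all eight
predictor subsets by DIC and flags models within 2 units as competing.

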