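# metaconn

Tools for asking what structures a metacommunity — species sorting along
environmental gradients, spatially autocorrelated processes, or dispersal
dynamics — from three plain tables: a site×species matrix (counts or
presence/absence), site coordinates (decimal-degree lat/lon), and a
site×environment table. The package targets community ecologists and
microbial-ecology workflows alike: everything operates on incidence/abundance
matrices and distance matrices, nothing is taxon-specific.

## What it computes

* **Beta diversity** — pairwise Sørensen dissimilarity partitioned into
  turnover (Simpson) and nestedness components (Baselga):
  `β_sor = (b+c)/(2a+b+c)`, `β_sim = min(b,c)/(a+min(b,c))`,
  `β_nes = β_sor − β_sim`; summaries, nestedness share, and
  Kruskal–Wallis / Mann–Whitney contrasts between metacommunities.
* **Incidence-function connectivity** — Hanski-style metric
  `c_ik = Σ_{j≠i} N_jk e^(−d_ij/α)`, the nearest-occupied-site metric N,
  per-site connectivity totals (stepping-stone ranking), and grid estimation
  of the kernel scale α from the distance decay of community similarity.
* **Spatial predictors** — classical db-MEM (PCNM construction: MST-edge
  truncation, `−d²/2`, double-centring, positive-eigenvalue axes), Moran's I,
  Mantel tests and Mantel correlograms with progressive Holm correction.
* **RDA variation partitioning** — Spearman collinearity screen, marginal
  environmental screening, redundancy analysis with Monte Carlo permutation
  tests, three-set (environment / space / connectivity) inclusion–exclusion
  partitioning swept across the α grid, plus a correction for the
  construction circularity of metric C (`connectivity_null_r2()`).
* **Synthetic metacommunities** — a generator with controlled
  species-sorting, dispersal-limitation and noise components (78 sites in
  three landscape blocks, 139 species, Gaussian niches, Gaussian-random-field
  environments, negative-exponential dispersal) so the whole chain is
  testable against ground truth.

## Worked example

```r
library(metaconn)

sim <- generate_metacommunity(scenario_config("dispersal", seed = 42))
cm  <- filter_rare_species(sim$community)    # drops single-site species

beta_summary(pairwise_partition(cm))
#> Pairwise beta diversity over 3003 site pairs
#>      index   mean     se
#> 1 beta.sor 0.8640 0.0018
#> 2 beta.sim 0.8306 0.0023
#> 3 beta.nes 0.0335 0.0008
#> beta.ratio (nestedness share): 3.9%
```

High beta diversity dominated by turnover (nestedness contributes only
3.9%) — sites replace species rather than nesting into each other.

```r
estimate_alpha(cm, sim$geometry)$alpha_star
#> [1] 50.7        # km; the planted kernel scale was 100 km (factor < 2)

id <- identify_generator(sim, seed = 42)
#> collinearity screen: dropping 'EVI' (Spearman rho = -0.921 with 'AMT')
id$varpart
#> Three-set variation partitioning (alpha = 50.7 km)
#>   single-set r2: E = 0.091, S = 0.369, C = 0.330
#>   total (ESC) r2 = 0.728
id$c_floor; id$generator
#> [1] 0.093       # adjusted r2 that metric C explains by construction alone
#> [1] "dispersal"
```

The classifier compares Ezekiel-adjusted fractions (E 0.015, S 0.048,
C 0.095 − floor 0.093) and reads spatial structure without an environmental
signal as dispersal dynamics — correctly identifying the generator. Site
connectivity totals at large α rank stepping-stone candidates:

```r
head(site_connectivity(connectivity_bundle(cm, sim$geometry, 500)), 3)
#>     site    total rank stepping_stone
#> s54  s54 1590.404    1           TRUE
#> s58  s58 1580.510    2           TRUE
#> s67  s67 1576.740    3           TRUE
```

`run_pipeline(sim, "out/")` runs the full per-metacommunity workflow (beta
summaries, environmental screening, correlograms, MEM, α-swept variation
partitioning, site connectivity) and writes seven artefacts including a
`manifest.json` with seeds, parameters and file checksums. A thin CLI lives
at `inst/cli/metaconn.R` (`Rscript inst/cli/metaconn.R run-all --seed 1`).

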