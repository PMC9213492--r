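# fishinv

Tools for quantifying and explaining large-scale invasion of freshwater
fish communities, written for invasion ecologists and river managers who
work with national-scale electrofishing surveys: site × species abundance
classes, per-site environmental covariates, and barrier inventories on a
river network.

## What it computes

**Invasion metrics.** Ordinal field abundance classes (0–5) become
body-mass-corrected abundances (class midpoint × body-size weight); from
these the package derives the per-site *invasion degree*

> degree(site) = Σ exotic abundance / Σ total abundance ∈ [0, 1],

and, per exotic species, *colonization* C (% of sampled sites with
presence), *prevalence* P (mean % of the community where present), and the
*invasiveness index* C × P that ranks the invaders.

**Drivers.** Livestock units (0.01·poultry + 1·cattle + 0.1·sheep +
0.5·pigs), a configurable seven-parameter eutrophication proxy (high =
clean), inverse-distance interpolation of monitoring covariates, 10-km
radius aggregation, and a bounded river-fragmentation index over the
barriers reachable within 10 km of a site along the network:

> FI = (2/π)·arctan( Σ_b category_b / distance_b ) ∈ [0, 1),

with barrier categories 1 (small jump) to 4 (major dam).

**Boosted regression tree protocol.** Stochastic gradient boosting
(squared-error loss, depth-3 trees, learning rate 0.01, ≥ 1000 trees; 25 %
of sites held out per tree) with: variable importance (split improvements,
rescaled to sum 100); cross-validated R² from the held-out sites;
iterative deletion of predictors with VI < 7 plus a mechanised redundancy
rule; partial-dependence effect directions; a two-sided Moran's I test of
the residuals on Voronoi-adjacency weights; and, when spatial
autocorrelation is found, a Voronoi-neighborhood autocovariate refit kept
under a best-fit rule, with the SAC-explained share reported.

**Variation partitioning and RDA.** VIF screening (threshold 8) inside
four driver groups (Geography, Climate, Human factors, Land use);
15-fraction adjusted-R² partitioning with 999-permutation tests of the
unique fractions; redundancy analysis of the top invaders with
499-permutation axis tests. Both are implemented from linear algebra and
cross-checked against vegan in the test suite.

**Synthetic studies.** Because surveys of this kind are rarely public, a
generator builds landscapes (gradients + spatially autocorrelated Gaussian
fields), niche-structured native/exotic species pools, overdispersed
class-sampled communities, and Poisson barrier networks — with known
planted structure, so the whole chain is testable.

## Worked example

```r
library(fishinv)
cfg <- pipeline_config(seed = 11,
                       landscape = landscape_config(n_sites = 150, seed = 11),
                       brt = brt_config(seed = 11), top_n = 3)
res <- run_pipeline(cfg, out_dir = "invasion_run")
print(res)
```

```
Invasion analysis pipeline (config hash 208cd60733f75f06429eb4555ca1e274 )
Top invaders:
  rank   species    index colonization prevalence
1    1 sp_exo_03 853.6666     78.66667  10.851693
2    2 sp_exo_01 775.5028     71.33333  10.871534
3    3 sp_exo_05 281.6186     79.33333   3.549815
4    4 sp_exo_02 236.0996     63.33333   3.727889
5    5 sp_exo_06 220.2145     78.00000   2.823262
BRT pipeline result: CV R^2 = 0.751
  altitude             VI  87.78  negative
  eutrophication       VI  12.22  positive
Variation partitioning full adjusted R^2: 0.8299
RDA axis 1 explains 49.33 % of variance
```

Reading it: the simulated survey's most invasive species colonises 79 % of
sites and holds 11 % of the community where present (index = the product,
854 of a possible 10 000). The reduced boosted-tree model explains 75 % of
the held-out deviance in invasion degree, dominated by a negative altitude
effect and a positive eutrophication effect — the structure the default
generator plants. The four driver groups jointly account for 83 % of the
variance (adjusted), and the first constrained ordination axis carries
49 % of the top-invader community variance. `invasion_run/` receives the
ranking and degree CSVs, a JSON report per model, the fraction table and
Euler–Venn areas, RDA scores, and a manifest with the config hash; a rerun
with the same config and seed reproduces every file bit for bit.

A command-line wrapper over the same pipeline ships in
`inst/scripts/fishinv-cli.R`
(`Rscript fishinv-cli.R run-all --seed 1 --out run1`).

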