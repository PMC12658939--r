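# paguard

Counterfactual assessment of protected-area (PA) effects on terrestrial
species range loss.

Conservation planners need to know whether PAs actually slow range
contraction and local extinction, but PAs are not placed at random: they
sit preferentially on remote, high, sparsely populated land that would
have lost fewer species anyway. `paguard` implements the full
observational workflow for separating protection effects from placement
bias on a gridded landscape, for ecologists and conservation scientists
working with presence rasters and PA databases.

## What it computes

On a shared equal-area grid (~100 km² pixels):

* **Range change** per species from past/recent presence overlays
  (`LOST`, `RETAINED`, `GAINED`, `ABSENT`), richness maps, and the
  per-pixel **local extinction rate**
  `E = (species lost) / (species present in the past)`,
  undefined where past richness is 0 — gains never offset losses.
* **Protection time frames**: each pixel is `P70` (protected continuously
  since the past reference year), `P15` (protected later), `BUFFER`
  (within one pixel, ~10 km, of any PA) or `NEVER`. Centroid-only PA
  records of reported extent *A* become circles of radius √(A/π).
* **Propensity-score matching**: logistic propensity on quartile-binned
  elevation, slope, population density and travel time plus bioanthrome
  (biome × anthrome) indicators; greedy 1:1 nearest-neighbour matching
  without replacement, no caliper; balance via absolute standardized mean
  differences, `SMD = |mean_T − mean_C| / SD` (< 0.1 = balanced); ATT as
  the mean matched-pair difference in % species lost with a paired-normal
  95% CI. Four comparisons: protected vs never, P70 vs P15, protected vs
  buffer, buffer vs never.
* **Boosted multilevel effects**: depth-2 gradient-boosted trees
  (learning rate 0.1, 5-fold CV tree selection) with per-category partial
  dependence and split-gain relative influence.
* **Regressions**: % range lost ~ ln(Δ protected proportion + 0.01);
  % range lost ~ ln(protected extent + 1); per-bioanthrome
  % locally extinct ~ Δ PA coverage + area.
* **Synthetic worlds** with known truth: spatially autocorrelated
  covariates, confounded PA placement (seed probability ∝
  exp(γ·(z_elev + z_travel))), and a per-pixel extirpation probability
  `plogis(β0 + β·z + δ_category)`, so every estimate can be compared with
  its true ATT.

## Worked example

Simulate the standard confounded world (200×200 grid, 50 species, 60 PAs,
γ = 1.5), build the pixel table and run the protected-vs-never matched
comparison:

```r
library(paguard)

world <- gen_world(world_config(seed = 1))
tab   <- world_pixel_table(world)
res   <- run_comparison(tab, "a")

res$effect
#> <effect_estimate> ATT -7.822 [-9.284, -6.360] (n_pairs 3277; T 10.83 vs C 18.65)

res$balance
#>                covariate smd_before smd_after
#> 1               distance    0.87761   0.00948
#> 2              elevation    0.55971   0.01355
#> 3                  slope    0.00683   0.08773
#> 4            pop_density    0.16831   0.08389
#> 5            travel_time    0.53723   0.00699
#> 6 bioanthromes (average)    0.09655   0.02047

res$naive_diff        # raw inside-outside contrast
#> [1] -11.83
world$truth$att[["a"]]  # generative truth
#> [1] -6.67
```

Reading: matched pixels under protection lost on average 7.8 percentage
points fewer of their species than comparable never-protected pixels
(10.8% vs 18.7% among matched units). The naive contrast (−11.8) overstates
the benefit because PAs sit on low-risk land; matching removes most of that
placement bias relative to the known truth (−6.7), and the large
before-matching SMDs on elevation, travel time and the propensity score
collapse below 0.1 after matching.

The whole pipeline — simulation, range change, protection, covariates,
matching (all four comparisons), boosted model, regressions, with every
artifact written to disk and a reproducibility manifest — is one call:

```r
run_world_pipeline(world_config(seed = 1), out_dir = "run1")
```

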