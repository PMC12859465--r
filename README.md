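# olcn

Quantification of osteocyte lacunar-canalicular network (OLCN) integration
across bone remodeling interfaces in nano-CT gray-value volumes.

## The problem

Bone is remodeled in patches: tissue formed in different remodeling cycles
is separated by hyper-mineralized *cement lines* a few micrometers thick.
The osteocyte network — ellipsoidal lacunae connected by nano-scale
canaliculi — may or may not grow across these interfaces, and the degree of
integration depends on local tissue conditions. In phase-retrieved
synchrotron nano-CT, voxel gray value (GV) tracks mass density and hence
the degree of mineralization: pores are darkest, younger matrix is darker
than older matrix, cement lines are brightest. `olcn` turns this contrast
into three quantitative measurements per volume:

1. **Normalized mean GV** per remodeling region — mineral-matrix mean GV
   divided by the region's lacunar mean GV (cancelling low-frequency
   artifacts) — and an age ranking (rank 1 = youngest = lowest value).
2. **Projected canalicular porosity** per region, from minimum-intensity
   projections with black top-hat segmentation:

   `pCan.P = sum_i pCan.V(i) / sum_i pMin.V(i)`

   where `pCan.V(i)` and `pMin.V(i)` are the canalicular and mineral pixel
   counts of projection `i` — a relative network-density measure, not a 3D
   porosity.
3. **N.Conn** per candidate lacuna — the number of canalicular components
   of the lacuna's connected cluster that cross the interface band
   (dilation of the older region minus itself) within 25 um of the lacuna.

A synthetic phantom generator (`generate_phantom` and the canned
`default_validation_phantom`, `porosity_validation_phantom`,
`connection_validation_phantom`) builds nano-CT-like bone volumes with
full ground truth — age-ordered regions, a wavy cement sheet, lacunae,
crossing/looping/intra-region canaliculi, image noise — so every stage is
validated without external data.

## Worked example

```r
library(olcn)
res <- run_pipeline(default_phantom_config(seed = 1))
res$region_stats
#>   region_id mean_gv_mineral mean_gv_lacunar norm_mean_gv n_lacunae excluded rank
#> 1         1        149.9937        59.63441     2.515220         5    FALSE    1
#> 2         2        165.0009        61.31818     2.690896         2    FALSE    2
res$porosity
#>   region_id     pcan_p flagged
#> 1         1 0.03464203   FALSE
#> 2         2 0.02166359   FALSE
res$connections[, c("lacuna_id", "n_conn")]
#>   lacuna_id n_conn
#> 1         1      3
#> 2         3      2
#> 3         5      1
#> 4         7      0
```

Region 1 is ranked youngest (normalized mean GV 2.52 vs 2.69): its matrix
is less mineralized. Its projected canalicular porosity is 1.6 times that
of the older region — the younger network is denser. The four candidate
lacunae near the cement line carry 3, 2, 1 and 0 interface crossings,
which equals the generator's ground truth exactly (the 0-crossing lacuna
carries two canalicular loops, which approach the cement line but never
cross it). The numbered scripts under `analysis/` run these stages one at
a time with commentary and write their tables under `results/`.

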