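# lakecover

Multitemporal land-cover dynamics of seasonal lakes from multispectral
imagery, as a tested R pipeline.

Seasonal floodplain lakes swing between a high-water stand that drowns
their fringes and a dry stand that exposes mudflats and wetland
vegetation. Quantifying that rhythm from satellite imagery is a standard
but many-staged exercise, and `lakecover` packages the whole chain for
analysts who want each stage reproducible and unit-tested:

1. **Per-scene supervised classification** into water / vegetation /
   mudflat / sand, with three interchangeable methods:
   - a Gaussian **maximum-likelihood classifier** (MLC):
     $L_i = \arg\max_l \log p(z_i \mid \mu_l, \Sigma_l)$ with
     population-covariance fits and a diagonal ridge;
   - a **one-vs-rest kernel-SVM decision tree**: K−1 soft-margin binary
     machines ($0 \le a_i \le C$, $\sum a_i y_i = 0$, decision
     $f(x)=\sum a_i y_i k(x_i,x)+b$) trained by a deterministic SMO
     solver, each peeling one class off the pool;
   - their **agreement fusion**: pixels where MLC and SVM agree keep the
     label; the SVM tree is retrained on the training regions plus a
     seeded sample of agreed pixels and relabels only the disagreements.
2. **Accuracy assessment**: confusion matrices with OA / UA / PA /
   Cohen's kappa, McNemar paired comparison, per-scene method selection,
   and Jeffries–Matusita separability screening ("above 1.9").
3. **Area time series**: per-scene class areas (km²), descriptive
   statistics, two-sided Grubbs outlier test (critical values from the
   t-quantile formula), Pearson correlations, and inter-/intra-annual
   share aggregation.
4. **Pixel-wise multi-year analytics**: inundation / vegetation frequency
   (majority-rule annual presence, half-open bins (0,3], (3,5], (5,7],
   (7,9]), coefficient-of-variation stability maps
   ($CV = \bar F^{-1}\sqrt{\sum(F_i-\bar F)^2/n}\times 100\%$), and
   land-category transfer matrices with decreasing/increasing marginals.
5. A **seeded synthetic-scene generator** (basin DEM, sinusoidal stage
   peaking in the June–September high-water season, elevation-banded
   ground truth, Gaussian sensor noise) so the full pipeline runs and is
   tested with no satellite data, plus a packaged 41-record area series
   for the deterministic statistics.

See `vignettes/lake-dynamics.Rmd` for the model details and every design
choice.

## Worked example

```r
library(lakecover)

# packaged monitoring series: 41 dated scenes, areas in km2
s <- load_area_fixture()
descriptive_stats(s, "water")
#> mean 2020.05  sd 770.03  min 602.57 (2015-02-13)  max 3163.51 (2020-08-21)
series_correlations(s)
#>                      pair          r r_squared
#> 1        water-vegetation -0.9207930 0.8478597
#> 2      water-mudflat_sand -0.8817564 0.7774944
#> 3 vegetation-mudflat_sand  0.6279259 0.3942909
grubbs(s$water_km2)
#> <grubbs_result> G = 1.8408 vs G_crit(41, 0.05) = 3.0466 -> no outlier
round(setNames(annual_share(s)$water, annual_share(s)$year), 1)
#> 2013 2014 2015 2016 2017 2018 2019 2020 2021
#> 56.4 67.0 53.3 53.8 62.7 50.0 65.5 77.0 70.0
```

The strong water–vegetation anti-correlation (r ≈ −0.92) is the
submergence signature of a seasonal lake: rising water drowns the
vegetated fringe. Annual water share spans 50 % (2018) to 77 % (2020), a
27-point range, and no class series contains a Grubbs outlier at
α = 0.05.

Classification on a simulated campaign (64×64 grid, 9 years × 4 scenes):

```r
cfg  <- sim_config(seed = 1)
pack <- simulate_scenes(cfg)
tr   <- sample_rois(pack$scenes[[1]]$truth, pack$scenes[[1]]$image, 100, seed = 8)
separability_matrix(tr)      # all pairwise JM = 2.0 at default noise
map  <- fuse_classify(pack$scenes[[20]]$image, tr, C = 10, seed = 9)$map
confusion(as.vector(map$labels), as.vector(pack$scenes[[20]]$truth$labels))$oa
#> [1] 1
class_areas(map)
#>         date water_km2 vegetation_km2 mudflat_km2 sand_km2 mudflat_sand_km2 total_km2
#> 1 2005-11-15    2.0817         0.7245      0.5499   0.3303           0.8802    3.6864
```

`run_pipeline(cfg, "out/")` chains all stages and writes CSV/JSON/ASCII-grid
artifacts plus a JSON run report; identical config + seed gives
byte-identical outputs. A command-line interface with `simulate`,
`classify`, `evaluate`, `areas`, `stats`, `frequency`, `stability`,
`transfer` and `run` subcommands lives at `inst/cli/lakecover.R`.

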