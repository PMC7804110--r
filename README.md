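# retgrid

Location-specific normative analysis of macular OCT layer thickness on the
fovea-centred 8×8 grid.

Global averages and ETDRS-sector summaries of retinal layer thickness blur
spatial structure that matters clinically: ageing thins different parts of
the macula at different rates, and the retinal nerve fibre layer is
organised radially around the optic nerve head rather than concentrically
around the fovea. `retgrid` is for researchers building layer-specific
normative databases from Spectralis-style 8×8 grid exports (64 cells of
~860 µm, thickness in µm per retinal layer) and for anyone who needs
age-corrected, spatially resolved reference values for the RNFL, GCL, IPL,
INL, OPL, ONL+HFL, IS/OS and RPE.

## The method

1. **Covariate screening.** Per-eye mean thickness is regressed on age, sex,
   ethnicity, spherical-equivalent refraction and BCVA; backward step-wise
   elimination (α = 0.05) decides whether eyes are grouped into age-interval
   cohorts, sexes, or analysed as one cohort.
2. **Spatial clustering.** Each grid location is described by its mean
   thickness per group. Hierarchical clustering with within-groups linkage
   under squared Euclidean distance proposes a cluster count k; k-means
   assigns locations; any cluster pair with

   d′ = |x̄₁ − x̄₂| / √(0.5 (σ₁² + σ₂²)) < 2

   is merged (smallest d′ first, statistics recomputed from the pooled
   member values) until all pairs are separated by at least two pooled SDs.
3. **Age regression.** Per cluster, linear and quadratic OLS on cohort mean
   thickness versus representative cohort age, y = ax² + bx + c. The vertex
   x = −b/2a is the estimated age at peak thickness; the post-vertex slope
   (µm/year, OLS over ≥ 3 cohort means at ages beyond the vertex) is the
   rate of decline; an ANCOVA-equivalent interaction F-test decides whether
   cluster slopes pool. Age-correction moves an observed thickness along the
   fitted curve to a reference age.
4. **ETDRS comparison.** The grid is mapped onto ETDRS sectors
   (central / inner / outer × superior / nasal / inferior / temporal) and
   coefficients of variation (SD/mean) compare the dispersion of sector
   versus cluster summaries (Mann–Whitney U).

Because clinical grid datasets are rarely shareable, the package ships a
synthetic-cohort generator (`simulate_cohort()`) with known ground truth —
253 eyes across six decade bins, concentric or radial spatial fields,
per-cluster quadratic ageing — so the whole pipeline is testable end to end.

## Worked example

```r
library(retgrid)

sim <- simulate_cohort(sim_config(), layers = "GCL", seed = 1)
analysis <- analyze_layer(sim$datasets$GCL, seed = 1)
analysis
#> <layer_analysis> GCL: grouped by age, 4 candidate pattern(s)
#> <pattern_evaluation> hierarchical/age, 5 cluster(s)
#>   mean R^2 0.9966, mean SS 0.03885, mean SD-resid 0.08569
#>   slope homogeneity p = 0.938; pooled slope -0.1187 um/yr

tidy(analysis)
#> # A tibble: 5 × 10
#>   cluster form      r_squared ss_resid sd_resid vertex_age beyond_cohort post_vertex_slope zero_slope_p peak_um
#>     <int> <chr>         <dbl>    <dbl>    <dbl>      <dbl> <lgl>                     <dbl>        <dbl>   <dbl>
#> 1       1 quadratic     0.996   0.0492   0.0992       38.1 FALSE                    -0.123       0.0370    50.0
#> 2       2 quadratic     0.994   0.0618   0.111        38.0 FALSE                    -0.109       0.0299    42.9
#> 3       3 quadratic     0.998   0.0228   0.0675       39.4 FALSE                    -0.109       0.0333    36.0
#> 4       4 quadratic     0.997   0.0449   0.0948       41.3 FALSE                    -0.132       0.0313    30.0
#> 5       5 quadratic     0.999   0.0156   0.0558       42.1 FALSE                    -0.120       0.0354    24.1
```

Screening chose age grouping; the winning pattern has five concentric
clusters (cluster 1 the thickest, parafoveal). Every cluster is fitted by a
downward quadratic peaking at 38–42 years, declining afterwards at 0.11–0.13
µm/year; the slopes are homogeneous (p = 0.94), so a pooled loss of −0.12
µm/year is reported. `autoplot(analysis$final$pattern)` draws the cluster
topography; `autoplot(analysis$final)` the per-cluster trajectories.
`age_correct()` then converts an observed thickness at any age to its
reference-age equivalent using the cluster's fitted curve.

A small synthetic example CSV ships with the package:

```r
path <- system.file("extdata", "synthetic_gcl_grid.csv", package = "retgrid")
ds <- load_grid_dataset(path, "GCL")
excl <- apply_exclusions(normalize_orientation(ds))
```

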