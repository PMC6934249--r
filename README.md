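# metrogrid

Official urbanization statistics depend on administrative definitions of
"urban", which vary across countries and over time and systematically
miss dense settlement outside municipal boundaries. metrogrid is for
spatial demographers and urban researchers who want a *consistent*,
definition-light delineation of urban areas from two ingredients that
exist almost everywhere: census population counts for coarse zones, and
gridded covariates (land cover, lights at night, terrain, settlement
layers).

The package implements a two-stage pipeline:

1. **Dasymetric disaggregation.** A regression random forest (500 trees)
   is fitted at zone level to predict natural-log population density,
   `ln(N_z / A_z)`, from zonal covariate means. Evaluated per 100 m cell
   and exponentiated, the forest gives a weight surface `w_i` (zero on
   uninhabitable cells), and each zone's count is redistributed as

   `persons_i = N_z * w_i / sum_{j in z} w_j`,

   conserving every zone total exactly. Out-of-bag error provides the
   model diagnostic (`oob_pseudo_r2`).

2. **Agglomeration delineation.** Cells with density ≥ τ persons/ha
   (default 7.5; 5 and 10 as sensitivity settings) are grouped into
   contiguous regions; holes are filled; regions under 2 ha are dropped;
   a graph connects settlements whose boundaries lie within 150 m; and
   Newman's leading-eigenvector modularity method (with a deterministic
   Kernighan–Lin refinement) partitions each graph component into
   communities, which are merged into metropolitan agglomerations and
   classified into a seven-level size hierarchy (5 k / 20 k / 100 k /
   1 M / 10 M / 40 M breaks).

Everything runs on plain-text formats: ESRI ASCII grids for rasters,
GeoJSON for polygons, CSV for counts. A synthetic landscape generator
(`generate_landscape()`, `generate_planted_clusters()`) produces full
test scenes — covariates, truth surfaces, districts, counts, planted
cluster structure — so the pipeline is exercisable end to end without
any external data.

## Worked example

```r
library(metrogrid)

sc  <- generate_landscape(scene_spec(seed = 42))       # synthetic inputs
dis <- disaggregate_population(sc$zones, sc$counts, 2011, sc$stack,
                               mask = sc$mask, seed = 42)
glance(dis$model)
#> # A tibble: 1 × 5
#>   n_zones n_trees  mtry oob_mse oob_pseudo_r2
#>     <int>   <int> <dbl>   <dbl>         <dbl>
#> 1      16     500     1   0.254         0.906

del <- delineate_agglomerations(dis$population, tau_per_ha = 7.5)
del
#> <ma_delineation> tau 7.5 pp/ha, d_max 150 m, min area 2 ha
#>   51 settlements -> 7 agglomerations, urban population 29088

tabulate_hierarchy(del$agglomerations, sum(sc$counts$count))
#> # A tibble: 7 × 3
#>   size_class             n population
#>   <ord>              <int>      <dbl>
#> 1 <5k town               5      2923.
#> 2 5-20k town             2     26165.
#> 3 20-100k town           0         0
#> ...
#> urban 29088 of 36083 persons (80.61% urban)
```

The OOB pseudo-R² of 0.906 says the forest explains most of the
zone-level variance in log density; 51 thresholded settlements collapse
into 7 agglomerations, and the hierarchy table shows how their
population distributes across size classes — here a dense synthetic
landscape where 80.6% of the census population ends up inside an
agglomeration. `reaggregate_check(dis$population, sc$zones, sc$counts,
2011)` returns r = 1 over the fitting districts (conservation) and can
be pointed at independent finer polygons for genuine validation.

A thin command-line wrapper with `synth` / `disaggregate` / `delineate`
/ `summarize` subcommands is installed under `inst/cli/metrogrid.R`.

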