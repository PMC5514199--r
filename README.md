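# landfrag

Class-level landscape fragmentation metrics and protected-area
deforestation trends for categorical land-cover raster time series.

Long-running land-cover mapping programmes produce, per site and year, a
three-class raster — mature forest (MF), non-forest (NF), secondary forest
(SF) — and two recurring questions: *how is the spatial pattern of each
class changing*, and *are conservation units (CUs) actually deflecting
deforestation*? `landfrag` computes, per year × zone × class:

- **ED** — edge density, `Σ edge length / A` (m/ha), with edges as cell
  sides between different substantive classes;
- **CLUMPY** — clumpiness, the normalised deviation of the like-adjacency
  proportion `G_i = g_ii / (Σ_k g_ik − min_e_i)` from the areal proportion
  `P_i`; −1 = checkerboard, 0 = random, 1 = maximally clumped;
- **AREA_AM** — area-weighted mean patch size, `Σ a_j² / Σ a_j` (ha);
- **SHAPE_AM** — area-weighted mean patch shape index, `p_j / min_p(a_j)`
  per patch, 1 for a square and growing with irregularity;

plus, per inter-map interval and zone, the **relative incidence of
deforestation**

```
RID_i = (D_i / D_total) / (A_i / A_total)
```

(share of deforested area over share of landscape area; < 1 means a zone
receives less deforestation than its size predicts), and per series a
**GLS linear trend test** with ARMA error structure selected by AICc on an
annual lattice that respects 1–4 year mapping gaps.

Patches use 8-neighbour (queen) connectivity; CLUMPY adjacencies use
4-neighbour (rook) double-counted cell sides. A seeded synthetic
landscape-dynamics generator (contagious road-driven clearing, fishbone
settlements, irregular wildfire scars, fallow–regrowth succession,
CU protection factor) provides reproducible test data; see the methods
vignette (`vignettes/landscape-fragmentation.Rmd`) for the model details
and the generator's scope.

## Worked example

```r
library(landfrag)

g <- matrix(2L, 10, 10)          # 10x10 non-forest matrix, 30 m cells
g[4:7, 4:7] <- 1L                # one centred 4x4 mature-forest patch
class_metrics(land_raster(g, cell_size = 30, year = 1984))
#>   year zone class class_area_ha n_patches    ED CLUMPY AREA_AM SHAPE_AM
#> 1 1984  all    MF          1.44         1 53.33      1    1.44    1.000
#> 2 1984  all    NF          7.56         1 53.33      1    7.56    1.474
#> 3 1984  all    SF          0.00         0  0.00     NA      NA       NA
```

The MF patch is 16 cells (1.44 ha), a perfect square (`SHAPE_AM = 1`) and
a single compact block (`CLUMPY = 1`); its 16 edge sides of 30 m over the
9 ha landscape give `ED = 53.33` m/ha, and the NF class shares the same
edge. SF is absent, so its pattern metrics are `NA` (never zero-filled).

A full synthetic run — simulate, stratify inside/outside the CU, compute
metrics, RID and trends:

```r
pres  <- scenario_presets(seed = 1)
ser   <- generate_series(pres$spontaneous_with_fires)
zones <- zones_from_mask(attr(ser, "cu_mask"))
tt    <- trend_table(metrics_for_series(ser, zones),
                     rid_series(ser, zones))
tt[tt$metric %in% c("ED", "RID") & (is.na(tt$class) | tt$class == "MF"), ]
#>         zone class metric  n    slope      se p_value ar_order ma_order
#> 1  inside_CU    MF     ED 24  2.63001 1.03354  0.0185        1        0
#> 2 outside_CU    MF     ED 24  2.03704 1.31334  0.1352        1        0
#> 3  inside_CU  <NA>    RID 23  0.01602 0.00984  0.1186        0        0
#> 4 outside_CU  <NA>    RID 23 -0.00961 0.00591  0.1186        0        0
```

Mature-forest edge density rises significantly inside the CU in this
scenario because its two wildfires burn regardless of protection — fire
does not respect administrative boundaries — while budgeted clearing is
suppressed inside. RID shows no significant drift in either zone over the
24 mapped years.

`run_pipeline(run_config(site = "demo", preset = "spontaneous_with_fires",
out_dir = "out"))` writes the metrics/RID/trend CSVs plus a JSON run log
naming every defaulted convention; `inst/cli/landfrag.R` wraps the same
functions as shell subcommands (`run`, `metrics`, `rid`, `trend`,
`simulate`, `make-fixture`).

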