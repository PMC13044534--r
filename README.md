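# tmequant

Single-cell quantification of the tumor microenvironment (TME) in primary
and metastatic pancreatic ductal adenocarcinoma (PDAC), from multiplexed
immunofluorescence / immunohistochemistry cell tables and mass-cytometry
(CyTOF) event tables.

The package is aimed at analysts who have *segmented* single-cell exports
(one row per cell: centroid in µm, mean intensity per marker — e.g. QuPath
measurement exports) or CyTOF event tables, and who need the downstream
quantification chain to be calibrated, reproducible and testable:

* **FPR-calibrated gating.** Per-image, per-marker thresholds: arcsinh
  transform `asinh(x/150)`, exact two-class k-means threshold (in 1-D the
  global optimum is a contiguous split, found by scanning all cuts), a
  `median + 3·MAD` fallback for unimodal channels, 99th-percentile caps,
  and negative-control floors. Floors either sit at the 99.5th percentile
  of unstained controls (macrophage panel: CD68/CCR2/CD163) or enforce
  per-marker false-positive-rate budgets (CAF panel: PDPLN ≤ 5 %,
  PDGFRβ ≤ 10 %, CK19 ≤ 4 %, αSMA ≤ 1 %) via the ceiling order statistic
  `sorted(x)[⌈(1−q)n⌉]`, which makes the in-sample control FPR guarantee
  exact. Images with < 500 cells are excluded.
* **Exclusive phenotyping.** Precedence-based lineage labels
  (CK19 > CD3 > CD19 > CD68 > αSMA, configurable), IL6-defined CAF
  subclasses (myCAF = αSMA⁺IL6⁻, iCAF = αSMA⁺IL6⁺), composition (% of
  total and of phenotyped cells), occupancy-grid densities (cells·mm⁻²),
  T-cell transcription-factor profiles, collagen-positive area fractions.
* **Spatial layer.** Directional nearest-neighbor distance matrices
  (median/min of per-reference-cell nearest-target distances),
  hierarchically clustered heatmap orders, class networks (nodes = percent
  of cells, edges = `exp(−d/λ)` of symmetrized median distances) with
  seeded spinglass communities (seed 123), and four-region tumor-structure
  mapping (intratumoral / internal margin / external margin / stroma) with
  per-region infiltration summaries.
* **CyTOF chain.** Bead/Gaussian/event-length cleanup, cisplatin live gate,
  DNA singlet box, ≥ 500-live-cell sample retention, hierarchical subset
  gating (CD45⁻, other CD45⁺, CD4, CD8, CD4CD8, CD19) with ≥ 25-event
  parent cutoffs, Boolean 2⁵ checkpoint-combination profiling
  (CTLA4, LAG3, PD-1, TIGIT, TIM3) and configurable B-cell subsets.
* **Statistics.** Mann–Whitney (exact for small tie-free samples),
  Wilcoxon signed-rank, two-way type-II ANOVA, Šídák/Bonferroni.
* **Synthetic-tissue generator.** Every stage is validated against a
  generator that plants ground truth: site composition profiles
  (e.g. αSMA⁺ 25.5 % primary vs 11.2 % metastatic, CD68⁺ 2.44 % vs
  8.29 %, CD8 7.99 % vs 0.90 %), two-component log-normal intensities,
  tumor nests and stromal immune clusters, exact-count collagen images,
  and CyTOF events with copula-correlated checkpoint co-expression.

## Worked example

```r
library(tmequant)

cfg <- generator_config(n_samples_per_site = 1, seed = 42)
tissue <- gen_tissue(cfg, "metastatic")
controls <- gen_control(cfg, 20000)

# adaptive, control-floored gates for the macrophage panel
gates <- build_gates(tissue$cells, controls, macrophage_panel())
gates[, c("marker", "method", "raw_threshold", "floor_value", "final_threshold")]
#>   marker method raw_threshold floor_value final_threshold
#> 1   CD68 kmeans      390.2078    99.76341        390.2078
#> 2   CCR2 kmeans      388.9281   101.16981        388.9281
#> 3  CD163 kmeans      379.3100   100.45089        379.3100
```

Each marker was bimodal, so the gate is the exact two-class k-means
threshold; the control floor (99.5th percentile of unstained controls,
≈ 100) lies far below it and the clipping is a no-op.

```r
pos <- call_positivity(tissue$cells,
                       manual_gates(unique(tissue$cells$image_id),
                                    mixture_midpoint_thresholds(cfg)))
labeled <- assign_lineage(pos, phenotype_scheme())
comp <- composition_summary(labeled, tissue_area(labeled),
                            scheme_classes(phenotype_scheme()))
comp$classes
#>   class count pct_of_total pct_of_phenotyped density_mm2
#> 1  CK19  4510        45.10             62.37      1191.5
#> 2   CD3   550         5.50              7.61       145.3
#> 3  CD19   196         1.96              2.71        51.8
#> 4  CD68   788         7.88             10.90       208.2
#> 5  aSMA  1187        11.87             16.42       313.6
#> 6 other  2769        27.69                NA       731.6
comp$mycaf_icaf_ratio
#> [1] 5.86
```

The recovered composition sits on the planted metastatic profile (CK19
45 %, αSMA 11.2 %, CD68 8.29 %, CD3 = CD4+CD8 ≈ 5.9 %) to within
multinomial sampling error; `other` cells are excluded from the
percent-of-phenotyped denominator. The myCAF:iCAF ratio reflects the
planted 15 % IL6 positivity among metastatic CAFs.

```r
assn <- map_structures(labeled)         # tumor mask, margins, regions
inf <- infiltration_summary(assn, labeled)
subset(inf, class == "CD68")
#>    class          region   n   pct
#> 9   CD68    intratumoral   0  0.00
#> 10  CD68 internal_margin  16  2.03
#> 11  CD68 external_margin  52  6.60
#> 12  CD68          stroma 720 91.37
```

Macrophages concentrate in the stroma and margins, recovering the planted
extranest placement of immune clusters; the four regions partition every
cell and the per-class percentages sum to 100.

## Analysis workflow

`analysis/` contains numbered drivers that run the full study on the
synthetic cohort (3 samples/site, 10,000 cells/image, seed 1234) and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort + controls + CyTOF + truth
Rscript analysis/02_gating.R        # adaptive + manual gates, QC log, control FPR
Rscript analysis/03_phenotyping.R   # composition, TF profiles, collagen
Rscript analysis/04_spatial.R       # distances, communities, infiltration
Rscript analysis/05_cytof.R         # cleanup, subsets, checkpoint combos
Rscript analysis/06_stats_report.R  # site comparisons + report manifest
```

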