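---
title: "Quantifying the tumor microenvironment: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the tumor microenvironment: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

tmequant quantifies the cellular composition and spatial organization of
primary and metastatic pancreatic ductal adenocarcinoma (PDAC) tissue from
segmented single-cell measurement tables, and profiles immune-checkpoint
co-expression from mass-cytometry event tables. This vignette explains the
models and procedures the package implements, the tunable parameters that
matter, the synthetic-data generator the package is validated against, and
the design decisions taken where the methodology was genuinely open.

```{r setup}
library(tmequant)
```

## The analysis problem

Multiplexed immunofluorescence and immunohistochemistry produce, after
segmentation, one row per cell with a centroid (µm) and a mean intensity
per marker channel. Every downstream claim — "metastases carry more
macrophages", "T cells sit in the stroma rather than the tumor" — rests on
converting those continuous intensities into per-cell positive/negative
calls and then into compositions, densities, distances and regional
fractions. The package implements that chain as explicit, testable
operations:

1. **Gating** (`build_gates()`, `call_positivity()`): per-image, per-marker
   thresholds with negative-control calibration.
2. **Phenotyping** (`assign_lineage()`, `composition_summary()`): exclusive
   lineage labels, composition, density and collagen area summaries.
3. **Spatial analysis** (`min_distance_matrix()`, `detect_communities()`,
   `map_structures()`): directional distance summaries, class networks with
   seeded spinglass communities, four-region tumor-structure mapping.
4. **Mass cytometry** (`clean_events()` through
   `checkpoint_combinations()`): event QC, viability/singlet gating,
   hierarchical subsets, Boolean checkpoint combinations.
5. **Statistics** (`mann_whitney()`, `two_way_anova()`, `adjust_p()`).

## Gating model

### Transform and threshold

CAF-panel intensities are compressed with `asinh(x / 150)`; the cofactor
150 is the package default for fluorescence intensities (the transform is
approximately linear below the cofactor and logarithmic above it, so
background noise is preserved while high signals are compressed).

The per-image raw threshold for each marker is the **two-class k-means
threshold**. In one dimension the globally optimal two-cluster solution is
a contiguous split of the sorted values, so `kmeans_threshold()` scans all
n−1 candidate cuts with prefix sums and returns the midpoint of the two
cluster means. We solve the 1-D problem exactly rather than by Lloyd
iteration: the global optimum is Lloyd-stable, the answer is independent of
initialization, and equality with an exhaustive within-class-variance scan
is then a theorem rather than an empirical hope. The test suite still
checks it against an independent naive per-cut oracle.

### Unimodal channels and the MAD fallback

k-means always returns a split, even for a channel with no positive
population, so a separation test decides whether a channel is treated as
unimodal, in which case the conservative fallback
`median + 3 × MAD` (MAD unscaled — no 1.4826 normality constant) is used.
The criterion in `is_unimodal()` declares a channel unimodal when the two
cluster centers are closer than **3.5 pooled within-cluster SDs**, or when
the minority cluster holds under 1% of cells. The constant was derived from
the behavior of the split statistic itself: the optimal split of a single
Gaussian separates its halves by ≈2.65 pooled within-SDs (≈2.8 for the
right-skewed arcsinh-transformed log-normal background), while
two-component mixtures at 4-component-SD separation measure ≥4.1. A cutoff
of 3.5 therefore sends genuinely unimodal channels to the fallback and
resolvable mixtures to k-means. A smaller constant (e.g. 2) would classify
every unimodal Gaussian as bimodal; a larger one would push resolvable
mixtures into the fallback.

The fallback has a documented weakness the package does not hide: on a
right-skewed background, `median + 3 × MAD` sits near the 91st–94th
percentile, i.e. a ~6–9% false-positive rate if left unfloored. This is
why control floors exist, and why composition recovery for very rare
classes should use the manual-threshold mode (below).

### Floors, caps and false-positive-rate budgets

Two floor rules calibrate gates on unstained negative controls:

* **Fixed percentile** (macrophage panel): the floor is the 99.5th
  percentile of control intensities, computed with the package-wide
  interpolating quantile convention (type 7).
* **FPR budgets** (CAF panel): PDPLN 5%, PDGFRβ 10%, CK19 4%, αSMA 1%. The
  floor is the ceiling order statistic `sorted(x)[⌈(1−q)·n⌉]`. With this
  choice the number of control cells *strictly above* the floor is at most
  `q·n` for every control size n, so the in-sample guarantee is exact. An
  interpolated quantile does not have this property (at n = 777, q = 0.05
  it admits 39/777 = 5.02% exceedances), which is why the budget rule uses
  the order statistic while descriptive percentiles elsewhere use type 7.

Gates are capped at the 99th percentile of each image's transformed
intensities, computed **per image** (whether a cohort-level cap was ever
intended is unknowable from the procedure's description; per-image keeps
images independent and is the configurable default). Floors are calibrated
on the transformed scale so floors and data share one scale. The final
threshold is `min(max(raw, floor), cap)`; positivity is strict
(`intensity > threshold`), so ties at the threshold are negative and the
control FPR bound cannot be broken by ties.

Images with fewer than 500 cells are excluded before gating
(`qc_filter()`), with the boundary count retained.

### Manual mode

`manual_gates()` reproduces the visual-cutoff workflow used for
multiplex-IHC panels: fixed per-marker thresholds applied to every image.
For synthetic cohorts, `mixture_midpoint_thresholds()` places these at the
log-scale midpoint between the generator's negative and positive
components, where both error rates are below 0.2%. Composition recovery of
very rare classes (e.g. CD8 T cells at 0.9% of metastatic tissue) runs
through this mode: a 0.9% class trips the minority-cluster clause, and the
MAD fallback's background FPR would otherwise swamp a sub-1% population.
That is a property of the adaptive fallback itself, and the package's
adaptive route is validated instead on panel markers whose planted
fractions are resolvable by k-means.

## Phenotyping

Exclusive lineage labels are assigned by the first positive marker in a
precedence order, default **CK19 > CD3 > CD19 > CD68 > αSMA**: epithelial
identity dominates (CK19 marks the malignant compartment), immune lineages
come before the stromal marker. Multi-lineage co-positivity resolution is
not derivable from any published description, so the order is explicit and
configurable; the T-cell scheme additionally reports CD4⁺CD8⁺
double-positives as their own class. Modifiers (IL6, transcription
factors) are recorded independently: an αSMA⁺IL6⁺ cell is an iCAF, an
αSMA⁺IL6⁻ cell a myCAF, and a CD3⁺IL6⁺ cell keeps both facts.

Tissue area uses an occupancy grid (bins of 50 µm, ≈2 cell diameters,
containing ≥1 cell × bin area) rather than a pixel-level mask — a
deterministic surrogate reproducible from the cell table alone. Density
tests therefore compare pipeline output to truth computed with the same
surrogate. Collagen area fraction is the percentage of tissue pixels
(gray level above a tissue threshold) that exceed a signal threshold, both
fixed once per cohort.

Percentages below a minimum subset size (default 25 cells) are reported
missing in transcription-factor profiles: a percentage over a handful of
cells invites overinterpretation.

## Spatial analysis

**Distance matrices.** For each (reference, target) class pair, each
reference cell's distance to its nearest target (self excluded on the
diagonal) is summarized by the median and minimum over reference cells.
The matrices are directional. Per-image matrices are pooled across a
cohort by the elementwise median (the pooling statistic is stated once and
used everywhere). Heatmap columns are ordered by complete-linkage
Euclidean clustering of target columns.

**Networks and communities.** Nodes are classes weighted by percent of
cells (classes under `min_pct`, default 1%, are dropped — tiny populations
destabilize the spin model); edges carry an attraction weight
`exp(−d/λ)` of the symmetrized median-of-minimum distance. The spinglass
community objective needs affinities, while the biology supplies
distances, so an inversion is unavoidable; the exponential kernel with λ
set to the cohort median of pairwise distances makes a typical pair's
weight `exp(−1)` and is configurable. Communities come from
`igraph::cluster_spinglass` (25 spins, γ = 1) with the RNG seeded
immediately before the run — seed 123 by convention — making partitions
bit-reproducible; disconnected graphs fall back to per-component runs. On
planted two-block graphs of ≤8 nodes the partition matches exhaustive
modularity maximization over all set partitions.

**Tumor structures.** Tumor-cell density is rasterized on a 50 µm grid;
the tumor mask is the set of bins above 25% of the mean non-zero tumor bin
count; boundary bins are mask bins 4-adjacent to non-mask bins. Cells
within 100 µm (default margin) of the boundary form the internal/external
margins depending on which side of the mask they sit; remaining cells are
intratumoral or stroma. The four regions partition the cells by
construction. Fractured tissue is reduced to its largest 4-connected
occupancy component before mapping. The mask threshold, grid and margin
defaults are explicit surrogates for an external tool's unstated defaults
and are all arguments.

**Eligibility.** Infiltration analysis requires a "clear tumor–stroma
boundary". The deterministic surrogate: the tumor mask must occupy 5–95%
of occupied tissue bins and the boundary must be at least 10 bins long.
An all-tumor image (mask share 100%) is ineligible, as is an image with no
coherent tumor region.

## Mass cytometry

Cleanup drops bead-flagged events, then keeps events inside per-sample
percentile windows (default 1st–99th) on the four Gaussian discriminator
channels and event length. A percentile window can only remove what lies
beyond its tails: a contamination class larger than the tail fraction
cannot be fully removed by construction, which is why the generator plants
merged ion clouds at 1% (see below). Live intact singlets are
cisplatin-low events inside the DNA1/DNA2 box; samples need ≥500 live
cells to be retained, and parent populations need ≥25 events (CD3 and CD19
cutoffs) before their phenotypes are profiled.

The gating tree partitions live singlets exhaustively and exclusively:
CD45⁻ first (the root dominates any lineage signal), then CD45⁺CD3⁺ T
cells split into CD4/CD8/double-positive, CD3⁻CD19⁺ B cells, remainder
"other CD45⁺". Checkpoint combinations map each T cell to one of 2⁵ = 32
Boolean states over CTLA4, LAG3, PD-1, TIGIT, TIM3 — fixed in that order
for the hierarchical (sunburst) table — with frequencies, a per-cell
checkpoint-count histogram, and exact agreement with a per-cell
enumeration oracle. The six default B-cell subset rules (naïve IgD⁺CD27⁻,
memory CD27⁺, regulatory potential PD-1 and/or PD-L1, extrafollicular,
plasmablast, unswitched memory) are package conventions, stated as such
and fully configurable.

Thresholds for synthetic data come from the generator's known mixtures
(log-scale valley midpoints); real data takes a manual threshold table,
mirroring practice where gates are set against healthy-donor reference
material.

## The synthetic-tissue generator

The generator plants ground truth at every level so each downstream stage
is testable by direct counting, with no external data.

* **Composition.** Per-site class fractions are the study conditions:
  primary tissue is fibroblast-rich and T-cell-infiltrated (αSMA⁺ 25.5%,
  CD8 7.99%, CD4 3.19%, CD68⁺ 2.44% of cells), metastases are
  macrophage-rich and T-cell-poor (αSMA⁺ 11.2%, CD8 0.90%, CD4 5.04%,
  CD68⁺ 8.29%). CK19⁺ and "other" fractions fill the remainder at levels
  typical of tumor-rich sections. Labels are drawn multinomially — not by
  fixed counts — so recovery tolerances are sampling-error statements.
  Since only cohort means and SDs of compositions are knowable, the
  generator treats between-sample variability as residing in the
  multinomial sampling alone; planted fractions are identical across
  samples of a site.
* **Intensities.** Two-component log-normals per marker (background
  location log 40, sdlog 0.35; positive location log 600, sdlog 0.45,
  arbitrary units). Fluorescence intensities are strictly positive and
  right-skewed, and a log-normal mixture makes the arcsinh compression
  meaningful. The separation is several background SDs — resolvable, not
  trivial.
* **Space.** CK19⁺ cells fall uniformly in 3 circular nests (radius
  300 µm) inside a 2 × 2 mm field; immune cells cluster (radius 60 µm,
  ~50 cells/anchor) around anchors rejected from nest interiors;
  fibroblasts are biased to the extranest stroma. This plants a
  detectable stromal immune gradient and non-trivial communities.
  Coordinates follow the image convention (origin top-left, y downward).
* **Collagen.** A circular tissue disk on a dark background; an exact
  count `round(truth × n_tissue)` of tissue pixels is raised to the signal
  level, so the measured fraction equals truth to within one pixel. Gray
  bands (background < 15, tissue 45–75, signal 150–220) are separated so
  the fixed thresholds (30, 120) recover masks exactly. Planted fractions
  default to 0.35 (primary) vs 0.15 (metastatic) — desmoplastic primary
  disease against less fibrotic metastases, at levels realistic for
  picrosirius-red morphometry.
* **CyTOF.** Events are beads (2%), debris (4%), doublets (4%, DNA
  doubled), dead cells (10%, cisplatin-high), merged ion clouds (1%,
  extreme Gaussian width) and live singlets. The merged fraction is 1%
  deliberately: the default 1st–99th cleanup window can only remove events
  beyond its 1% tail, so a larger planted fraction could not satisfy a
  removal guarantee and would misrepresent what percentile windows do.
  Checkpoint positivity on T cells uses a Gaussian copula on a latent
  exhaustion score (ρ = 0.5): marginals are preserved exactly (CD4 TIGIT
  41.26/38.38%, TIM3 31.98/28.54%; CD8 CTLA4 42.06/60.07%, TIGIT
  50.61/62.84% for primary/metastatic) while all-marker co-expression
  exceeds independence whenever ρ > 0.

What the generator does **not** emulate: segmentation error, spillover and
staining batch effects, spatially varying background, irregular tissue
outlines, cell-size/shape features, and any real correlation between a
cell's neighborhood and its marker expression. Passing recovery tests
therefore demonstrates the correctness of the quantification chain under a
known model, not robustness to those real-data pathologies — the
calibration guarantees (FPR budgets, partitions, exactness of order
statistics) hold regardless, but accuracy claims transfer only as far as
the model does.

## Statistics

Mann–Whitney tests are exact (full enumeration regime) when the combined
sample size is ≤12 without ties, otherwise normal approximation with tie
and continuity correction; Wilcoxon signed-rank analogously at n ≤ 15
after dropping zero differences. Two-way ANOVA uses type-II sums of
squares because per-sample class percentages are unbalanced across sites;
percentage responses are analyzed untransformed (an arcsine-square-root
variant can be applied upstream by the caller, but is not the default).
Šídák (`1−(1−p)^m`) and Bonferroni (`min(1, mp)`) adjustments are both
reported; Šídák is uniformly no larger. Significance is two-sided p < 0.05
throughout.

## Numerical conventions and degenerate inputs

* One quantile convention for descriptive percentiles (type 7,
  interpolating); ceiling order statistics for FPR-budget floors (exact
  in-sample guarantee).
* Ties at a gate threshold are negative.
* Constant intensity vectors: k-means refuses (degenerate), the fallback
  returns the constant, `is_unimodal()` returns TRUE.
* A class absent from an image yields missing (never zero) distance
  entries; a single-cell class has no self-distance.
* Zero iCAFs: the myCAF:iCAF ratio is reported missing, not infinite.
* Empty event tables, empty tissue masks and all-zero differences raise
  or flag rather than silently returning numbers.

## Problem sizes

The validation suite runs the generator at 10,000 cells/image for
composition recovery (sampling SD ≈ 0.5 pp for a 25% class), 50,000
events/sample for CyTOF subset recovery (SD ≈ 0.2 pp), 512×512 collagen
images (~160,000 tissue pixels), oracle comparisons at n ≤ 2,000
(thresholds), n ≤ 500 (distances) and ≤8 nodes (exhaustive partitions,
Bell(8) = 4,140), and 200–1,000 simulations for power/level checks. The
bundled analysis workflow uses 3 samples/site at the same per-image sizes.
These sizes were chosen so Monte-Carlo error sits well inside each stated
tolerance.

## Known limitations

* The adaptive MAD fallback over-calls rare populations on skewed
  backgrounds unless floored; the package surfaces this rather than
  patching it, and offers manual mode for rare-class work.
* The occupancy-grid area is a surrogate; densities are comparable within
  a cohort analyzed with one bin size, not across bin sizes.
* Structure mapping quantizes boundaries at the grid scale (default
  50 µm); margin assignments within half a bin of a boundary are
  grid-dependent.
* Community detection on near-uniform networks legitimately returns a
  single community; modularity near zero is a finding, not a failure.
* Sample sizes of the bundled workflow (3 samples/site) support
  demonstration and determinism checks, not powered inference.
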