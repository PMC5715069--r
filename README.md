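# gdstages

Staging, lineage and repertoire analysis of γδ T cell development in the
adult mouse thymus.

Most studies split developing γδ thymocytes only into immature
(CD24^high) and mature (CD24^low) cells. Adding CD117, CD200 and CD371 to
CD24, CD25 and CD73 resolves seven developmental populations, **A–G**,
which organise into three pathways ending in adaptive-naive (γδTn, export
at stage C), IFN-γ-producing (γδT1, export at stage E) and
IFN-γ/IL-4-co-producing (γδNKT, export at stage G) effector subsets.
`gdstages` implements the complete computational chain behind that model,
for immunologists analysing six-marker cytometry panels and
population-level RNA-Seq of sorted thymocyte subsets:

* **Staging** — marker-signature gating of events into A–G via a fixed
  decision tree (CD24^lo → G; else CD73⁺ → E/F by CD117; else CD200⁺ → D;
  else CD371⁺ → A/B by CD25; else C), with explicit, configurable
  positivity thresholds (KDE-valley, negative-control quantile, or
  manual).
* **Unsupervised rediscovery** — batch self-organizing map (10×10 grid)
  with average-linkage metaclustering at *k* = 7, cluster mean profiles,
  cluster→stage matching, and seeded t-SNE embedding.
* **Lineage inference** — pairwise Euclidean distances
  d(p,q) = √Σ_g (x_pg − x_qg)² between population transcriptomes
  (log2 CPM, replicate means), the minimum spanning tree as the model of
  developmental relatedness (leaves = candidate export stages, degree-≥3
  nodes = branch points), population PCA, and Isomap / diffusion-map
  progression on per-population down-samples.
* **Marker screen** — per-gene one-way ANOVA between stage groups,
  Benjamini–Hochberg correction, and the four-way candidate filter
  |log2FC| > 3 ∧ q < 0.05 ∧ surface GO term (GO:0009986/GO:0005886) ∧
  max group mean log2 expression > 7.
* **Repertoire** — VDJtools-style clonotype tables: in-frame filtering,
  hypergeometric depth equalisation (e.g. 1200/724 reads), CDR3
  motif read fractions by regular expression, V/J usage, and inverse
  Simpson diversity D = 1/Σp².
* **Emigration blockade** — stage-wise fold changes under thymic-export
  blockade, terminal-stage calling (sustained accumulation), and the
  pooled-variance Student's t test.
* **Synthetic data** — seeded generators for all three data types with
  exact ground truth (stage labels, designed 7-node expression topology,
  planted CDR3 motifs and V usage, planted accumulation factors), so the
  whole pipeline is testable end to end without external data.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods for fitted objects, and `plot_*()` / `autoplot()`
functions for each result type.

## Worked example

Simulate a thymus, gate it, and recover the developmental tree:

```r
library(gdstages)
library(dplyr)

events <- simulate_cytometry(cytometry_sim_config(n_events = 10000, seed = 1)) |>
  arcsinh_transform()
thresholds <- fit_positivity_thresholds(events, "valley")
staged <- assign_stages(events, thresholds)

mean(staged$stage == staged$meta_true_stage)
#> [1] 1

stage_composition(staged, by = "meta_subset") |> filter(meta_subset == "Vg1.1")
#> # A tibble: 7 × 4
#>   meta_subset stage     n fraction
#>   <chr>       <chr> <int>    <dbl>
#> 1 Vg1.1       A       715    0.143
#> 2 Vg1.1       B       720    0.144
#> 3 Vg1.1       C       720    0.144
#> 4 Vg1.1       D       710    0.142
#> 5 Vg1.1       E       717    0.143
#> 6 Vg1.1       F       717    0.143
#> 7 Vg1.1       G       712    0.142
```

Every event lands in its true stage, and the seven stages appear at the
simulated equal proportions in both TCR subsets. Next, transcriptional
distances between populations and the lineage tree:

```r
sim <- simulate_expression(expression_sim_config(seed = 1))
dm <- distance_matrix(sim$log2, sim$samples, subset = "Vg1.1")
graph <- build_lineage_graph(dm, method = "mst")
graph
#> <lineage_graph> mst over 7 nodes; leaves: A, C, E, G; branch points: B, F
#> # A tibble: 6 × 3
#>   from  to    weight
#>   <chr> <chr>  <dbl>
#> 1 D     F       13.0
#> 2 E     F       13.1
#> 3 F     G       13.5
#> 4 B     D       13.6
#> 5 B     C       13.6
#> 6 A     B       13.8
```

The minimum spanning tree of the noisy simulated transcriptomes is
exactly the designed topology: the root A and the three export stages C,
E and G are leaves, and the two decision points B (naive vs TCR-selected)
and F (γδT1 vs γδNKT) are the branch points. Edge weights are the
Euclidean distances between population mean transcriptomes. Repertoire
statistics on a library with a CDR3 motif planted at 50% of in-frame
reads, depth-equalised to 1200 reads:

```r
lib <- simulate_clonotypes(repertoire_sim_config(
  planted_motifs = c(CALWELGF = 0.5), total_reads = 3000, seed = 1))$table |>
  filter_in_frame() |>
  downsample_reads(1200, seed = 1)
motif_fraction(lib, "CALWELGF")
#> [1] 0.5008333
inverse_simpson(lib)
#> [1] 27.12861
```

The planted motif is recovered within binomial sampling error, and the
library behaves as ~27 effective clones. `run_pipeline()` chains all of
the above (plus clustering, the marker screen and the blockade analysis)
from a single YAML-able config and writes a checksummed run manifest.

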