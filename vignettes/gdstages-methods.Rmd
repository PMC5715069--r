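---
title: "Methods: staging, lineage and repertoire analysis of developing gamma-delta thymocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staging, lineage and repertoire analysis of developing gamma-delta thymocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gdstages implements the computational chain behind a seven-stage model of
γδ T cell development in the adult mouse thymus. Six surface markers —
CD24, CD25, CD73, CD117, CD200 and CD371 — jointly define seven
populations, A through G, that organise into three developmental pathways
ending in adaptive-naive (γδTn, via stage C), IFN-γ-producing (γδT1, via
stage E) and IFN-γ/IL-4-co-producing (γδNKT, via stage G) effector cells.
The package covers six analysis stages plus a synthetic-data layer, and
this vignette records the models, the tunable parameters, and the design
decisions taken where the methods were genuinely open.

```{r setup}
library(gdstages)
library(dplyr)
```

## The staging model

Each stage is a marker positivity pattern (`stage_signatures()`). Gating
is a fixed decision tree mirroring bi-axial cytometry practice:

1. CD24^lo^ events are **G** (the classical "mature" gate);
2. otherwise CD73^+^ events are **E** (CD117^+^) or **F** (CD117^−^);
3. otherwise CD200^+^ events are **D**;
4. otherwise CD371^+^ events are **A** (CD25^+^) or **B** (CD25^−^);
5. everything else is **C**.

The tree makes the assignment a total partition: every event receives
exactly one stage, whatever its pattern. At load time the signature table
is checked for ambiguity by enumerating all 2^6 positivity patterns; a
table in which one pattern satisfies two signatures, or in which some
stage can never be a first match under the gating order, is rejected. The
CD117 status of stages A–D and G is deliberately `any`: the published
staging scheme constrains CD117 only where it separates E from F.

Intensities are arcsinh-transformed (`x -> asinh(x / cofactor)`), the
standard cytometry variance-stabilising transform. The cofactor defaults
to 150, conventional for fluorescence-scale data; it is a display/scale
choice, and gating is invariant to any monotone per-marker transform
applied consistently to events and thresholds (a property the test suite
asserts).

Positivity thresholds are explicit rather than graphical. Three methods
are provided: `valley` (default) takes the kernel-density minimum between
the two highest modes of each marker; `quantile` takes a high quantile
(default 0.999) of a labelled negative-control population, emulating an
FMO-style gate; `manual` passes user values through. `valley` refuses
unimodal markers rather than guessing, advising a manual threshold.

## Synthetic data as ground truth

No deposited cytometry or sequencing data are required: every downstream
stage is exercised against generators whose ground truth is known exactly.
The generators are first-class, seeded, and deterministic.

**Cytometry** (`simulate_cytometry()`): each stage × marker combination is
a single log-normal component (`neg`, `pos`, `hi`, `lo`). The published
material shows uni- or bimodal marker histograms but no distributional
model, so component locations are package defaults chosen to give > 4 SD
separation between positive and negative components after the arcsinh
transform — an idealised staging problem, deliberately easier than real
data (see *Limitations*). Stage counts in the reference group use
largest-remainder allocation, so expected fractions are hit exactly;
treated groups draw Poisson counts around `reference × accumulation
factor`. The default blockade factors
(`blockade_treatment_effects()`) reproduce the reported pattern: C, E and
G reach ten-, five- and ten-fold at day 10 while D and F rise early and
stall.

**Expression** (`simulate_expression()`): population mean profiles are
placed along a designed 7-node tree (default A–B, B–C, B–D, D–F, F–E,
F–G; branch points B and F, leaves A, C, E, G — the three-pathway
structure). Each tree edge owns a disjoint block of 30 signature genes
shifted by 2 log2 units on the child side, so squared Euclidean distance
between stage means is proportional to tree path length and the designed
tree is the unique minimum spanning tree of the noiseless profiles.
Counts are negative-binomial (dispersion 0.05, a typical bulk-replicate
value) around expected counts obtained by renormalising the designed
abundances so CPMs sum to 10^6 and scaling to a 2 × 10^5-read library;
values are returned as log2(CPM + 1). Two replicates × two TCR subsets ×
seven stages give 28 samples, matching the two-library RNA-Seq design the
package emulates. The ground-truth means are defined as the noiseless
pass-through of the same normalisation, so at `dispersion = 0` the
simulation reproduces them to machine precision.

**Repertoire** (`simulate_clonotypes()`): clone weights follow a power
law; planted CDR3 motifs carry exactly their target fraction of in-frame
read mass; out-of-frame mass (stop `*` or frameshift `_`) is exact; V
segments are assigned by a largest-first greedy fill of per-segment mass
deficits. One multinomial draw then produces counts, so measured
quantities deviate from targets only by sampling error — which is what the
recovery tolerances in the tests assert (e.g. a 50% motif at 1200 reads
is recovered within ±3 binomial SE = ±0.043).

**GO annotation** (`simulate_go_annotation()`): each gene is a
surface-term member with a set probability, every gene appears in the
map, and non-members carry background terms.

## Unsupervised population discovery

`som_fit()` is a batch self-organizing map: a 10 × 10 grid (default),
20 epochs, Gaussian neighbourhood with radius shrinking linearly from
half the grid span to 0.5, best-matching units with lowest-index
tie-breaking, codebook initialised from a seeded sample of events. Batch
mode makes training deterministic given the seed and makes the
single-node grid provably converge to the data mean. Quantisation error
is tracked per epoch.

`metacluster()` cuts an average-linkage dendrogram of codebook vectors at
*k* (default *k* = 7, the cluster number at which the original automated
clustering yielded seven similar-sized, interpretable populations). One
refinement proved necessary: nodes that are the best-matching unit of no
event sit in the empty space *between* populations (they are pulled there
by the neighbourhood function) and, under average linkage, can absorb a
cluster of their own, forcing two genuine populations to merge. The
agglomeration therefore uses occupied nodes only; unoccupied nodes
inherit the label of their nearest occupied node, so the node labelling
remains total. `cluster_profile()` reports per-cluster mean intensities
(empty clusters yield flagged NaN rows), and `match_clusters_to_stages()`
maps thresholded cluster means back to stage signatures — here strictly,
with no fall-through: a profile satisfying no signature is `unassigned`,
and two clusters mapping to one stage are kept and flagged rather than
silently merged.

`embed_events()` delegates 2-D embedding to Barnes–Hut t-SNE (Rtsne),
seeded and single-threaded for determinism. Its contract is shape,
determinism and neighbourhood preservation; the tests assert that a
k-NN readout of the embedding recovers true stages and that 15-NN
neighbourhoods are preserved better than by a random embedding.

## Lineage inference

`distance_matrix()` computes pairwise Euclidean distances between
population transcriptomes on log2(CPM + 1) over all retained genes, after
averaging biological replicates (the convention adopted for all
population-level visualisation). An exclusion list is applied first —
real analyses exclude, for example, a 41-transcript erythrocyte signature
carried by one contaminated sample; the list is user-supplied
configuration, not package data.

"Connecting the least transcriptionally different populations" is
formalised as the **minimum spanning tree**: the unique minimal connected
realisation of pairwise similarity. Kruskal's algorithm is implemented
directly so ties can be broken lexicographically (edge weight, then node
labels), making the graph deterministic; the test suite checks it against
exhaustive enumeration of all 7^5 labelled spanning trees via Prüfer
sequences. Because the published diagrams could also be read as a
nearest-neighbour sketch, a symmetrised k-NN graph (`method = "knn"`) is
provided alongside. Leaves of the tree are candidate thymic-export end
points; nodes of degree ≥ 3 are branch points.

`pca_populations()` is column-centred SVD of samples in gene space, with
explained-variance fractions; it corroborates branching rather than
defining it.

Two single-cell progression methods operate on per-population
down-samples (default 100 cells per population, seeded):

* `isomap_progression()` — symmetrised k-NN graph (default k = 10) on
  Euclidean marker distances, geodesics by Dijkstra shortest paths,
  classical MDS of the geodesic matrix. With a complete graph it reduces
  exactly to classical MDS (asserted at 10^-6). A fragmented graph is an
  error advising a larger k, not a silent per-component embedding.
* `diffusion_progression()` — Gaussian kernel with bandwidth defaulting
  to the median pairwise distance, density normalisation at α = 1,
  row-stochastic Markov matrix, eigendecomposition via the symmetric
  conjugate for stability, coordinates = non-trivial right eigenvectors
  scaled by eigenvalues, with deterministic sign fixing. The trivial
  eigenvalue is 1; a disconnected kernel shows a second unit eigenvalue
  (both asserted).

Neither method is rooted or directed: direction along the recovered
progression is a biological argument, not an algorithmic output.

## The surface-marker candidate screen

`normalize_log2()` produces log2(CPM + pseudocount); the screen otherwise
expects an already normalised, batch-corrected matrix (array
normalisation and batch correction are upstream concerns, out of scope).
`differential_f_test()` is a plain one-way ANOVA per gene — parametric F,
no moderation or shrinkage — vectorised over genes and cross-checked in
the tests against `anova(lm())` and against the squared pooled t
statistic. Degenerate genes (zero between- and within-group variance) are
flagged and given p = 1 by convention. `bh_adjust()` applies
Benjamini–Hochberg step-up (via `p.adjust`) after validating the input
range.

`screen_candidates()` is the four-way intersection: |log2FC| > 3,
BH-adjusted p < 0.05, annotation with a surface-expression GO term
(GO:0009986 cell surface or GO:0005886 plasma membrane), and maximal
group mean log2 expression > 7. All inequalities are strict, so a fold
change of exactly 3 fails. Two readings were open and are both
configurable: the fold-change filter is absolute by default (`signed =
FALSE`), since candidate markers may rise in either compared stage; and
"relative expression > 7" is read as a maximum over compared group means,
since a usable marker need only be expressed in one of them. Genes absent
from the GO map are non-members by definition and are counted and
reported, not dropped silently. `signature_score()` z-scores panel genes
across populations and averages them, the heat-map score used for
effector-programme panels.

## Repertoire statistics

Clonotype tables are VDJtools-style TSVs (`count`, `freq`, `cdr3nt`,
`cdr3aa`, `v`, `d`, `j`). In-frame filtering keeps rows whose CDR3
nucleotide length is divisible by 3 and whose amino-acid string has no
stop (`*`) or frameshift (`_`) mark — the standard clonotype-tool
convention, adopted because the source method states only that
out-of-frame transcripts were removed. `downsample_reads()` equalises
library depth by hypergeometric sampling without replacement (exactly the
"reduce reads to equal numbers" operation; the reference depths are 1200
reads for CDR3δ and 724 for CDR3γ libraries); an under-depth library is
an error because it must be excluded, not padded. Motif abundance is a
read fraction matched by a case-insensitive regular expression — the
effector-associated motif sequences themselves are user configuration,
because they are not printed in the source and hard-coding guesses would
be worse than requiring them. Diversity is the inverse Simpson index
1/Σp² (plug-in by default; an unbiased finite-sample estimator is
available via `unbiased = TRUE`).

## Emigration-blockade analysis

`fold_changes()` computes per-stage count ratios against the untreated
group, averaging replicates (per-mouse counts) first. A terminal
(export-ready) stage is one that both accumulates strongly by the final
time point (fold ≥ 3) and keeps accumulating between time points
(fold ratio day-10/day-5 ≥ 1.5). The narrative criterion being
formalised — "continued to accumulate" versus "increased only slightly" —
has no published numeric form, so both thresholds are explicit, default
values that cleanly separate ten-/five-/ten-fold accumulators from
sub-two-fold stages, and configurable. `student_t_test()` is the
two-sided equal-variance pooled t test used for group comparisons, with
no multiple-testing correction across stages (matching the reporting
convention of the analyses it mirrors).

## Orchestration

`run_pipeline()` runs the configured steps in dependency order from one
flat configuration (list or YAML): simulate → stage → cluster → lineage →
screen → repertoire → emigration. Each step writes plain-text tables
under `out_dir`; a `manifest.json` records package version,
configuration, seeds and MD5 checksums per output, and identical
configurations reproduce identical checksums. A failing step aborts with
its name; its partially written files keep a `.partial` suffix. The
package's function surface plus this orchestrator are the interface —
there is no separate shell executable, as the intended users work in R.

## Problem sizes and numerical choices

The default study conditions are: 10,000 cytometry events per group
(seven equal stages, two subsets), 500 genes × 28 samples for
expression, 100 cells per population for progression, and 1200/724-read
repertoire libraries. The validation suite uses these sizes directly; the
end-to-end recovery checks (staging accuracy ≥ 99%, clustering ARI ≥
0.90, MST tree recovery in ≥ 95/100 replicates, pseudotime correlation ≥
0.95/0.90, exact planted-screen recovery, motif recovery within binomial
error, terminal set exactly {C, E, G}) all run within minutes on one
core.

Numerical details worth knowing: best-matching-unit and nearest-node
ties break to the lowest index; MST ties break lexicographically;
diffusion-map eigenvectors are sign-fixed by their largest-magnitude
entry; KDE valley-finding uses 512 grid points; distances are computed
via an expanded-square form clipped at zero. Degenerate inputs
(constant expression matrices, empty clusters, unimodal markers,
zero-variance genes, under-depth libraries, zero reference counts)
raise errors or flagged conventions rather than propagating NaN.

## Limitations

The synthetic generators are designed for testability, not biological
realism. Marker components are single log-normals with strong
separation: real cytometry has spillover, debris, doublets, batch drift
and continuous transitional phenotypes, so the near-perfect staging
accuracy and ARI on synthetic data say nothing quantitative about real
samples — they say the algorithms are correct, not that the biology is
easy. Expression noise is pure negative-binomial around designed means;
there are no batch effects, no length/GC biases and no correlated gene
modules beyond the planted blocks. Clonotype tables are generated at the
table level: read-level errors, alignment artefacts and clonotype
assembly are upstream of this package's scope, as are compensation,
probe-level array processing and pseudoalignment.
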