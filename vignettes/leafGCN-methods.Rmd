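---
title: "Methods: clustering, co-expression networks and leaf physiology in leafGCN"
author: "leafGCN authors"
date: "`r Sys.Date()`"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering, co-expression networks and leaf physiology in leafGCN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafGCN)
```

# Scope

leafGCN reconstructs the transcription-factor (TF) network that couples
photosynthesis and leaf development in leaves of *Cichorium endivia*-type
leafy crops from bulk RNA-seq. The pipeline has five stages: construction
of a curated TF/photosynthesis gene database from an annotated
transcriptome; within-sample normalization; K-means clustering of
condition-mean expression profiles with an a-posteriori rule for the
number of clusters; a thresholded Pearson co-expression network with
joint-centrality hub detection; and guilt-by-association mining of
developmental genes inside the photosynthesis modules. A negative-binomial
simulator with planted structure makes every stage testable without any
external download; the chlorophyll-fluorescence, SPAD and malondialdehyde
formulas used for the physiological side of such studies are implemented
as plain vectorized functions.

# Database construction

Candidate records pass four filters, applied in a fixed order and
accounted per stage in a `FilterReport`:

1. **Genome hits** — a transcript must map to at most one locus of the
   reference genome (`genome_hits <= 1`, inclusive; hit counts are consumed
   as an annotation column, the alignment itself is out of scope).
2. **Protein completeness** — the full-length fraction, deduced protein
   length over annotated reference protein length, must be at least 0.7
   (inclusive). A record without a usable reference length cannot certify
   completeness and fails the stage; this is the conservative reading.
3. **MapMan validation** — applies to TF records only. Photosynthesis
   (PHOTO) records are selected by GO homology upstream and pass this
   stage regardless of their flag.
4. **Leaf expression** — a gene is removed iff its read count is below 10
   in *strictly more than* 90% of the samples; a gene low in exactly 90%
   of samples is kept. The boundary is read literally.

Filter composition is monotone and the report's stage arithmetic always
balances (`n_out = n_in - n_removed`, chained), which the tests verify
together with exact recovery of failure counts planted by the simulator.

# Normalization

Counts are normalized to RPKM,
$\mathrm{RPKM}_{gs} = 10^9 c_{gs} / (L_g N_s)$, with transcript length
$L_g$ in bp and $N_s$ the per-sample mapped total. When mapped totals are
known (the simulator records them; an aligner reports them for real data)
they are used; otherwise the column sum is the standard proxy. The
distinction matters: when the analyzed genes are a curated panel within a
much larger transcriptome, the panel's column sum is *not* the mapped
total, and using it injects a compositional common factor across all
genes — strong modules then induce spurious correlation among unrelated
genes. RPKM values are transformed as $\log_2(x + 1)$ and, for
clustering only, z-scaled per gene; constant genes cannot be scaled and
are flagged and excluded from clustering and correlation.

Cluster profiles are condition means: replicates are averaged per
cultivar-by-year group **on the RPKM scale**, then log-transformed, then
scaled — this order follows the reference workflow (RPKM means, then
log). With four cultivars and two production years this yields eight
condition-mean columns. The co-expression network, by contrast, is built
on the log2 RPKM of all individual samples.

# K-means clustering and the choice of k

`kmeansFit()` runs Lloyd iterations (via `stats::kmeans`) from k-means++
starts and keeps the best of `nInit = 50` restarts by the within-cluster
sum of squares; given a seed, the fit is deterministic. Cluster labels
are canonicalized by decreasing cluster size, so "clusters 1 and 2" are
always the two dominant modules. Distances are Euclidean on z-scaled
profiles; on standardized rows the Euclidean and centered-Pearson
orderings coincide, which resolves the usual ambiguity between the two
similarity measures without changing the result.

`kDiagnostics()` reports, per k, the SSE, the mean silhouette width
(Euclidean, via the cluster package) and the Calinski–Harabasz index
$\frac{B/(k-1)}{W/(n-k)}$. These are descriptive; the selection rule is
a-posteriori: `selectK()` returns the **largest** k in the range (default
2–15) whose fitted centroids have maximum pairwise Pearson correlation
strictly below 0.8. The rationale: once two centroids become
near-collinear, a real cluster has been split. k values are evaluated
descending and the first success returned; if none qualifies the minimum
k is returned with a `fallback` flag and a warning. A gene's
**score to core** is the Pearson correlation between its profile and its
own cluster centroid (the "correlation index with centroid" reading);
it is scale-invariant and lies in $[-1, 1]$, and `coreDriver()` returns
the gene closest to a cluster core with lexicographic tie-breaking.

# Co-expression network

Pearson correlations are computed for all unordered gene pairs over all
samples; the two-sided p-value uses $t = r\sqrt{(n-2)/(1-r^2)}$ with
$n - 2$ degrees of freedom. Edges keep pairs with $|r| \ge 0.8$ **and**
$p \le 0.05$, both inclusive; no multiple-testing correction is applied
(none is standard for this construction, and at 23 samples
$|r| \ge 0.8$ implies $p \ll 0.05$ anyway). The graph is simple,
undirected and unweighted; the correlation sign is carried as an edge
attribute only.

Topology metrics follow the usual definitions: degree; betweenness by
Brandes' algorithm (igraph), normalized by $2/((n-1)(n-2))$; closeness
$(n_c - 1)/\sum d$ within each node's connected component of size
$n_c$; local clustering coefficient $2T(v)/(\deg(v)(\deg(v)-1))$, zero
below degree 2. The global clustering coefficient is the mean local
coefficient; whether degree-<2 nodes enter the mean (as zeros) is a
convention switch, defaulting to inclusion. The characteristic path
length averages shortest-path lengths over connected ordered pairs;
disconnected pairs are excluded rather than treated as infinite. All of
these are verified in the tests against an independent oracle that
enumerates every simple path on small random graphs.

**Hubs** are genes in the top decile simultaneously for degree,
betweenness and closeness: each top set holds the best
$\lceil 0.1 n \rceil$ nodes by one metric, extended by ties at the
cutoff value, and the hub set is the intersection of the three, ordered
by degree. `maxDegreeGene()` reports the single most connected gene.
`subnetwork()` induces module views and can re-threshold at a stricter
$|r|$ (0.9 by default in the pipeline configuration) as used for focused
network figures. Edge lists and Cytoscape SIF files can be exported.

# Guilt by association and differential expression

`selectDevelopmental()` searches chosen clusters (by default the two
dominant, anticorrelated modules) for genes carrying a GO term — default
`GO:0044767`, developmental process — with score to core at or above a
floor (default 0.893, a deliberately tight cutoff that keeps only genes
sitting essentially on the cluster core). GO matching is exact-term;
ancestor propagation is the annotation producer's job, which keeps the
package free of ontology files.

`consistentDegs()` intersects per-comparison DEG tables (gene, log2 fold
change, FDR — the differential model itself, e.g. edgeR with TMM, is
upstream and out of scope): a gene qualifies iff it passes FDR ≤ 0.05
and |log2FC| ≥ 1 **with the same sign** in every comparison of every
group-A against every group-B cultivar in both years. Sign consistency
is required because a gene "always differentially expressed" between
broad- and curly-leaved types must not flip direction. A missing
comparison is an error, not a silently smaller intersection.

`termEnrichment()` uses the upper-tail hypergeometric test per term with
Benjamini–Hochberg adjustment. No enrichment method is canonical for
this kind of figure, so the simplest defensible choice was made and its
null behavior (super-uniform p-values under label permutation) is
tested.

# Leaf physiology

All formulas are implemented exactly as printed in the standard
chlorophyll-fluorescence literature, vectorized, with domain guards:

* $F_v/F_m = (F_m - F_0)/F_m$ (dark-adapted; healthy leaves fall in
  0.75–0.85);
* $\Phi_{PSII} = (F_m' - F_s)/F_m'$ (light-adapted);
* $\mathrm{Abs} = 1 - R/NI$ from red and near-infrared reflectance;
* $\mathrm{ETR} = \Phi_{PSII} \times \mathrm{PPFD} \times 0.5 \times
  \mathrm{Abs}$, with PPFD defaulting to 370 µmol m⁻² s⁻¹ (the actinic
  intensity near growth light) and 0.5 the PSII light fraction;
* chlorophyll (µg cm⁻²) $= 99 \cdot \mathrm{SPAD}/(144 - \mathrm{SPAD})$,
  strictly increasing on $[0, 144)$ with a fixed point at 45;
* MDA (nmol g⁻¹ FW) from $(A_{532} - A_{600})/155$ mM with a 1 cm path
  length (the universal cuvette for this assay), scaled through the
  assay dilution (default 3: 1 mL supernatant + 2 mL reagent) and the
  extract volume per gram fresh weight; the per-gram bookkeeping is
  exposed as explicit arguments because published protocols describe the
  volumes but rarely write the final conversion out. A negative
  difference (A600 > A532) is clamped to zero with a warning.

`fluorescenceTable()` ships the published per-cultivar means of these
parameters for two endive and two escarole cultivars; recomputing ETR
from its $\Phi_{PSII}$ and Abs columns reproduces the printed ETR column
within 0.5% — the residual is rounding of the printed inputs. The
acceptance script does exactly this recomputation.

# The synthetic-data generator

`simulateCounts()` emulates the statistical structure of a two-year,
four-cultivar leaf RNA-seq study:

* **Design** — 23 samples by default: 4 cultivars × 2 years × 3
  biological replicates, with one cultivar-year at 2 (the published
  design reports three replicates per cultivar and 23 samples in total;
  which cell lost a sample is not stated, so the last one was chosen).
* **Latent factors** — one standard-normal factor per anticorrelated
  module pair, drawn at the cultivar-by-year condition level with a
  replicate jitter of 0.15: module expression differs between cultivars
  and years, not arbitrarily between replicates. Drawing the factor per
  sample instead would make condition means of the exponential model
  Jensen-dominated by the largest replicate and destroy the planted
  centroid anticorrelation under the "RPKM means then log" order.
  Factors are sampled with **exact moments** (via `MASS::mvrnorm`
  empirical sampling, then per-sample standardization), so the realized
  cross-module correlation equals the target (−0.97 by default) instead
  of wobbling with a handful of condition draws.
* **Counts** — gene mean $= \mathrm{baseline} \times
  \exp(\mathrm{loading} \times \mathrm{factor} \times \mathrm{sign})$,
  negative-binomial sampling around that mean (baseline 500, dispersion
  0.05 by default), transcript lengths uniform on 500–3000 bp.
* **Modules** — two anticorrelated modules of 465 and 281 genes at
  loading 0.9 plus 1100 independent background genes by default,
  matching the scale of the real database's dominant module pair.
* **Mapped totals** — simulated per sample (20 million reads, 10%
  lognormal variation) and recorded in metadata, because the simulated
  genes stand for a curated panel within a full transcriptome; treating
  the panel's column sums as mapped totals would compositionally couple
  all genes to the dominant modules.
* **Hubs** — module genes are given graded loadings
  (`loadingSpread`) and planted hubs sit at the top of the gradient
  (`hubLoading`, low `hubDispersion` noise — hubs are core genes with
  tight profiles), with `hubExtraTargets` background genes weakly loaded
  on the host module's factor. In a thresholded correlation network only
  the highest-loading, lowest-noise genes stay above the edge threshold
  against marginal genes, so hubs acquire jointly high degree,
  betweenness and closeness while remaining module members. An explicit
  hub-private factor was tried and rejected: correlation triangle
  geometry forces any gene strongly tied to both the module and private
  targets to leak target–module edges, and pendant stars depress the
  hub's own closeness.
* **Planted failures** — `nSilentGenes` background genes are simulated
  near zero counts (they fail the leaf-expression filter by
  construction), and `simulateAnnotation()` plants exactly-one-filter
  failures on distinct genes so `buildDatabase()`'s report can be checked
  against the configuration exactly.

`hubStudyConfig()` freezes the benchmark for hub recovery: 48 samples
(six replicates per condition), two 40-gene modules at loading 0.26
(spread 0.04), five hubs per module at loading 1.0, four targets per
hub, 150 background genes, dispersion 0.02. The compact size keeps the
top-decile cutoff close to the number of planted hubs, and the moderate
module loading prevents the modules from saturating into cliques in
which degree no longer discriminates; at this design the joint
top-decile criterion recovers the ten planted super-connectors with a
mean Jaccard above 0.9 across seeds.

**What the simulator does not emulate:** library-size composition
effects beyond the lognormal depth factor, gene-length–expression
coupling, isoforms, batch effects, heavy-tailed per-gene dispersions,
and correlated background structure. Passing tests on the simulator
therefore demonstrate that the pipeline recovers the structure it
assumes, not that real leaf data satisfy those assumptions.

# Numerical choices and degenerate inputs

* k-means++ restarts that produce an empty cluster are discarded and
  redrawn from the remaining restarts; assignment ties go to the lowest
  cluster index (the behavior of the underlying Lloyd implementation).
* `selectK` evaluates k descending and stops at the first success —
  equivalent to "highest qualifying k" at lower cost.
* Correlation values are clipped to $[-1, 1]$ before the t-transform;
  $|r| = 1$ maps to $p = 0$.
* Constant profiles are an error in `pairwiseCorrelation()` and a flag
  in `zscale()`; a constant centroid makes score-to-core undefined and
  raises an error rather than returning NA.
* Empty graphs, empty universes, zero mapped totals, SPAD ≥ 144,
  F0 > Fm and missing comparison cells all raise informative errors.

# Problem sizes used in the checks

The test suite exercises the full default simulation (1846 genes × 23
samples) for module recovery, 600 background genes (≈180,000 pairs) for
the null edge rate, five seeds of the compact hub benchmark, and 200
random graphs of up to 8 nodes against the exhaustive path-enumeration
oracle; the whole suite runs in well under a minute on one core.

# Limitations

Score-to-core is defined as a Pearson correlation; if a different
closeness-to-centroid statistic is preferred, only `scoreToCore()` needs
replacing. The centroid-correlation k rule inherits K-means'
sensitivity to initialization, mitigated but not removed by 50
k-means++ restarts. Closeness uses the per-component convention, which
assigns high closeness to tiny isolated components — the joint hub
criterion is robust to this because such nodes never rank in degree and
betweenness simultaneously, but closeness rankings alone should not be
interpreted on fragmented graphs. The enrichment test conditions on the
annotation as given and is exact-term only.
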