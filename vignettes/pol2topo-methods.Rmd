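---
title: "Methods: spike-in normalized Pol2 contact topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in normalized Pol2 contact topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pol2topo)
```

# Scope and model

`pol2topo` analyses protein-centric chromatin contacts (HiChIP) between
two conditions, asking where RNA polymerase II clustering is gained or
lost. The pipeline is deliberately simple and transparent: no
statistical loop caller, no matrix balancing. Its core objects are

* **valid pairs** — one ligation contact between two loci, tagged
  `human` or `spikein` by chromosome-name prefix;
* **contacts** — valid pairs aggregated on a fixed bin grid, scored as
  `aqua_cpm = raw_count * 1e6 / spikein_valid_pairs` (RRPM);
* **topological features** — connected components of the thresholded
  contact graph: peaks (0 edges), loops (1), clusters (≥ 2);
* **gene metrics** — region-wise Pol2 signal ratios per gene (TR, PULR).

## Why spike-in normalization

Foreign chromatin added at a fixed input ratio (1:10 mouse:human for
HiChIP) passes through pull-down and sequencing with the sample, so its
final pair count measures everything *except* the biology: input mass,
IP efficiency, depth. Dividing by it yields cross-sample-comparable
units. The exact canonical denominator is a convention; we use the
spike-in total alone (RRPM). Every cross-condition conclusion in the
package depends only on the *ratio* of the statistic between samples,
which is invariant to this choice up to a constant, and a documented
property test asserts invariance under joint rescaling of human and
spike-in counts.

A consequence worth stating: if treated and control received the same
chromatin input, the spike-in totals of the two libraries estimate the
same quantity, and `log2(aqua_cpm_trt / aqua_cpm_ctrl)` estimates the
true per-contact fold change even when the treated library globally
lost contacts. Depth-based CPM would not.

## Filtering choices

* Cis pairs at distance **≤ 1000 bp are removed** (boundary removed);
  they are dominated by spurious adjacent-fragment ligations in
  MNase-based protocols. Trans pairs are kept through normalization but
  excluded from distance-windowed analyses.
* **PCR duplicates are kept** by default. In punctate pull-downs
  duplicates concentrate at true peaks; removing them flattens real
  signal. A `drop_duplicates` flag exists for non-punctate use.
* Contacts are binned at **5 kb** (`anchor_bin`); bin distance is the
  difference of bin midpoints.

## Feature calling (peak3D rule)

Edges with `aqua_cpm` strictly above a preselected threshold are
clustered by shared anchors (union–find; an independent
breadth-first-search oracle in the test suite checks the partition on
random graphs). Classification is purely structural: 1 edge = loop,
≥ 2 edges = cluster; 1D Pol2 peaks whose bin carries no passing edge
become 0-edge peak features. The numeric threshold is a config value
with no universal default — it should sit above the sporadic background
count scale (the acceptance script uses 3 raw-count equivalents against
a planted rate of 50). Feature identifiers are coordinate-sorted, so
all downstream tables are deterministic. Raising the threshold can only
remove edges but can *split* clusters into loops, so cluster counts are
not monotone in the threshold — both facts are asserted in tests.

Ranking by total AQuA signal provides the hockey-stick style ordering.
The upstream study names a ranking algorithm without specifying it;
ranking by total normalized signal is this package's documented
stand-in, with deterministic tie-breaks (span, then id).

## Annotation conventions

* Overlap is binary per anchor (≥ 1 bp, half-open); TF occupancy is a
  count of peaks.
* Interval-to-point distance uses the open end boundary: the distance
  from `[s, e)` to a point `p ≥ e` is `p − e`. With the inclusive
  ≤ 5 kb window this makes the proximal/distal boundary exactly
  reproducible.
* Loop categories are symmetric in anchor order (labels sorted before
  joining), so they cannot depend on storage order.
* Two CpG summaries are emitted at feature level (fraction of loop
  *ends* in CpG, counted per edge; and per-anchor flags) because the
  corresponding published percentage has an ambiguous denominator.

## Differential analysis

Units (edges keyed by anchor pairs) absent in one condition get signal
0 rather than being dropped: collapse means disappearance, and
dropping would bias toward the null. L2FC uses a pseudocount ε
(default 0.5 CPM, config-exposed; no published value exists). The
long-range window 25 kb–3 Mb is inclusive at both ends. APA averages
`(2·flank+1)²` submatrices centred on loop anchor pairs; enrichment is
center over the mean of four corner quadrants of side
`max(1, flank %/% 2)`, ε-guarded. Whether the published "±1 kb bins"
denotes bin size or flank is ambiguous; both presets exist
(`apa_bin_size` 5000 or 1000) and nothing downstream depends on the
resolution of that ambiguity.

## Gene regions, TR and PULR

Plus strand, half-open, 0-based: promoter `[TSS−800, TSS−30)`, TSSR
`[TSS−30, TSS+300)`, body `[TSS+300, TES)`, TESR `[TES, TES+4000)`.
Boundary bases are counted exactly once. Minus-strand genes use the
interval reflection about the TSS/TES points that preserves all four
region lengths: promoter `[TSS+30, TSS+800)`, TSSR `[TSS−300, TSS+30)`,
body `[TES, TSS−300)`, TESR `[TES−4000, TES)`. This is the unique
half-open mirroring under which a uniform-coverage gene gives identical
metrics on both strands (the worked example: lengths 770/330/1700/4000,
PULR = 0.7, TR = 330/1700).

`TR = signal_TSSR / signal_body` (pausing). `PULR` defaults to
`(promoter + TSSR + body) / TESR` — "everything before the TES over
what lies past it". A narrower reading of the published definition
omits the body; both are implemented
(`pulr_numerator = "pre_tes" | "promoter_tssr_only"`), defaulting to
the inclusive form, which matches the published main-text description
of the metric. Signals are areas (coverage × bp); the ratios are
invariant to sum-vs-mean summarization only because region lengths are
fixed, which is why area is used throughout. Zero denominators give
`NA`, never `Inf`. Genes ≤ 300 bp have an empty body and are flagged.

# The synthetic world

The generator states, once, the world the pipeline is tested against:

| parameter | default | why |
|---|---|---|
| clusters | 50 | desk-scale stand-in for the ~374 published P3F clusters |
| loops/cluster | Poisson(7.7), min 2 | published cohort mean |
| anchor grid | 5 kb | contact-map bin size |
| contact rate λ | 50 pairs/loop | well above background, Poisson noise ~14% per loop |
| spike-in fraction ρ | 0.1 | 1:10 chromatin input |
| background | 0.5 × planted pairs, distance^−1 decay | free parameter; the source does not model background |
| γ_d (distal P3F loss) | 0.5 | a 2-fold collapse, median L2FC −1 |
| γ_c (CpG×CpG gain) | 2.0 | a 2-fold gain, median L2FC +1 |
| γ_t (TESR depletion) | 0.5 | doubles PULR exactly |
| CpG-promoter loops | 150 | sized a priori so a category median has 3σ margin in a ±0.1 null band: per-unit L2FC SD at λ=50 is √(2/50)/ln 2 ≈ 0.29, median SE ≈ 1.253·0.29/√n, so n ≥ ~120 |

Genes sit in non-overlapping slots (one per ~200 kb), enhancers on a
5-kb grid 15–80 kb upstream of their TSS (hence unambiguously distal
under the 5-kb window), 30% of enhancers carry P3F and every P3F peak
is nested in a p300 peak. CpG islands (500–2000 bp) are centred on an
exactly-`round(fraction·n)` subset of TSSs. Contact pair positions are
placed at bin midpoints so that binning recovers planted anchors
exactly — this removes anchor-matching ambiguity from recovery tests by
construction.

The architecture (which loops exist) is drawn from `arch$seed` alone,
so control and treated share it; only Poisson counts are
condition-specific (`count_seed`). The spike-in total is drawn from the
*baseline* expected human total, not the condition-modified one,
mimicking constant chromatin input — this is precisely what lets AQuA
L2FC estimate the planted factors.

What the generator does **not** emulate: restriction/MNase fragment
structure, ChIP efficiency variation, trans contacts, copy-number or
mappability artefacts, overlapping transcripts, and realistic
distance-dependent loop strength. A green recovery test therefore
establishes correctness of the bookkeeping and estimators under the
stated noise model, not performance on real libraries.

## Numerical choices and degenerate inputs

* Thresholding is strict (`>`), matching the "above threshold" rule;
  ties at the 1000-bp filter are removed ("1000 bp or less").
* Union–find uses size-weighted union with path halving; partitions
  are compared to a BFS oracle, not assumed.
* `l2fc` requires ε > 0 and is finite by construction; rank tables
  break ties by unit id.
* Empty inputs: empty BED/bedGraph/pair files parse to empty tables;
  empty gene lists give distal/∞ annotations; APA with zero usable
  loops is an error, not a silent zero matrix.
* Coordinates are 0-based half-open internally everywhere;
  `allValidPairs` positions (1-based) are converted on read and
  restored on write.

## Known limitations

* The AQuA denominator is the spike-in total alone; if a study's
  convention also involves human depth, absolute values differ by a
  per-sample constant (cross-condition ratios do not, given equal
  inputs).
* Trans features are carried but under-analysed by design (span and
  distance are cis concepts).
* No significance testing of differential loops — the upstream
  analysis reports distributions, and so does this package.
* The CLI covers the pipeline path end to end but is a thin
  convenience layer; programmatic use is the primary interface.
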