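---
title: "Methods: topology, modules, and motifs of regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology, modules, and motifs of regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trntopo)
```

This vignette is the package's own account of the methods it implements:
the statistical model behind each stage, the conventions and numerical
choices made where the literature leaves them open, what the synthetic
generator does and does not emulate, and the known limitations.

## The data model

A transcriptional regulatory network (TRN) is a directed graph from
regulators — DNA-binding transcription factors (TFs) and σ factors — to
the genes they control. The package's `trn` container holds a node table
(`id`, `class` ∈ {TF, sigma, target}) and an edge table (`regulator`,
`target`, `mode`, `evidence`). Conventions, chosen to be robust to the
quirks of curated database exports:

* Identifiers are trimmed and compared case-insensitively; the first-seen
  spelling is kept for display, and σ-factor names are canonicalized to the
  `sigX` spelling (curated exports mix `SigA`/`sigA`).
* Duplicate `(regulator, target)` rows — the same interaction listed under
  several promoters — collapse to one edge. Co-occurring activation and
  repression reconcile to `dual`; the strongest evidence level wins.
* A regulator reported as both TF and σ factor is a load error rather than
  a silent overwrite, since the class drives downstream subnetwork
  extraction.
* Self-loops (autoregulation, e.g. `hrcA`) are biologically real and are
  preserved in the graph and in degree counts; motif matching handles them
  separately (below).
* Isolated nodes survive serialization through `#! node` directive lines in
  the TSV dialect, so a write/parse round trip is lossless and the
  canonical (byte-sorted) serialization is reproducible byte-for-byte.

## Degree structure and tail fits

`degree_stats()` computes the degree histogram over *all* nodes (zero-degree
nodes count in the denominator) for one direction; a self-loop adds one to
both the in- and the out-degree of its node. The CCDF — the fraction of
positive-degree nodes with degree ≥ k — conditions on k ≥ 1 because log 0
is undefined; this convention is stated rather than hidden so results are
reproducible.

`fit_tail()` follows the classical regression approach: ordinary least
squares of log₁₀ CCDF on log₁₀ k (power law) or on k (exponential), with R²
as the goodness-of-fit measure and `compare_models()` choosing the higher
R² (ties go to the power law, with a warning, so the choice is
deterministic). Two conventions are worth spelling out:

* **The off-by-one.** A density P(k) ∝ k^(−γ) has CCDF ∝ k^(−(γ−1)), so the
  fitted CCDF slope *understates* the exponent by one. The fit object
  reports both the raw slope and the implied P(k) exponent (slope − 1) to
  remove the ambiguity.
* **Fit range.** The default is all k ≥ 1 (no cutoff), with `k_min`
  available; at least 3 distinct degrees are required, otherwise the fit
  errors rather than returning an unreliable line.

This is deliberately *not* maximum-likelihood (Clauset-style) power-law
fitting: the regression-on-CCDF approach is what the comparative TRN
literature uses, and R²-versus-R² is its model-selection rule. The known
cost is that the sparse extreme tail of an empirical CCDF scatters below
the true line, so single-draw exponent estimates carry noise of roughly
±0.1–0.25 at a few hundred samples; validation therefore averages the
estimate over several generator seeds (see "Problem sizes" below).

Clustering coefficients use the undirected simple projection (self-loops
removed, reciprocal edges merged); nodes with projected degree < 2
contribute 0 to the mean, the convention of the hierarchical-modularity
literature this analysis follows.

## Module detection

The association function s(i,j) = 1/d(i,j)², with d the shortest-path
length on the undirected projection, amplifies close regulatory
relationships (s = 1 for neighbours) and damps remote ones (1/4, 1/9, …);
unreachable pairs get exactly 0 and the diagonal is 1. Distances are
computed undirected because the association is a closeness measure feeding
a symmetric clustering; directed distances would make the matrix
asymmetric, which agglomerative clustering cannot consume.

`cluster_modules()` runs average-linkage (UPGMA) agglomeration on the
dissimilarity D = 1 − s. The monotone transform to a dissimilarity
preserves the ordering of associations, which is all average linkage uses.
Three deliberate choices:

* **Only the largest connected component is clustered.** Disconnected
  regulator groups have association 0 to everything, so their merge order
  within a dendrogram would be arbitrary; each extra component instead
  becomes its own module, appended after the cut modules and reported
  separately (`component_modules`).
* **The default cut is the largest gap in consecutive merge heights**, with
  the gap between the final merge and the maximum dissimilarity 1 standing
  for the single-module cut — so an unstructured network can legitimately
  come back as one module. An explicit module count is available when a
  fixed granularity is wanted (for example, cutting the regulator
  subnetwork of a curated TRN into its known number of modules).
* **Determinism.** Node order is byte-wise lexicographic everywhere, module
  indices renumber to the byte-order of each module's smallest member, and
  no stage draws random numbers, so partitions are bit-reproducible.

Girvan–Newman community detection (iterative removal of the highest
edge-betweenness edge, via igraph) is the alternative method;
`compare_partitions()` quantifies agreement by the adjusted Rand index and
normalized mutual information, plus a module-by-module Jaccard matrix and
set-relation labels (equal / subset / superset / overlap / disjoint) that
express the typical finding that different methods recover the same
modules at different granularity. ARI and NMI are computed in-package from
the contingency table (Hubert–Arabie; Danon normalization) because the
igraph implementation rejects the all-singletons edge case; the degenerate
zero-denominator cases (two trivial partitions) compare as 1 when
identical. Map-equation or other external partitions load through the
two-column TSV exchange format.

## Motif census

`find_motifs()` enumerates feed-forward motifs (FF: A→B, B→C, A→C) and
complex feed-forward motifs (CFF: an FF plus the feedback edge B→A) as
**induced** subgraphs, the mfinder convention: any additional edge among
the three nodes (C→A, C→B, or B→A for an FF) disqualifies the triple, so
the FF and CFF classes are disjoint by construction. Self-loops are ignored
for motif membership; edge modes are ignored because the motif definitions
are sign-blind. In a CFF the two regulators are topologically
interchangeable, so the byte-smaller identifier is reported as master to
make the instance list canonical.

The null model is the standard degree-preserving switching algorithm:
repeated double-edge swaps, rejecting any swap that would create a
self-loop or duplicate edge, so every node's (in, out) degree pair is
conserved exactly — asserted programmatically after every randomization.
Existing self-loops are pinned in place (they cannot participate in motifs
and swapping them would alter loop counts). Defaults follow common
practice: 1,000 randomizations, 100 swap attempts per edge, and an
empirical p-value with a +1 pseudocount, p = (1 + #{null ≥ obs})/(1 + n),
so p is never exactly 0; a motif class is *selected* when p < 0.01.

Embedding is defined on the regulator pair only: an instance is embedded
when master and local share a module, and mediates inter-module cross-talk
otherwise. Targets are mostly structural genes outside the regulator
partition and do not enter the rule. Role profiles count master (A) versus
local (B) appearances per regulator; the same gene can be master in one
instance and local in another, so the dominant count classifies it, with
exact ties reported as `mixed`.

## The synthetic generator

`simulate_trn()` produces networks with the statistical structure the
analysis assumes, plus the ground truth needed to score recovery:

* regulators split into planted modules, wired by intra- versus
  inter-module edge probabilities (the planted structure is undefined
  unless intra > inter — enforced);
* per-regulator target fan-out drawn from a discrete power law on
  [1, n_targets] by inverse-CDF sampling (truncation avoids pathological
  fan-outs in a finite network); `n_targets` is a *pool* — only sampled
  targets become nodes;
* planted FF/CFF instances on regulator pairs with **fresh** targets, which
  guarantees the planted instance survives induced-subgraph matching; FF
  pairs are placed within one module with probability 0.89 and across
  modules otherwise, and CFF pairs always within one module, mirroring the
  predominantly module-embedded placement of these motifs in real TRNs;
* optionally a housekeeping σA-like hub wired to a stated fraction of the
  realized node set (so hub out-degree / node count matches the coverage
  parameter to within one node);
* evidence labels drawn 90% strong / 10% weak so the evidence-filtering
  stage is exercised end-to-end.

Default parameters emulate a curated *B. subtilis*-scale TRN: 70 regulators
(about 22% σ factors, matching 16 of 70), nine modules, out-degree exponent
2.1, hub coverage 46.5%, sparse regulator–regulator wiring (intra 0.12 /
inter 0.005, giving on the order of 80 regulator–regulator edges). The
generator is a pure function of its spec, including the seed.

**What passing tests on generated networks do and do not show.** The
generator reproduces the degree laws, the hub, the modular block structure,
and planted motif excess — so oracle-equivalence, conservation, and
recovery tests validate the *algorithms*. It does not reproduce pervasive
co-regulation (real regulons share large target sets, which is what drives
both the high clustering coefficient ≈ 0.5 of curated TRNs and their strong
global FF excess), promoter-level detail, or the literature-derived
functional annotation of modules. Consequently the emulated network's mean
clustering is much lower than a real TRN's, and its global FF excess over
the switching null is modest and varies from draw to draw — properties of
the emulation, stated here so they are not mistaken for analysis defects.

## Numerical choices and degenerate inputs

* Classed conditions (`trntopo_*_error`/`_warning`) for every failure mode:
  empty networks, malformed lines, class conflicts, degenerate (all-zero)
  degree distributions, insufficient fit points, mismatched fit ranges,
  over-large cuts, incomparable partitions, unswappable graphs.
* Exact-fit R² is compared to 1 at machine precision in validation; the
  `lm` "essentially perfect fit" warning is suppressed inside `fit_tail()`
  because exact synthetic inputs are a supported use.
* Networks with fewer than two swappable (non-loop) edges are returned
  unchanged from the null with a warning rather than spinning.
* All stochastic stages take explicit integer seeds; randomization *i* of a
  significance run uses `seed + i`, keeping runs independent and
  reproducible.

## Problem sizes used in validation

Validation suites run on sizes chosen to make the statistical claims
stable while keeping the whole suite quick to run:

* oracle equivalence on all 63 non-empty 3-node digraphs plus 100 random
  fixtures of up to 8 nodes;
* degree conservation of the null across 200 seeds on a ~50-regulator
  fixture;
* planted-module recovery averaged over 50 generator seeds at the
  well-separated condition (intra 0.3 / inter 0.01, 4 modules of 10);
  recovery at this condition ranges roughly 0.76–1.0 ARI per draw, which is
  why the claim is about the mean;
* exponent recovery averaged over several 800-regulator draws (single-draw
  CCDF fits carry ±0.1–0.25 noise, as noted above);
* significance runs at 200 randomizations, for which the smallest
  attainable p is 1/201 ≈ 0.005, comfortably below the 0.01 selection
  threshold.

## Known limitations

* The CCDF regression estimator is biased by tail sparsity; for precise
  exponent estimation on real data, a maximum-likelihood fit would be the
  complement (deliberately out of scope here, as the regression is the
  method under study).
* Average linkage on 1 − s inherits the coarse distance spectrum of
  unweighted shortest paths (s takes few distinct values on small
  diameters), so dendrogram gaps — and hence the auto cut — can be
  shallow on dense networks; the explicit cut exists for exactly this case.
* The switching null conserves degrees only; TRN features such as operon
  structure or promoter sharing are not conditioned on, which is the
  standard — but known — simplification of motif-significance testing.
* Girvan–Newman and map-equation partitions of the same network may differ
  in granularity; the comparison report is designed to express
  subset/superset structure rather than force a single "correct" module
  count.
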