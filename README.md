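# trntopo

Topology, modules, and motifs of bacterial transcriptional regulatory
networks (TRNs).

A TRN is a directed graph whose edges point from a regulator — a DNA-binding
transcription factor (TF) or a σ factor — to the genes it controls. Curated
databases export these networks as edge lists annotated with the regulator
class, the regulatory mode (activation / repression / dual), and the
strength of the experimental evidence. `trntopo` implements the standard
topological analysis of such a network for systems biologists:

* **Degree structure.** In-/out-degree distributions *P(k)*, the
  complementary cumulative distribution (CCDF), the degree-dependent
  clustering coefficient *C(k)*, and least-squares tail fits on the CCDF.
  A scale-free out-degree *P(k) ∝ k^(−γ)* appears as a log-log CCDF line of
  slope −(γ−1); the fit reports both the slope and the implied *P(k)*
  exponent, and its R² is compared against an exponential alternative to
  choose the better model.
* **Module detection.** Shortest-path association *s(i,j) = 1/d(i,j)²* over
  the regulator subnetwork (global housekeeping hubs such as σA can be
  excluded, since a regulator wired to half the genome collapses all
  structure into one mega-module), followed by hierarchical agglomerative
  average-linkage clustering of the dissimilarity 1 − *s*. Girvan–Newman
  edge-betweenness communities serve as the alternative method, and any
  externally produced partition can be loaded for comparison (adjusted Rand
  index, normalized mutual information, module-wise Jaccard and set
  relations).
* **Motif census.** Feed-forward motifs (FF: A→B, B→C, A→C) and complex
  feed-forward motifs (CFF: an FF plus the B→A feedback edge), matched as
  induced subgraphs so the two classes are disjoint. Over-representation is
  assessed against a degree-preserving edge-switching null model
  (empirical *p* with a +1 pseudocount; a class is a *motif* when
  *p* < 0.01). Per-regulator master/local role profiles, per-pair target
  counts, and the fraction of motifs embedded within modules versus
  mediating inter-module cross-talk complete the census.
* **Synthetic networks.** A seeded generator with planted modules, planted
  FF/CFF motifs, power-law out-degree, and an optional σA-like hub, so the
  whole pipeline can be validated against known ground truth.
* **Pipeline.** `run_trn_pipeline()` chains every stage from a YAML or list
  config into one machine-readable report; `inst/scripts/trn.R` exposes the
  same steps as a command-line tool.

## Worked example

A miniature curated-style edge list ships with the package:

```r
library(trntopo)

f <- system.file("extdata", "example_trn.tsv", package = "trntopo")
net <- parse_trn(f)
#> Parsed example_trn.tsv: 14 nodes, 17 edges.

regulator_subnetwork(filter_evidence(net, "strong"), exclude = "sigA")
#> <trn> 6 nodes (5 TF, 1 sigma, 0 target-only), 4 edges
```

Evidence filtering keeps strongly supported interactions; the regulator
subnetwork keeps only regulator→regulator edges, dropping the housekeeping
factor σA whose fan-out would otherwise tie everything together. Motif
enumeration on the full network finds one of each class:

```r
find_motifs(net)
#> # A tibble: 2 × 4
#>   motif_type master local target
#> 1 CFF        abrB   spo0A spoIIE
#> 2 FF         sigA   ccpA  ackA
```

The FF is σA activating both `ccpA` and its target `ackA`; the CFF is the
mutual `abrB`/`spo0A` switch co-regulating `spoIIE` — the classic
sporulation-entry feedback. Role profiles count how often each regulator
occupies the master (A) versus local (B) position:

```r
regulator_roles(find_motifs(net))
#> # A tibble: 4 × 4
#>   regulator n_master n_local role
#> 1 abrB             1       0 master
#> 2 sigA             1       0 master
#> 3 ccpA             0       1 local
#> 4 spo0A            0       1 local
```

On a realistically sized network the same verbs chain together:

```r
sim <- simulate_trn(trn_spec(seed = 1))        # planted-truth network
ds  <- degree_stats(sim$network, "out")
fit <- fit_tail(ccdf(ds), "power_law")         # implied P(k) exponent
part <- cluster_modules(
  regulator_subnetwork(sim$network, exclude = "sigA"), cut = 9)
sig <- motif_significance(sim$network, n_random = 1000, seed = 1)
motif_embedding(find_motifs(sim$network), part)
```

or in one call:

```r
report <- run_trn_pipeline(list(synthetic = list(seed = 1), n_random = 1000))
```

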