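# regnda

Meta-curation and natural decomposition of bacterial transcriptional
regulatory networks, in R.

Curated regulatory knowledge for bacteria exists as regulon-level edge
lists — a transcription factor, its targets, the effect and the evidence —
scattered across databases and publications, under inconsistent gene
naming and with poor mutual overlap. `regnda` is for systems biologists
who want to (i) reconcile such datasets into one non-redundant network
model and (ii) dissect that model's architecture above the regulon level.
It provides:

* **Identity resolution** — a constrained bipartite mapping of arbitrary
  gene symbols onto locus tags; ambiguous (degenerate) names are marked
  taboo instead of being guessed.
* **Meta-curation** — evidence classification (strong/weak), overlap
  quantification, and merging of datasets with lattice reconciliation of
  conflicting effects (`activation` ∧ `repression` → `dual`) and evidence
  (the strongest report wins).
* **Global properties** — degree / out-degree / clustering distributions
  with robust power-law fits (Huber's T M-estimation on log-log data,
  k = 1.345), insensitive to tail outliers.
* **The natural decomposition approach (NDA)** — fits the
  clustering-vs-out-degree curve `C(k_out) = a·k_out^(−b)` and derives the
  network-specific threshold

  `κ = (a·b)^(1/(b+1))`, the out-degree where `dC/dk_out = −1`,

  the equilibrium between hubness and modularity. Genes with `k_out > κ`
  are **global regulators**; removing them and re-attaching structural
  genes yields **modules**, the **basal machinery** (strictly globally
  regulated genes) and **intermodular genes** (regulated by ≥ 2 modules),
  a partition of every gene into four systems-level classes.
* **Module annotation** — hypergeometric GO biological-process enrichment
  with Benjamini–Hochberg FDR control (q ≤ 0.05) and guilt-by-association
  reporting for hypothetical genes in enriched modules.
* **Synthetic benchmarks** — seeded generators of planted networks,
  identity dictionaries and GO annotations with exact ground truth, so the
  whole pipeline is testable offline.

Models serialize to a documented JSON dialect (`read_regnet_json()` /
`write_regnet_json()`), and `inst/cli/regnet` exposes the pipeline as
shell subcommands (`convert`, `resolve`, `merge`, `properties`,
`decompose`, `annotate`, `fixtures`, `run`).

## Worked example

```r
library(regnda)

# a planted benchmark: 5 modules x 20 genes, 3 hubs, 10 basal, 6 intermodular
p <- generate_planted_network(planted_network_spec(seed = 1))
p$network
#> <regnet> planted benchmark
#>   119 nodes (119 genes, 0 complexes), 260 interactions
#>   genome: 119 genes (coverage 100.0%)
#>   evidence: 220 strong / 40 weak / 0 unknown

compute_kappa(p$network)
#> <kappa_result> kappa = 4.307 from C(k_out) = 26.09 * k_out^(-1.52) (3 points)

d <- nda_decompose(p$network)
d
#> <nda_decomposition> 3 global regulators, 100 modular genes in 5 modules,
#>   10 basal machinery, 6 intermodular (kappa = 4.31)

go <- generate_go_annotations(p$partition, seed = 1)
head(annotate_modules(p$partition, go$annotations)[
  , c("module", "term", "k", "n", "K", "N", "q_value")], 3)
#>   module       term  k  n  K   N      q_value
#> 1    1.1 GO:9000001 18 20 20 100 3.369513e-15
#> 2    1.2 GO:9000002 18 20 19 100 3.450163e-16
#> 3    1.3 GO:9000003 18 20 20 100 3.369513e-15
```

Reading the numbers: the fitted clustering curve is anchored at the three
hub out-degrees (40, 51, 62), giving κ ≈ 4.3 — above every module TF
(out-degree ≤ 3) and below every hub — so exactly the three planted hubs
are classified as global regulators. The decomposition recovers the five
planted modules (ids `1.1` … `1.5`, all in one connected island) and the
basal/intermodular gene sets exactly. Each module is enriched for its
planted GO term: e.g. 18 of module `1.1`'s 20 genes carry `GO:9000001`,
which annotates only 20 of the 100 genes in the background, q ≈ 3e-15.

Real curated data enters through `read_edge_tsv()` (with an
`evidence_scheme()` mapping free-text evidence codes to strong/weak),
`read_identity_tsv()`, `read_complex_tsv()` and `read_go_tsv()`, or as a
ready model via `read_regnet_json()`; `run_pipeline()` wires all stages
and writes every artifact plus a summary JSON.

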