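---
title: "Dissecting bacterial regulatory networks: meta-curation and the natural decomposition approach"
author: "regnda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting bacterial regulatory networks}
  %\VignetteEncoding{UTF-8}
---

## The problem

Curated knowledge about bacterial transcriptional regulation accumulates as
regulons: one transcription factor (TF), its target genes, the sign of each
interaction and the experimental evidence behind it. Databases and
high-throughput studies publish these regulons as edge lists under
inconsistent gene naming, with partial overlap and very different coverage
of the genome. Two questions follow. First, how do we reconcile several
such datasets into one non-redundant network model without duplicating
genes or interactions? Second, once a model exists, how is the network
organised above the regulon level — which regulators are global, which
genes form functional modules, and which genes integrate the responses of
several modules?

`regnda` implements a complete pipeline for both: identity resolution and
meta-curation of edge lists into a single directed graph model, and the
natural decomposition approach (NDA) that classifies every gene into one
of four systems-level classes and extracts the module structure.

## The network model

A model is a directed graph. Nodes are genes, or heteromeric regulatory
complexes collapsed from their subunit genes; edges are regulatory
interactions typed by effect (`activation`, `repression`, `dual`,
`unknown`) and evidence class (`strong`, `weak`, `unknown`). Three
construction rules shape the graph:

* **Sigma factors** redirect RNA polymerase to specific promoter sets, so
  a sigma-factor node's outgoing interactions are modelled as activations.
* **Complexes.** When the genes encoding the subunits of a regulatory
  complex are regulated by the same regulators and have no independent
  regulatory activity, they are replaced by a single complex node that
  inherits the shared in-edges and carries the complex's out-edges.
  Otherwise the complex is added as a separate node activated by its
  subunit genes, and only the complex-mediated out-edges move to it.
* **Evidence.** An interaction supported by at least one strong evidence
  code (direct physical or solid genetic support) is strong; otherwise it
  is weak. Interactions with no recorded evidence default to weak, which
  is the conservative reading: nothing about them licenses the strong
  class, and the strong projection (`project_subnetwork(evidence =
  "strong")`) should only ever shrink when evidence is missing.

When datasets disagree on an edge, the merge reconciles fields through two
small lattices: evidence takes the maximum of `unknown < weak < strong`
(a report can only ever add support), and effect joins through
`unknown < {activation, repression} < dual`, so a conflict between an
activation report and a repression report is recorded as `dual`. The
source datasets only say effects are inherited; the conflict rule is this
package's choice, and `dual` is the honest summary of contradictory
curation rather than a silent overwrite.

## Identity resolution

Gene symbols are ambiguous: datasets mix canonical names, locus tags,
synonyms and database identifiers, and the same name can denote different
genes. The resolver models the identity dictionary as a bipartite graph
between locus tags and names (one canonical link per entry, one synonym
link per synonym) and maps symbols in constrained passes:

1. a symbol equal to a locus tag maps to itself — locus tags are the
   unambiguous key set, so they win over a same-spelled name;
2. a symbol equal to a unique canonical name maps through that link;
3. any other symbol maps through the bipartite graph only if its name
   node has degree exactly one; degree greater than one is degeneracy and
   the name becomes *taboo* — kept verbatim in the model for historical
   consistency, never silently guessed;
4. symbols absent from the dictionary are likewise reported as
   unresolved rather than dropped.

Matching is case-sensitive because bacterial gene symbols are
case-meaningful (`sigA` vs `SigA` conventions differ across sources); a
case-insensitive retry runs only for symbols the exact passes could not
find at all. After resolution, nodes denoting the same locus tag are
merged, their synonym sets unioned and duplicate edges reconciled through
the lattices above.

## Global properties and the kappa threshold

The NDA rests on an empirical regularity of hierarchical-modular
networks: modularity and hubness are antagonistic. A regulator deeply
embedded in one module has neighbours that also interact with each other
(high local clustering), while a global hub touches many otherwise
unrelated genes (clustering near zero). The package quantifies this with
the mean local clustering coefficient per distinct out-degree value,
`C(k_out)`, computed on the undirected simple projection of the graph
with self-loops removed — the conventional definition; plotting it
against out-degree follows the NDA's source formulation. Using one point
per degree value rather than one per node keeps a handful of hubs from
being swamped by hundreds of low-degree genes.

The curve is fitted as a power law `C(k_out) = a * k_out^(-b)` by linear
regression of the log-log transformed points. Degree-distribution tails
produce gross outliers, so the default estimator is robust: Huber's T
M-estimation (tuning constant 1.345, the standard 95%-efficiency choice)
by iterated reweighted least squares, tolerance 1e-8, at most 100
iterations, MAD residual scale. Points with a zero value are excluded
before the log transform (their logarithm is undefined); on noiseless
log-linear data the robust fit equals ordinary least squares, and the
package falls back to the OLS solution outright when the OLS residuals
are numerically zero, where the reweighting iteration has nothing to do.
At least three positive points are required for any fit.

The **kappa value** is the out-degree at which the fitted curve loses
modularity exactly as fast as it gains hubness, `dC/dk_out = -1`:

    kappa = (a * b)^(1 / (b + 1))

(`compute_kappa` verifies nothing about the sign convention silently: a
non-decaying fit is an error, not a threshold). Genes with out-degree
above kappa — self-loops excluded, since self-regulation is not outreach —
are the network's **global regulators**.

## The decomposition

With the global regulators (GRs) identified, the controlled decomposition
proceeds:

1. remove the GRs and their edges;
2. *structural genes* — genes with zero regulatory out-degree — that are
   left with no regulator at all form the **basal machinery**: strictly
   globally regulated genes;
3. the weakly connected components of the remaining regulators are the
   pre-modules;
4. every other structural gene attaches to the pre-modules of its non-GR
   regulators: exactly one pre-module makes it a **modular** gene there;
   two or more make it **intermodular**, a gene whose promoter integrates
   physiologically disparate module responses;
5. GRs themselves are the fourth class, coordinating the whole.

The four classes are mutually exclusive and exhaustive, and removing GRs
plus intermodular genes provably disconnects distinct modules — both are
asserted in the test suite on every generated network.

Two boundary rules deserve a note, because the decomposition's sources
leave them open. *Structural* is defined on the original network: a TF
whose only targets are global regulators still has regulatory output, so
it becomes a one-TF module rather than basal machinery (basal genes never
have out-degree > 0). And module membership is conferred only by non-GR
regulators: a gene regulated by one module plus any number of GRs belongs
to that module — GRs coordinate everything and therefore distinguish
nothing.

Module identifiers mirror the island structure of the GR-free graph:
pre-modules lying in its largest connected island are numbered `1.1`,
`1.2`, ... by decreasing final size (ties broken by smallest member id),
remaining islands get `2`, `3`, ... Exactly one level of module structure
is produced; no further subdivision of large modules is attempted.

## Module annotation

Each module is annotated by functional enrichment of Gene Ontology terms
in the `biological_process` namespace (the namespace that reflects
physiology; terms are treated as flat labels, with no propagation through
the ontology graph). For a module of `n` genes in a background universe
of `N`, a term annotating `K` background genes and `k` module genes gets
the hypergeometric upper-tail p-value `P(X >= k)`. P-values are corrected
to q-values by Benjamini–Hochberg step-up FDR control and reported at
`q <= 0.05`. The multiple-testing family is the set of terms tested
within one module — the smallest defensible family; an atlas-wide family
would couple unrelated modules' reports to each other. The raw table is
available via `all_results = TRUE`.

Enriched modules drive guilt-by-association: a gene with a hypothetical,
uncharacterized or missing product description that sits in a module
enriched for a function is reported as a candidate for that function.

## The synthetic benchmark

`generate_planted_network()` builds networks with known ground truth that
emulate the architecture the NDA targets: a hub tier coordinating several
locally autonomous modules, a basal machinery, and intermodular genes
bridging module pairs. The default study conditions are 5 modules of 20
genes, 3 global regulators, 10 basal and 6 intermodular genes; each hub
regulates at least 6 structural genes per module (staggered so hub
out-degrees are distinct and at least 40) plus every basal gene, and each
intermodular gene reads one TF from each of two modules.

The generator's key design constraint is kappa separation. Because the
clustering curve is fitted to per-degree means bounded by 1, the closed
form `(a*b)^(1/(b+1))` can only exceed the out-degree of a node while
that node's degree lies *below* the fitted curve's support — at the point
where the fitted slope is -1 the curve's value is `kappa/b`, which for
in-range data caps kappa near the smallest fitted degree. The planted
networks therefore keep module TF neighbourhoods triangle-free (binary
regulatory trees; their clustering is exactly zero, so those degrees drop
out of the log-log fit) and give the hub tier nested target sets plus
hub–hub edges, producing three distinct high out-degrees with positive,
decaying clustering. The fit is anchored entirely at the hub tier and
kappa lands strictly between the module-TF out-degrees (at most 3) and
the smallest hub out-degree (40) — around 4.3 under the default
conditions. The generator recomputes kappa on every network it emits and
fails loudly if the requested counts break the separation.

Optional edge noise adds random within-module edges, rejection-sampled so
that no new triangle is closed and no noise source already sits in one,
and capped at out-degree 2 per source; this keeps the planted clustering
signature (and hence the kappa anchor) intact while still perturbing the
wiring the decomposition sees. Under these conditions class recovery is
complete at 5% noise in the test suite.

What the benchmark does *not* emulate: real degree distributions (the
planted out-degrees are three spikes, not a heavy tail), autoregulation,
overlapping modules, TFs shared between modules, or the partial and
biased coverage of real curation. Passing the recovery tests shows the
decomposition machinery is correct under its own assumptions, not that
any particular organism's network satisfies them.

## Numerical and interface choices

* **JSON dialect.** Models serialize to a fixed-key-order JSON document
  (`metadata` / `nodes` / `edges`; node keys `id`, `canonical`,
  `locus_tag`, `synonyms`, `kind`, `sigma`, `rna`, `product`, `subunits`,
  `class`, `module`; edge keys `source`, `target`, `effect`, `evidence`,
  `sources`). `class` and `module` are `null` until a decomposition is
  applied; `rna`, `subunits` and `sources` are this package's additions,
  required for the round-trip identity `read_regnet_json(
  write_regnet_json(x)) == x` that the test suite enforces. Validation
  errors name the JSON path of the offending value.
* **Genomic coverage** is `100 * gene nodes / genome size`; complex nodes
  are composites of genes that are already counted, so they are excluded
  from the numerator.
* **Atlas inclusion threshold**: models under 110 genes are flagged and
  can be filtered (`filter_small_networks`), the size below which curated
  corpora degenerate into disconnected single regulons.
* **Determinism.** Every generator takes an integer seed and restores the
  caller's RNG state; identical seeds give byte-identical JSON.
* **Problem sizes.** The test suite and the acceptance script run the
  default benchmark (119 nodes, ~260 edges) across 20 seeds, 1000 random
  (a, b) draws for the kappa closed form, 500 contamination trials for
  the robust fit, and exhaustive hypergeometric enumeration up to N = 12
  — sizes at which every oracle is exact and the whole suite stays fast.

## Limitations

The decomposition inherits the quality of its input curation: spurious
weak interactions inflate hub degrees and can shift kappa, which is why
the strong-evidence projection exists. Kappa itself is a property of the
*fitted* clustering curve; networks whose clustering does not decay with
out-degree (fewer than three positive per-degree points, or a rising
curve) have no kappa and the functions say so rather than guessing.
Orthology transfer between strains is out of scope by design — regulatory
sequences are plastic and regulon content does not transfer even between
strains of one species.
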