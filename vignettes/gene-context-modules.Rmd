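---
title: "Gene-context modules: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-context modules: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcmkit)
```

## The model

`gcmkit` rests on one biological premise: bacterial sub-pathways are usually
encoded by conserved gene clusters or operons, so the genes of a functional
unit sit close together on the chromosome. Homology-based annotation ignores
this and therefore over-calls pathways whose enzymes carry promiscuous
domains — every domain of the pathway may be present on a genome while the
pathway is not. The package turns the premise into three successively more
constrained module notions and one detection statistic.

**Pathway graphs.** A KGML file is parsed into a graph whose nodes are
compounds and whose edges are reactions; catalyst genes attach to edges.
Entries linking out to other pathway maps are kept but flagged `external`
and excluded from community detection, because constitutive sub-pathways
referenced from inside a map (glycolysis inside almost everything) would
otherwise blur module boundaries. A reversible reaction is one edge, not a
mirrored pair — all downstream graph analysis is undirected.

**IRMs.** Communities of compounds under Newman–Girvan modularity over the
collapsed, undirected reaction graph (parallel reactions become edge
weights, self-loops are ignored). Genes catalyzing a reaction whose
substrate and product land in different communities belong to neither
cleanly; these *linker genes* are duplicated into both modules and flagged,
to be settled by genomic context later.

**IMs.** On a given genome, all module genes are pooled and re-clustered by
genomic proximity: single-linkage connected components under the gene-rank
distance, with chaining threshold `distance_threshold`. Each component is
one intermediate module, inheriting the union of compounds and Pfams of
every reference module that contributed a gene. The same reference module
contributing to two components duplicates its compound list into both —
that is the "split" case; several modules feeding one component is the
"merge" case. Clustering is iterated to a fixed point (single-linkage is
already idempotent, so the loop exists as a safety net for linker
resolution, bounded by `max_iterations`).

**GCMs.** An IM becomes a gene-context module only with literature evidence
attached and a source/target compound pair declared; the compound list is
ordered along the reaction path from source to target. An empty evidence
list is refused by construction — an unvalidated module stays an IM.

**Detection.** For a module with Pfam set $P$ and a genome catalog, every
window of $2w+1$ consecutive genes containing at least one gene with a
domain in $P$ is scored with
$\mathrm{coverage} = 100\,|P \cap \text{window}|\,/\,|P|$, counting distinct
families once regardless of copy number, and counting every family of a
multi-domain gene. The module is present where coverage $\ge$ cutoff
(boundary inclusive). Strand is recorded but not constrained: operons are
usually strand-coherent, but imposing strandedness would silently drop
divergently transcribed clusters, so a strict mode is left to configuration.

## Parameters that matter

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `window_size` | flanking genes per side | 5 | an 11-gene window comfortably holds typical operons while keeping chance co-occurrence rare |
| `cutoff_percent` | % of distinct module Pfams | 100 | full-complement stringency; lower it deliberately when partial modules are biologically meaningful |
| `distance_threshold` | intervening genes | 10 | the minimum-distance merge score for proximity clustering |
| `e_threshold` (`read_domtbl`) | independent-domain E-value | 1e-5 | a conventional inclusion cutoff; set `Inf` for input pre-filtered by Pfam gathering thresholds |
| `consensus_k` | hit lists (of 6) | 4 | the at-least-4-of-6 consensus rule |
| `min_support` (`consolidate_ims`) | genomes | 1 | how many genomes must exhibit an IM pattern before it is kept |

All distances and windows are measured in gene-rank units (intervening
genes), not base pairs: window size is defined as a number of flanking
genes, and rank units make the statistic independent of gene length and
intergenic spacing. A base-pair mode was considered and rejected as a
default for exactly that dependence.

## Numerical and algorithmic choices

**Community detection.** The default method maximizes modularity exactly
for graphs up to `exact_max_nodes = 9` non-external compounds, by
enumerating all set partitions as restricted-growth strings over
lexicographically sorted node ids and keeping the first partition attaining
the maximum (Bell(9) = 21,147 partitions — cheap, and metabolic maps pruned
of external links are often this small). Larger graphs use greedy
Clauset–Newman–Moore agglomeration with lexicographic tie-breaking.
We measured plain greedy agglomeration against exhaustive enumeration on
random graphs of ≤ 8 nodes: it misses the optimum on roughly one graph in
ten, and a deterministic local-move refinement does not close the gap. Since
reproducible module boundaries on small pathway graphs are a contract of
this package, exactness below the threshold is the default rather than a
heuristic everywhere; Girvan–Newman edge-betweenness (via igraph) remains
selectable. After any method, communities are split into their connected
components — this never lowers modularity and keeps isolated compounds out
of foreign modules. All searches are deterministic: ties are broken on node
identity, never on hash or insertion order, and the `seed` argument exists
only for interface uniformity.

**Window evaluation.** Every window position containing an anchor
(module-domain-bearing) gene is evaluated — not only windows centered on
anchors. Centered-only evaluation is *not* equivalent: two domains $2w$
ranks apart share a $(2w+1)$-window but no anchor-centered window, and
would be missed. Evaluating all anchor-containing positions is provably
identical to exhaustive scanning of every contiguous interval of length
$\le 2w+1$ (any interval's leftmost anchor starts a full-length window
covering all its domain-bearing genes), which the test suite asserts
against an independent brute-force oracle. Call spans are trimmed to the
domain-bearing genes, and overlapping qualifying spans merge into maximal
calls reporting their best window's coverage. On circular replicons windows
wrap, a replicon shorter than the window is taken whole, and a call
spanning the origin is encoded as `end_rank < start_rank`.

**Distances on circles.** Rank distance uses the shorter arc,
`min(d, n − d)`; single-linkage clustering closes the circle when the
wrap-around gap is within the threshold. Intra-module spread is summarized
as the largest single-linkage gap, dropping the largest arc gap on circular
replicons. Average inter-module distances are computed and reported as
diagnostics, but merging decisions use the minimum — the merge rule is
stated on a minimum distance score, and averages would make merging depend
on module size.

**Linker resolution.** Positional clustering places each linker gene in
exactly one component, so the default `nearest` rule reduces to keeping
that placement (a genuine tie would have merged the competing clusters);
`duplicate` copies the linker into every cluster containing genes of any
module it bridges, for users who prefer recall over parsimony.

**Ties and degenerate inputs.** Compound order inside an IRM is topological
along intra-community directed edges when acyclic, else lexicographic with
a `cyclic` flag. Empty gene pools refine to an empty catalog; a genome
carrying none of a module's domains yields one explicit zero-coverage row
rather than silence. Genes with no domain hits are retained in catalogs so
rank distances reflect true gene spacing.

## What the synthetic generator emulates — and what it does not

`make_genome()` plants domain clusters at chosen ranks and spacings in a
background of random annotations drawn from a pool that never collides with
planted families. The two bundled suites encode the canonical scenarios:
four genomes that all contain a six-family domain complement but only one
in context (two dispersal patterns, one multi-homolog pattern, one
contiguous cluster), and the mannose-to-GDP-fucose contrast between a
clustered and a dispersed-homolog genome, with real domain families
(PF02878, PF00483, PF16363, PF01370) and recognizable locus tags. Synthetic
families use a reserved PF9xxxx namespace; evidence PMIDs in fixtures are
synthetic (9xxxxxx).

The generator does *not* emulate: realistic sequence content or gene-length
variation (all genes are 900 bp on a uniform grid), overlapping genes,
pseudogenes, domain-architecture noise (false HMMER hits, fragmented
domains), or horizontally acquired partial clusters. Passing tests
therefore demonstrate the correctness of the algorithms on their own terms
— they do not demonstrate that window 5 / cutoff 100 are optimal operating
points for real genomes, where annotation noise argues for the lower
cutoffs the interface exposes.

Problem sizes used by the test suite and the acceptance script — genomes of
100–500 genes, 50 random detector trials, 100 clustering and consensus
trials, 21 community graphs of ≤ 8 nodes — were chosen so each oracle
comparison is exhaustive at small n while the whole suite stays fast.

## Design decisions taken where the design was open

* **Relation elements.** Compound–compound `relation` entries in KGML
  without a backing reaction do not contribute edges by default
  (`use_relations = FALSE`): they encode layout adjacency more often than
  chemistry, and silently adding edges would change community structure.
* **Reference vs organism KGML.** Community detection is run once on the
  (reference or organism) map supplied; per-genome gene mapping happens
  afterward, via locus tags for organism files and via Pfam sets otherwise
  (`assign_module_genes(by = "locus" | "pfam")`).
* **Cross-genome consensus.** Per-genome IM sets are consolidated by
  pattern (contributing modules + Pfam set) with a `min_support` genome
  count, defaulting to 1 so single-genome analyses pass through unchanged.
* **Manual curation as data.** Curation outcomes (dropping
  promiscuous-domain false positives, renaming, compound edits) are an
  explicit overlay table applied by `apply_curation()`, never heuristics in
  code — curation should be reviewable and revertible.
* **Literature mining offline.** Query construction is deterministic and
  synonym-order-independent; hit lists are ingested from files (one PMID
  per line, six per module) rather than fetched live, because live search
  results drift and would make evidence irreproducible. Which PubMed fields
  to search is left to a `field_tag` the caller controls.
* **All qualifying windows are reported** (merged into maximal calls), not
  just the best one: partial, repeated occurrences of a module are
  themselves informative.

## Known limitations

* Gene clusters with identical domain composition but different substrate
  specificity (branched-chain keto-acid vs pyruvate dehydrogenase
  complexes) cannot be told apart by context alone; active-site analysis is
  out of scope.
* Pathways whose genes genuinely do not cluster (glycolysis and other
  constitutive pathways) are outside the method's reach by design.
* The exact community search is exponential and hard-capped; beyond
  `exact_max_nodes` the greedy fallback inherits the usual local-optimum
  caveats of agglomerative modularity maximization.
* Eukaryotic genomes, where pathway genes rarely cluster, are not a target.
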