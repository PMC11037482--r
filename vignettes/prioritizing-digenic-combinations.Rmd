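---
title: "Prioritizing digenic variant combinations with network propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing digenic variant combinations with network propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digenicRank)
```

## The problem

Digenic (more generally oligogenic) diseases are caused by the joint effect
of variants in two or more genes. A filtered exome still contains on the
order of a hundred candidate variants; the set of *digenic variant
combinations* — every unordered gene pair, with up to two variants per gene —
grows roughly quadratically and routinely reaches tens of thousands of
candidates even for small exomes, and millions for full ones. A
pathogenicity classifier for variant combinations alone cannot isolate the
causal combination in that haystack: many combinations look biochemically
plausible. `digenicRank` fuses two complementary signals:

* **PS**, a per-combination pathogenicity score in $[0, 1]$ produced by any
  scorer honouring the package's scorer contract (e.g. externally computed
  VarCoPP-style predictions consumed through `table_scorer()`), and
* **DS**, a per-gene-pair disease-relevance score derived from the patient's
  phenotype: HPO terms and/or a clinical gene-panel are used as seeds for a
  random walk with restart (RWR) over a heterogeneous knowledge graph, and
  the pair score is the mean of the two genes' walk scores.

## The propagation model

The knowledge graph is a typed, layered, unweighted network with gene, HPO
and disease nodes (and possibly others). Before propagation the graph is
*prepared*: node types that would leak curated oligogenic associations into
the evaluation are removed (`remove_node_type()`), all layers are flattened
into one simple undirected graph (an edge exists iff at least one layer
connects the pair), and the adjacency matrix is column-normalized into a
transition matrix $W$. The walk iterates

$$ p^{t+1} = (1 - r)\,W p^t + r\,p^0 $$

where $p^0$ places equal mass on every resolved seed node (summing to 1,
i.e. the walker starts uniformly at random from a seed) and $r$ is the
restart probability. The fixed point scores every node's proximity to the
seed set, mixing local and global topology via the guilt-by-association
principle: genes involved in the same disease tend to be close in
biological networks.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `r` (restart) | 0.3 | probability per step of teleporting back to the seeds; smaller values spread the walk further from the seeds |
| `tol` | 1e-9 | L1 stopping tolerance between iterates |
| `max_iter` | 1000 | iteration cap; convergence is geometric with ratio $\le 1-r$, so the cap is never near-binding at the default `r` |
| `maf_max` | 0.035 | retain variants with minor allele frequency at or below 3.5% |
| `synonymous_max_exon_distance` | 195 nt | synonymous variants farther than this from an exon edge are removed |
| `drop_intronic` | TRUE | intronic variants are removed |
| fusion `operator` | `mean` | how the scaled PS and DS are combined (`product`, `min`, `max` available) |

No stopping rule is implied by the model itself; `tol = 1e-9` with L1
distance was chosen because geometric contraction at $r = 0.3$ makes
convergence cheap (a few dozen iterations) and exactly reproducible. The
iterative solution is verified in the test suite against an independent
dense linear solve $p = r\,(I - (1-r)W)^{-1} p^0$ to within $10^{-6}$ in
the supremum norm.

### Design choices in graph handling

Several aspects of multiplex-heterogeneous propagation are genuinely open;
the package resolves them as follows.

* **Layer flattening.** The update above is written for a single $W$, so
  layers are flattened into the union of their edges rather than walked as
  a supra-adjacency matrix with inter-layer jump probabilities. The layer
  field is kept on every edge as provenance. A per-layer-normalized walk
  could be added behind configuration, but the defaults do not depend on it.
* **Undirected, unweighted edges.** Edge weights and directions in source
  data are discarded: the walk measures proximity, not directed flow.
* **Isolated nodes** are dropped from the walk index (keeping $W$ strictly
  column-stochastic without teleportation corrections) and score 0
  downstream; genes absent from the graph likewise contribute 0 to DS
  rather than raising an error, so whole-exome runs never abort on
  unannotated genes.
* **Namespaced node ids** (`GENE:BRCA1`, `HPO:HP:0000118`) prevent
  collisions between gene symbols and ontology identifiers.
* **Literal seed terms only.** HPO seeds are used exactly as given; no
  expansion to ontology ancestors or descendants is performed, and no
  semantic-similarity weighting. Seeds of both kinds (HPO and panel genes)
  share one uniform distribution over the resolved union.

## Scoring and ranking

PS and DS are min-max scaled *within each exome* so both signals have equal
weight regardless of their raw scales, and fused (by default) as
$FS = (PS_{scaled} + DS_{scaled})/2$. Combinations are ranked by descending
FS. Numerical conventions:

* a degenerate min-max (all values equal, or a single combination) maps to
  0.5, so a constant signal neither dominates nor vanishes in the mean;
* ties in FS are broken by higher $PS_{scaled}$, then bytewise by
  combination id, making rankings exactly reproducible;
* evaluation uses the *worst-case* rank for the truth combination among
  FS ties — the conservative reading for a user scanning the list.

Combination identifiers are canonical (genes in bytewise order, variant ids
sorted within each gene's subset), so identical combinations always receive
identical ids and, through the scorer contract's determinism requirement,
identical scores.

Variant handling follows VCF conventions: coordinates are 1-based, each ALT
allele of a multi-allelic record becomes its own variant, and a variant
annotated to several genes yields one record per gene. A homozygous
genotype is a single variant with `zygosity = "hom"` — the "at most two
variants per gene" rule counts distinct variants, not alleles. Variants
with missing MAF are kept: absence of frequency evidence should not discard
a candidate. Hemizygous (single-allele) genotypes are treated as
homozygous.

## The synthetic benchmark

Real benchmarks for this task need curated oligogenic combinations, cohort
exomes, a full knowledge graph and a trained combination classifier — none
of which fit in a self-contained package. The package therefore ships a
first-class synthetic benchmark (`simulate_spikein_benchmark()`) that
emulates the spike-in protocol end to end:

1. **Synthetic graph** (`generate_synthetic_graph()`): gene, HPO and
   disease nodes; Erdős–Rényi background edges within each admissible layer
   (protein-protein, pathway, HPO-gene, disease-gene, HPO-disease) at
   probability 0.05; a deterministic HPO "ontology" chain linking
   consecutive HPO terms (so phenotype seeds are never isolated, as in the
   real ontology's is-a backbone); two planted disease genes each connected
   to all three patient HPO seeds; and a couple of oligogenic-interaction
   nodes whose removal exercises graph preparation. Defaults: 30 background
   genes, 15 HPO terms, 10 diseases.
2. **Template exome** (`generate_template_exome()`): 120 variants over the
   background genes on two artificial contigs, with randomized MAF
   (about 20% common), consequence class (45% missense, 20% synonymous,
   15% intronic, 20% other), exon-edge distance and zygosity — so the
   variant filters have realistic work. Coordinates are arbitrary; no
   reference assembly is implied and none is needed.
3. **Spike-in** (`insert_combination()`): one rare heterozygous missense
   variant in each planted gene, inserted position-sorted with a truth
   manifest. The spec constructor refuses combinations the default filters
   would remove, since such a truth could never be ranked. The planted
   genes carry no background variants, so the truth pair contributes
   exactly one combination and recovery is unambiguous even under the
   worst-case tie rule (with two variants in one truth gene, the sub-subset
   combinations of the same pair would tie with the truth by construction).
4. **Scoring**: the deterministic surrogate scorer hashes each combination
   id to $[0,1)$ and pins the truth pair to PS = 0.99 via an override,
   emulating a classifier that correctly flags the pathogenic combination
   without being uniformly confident elsewhere.

Every random choice flows through explicit integer seeds (per-exome seeds
are derived arithmetically from the master seed); there is no global RNG
state, and identical configurations produce byte-identical ranking files.

The test suite asserts, at these defaults, that the truth combination ranks
first in at least 95 of 100 benchmark exomes and within the top 10 in all
of them, and that deleting the planted seed-gene edges (leaving all
background edges untouched) strictly worsens the median truth rank — the
degradation control showing that recovery is driven by the phenotype
signal, not by the scorer override alone.

### What passing these tests does and does not show

The generator emulates the *structure* of the benchmark (filters with work
to do, a disease module near the seeds, a scorer that is right about the
truth), not the statistics of real data: no linkage disequilibrium,
ancestry structure or realistic site-frequency spectrum; a knowledge graph
orders of magnitude smaller and denser near the planted module than a real
one; and a surrogate scorer whose errors are uniform rather than
structured. Recovery rates on this benchmark therefore validate the
pipeline's mechanics and determinism — they do not predict performance on
patient exomes, which in real deployments is limited by the completeness
and monogenic bias of phenotype-gene annotations.

## Problem sizes and costs

A benchmark exome at the defaults yields roughly 10,000–15,000 combinations
(about 70 kept variants over ~30 genes); a 100-exome cohort runs in a few
minutes on one CPU, dominated by combination enumeration and VCF parsing.
The propagation itself is a sparse matrix-vector iteration and is
negligible at this graph size; on large graphs it scales with the edge
count per iteration. `generate_combinations()` accepts a per-gene-pair
callback for streaming emission with bounded memory, which is the intended
interface at full-exome scale (tens of millions of combinations);
`count_combinations()` gives the exact total in closed form for capacity
planning, as $\sum_{A<B} f(n_A) f(n_B)$ with $f(n) = n + \binom{n}{2}$.

## Cross-validation support

For users retraining a combination classifier, `assign_grouped_folds()`
provides gene-pair-grouped fold assignment: all combinations sharing a gene
pair land in the same fold (shuffle groups, then greedily fill the smallest
fold), preventing information leakage between training and evaluation
folds. Per-fold retraining itself is the caller's responsibility — the
classifier is outside this package's scope by design.

## Known limitations

* Rankings come with no calibrated probabilities or confidence estimates.
* Combinations span exactly two genes; trigenic and higher-order
  combinations are out of scope.
* No inheritance-aware (trio) filtering, structural variants, or internal
  annotation: consequence, MAF and exon-edge distance are consumed from a
  precomputed sidecar table.
* The comparison against external single-variant prioritizers is supported
  only at the metric level (`single_variant_combination_rank()` implements
  the max-of-member-ranks convention); running those tools is out of scope.
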