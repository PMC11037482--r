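# digenicRank

Phenotype-driven prioritization of **digenic variant combinations** in
patient exomes.

## Who this is for

Diagnosing an oligogenic disease means finding *two* genes whose variants
jointly cause the phenotype. After standard exome filtering, the number of
candidate digenic combinations (every unordered gene pair, up to two
variants per gene) reaches tens of thousands even for a small exome — far
beyond what a clinician can review, and beyond what a combination
pathogenicity classifier alone can resolve. `digenicRank` is for
bioinformaticians building or evaluating digenic-prioritization pipelines:
it ranks all combinations of an exome by fusing biochemical and phenotypic
evidence, and ships a fully synthetic spike-in benchmark so the whole
pipeline runs and validates with no external downloads.

## The method

For each combination of genes $A$ and $B$:

* **PS** — a pathogenicity score in $[0,1]$ from a pluggable scorer
  (`table_scorer()` for precomputed VarCoPP-style predictions,
  `surrogate_scorer()` as a deterministic stand-in for benchmarks);
* **DS** — a disease-relevance score: a random walk with restart
  $p^{t+1} = (1-r)\,W p^t + r\,p^0$ (default $r = 0.3$) is run over a
  heterogeneous knowledge graph from the patient's HPO terms and/or
  gene-panel genes (uniform seed mass), where $W$ is the column-normalized
  adjacency of the layer-flattened graph; $DS = (DS_A + DS_B)/2$;
* **FS** — both scores are min-max scaled per exome and averaged:
  $FS = (PS_{scaled} + DS_{scaled})/2$. Combinations are ranked by
  descending FS.

Variant filters (MAF ≤ 3.5%, no intronic variants, synonymous variants
within 195 nt of an exon edge) are applied before enumeration. Evaluation
utilities compute the truth combination's rank (worst case under ties) and
cumulative top-K recovery curves; `assign_grouped_folds()` provides
gene-pair-grouped cross-validation assignment for scorer retraining.

## Worked example

Generate one synthetic benchmark case (graph + template exome + spiked-in
truth combination in genes `DGENE1`/`DGENE2`) and prioritize it:

```r
library(digenicRank)

case <- digenicRank:::build_benchmark_case("example_case", 2026L)
cfg <- run_config(
  vcf = case$vcf, annotation = case$annotation,
  graph_edges = case$graph_edges, graph_nodes = case$graph_nodes,
  hpo_ids = case$patient_hpo,                     # HP:0000001..3
  scorer = surrogate_scorer(seed = 2026L,
    overrides = c("DGENE1|DGENE2" = 0.99)))
res <- run_pipeline(cfg)
head(res$ranking[c("rank", "combination_id", "PS", "DS", "FS")], 3)
#>  rank                                               combination_id        PS
#>     1              DGENE1|DGENE2|chrA:9000001:G:T|chrB:9000002:C:A 0.9900000
#>     2 DGENE1|G003|chrA:9000001:G:T|chrA:243933:C:A,chrB:307487:T:A 0.9987795
#>     3                DGENE1|G016|chrA:9000001:G:T|chrA:2356121:G:A 0.9931433
#>          DS        FS
#>  0.10705932 0.9950136
#>  0.06260911 0.7918076
#>  0.06304339 0.7910175

truth_rank(res$ranking, case$truth_combination_id)
#> [1] 1
```

Of the 122 variants read, 71 survive the filters, yielding 9,762
combinations. The spiked-in truth ranks first: its PS is near-maximal
(0.99 by the scorer override) **and** its gene pair sits next to the
patient's HPO seeds in the graph, so its DS (0.107) dominates every
background pair (≤ 0.063) — rows 2–3 show combinations with *higher* raw
PS that still lose on the fused score. That is the point of the method:
neither score alone separates the truth, the fusion does.

A thin command-line front end wraps the same functions:

```sh
exec/digenic-rank run --vcf patient.vcf --annotation patient.tsv \
  --graph edges.tsv --nodes nodes.tsv --hpo hpo.txt --out out/
exec/digenic-rank simulate --n-exomes 100 --seed 1 --out bench/
exec/digenic-rank evaluate --results bench/results.tsv --kmax 50 --out eval/
```

## Using a real knowledge graph and scorer

The graph loader consumes any node-table/edge-list TSV pair
(`node_id  node_type` / `source_id  target_id  layer`, ids namespaced as
`GENE:...`, `HPO:...`, `DISEASE:...`); see `?bock_converter_notes` for the
mapping from the published BOCK export, including removal of the curated
oligogenic-interaction nodes before propagation. Externally computed
combination pathogenicity scores plug in through
`table_scorer("scores.tsv")`.
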