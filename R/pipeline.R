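#' Read a seed list file
#'
#' Plain text, one HPO term id or gene symbol per line; blank lines and
#' `#` comments ignored.
#'
#' @param path file path.
#' @return Character vector of ids.
#' @export
read_seed_file <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' End-to-end run configuration
#'
#' Bundles every input of a prioritization run. Defaults reproduce the
#' reference settings: restart probability 0.3, mean fusion, MAF cutoff
#' 3.5%, synonymous exon-edge cutoff 195 nt, intronic variants dropped,
#' oligogenic-interaction nodes removed from the graph before propagation.
#'
#' @param vcf,annotation paths to the patient VCF and annotation TSV.
#' @param graph_edges,graph_nodes paths to the knowledge-graph TSV pair.
#' @param hpo_ids,panel_genes character vectors of disease priors (at least
#'   one non-empty); a character scalar naming an existing file is read with
#'   [read_seed_file()].
#' @param scorer a [pathogenicity_scorer()].
#' @param filter_cfg a [filter_config()].
#' @param rwr_cfg an [rwr_config()].
#' @param operator fusion operator, see [fuse_scores()].
#' @param remove_node_types node types removed from the graph before
#'   propagation; default `"oligogenic"`.
#' @param sample VCF sample selector (multi-sample VCFs only).
#' @param out_dir optional output directory for `ranking.tsv` and
#'   `report.json`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(vcf, annotation, graph_edges, graph_nodes,
                       hpo_ids = character(0), panel_genes = character(0),
                       scorer = surrogate_scorer(),
                       filter_cfg = filter_config(),
                       rwr_cfg = rwr_config(),
                       operator = "mean",
                       remove_node_types = "oligogenic",
                       sample = NULL, out_dir = NULL) {
  as_ids <- function(x) {
    if (length(x) == 1 && is.character(x) && file.exists(x))
      read_seed_file(x) else as.character(x)
  }
  hpo_ids <- as_ids(hpo_ids)
  panel_genes <- as_ids(panel_genes)
  if (length(hpo_ids) == 0 && length(panel_genes) == 0)
    stop("at least one seed source (HPO terms or gene panel) is required")
  for (p in c(vcf, annotation, graph_edges, graph_nodes))
    if (!file.exists(p)) stop("input file not found: ", p)
  stopifnot(inherits(scorer, "pathogenicity_scorer"),
            inherits(filter_cfg, "filter_config"),
            inherits(rwr_cfg, "rwr_config"))
  structure(list(vcf = vcf, annotation = annotation,
                 graph_edges = graph_edges, graph_nodes = graph_nodes,
                 hpo_ids = hpo_ids, panel_genes = panel_genes,
                 scorer = scorer, filter_cfg = filter_cfg,
                 rwr_cfg = rwr_cfg, operator = operator,
                 remove_node_types = remove_node_types,
                 sample = sample, out_dir = out_dir),
            class = "run_config")
}

#' Run the full prioritization pipeline on one exome
#'
#' Executes filter, combine, pathogenicity scoring (PS), propagation (DS),
#' fusion and ranking: variants are read and filtered, digenic combinations
#' enumerated (at most two variants per gene), each combination scored by
#' the configured pathogenicity scorer, each gene pair scored by the random
#' walk with restart from the patient's seeds, and the per-exome min-max
#' scaled scores fused into the final score that orders the output.
#'
#' @param config a [run_config()].
#' @return list with `ranking` (data.frame from [rank_exome()]) and
#'   `report` (stage counts, walk convergence metadata, warnings). When
#'   `config$out_dir` is set, `ranking.tsv` and `report.json` are written
#'   there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warnings_seen <- character(0)
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  withCallingHandlers({
    variants <- read_annotated_variants(config$vcf, config$annotation,
                                        sample = config$sample)
    fl <- apply_variant_filters(variants, config$filter_cfg)
    combos <- generate_combinations(fl$kept)
    if (nrow(combos) == 0)
      stop("stage combine: no digenic combinations after filtering")
    graph <- load_graph(config$graph_edges, config$graph_nodes)
    for (tp in config$remove_node_types) graph <- remove_node_type(graph, tp)
    tm <- flatten_and_normalize(graph)
    seeds <- build_seed_vector(tm, config$hpo_ids, config$panel_genes)
    walk <- random_walk_restart(tm, seeds, config$rwr_cfg)
    records <- combos
    records$PS <- score_combinations(config$scorer, combos)
    records$DS <- pair_disease_score(walk, combos$gene_a, combos$gene_b)
    ranking <- rank_exome(records, operator = config$operator)
    report <- list(
      n_variants_read = nrow(variants),
      n_variants_kept = nrow(fl$kept),
      filter_report = fl$report,
      n_genes_with_variants = length(unique(fl$kept$gene)),
      n_combinations = nrow(combos),
      n_combinations_closed_form = count_combinations(fl$kept),
      graph_nodes_in_walk = length(tm$node_index),
      graph_isolated_dropped = length(tm$dropped),
      seeds_resolved = seeds$resolved_ids,
      seeds_unresolved = seeds$unresolved_ids,
      rwr_iterations = walk$iterations_used,
      rwr_converged = walk$converged,
      scorer = config$scorer$name,
      operator = config$operator,
      restart_probability = config$rwr_cfg$r,
      warnings = warnings_seen
    )
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_ranking(ranking, file.path(config$out_dir, "ranking.tsv"))
      report_out <- report
      report_out$filter_report <- NULL
      jsonlite::write_json(c(report_out,
                             list(filter_report = fl$report)),
                           file.path(config$out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(ranking = ranking, report = report)
  }, warning = note)
}

#' Simulate a spike-in benchmark cohort
#'
#' Generates `n_exomes` independent benchmark cases and prioritizes each
#' with the full pipeline. Every case consists of (i) a synthetic knowledge
#' graph in which the two planted disease genes are adjacent to all three
#' patient HPO seeds, (ii) a synthetic template exome over background genes,
#' (iii) a spiked-in truth combination of one rare heterozygous missense
#' variant in each planted gene, and (iv) a surrogate pathogenicity scorer
#' whose override pins the truth gene pair to `truth_ps`. The planted genes
#' carry no background variants, so the truth pair contributes exactly one
#' combination and its recovery is unambiguous under the worst-case tie
#' rule.
#'
#' @param n_exomes number of benchmark exomes.
#' @param seed master seed; per-exome seeds are derived deterministically.
#' @param remove_planted_edges degradation control: delete the planted
#'   seed-gene edges from each graph (background edges unchanged) before
#'   propagation.
#' @param truth_ps surrogate override score of the truth pair; default 0.99.
#' @param n_template_variants template exome size; default 120.
#' @param n_background_genes size of the background gene pool; default 30.
#' @param rwr_cfg an [rwr_config()].
#' @param operator fusion operator.
#' @return data.frame with one row per exome: `exome_id`,
#'   `truth_combination_id`, `truth_rank`, `total_combinations`.
#' @export
simulate_spikein_benchmark <- function(n_exomes = 100L, seed = 1L,
                                       remove_planted_edges = FALSE,
                                       truth_ps = 0.99,
                                       n_template_variants = 120L,
                                       n_background_genes = 30L,
                                       rwr_cfg = rwr_config(),
                                       operator = "mean") {
  results <- vector("list", n_exomes)
  base_dir <- file.path(tempdir(), paste0("spikein_", seed, "_",
                                          as.integer(remove_planted_edges)))
  dir.create(base_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n_exomes)) {
    exome_seed <- as.integer((as.numeric(seed) * 7919 +
                                as.numeric(i) * 104729) %% 2147483629)
    dir_i <- file.path(base_dir, sprintf("exome%04d", i))
    dir.create(dir_i, showWarnings = FALSE)
    case <- build_benchmark_case(dir_i, exome_seed,
                                 n_template_variants = n_template_variants,
                                 n_background_genes = n_background_genes,
                                 remove_planted_edges = remove_planted_edges)
    cfg <- run_config(
      vcf = case$vcf, annotation = case$annotation,
      graph_edges = case$graph_edges, graph_nodes = case$graph_nodes,
      hpo_ids = case$patient_hpo,
      scorer = surrogate_scorer(
        seed = exome_seed,
        overrides = stats::setNames(truth_ps,
                                    paste(case$truth_genes, collapse = "|"))),
      rwr_cfg = rwr_cfg, operator = operator)
    res <- suppressMessages(run_pipeline(cfg))
    results[[i]] <- data.frame(
      exome_id = sprintf("exome%04d", i),
      truth_combination_id = case$truth_combination_id,
      truth_rank = truth_rank(res$ranking, case$truth_combination_id),
      total_combinations = nrow(res$ranking),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  out
}

# One benchmark case: graph + template exome + spiked truth, all on disk.
build_benchmark_case <- function(dir, exome_seed, n_template_variants = 120L,
                                 n_background_genes = 30L,
                                 remove_planted_edges = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth_genes <- c("DGENE1", "DGENE2")
  patient_hpo <- c("HP:0000001", "HP:0000002", "HP:0000003")
  gspec <- synthetic_graph_spec(
    n_genes = n_background_genes, planted_genes = truth_genes,
    planted_seed_ids = patient_hpo, rng_seed = exome_seed)
  edge_path <- file.path(dir, "edges.tsv")
  node_path <- file.path(dir, "nodes.tsv")
  generate_synthetic_graph(gspec, edge_path, node_path,
                           include_planted_edges = !remove_planted_edges)
  background_genes <- sprintf("G%03d", seq_len(n_background_genes))
  tmpl_vcf <- file.path(dir, "template.vcf")
  tmpl_ann <- file.path(dir, "template_annotation.tsv")
  generate_template_exome(n_template_variants, background_genes,
                          rng_seed = exome_seed,
                          vcf_path = tmpl_vcf, annotation_path = tmpl_ann)
  comb <- data.frame(
    chrom = c("chrA", "chrB"), pos = c(9000001L, 9000002L),
    ref = c("G", "C"), alt = c("T", "A"),
    gene = truth_genes, zygosity = "het", consequence = "missense",
    maf = 0.001, exon_edge_distance = 10L, stringsAsFactors = FALSE)
  sspec <- spike_in_spec(tmpl_vcf, tmpl_ann, comb,
                         patient_hpo = patient_hpo)
  out_vcf <- file.path(dir, "patient.vcf")
  out_ann <- file.path(dir, "patient_annotation.tsv")
  ins <- insert_combination(sspec, out_vcf, out_ann,
                            manifest_path = file.path(dir, "truth.json"))
  list(vcf = out_vcf, annotation = out_ann,
       graph_edges = edge_path, graph_nodes = node_path,
       patient_hpo = patient_hpo, truth_genes = truth_genes,
       truth_combination_id = ins$truth_combination_id)
}
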