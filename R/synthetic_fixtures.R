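# Admissible node-type pair per layer of the synthetic graph.
SYNTH_LAYER_TYPES <- list(
  ppi = c("gene", "gene"),
  pathway = c("gene", "gene"),
  hpo_gene = c("hpo", "gene"),
  disease_gene = c("disease", "gene"),
  hpo_disease = c("hpo", "disease"),
  hpo_ontology = c("hpo", "hpo")
)

#' Specification of a synthetic multiplex-heterogeneous graph
#'
#' Describes a small knowledge graph with gene, HPO-term and disease nodes
#' used as a stand-in for a full public knowledge graph in tests and
#' benchmarks. Each layer connects one admissible node-type pair
#' (protein-protein and pathway layers between genes, annotation layers
#' between HPO terms/diseases and genes, and an HPO "ontology" chain linking
#' consecutive HPO terms so phenotype seeds are never isolated). Background
#' edges are Erdős–Rényi within each layer; on top of that, every planted
#' disease gene is connected to every planted seed, emulating a disease
#' module sitting close to the patient's phenotype terms.
#'
#' @param n_genes,n_hpo,n_disease node counts per type.
#' @param background_edge_prob per-layer probability of each admissible
#'   background edge; default 0.05.
#' @param planted_genes gene symbols of the planted disease genes (appended
#'   to the gene set if absent).
#' @param planted_seed_ids raw seed ids, e.g. `HP:0000001` (must reference
#'   generated HPO/disease nodes).
#' @param layers layer names; subset of
#'   `ppi, pathway, hpo_gene, disease_gene, hpo_disease, hpo_ontology`.
#' @param n_oligogenic number of curated oligogenic-interaction nodes (type
#'   `oligogenic`) linked to random genes and diseases; they exercise the
#'   node-type removal step of graph preparation.
#' @param rng_seed integer seed; all randomness flows through it.
#' @return An object of class `synthetic_graph_spec`.
#' @export
synthetic_graph_spec <- function(n_genes = 30L, n_hpo = 15L, n_disease = 10L,
                                 background_edge_prob = 0.05,
                                 planted_genes = c("DGENE1", "DGENE2"),
                                 planted_seed_ids = c("HP:0000001",
                                                      "HP:0000002",
                                                      "HP:0000003"),
                                 layers = names(SYNTH_LAYER_TYPES),
                                 n_oligogenic = 2L,
                                 rng_seed = 1L) {
  stopifnot(n_genes > 0, n_hpo > 0, n_disease > 0,
            background_edge_prob >= 0, background_edge_prob <= 1,
            all(layers %in% names(SYNTH_LAYER_TYPES)))
  structure(list(n_genes = as.integer(n_genes), n_hpo = as.integer(n_hpo),
                 n_disease = as.integer(n_disease),
                 background_edge_prob = background_edge_prob,
                 planted_genes = planted_genes,
                 planted_seed_ids = planted_seed_ids,
                 layers = layers, n_oligogenic = as.integer(n_oligogenic),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_graph_spec")
}

synth_hpo_ids <- function(n) sprintf("HP:%07d", seq_len(n))

#' Generate a synthetic multiplex-heterogeneous graph
#'
#' Realizes a [synthetic_graph_spec()]: samples the background edges of each
#' layer, adds the HPO ontology chain, plants the seed-to-disease-gene
#' edges, and attaches the oligogenic-interaction nodes. Deterministic given
#' `spec$rng_seed`. Optionally writes the node-table/edge-list TSV pair
#' consumed by [load_graph()].
#'
#' @param spec a [synthetic_graph_spec()].
#' @param edge_path,node_path optional output TSV paths.
#' @param include_planted_edges set FALSE to omit the planted seed-gene
#'   edges (degradation control in benchmarks); all background randomness is
#'   drawn identically either way.
#' @return A [hetero_graph()] (invisibly when files are written).
#' @export
generate_synthetic_graph <- function(spec, edge_path = NULL, node_path = NULL,
                                     include_planted_edges = TRUE) {
  stopifnot(inherits(spec, "synthetic_graph_spec"))
  genes <- sprintf("G%03d", seq_len(spec$n_genes))
  genes <- unique(c(genes, spec$planted_genes))
  hpo <- synth_hpo_ids(spec$n_hpo)
  disease <- sprintf("D%03d", seq_len(spec$n_disease))
  nodes <- data.frame(
    node_id = c(namespace_gene(genes), namespace_hpo(hpo),
                paste0("DISEASE:", disease)),
    node_type = c(rep("gene", length(genes)), rep("hpo", length(hpo)),
                  rep("disease", length(disease))),
    stringsAsFactors = FALSE
  )
  by_type <- split(nodes$node_id, nodes$node_type)

  edges <- withr::with_seed(spec$rng_seed, {
    out <- list()
    for (layer in spec$layers) {
      types <- SYNTH_LAYER_TYPES[[layer]]
      if (layer == "hpo_ontology") {
        # deterministic is-a chain over HPO terms
        h <- by_type$hpo
        if (length(h) >= 2)
          out[[layer]] <- data.frame(source_id = h[-length(h)],
                                     target_id = h[-1], layer = layer,
                                     stringsAsFactors = FALSE)
        next
      }
      a <- by_type[[types[1]]]
      b <- by_type[[types[2]]]
      if (identical(types[1], types[2])) {
        pairs <- t(utils::combn(a, 2))
      } else {
        pairs <- as.matrix(expand.grid(a, b, KEEP.OUT.ATTRS = FALSE,
                                       stringsAsFactors = FALSE))
      }
      keep <- stats::runif(nrow(pairs)) < spec$background_edge_prob
      if (any(keep))
        out[[layer]] <- data.frame(source_id = pairs[keep, 1],
                                   target_id = pairs[keep, 2], layer = layer,
                                   stringsAsFactors = FALSE)
    }
    # oligogenic-interaction nodes: each links 2 genes and 1 disease
    if (spec$n_oligogenic > 0) {
      oli <- paste0("OLIGOGENIC:OLI", sprintf("%03d", seq_len(spec$n_oligogenic)))
      links <- lapply(oli, function(o) {
        g2 <- sample(by_type$gene, 2)
        d1 <- sample(by_type$disease, 1)
        data.frame(source_id = o, target_id = c(g2, d1),
                   layer = c("oligogenic_gene", "oligogenic_gene",
                             "oligogenic_disease"),
                   stringsAsFactors = FALSE)
      })
      out[["oligogenic"]] <- do.call(rbind, links)
      nodes <- rbind(nodes, data.frame(node_id = oli,
                                       node_type = "oligogenic",
                                       stringsAsFactors = FALSE))
    }
    do.call(rbind, out)
  })

  if (include_planted_edges &&
      length(spec$planted_genes) > 0 && length(spec$planted_seed_ids) > 0) {
    seeds_ns <- ifelse(startsWith(spec$planted_seed_ids, "HP:"),
                       namespace_hpo(spec$planted_seed_ids),
                       paste0("DISEASE:", spec$planted_seed_ids))
    planted <- expand.grid(source_id = seeds_ns,
                           target_id = namespace_gene(spec$planted_genes),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    planted$layer <- ifelse(startsWith(planted$source_id, "HPO:"),
                            "hpo_gene", "disease_gene")
    missing_seed <- setdiff(seeds_ns, nodes$node_id)
    if (length(missing_seed) > 0)
      stop("planted seed ids not among generated nodes: ",
           paste(missing_seed, collapse = ", "))
    edges <- rbind(edges, planted)
  }
  g <- hetero_graph(nodes, edges)
  if (!is.null(edge_path) && !is.null(node_path)) {
    write_graph(g, edge_path, node_path)
    return(invisible(g))
  }
  g
}

#' Generate a synthetic template exome (VCF + annotation TSV)
#'
#' Stand-in for a real sequenced exome: `n_variants` single-nucleotide
#' variants on two artificial contigs, assigned to genes drawn from `genes`,
#' with randomized minor allele frequency, consequence class, exon-edge
#' distance and zygosity so the variant filters have realistic work to do
#' (a fraction of variants is common, intronic, or synonymous-far-from-exon
#' and must be removed). Coordinates are arbitrary — no reference assembly
#' is implied and none is required downstream. Byte-identical outputs for a
#' fixed `rng_seed`.
#'
#' @param n_variants number of template variants.
#' @param genes gene symbols to distribute variants over.
#' @param rng_seed integer seed.
#' @param vcf_path,annotation_path output paths.
#' @return Invisibly, the generated annotation data.frame (one row per
#'   variant, including genotype).
#' @export
generate_template_exome <- function(n_variants, genes, rng_seed,
                                    vcf_path, annotation_path) {
  stopifnot(n_variants >= 0, length(genes) >= 1)
  bases <- c("A", "C", "G", "T")
  df <- withr::with_seed(rng_seed, {
    if (n_variants == 0) {
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), gene = character(0),
                 consequence = character(0), maf = numeric(0),
                 exon_edge_distance = integer(0), gt = character(0),
                 stringsAsFactors = FALSE)
    } else {
      pos_pool <- sample.int(5000000L, n_variants)
      ref <- sample(bases, n_variants, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
      maf <- ifelse(stats::runif(n_variants) < 0.20,
                    stats::runif(n_variants, 0.035, 0.5),   # common
                    stats::runif(n_variants, 0, 0.035))     # rare
      maf[stats::runif(n_variants) < 0.05] <- NA             # unknown
      data.frame(
        chrom = sample(c("chrA", "chrB"), n_variants, replace = TRUE),
        pos = pos_pool,
        ref = ref, alt = unname(alt),
        gene = sample(genes, n_variants, replace = TRUE),
        consequence = sample(c("missense", "synonymous", "intronic", "other"),
                             n_variants, replace = TRUE,
                             prob = c(0.45, 0.20, 0.15, 0.20)),
        maf = round(maf, 6),
        exon_edge_distance = sample(0:400, n_variants, replace = TRUE),
        gt = sample(c("0/1", "1/1"), n_variants, replace = TRUE,
                    prob = c(0.85, 0.15)),
        stringsAsFactors = FALSE
      )
    }
  })
  df <- df[order(df$chrom, df$pos, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  write_simple_vcf(df, vcf_path)
  write_annotation_tsv(df, annotation_path)
  invisible(df)
}

# Minimal single-sample VCFv4.2 writer (GT only); deterministic output.
write_simple_vcf <- function(df, path, sample_name = "SAMPLE01") {
  contigs <- sort(unique(df$chrom), method = "radix")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=digenicRank synthetic exome generator",
    sprintf("##contig=<ID=%s>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- if (nrow(df) == 0) character(0) else
    paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", "PASS", ".", "GT",
          df$gt, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

write_annotation_tsv <- function(df, path) {
  ann <- df[c("chrom", "pos", "ref", "alt", "gene", "consequence", "maf",
              "exon_edge_distance")]
  ann$maf <- ifelse(is.na(ann$maf), "NA", format(ann$maf, scientific = FALSE,
                                                 trim = TRUE))
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Specification of a spike-in benchmark exome
#'
#' Describes a known pathogenic digenic combination to insert into a
#' template exome, together with the patient's disease priors (HPO terms
#' and/or a gene panel). The inserted variants must pass the default
#' [filter_config()] — otherwise the truth combination could never be
#' generated, let alone ranked.
#'
#' @param template_vcf,template_annotation paths to the template exome.
#' @param combination data.frame with one row per inserted variant: `chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `zygosity` (`het`/`hom`), `consequence`,
#'   `maf`, `exon_edge_distance`; exactly two genes, 1-2 variants each.
#' @param patient_hpo character vector of HPO term ids (may be empty).
#' @param patient_panel character vector of panel gene symbols (may be
#'   empty); at least one of the two prior sources must be non-empty.
#' @return An object of class `spike_in_spec`.
#' @export
spike_in_spec <- function(template_vcf, template_annotation, combination,
                          patient_hpo = character(0),
                          patient_panel = character(0)) {
  stopifnot(is.data.frame(combination))
  need <- c("chrom", "pos", "ref", "alt", "gene", "zygosity", "consequence",
            "maf", "exon_edge_distance")
  if (!all(need %in% names(combination)))
    stop("combination needs columns: ", paste(need, collapse = ", "))
  genes <- unique(combination$gene)
  if (length(genes) != 2)
    stop("a digenic combination must span exactly 2 genes, got ",
         length(genes))
  per_gene <- table(combination$gene)
  if (any(per_gene < 1 | per_gene > 2))
    stop("each gene must carry 1-2 inserted variants")
  if (length(patient_hpo) == 0 && length(patient_panel) == 0)
    stop("at least one disease prior (HPO terms or gene panel) is required")
  fl <- apply_variant_filters(
    data.frame(combination,
               variant_id = variant_key(combination$chrom, combination$pos,
                                        combination$ref, combination$alt),
               stringsAsFactors = FALSE))
  if (nrow(fl$kept) < nrow(combination))
    stop("inserted variant(s) would be removed by the default filters; ",
         "the truth combination must survive filtering")
  structure(list(template_vcf = template_vcf,
                 template_annotation = template_annotation,
                 combination = combination,
                 patient_hpo = patient_hpo, patient_panel = patient_panel),
            class = "spike_in_spec")
}

truth_id_of <- function(combination) {
  genes <- sort(unique(combination$gene), method = "radix")
  vk <- variant_key(combination$chrom, combination$pos, combination$ref,
                    combination$alt)
  combination_id(genes[1], vk[combination$gene == genes[1]],
                 genes[2], vk[combination$gene == genes[2]])
}

#' Insert a known pathogenic combination into a template exome
#'
#' Writes the template VCF plus the inserted variant records
#' (position-sorted), the combined annotation TSV, and a truth manifest
#' (JSON) recording the truth combination id and the patient's disease
#' priors. If an inserted position is already variant in the template, the
#' template genotype is overwritten and a message is logged.
#'
#' @param spec a [spike_in_spec()].
#' @param out_vcf,out_annotation output paths for the spiked exome.
#' @param manifest_path optional path for the truth manifest JSON.
#' @return Invisibly, a list with `truth_combination_id`, `manifest`, and
#'   the output paths.
#' @export
insert_combination <- function(spec, out_vcf, out_annotation,
                               manifest_path = NULL) {
  stopifnot(inherits(spec, "spike_in_spec"))
  lines <- readLines(spec$template_vcf)
  if (length(lines) == 0 || !startsWith(lines[1], "##fileformat=VCF"))
    stop("malformed template VCF: ", spec$template_vcf)
  is_header <- startsWith(lines, "#")
  header <- lines[is_header]
  body <- lines[!is_header]
  comb <- spec$combination
  comb_chroms <- sort(unique(comb$chrom), method = "radix")
  # declare any new contig before the FORMAT header line
  declared <- sub("^##contig=<ID=([^>]*)>$", "\\1",
                  grep("^##contig=", header, value = TRUE))
  new_contigs <- setdiff(comb_chroms, declared)
  if (length(new_contigs) > 0) {
    at <- max(grep("^##contig=", header), 1L)
    header <- append(header, sprintf("##contig=<ID=%s>", new_contigs),
                     after = at)
  }
  gt <- ifelse(comb$zygosity == "hom", "1/1", "0/1")
  ins <- paste(comb$chrom, comb$pos, ".", comb$ref, comb$alt, ".", "PASS",
               ".", "GT", gt, sep = "\t")
  # drop template records at an inserted (chrom, pos): genotype overwritten
  if (length(body) > 0) {
    f <- strsplit(body, "\t", fixed = TRUE)
    body_key <- vapply(f, function(x) paste(x[1], x[2]), "")
    clash <- body_key %in% paste(comb$chrom, comb$pos)
    if (any(clash)) {
      message(sum(clash), " template record(s) overwritten by inserted ",
              "variants at the same position")
      body <- body[!clash]
    }
  }
  body <- c(body, ins)
  f <- strsplit(body, "\t", fixed = TRUE)
  ord <- order(vapply(f, `[`, "", 1L), as.integer(vapply(f, `[`, "", 2L)),
               method = "radix")
  writeLines(c(header, body[ord]), out_vcf)

  ann <- utils::read.delim(spec$template_annotation, sep = "\t",
                           header = TRUE, colClasses = "character",
                           quote = "", na.strings = NULL)
  add <- data.frame(chrom = comb$chrom, pos = as.character(comb$pos),
                    ref = comb$ref, alt = comb$alt, gene = comb$gene,
                    consequence = comb$consequence,
                    maf = as.character(comb$maf),
                    exon_edge_distance = as.character(comb$exon_edge_distance),
                    stringsAsFactors = FALSE)
  ann <- rbind(ann[names(add)], add)
  ann <- ann[order(ann$chrom, as.integer(ann$pos), method = "radix"), ,
             drop = FALSE]
  utils::write.table(ann, out_annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth_id <- truth_id_of(comb)
  manifest <- list(
    truth_combination_id = truth_id,
    gene_pair = sort(unique(comb$gene), method = "radix"),
    variants = data.frame(
      variant_id = variant_key(comb$chrom, comb$pos, comb$ref, comb$alt),
      gene = comb$gene, zygosity = comb$zygosity, stringsAsFactors = FALSE),
    patient_hpo = spec$patient_hpo,
    patient_panel = spec$patient_panel,
    template_vcf = spec$template_vcf
  )
  if (!is.null(manifest_path))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(list(truth_combination_id = truth_id, manifest = manifest,
                 vcf = out_vcf, annotation = out_annotation))
}
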