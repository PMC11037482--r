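# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; nothing is read from disk except what a test writes.

# --- graphs ----------------------------------------------------------------

toy_nodes <- function(ids, types) {
  data.frame(node_id = ids, node_type = types, stringsAsFactors = FALSE)
}

toy_edges <- function(src, dst, layer = "l1") {
  data.frame(source_id = src, target_id = dst, layer = layer,
             stringsAsFactors = FALSE)
}

# random mixed-type graph with at least one edge, <= n_max nodes
make_random_graph <- function(seed, n_max = 50) {
  withr::with_seed(seed, {
    n <- sample(5:n_max, 1)
    types <- sample(c("gene", "hpo", "disease"), n, replace = TRUE)
    prefix <- c(gene = "GENE:", hpo = "HPO:", disease = "DISEASE:")[types]
    ids <- paste0(prefix, "N", seq_len(n))
    pairs <- t(utils::combn(seq_len(n), 2))
    keep <- stats::runif(nrow(pairs)) < 0.15
    if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
    hetero_graph(
      toy_nodes(ids, types),
      toy_edges(ids[pairs[keep, 1]], ids[pairs[keep, 2]])
    )
  })
}

# independent RWR oracle: direct linear solve of p = r p0 + (1 - r) W p
rwr_linear_solve <- function(tm, p0, r) {
  W <- as.matrix(tm$W)
  n <- nrow(W)
  solve(diag(n) - (1 - r) * W, r * p0)
}

# sample 1-3 seeds from the walk index, split by namespace for the API
sample_seeds <- function(tm, seed) {
  withr::with_seed(seed, {
    ids <- sample(names(tm$node_index), sample(1:3, 1))
    list(hpo = ids[startsWith(ids, "HPO:") | startsWith(ids, "DISEASE:")],
         genes = ids[startsWith(ids, "GENE:")])
  })
}

build_seeds_for <- function(tm, seed) {
  s <- sample_seeds(tm, seed)
  # DISEASE seeds are passed pre-namespaced through the hpo slot
  build_seed_vector(tm, hpo_ids = s$hpo, panel_genes = s$genes)
}

# --- variants and combinations --------------------------------------------

# minimal kept-variant frame: one row per (gene, variant)
make_variants <- function(genes, n_per_gene) {
  rows <- mapply(function(g, n) {
    if (n == 0) return(NULL)
    data.frame(gene = g,
               variant_id = sprintf("chr1:%d:A:T", seq_len(n) + match(g, genes) * 1000),
               stringsAsFactors = FALSE)
  }, genes, n_per_gene, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene = character(0),
                                      variant_id = character(0))
  rownames(out) <- NULL
  out
}

# brute-force enumeration oracle: explicit subset lists, nested pair loops
brute_force_combinations <- function(kept) {
  by_gene <- lapply(split(kept$variant_id, kept$gene), unique)
  genes <- sort(names(by_gene))
  out <- character(0)
  subsets_of <- function(v) {
    subs <- as.list(v)
    if (length(v) >= 2)
      subs <- c(subs, utils::combn(v, 2, simplify = FALSE))
    subs
  }
  for (ia in seq_along(genes)) for (ib in seq_along(genes)) {
    if (ib <= ia) next
    for (sa in subsets_of(by_gene[[genes[ia]]]))
      for (sb in subsets_of(by_gene[[genes[ib]]]))
        out <- c(out, paste(genes[ia], genes[ib],
                            paste(sort(sa), collapse = ","),
                            paste(sort(sb), collapse = ","), sep = "|"))
  }
  sort(out)
}

# --- files ------------------------------------------------------------------

write_toy_vcf <- function(path, records,
                          samples = "S1") {
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=chr1>",
              "##contig=<ID=chr2>",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

write_toy_annotation <- function(path, df) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
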