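#' Variant filter configuration
#'
#' Defaults follow the filtering used to assemble reported causative
#' oligogenic variants: drop common variants (minor allele frequency above
#' 3.5%), drop intronic variants, and drop synonymous variants lying more
#' than 195 nucleotides from the nearest exon edge. Variants with missing MAF
#' are kept (absence of frequency evidence is treated as rare).
#'
#' @param maf_max maximum minor allele frequency retained; default 0.035.
#' @param synonymous_max_exon_distance maximum distance (nucleotides) from an
#'   exon edge at which a synonymous variant is retained; default 195.
#' @param drop_intronic drop intronic variants; default TRUE.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(maf_max = 0.035,
                          synonymous_max_exon_distance = 195,
                          drop_intronic = TRUE) {
  stopifnot(is.numeric(maf_max), maf_max > 0, maf_max < 1,
            is.numeric(synonymous_max_exon_distance),
            synonymous_max_exon_distance >= 0,
            is.logical(drop_intronic))
  structure(list(maf_max = maf_max,
                 synonymous_max_exon_distance = synonymous_max_exon_distance,
                 drop_intronic = drop_intronic),
            class = "filter_config")
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Read a single-sample VCF and join per-variant annotations
#'
#' Parses a VCF (v4.2) with `vcfR`, decomposes multi-allelic records into one
#' entry per ALT allele, derives zygosity from the sample genotype, and joins
#' a sidecar annotation TSV keyed by (chrom, pos, ref, alt, gene) carrying
#' `consequence`, `maf` and `exon_edge_distance`. A variant annotated to
#' several genes yields one row per gene. Records without a matching
#' annotation row are dropped with a counted warning; genotypes not carrying
#' the ALT allele (or missing) are skipped.
#'
#' @param vcf_path path to the VCF file.
#' @param annotation_path path to the annotation TSV with header
#'   `chrom pos ref alt gene consequence maf exon_edge_distance` (missing
#'   `maf`/`exon_edge_distance` written as `NA` or `.`).
#' @param sample sample name to use when the VCF has several samples;
#'   mandatory in that case.
#' @return data.frame of variants: `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `zygosity` (`het`/`hom`), `maf`, `consequence`, `exon_edge_distance`,
#'   `variant_id`.
#' @export
read_annotated_variants <- function(vcf_path, annotation_path, sample = NULL) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  if (!file.exists(annotation_path))
    stop("annotation file not found: ", annotation_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcf@gt
  samples <- colnames(gt)[-1]
  if (length(samples) == 0) stop("VCF carries no sample genotype column")
  if (length(samples) > 1) {
    if (is.null(sample))
      stop("multi-sample VCF: a sample selector is required (samples: ",
         paste(samples, collapse = ", "), ")")
    if (!sample %in% samples) stop("sample not found in VCF: ", sample)
  } else {
    sample <- samples[1]
  }
  if (nrow(fix) == 0) {
    empty <- empty_variant_frame()
    return(empty)
  }
  fmt <- gt[, "FORMAT"]
  gt_field <- mapply(function(f, v) {
    keys <- strsplit(f, ":", fixed = TRUE)[[1]]
    vals <- strsplit(v, ":", fixed = TRUE)[[1]]
    i <- match("GT", keys)
    if (is.na(i) || i > length(vals)) NA_character_ else vals[i]
  }, fmt, gt[, sample], USE.NAMES = FALSE)

  rows <- vector("list", nrow(fix))
  for (k in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[k], ",", fixed = TRUE)[[1]]
    g <- gt_field[k]
    if (is.na(g)) next
    alleles <- strsplit(g, "[/|]")[[1]]
    for (ai in seq_along(alts)) {
      n_alt <- sum(alleles == as.character(ai))
      if (n_alt == 0) next
      rows[[k]] <- rbind(rows[[k]], data.frame(
        chrom = fix$CHROM[k], pos = as.integer(fix$POS[k]),
        ref = fix$REF[k], alt = alts[ai],
        zygosity = if (n_alt >= 2 ||
                       (length(alleles) == 1 && n_alt == 1)) "hom" else "het",
        stringsAsFactors = FALSE))
    }
  }
  vars <- do.call(rbind, rows)
  if (is.null(vars)) return(empty_variant_frame())

  ann <- read_annotation_table(annotation_path)
  vars$vkey <- variant_key(vars$chrom, vars$pos, vars$ref, vars$alt)
  ann$vkey <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  merged <- merge(vars[c("vkey", "zygosity")],
                  ann[c("vkey", "gene", "consequence", "maf",
                        "exon_edge_distance")],
                  by = "vkey")
  n_dropped <- sum(!vars$vkey %in% ann$vkey)
  if (n_dropped > 0)
    warning(n_dropped, " VCF record(s) had no annotation row and were dropped")
  if (nrow(merged) == 0) return(empty_variant_frame())
  parts <- strsplit(merged$vkey, ":", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    ref = vapply(parts, `[`, "", 3L),
    alt = vapply(parts, `[`, "", 4L),
    gene = merged$gene,
    zygosity = merged$zygosity,
    maf = merged$maf,
    consequence = merged$consequence,
    exon_edge_distance = merged$exon_edge_distance,
    variant_id = merged$vkey,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos, out$alt, out$gene, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_variant_frame <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), gene = character(0), zygosity = character(0),
             maf = numeric(0), consequence = character(0),
             exon_edge_distance = numeric(0), variant_id = character(0),
             stringsAsFactors = FALSE)
}

read_annotation_table <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           na.strings = c("NA", "."))
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "maf",
            "exon_edge_distance")
  missing <- setdiff(need, names(ann))
  if (length(missing) > 0)
    stop(path, ": annotation table missing columns: ",
         paste(missing, collapse = ", "))
  ann$pos <- as.integer(ann$pos)
  ann$maf <- as.numeric(ann$maf)
  ann$exon_edge_distance <- as.numeric(ann$exon_edge_distance)
  bad_maf <- !is.na(ann$maf) & (ann$maf < 0 | ann$maf > 1)
  if (any(bad_maf))
    stop(path, ": maf outside [0, 1] in ", sum(bad_maf), " row(s)")
  ann
}

#' Apply exome variant filters
#'
#' A variant is removed iff it violates any rule of the [filter_config()]:
#' MAF above the cutoff, intronic consequence, or synonymous consequence
#' farther from the nearest exon edge than allowed. Rules are evaluated
#' independently, so the per-rule removal counts in the report can overlap.
#'
#' @param variants data.frame from [read_annotated_variants()].
#' @param cfg a [filter_config()].
#' @return list with `kept` (filtered data.frame) and `report` (data.frame of
#'   per-rule removal counts plus totals).
#' @export
apply_variant_filters <- function(variants, cfg = filter_config()) {
  stopifnot(is.data.frame(variants), inherits(cfg, "filter_config"))
  maf_rule <- !is.na(variants$maf) & variants$maf > cfg$maf_max
  intronic_rule <- if (cfg$drop_intronic)
    variants$consequence == "intronic" else rep(FALSE, nrow(variants))
  syn_rule <- variants$consequence == "synonymous" &
    !is.na(variants$exon_edge_distance) &
    variants$exon_edge_distance > cfg$synonymous_max_exon_distance
  removed <- maf_rule | intronic_rule | syn_rule
  kept <- variants[!removed, , drop = FALSE]
  rownames(kept) <- NULL
  report <- data.frame(
    rule = c("maf_above_max", "intronic", "synonymous_far_from_exon",
             "total_removed", "total_kept"),
    n = c(sum(maf_rule), sum(intronic_rule), sum(syn_rule),
          sum(removed), sum(!removed)),
    stringsAsFactors = FALSE
  )
  list(kept = kept, report = report)
}

# All non-empty subsets of size 1 or 2 of a gene's variants, each subset
# labelled by its sorted comma-joined variant ids.
gene_variant_subsets <- function(variant_ids) {
  ids <- sort(unique(variant_ids), method = "radix")
  labels <- ids
  if (length(ids) >= 2) {
    pairs <- utils::combn(ids, 2)
    labels <- c(labels, paste(pairs[1, ], pairs[2, ], sep = ","))
  }
  sort(labels, method = "radix")
}

#' Canonical identifier of a digenic combination
#'
#' Genes are ordered bytewise and variant ids within a gene's subset are
#' sorted, so the identifier is invariant under gene-pair reordering and
#' stable across runs.
#'
#' @param gene_a,gene_b gene symbols.
#' @param variants_a,variants_b character vectors (or comma-joined strings)
#'   of variant ids in each gene.
#' @return character scalar `geneA|geneB|ids_a|ids_b`.
#' @export
combination_id <- function(gene_a, variants_a, gene_b, variants_b) {
  join <- function(v) paste(sort(unlist(strsplit(v, ",", fixed = TRUE)),
                                 method = "radix"), collapse = ",")
  la <- join(variants_a)
  lb <- join(variants_b)
  if (gene_a > gene_b) {
    tmp <- gene_a; gene_a <- gene_b; gene_b <- tmp
    tmp <- la; la <- lb; lb <- tmp
  }
  paste(gene_a, gene_b, la, lb, sep = "|")
}

#' Enumerate digenic variant combinations
#'
#' For every unordered pair of genes that both carry at least one kept
#' variant, emits every combination of a subset of 1-2 variants in the first
#' gene with a subset of 1-2 variants in the second. Emission order is
#' deterministic (bytewise lexicographic by `combination_id`). With a
#' `callback`, combinations are produced one gene pair at a time and never
#' materialized globally, bounding memory by the largest per-pair block.
#'
#' @param kept data.frame of filtered variants (needs `gene`, `variant_id`).
#' @param callback optional `function(chunk)` receiving one data.frame per
#'   gene pair; when supplied the function returns the emitted row count.
#' @return data.frame with `combination_id`, `gene_a`, `gene_b`,
#'   `variants_a`, `variants_b` (comma-joined variant ids), or the total row
#'   count when streaming through `callback`.
#' @export
generate_combinations <- function(kept, callback = NULL) {
  stopifnot(is.data.frame(kept))
  genes <- sort(unique(kept$gene), method = "radix")
  if (length(genes) < 2) {
    warning("fewer than 2 genes carry kept variants; no combinations")
    empty <- data.frame(combination_id = character(0), gene_a = character(0),
                        gene_b = character(0), variants_a = character(0),
                        variants_b = character(0), stringsAsFactors = FALSE)
    return(if (is.null(callback)) empty else 0L)
  }
  subsets <- lapply(split(kept$variant_id, kept$gene), gene_variant_subsets)
  subsets <- subsets[genes]
  n_emitted <- 0
  chunks <- if (is.null(callback)) vector("list", 0) else NULL
  for (ia in seq_len(length(genes) - 1)) {
    for (ib in seq(ia + 1, length(genes))) {
      ga <- genes[ia]; gb <- genes[ib]
      sa <- subsets[[ga]]; sb <- subsets[[gb]]
      grid <- expand.grid(variants_a = sa, variants_b = sb,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      chunk <- data.frame(
        combination_id = paste(ga, gb, grid$variants_a, grid$variants_b,
                               sep = "|"),
        gene_a = ga, gene_b = gb,
        variants_a = grid$variants_a, variants_b = grid$variants_b,
        stringsAsFactors = FALSE
      )
      chunk <- chunk[order(chunk$combination_id, method = "radix"), ,
                     drop = FALSE]
      n_emitted <- n_emitted + nrow(chunk)
      if (is.null(callback)) chunks[[length(chunks) + 1]] <- chunk
      else callback(chunk)
    }
  }
  if (!is.null(callback)) return(n_emitted)
  out <- do.call(rbind, chunks)
  out <- out[order(out$combination_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Closed-form count of digenic combinations
#'
#' A gene with `n` variants contributes `f(n) = n + n(n-1)/2` admissible
#' subsets (singletons plus unordered pairs); the total combination count is
#' the sum of `f(n_A) * f(n_B)` over unordered gene pairs, computed here
#' without enumeration as `(S^2 - sum(f^2)) / 2` with `S = sum(f)`.
#'
#' @param kept data.frame of filtered variants (needs `gene`, `variant_id`).
#' @return Non-negative count (double; exome-scale counts can exceed
#'   `.Machine$integer.max`).
#' @export
count_combinations <- function(kept) {
  stopifnot(is.data.frame(kept))
  n_per_gene <- vapply(split(kept$variant_id, kept$gene),
                       function(v) length(unique(v)), integer(1))
  if (length(n_per_gene) < 2) return(0)
  f <- n_per_gene + n_per_gene * (n_per_gene - 1) / 2
  (sum(f)^2 - sum(f^2)) / 2
}
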