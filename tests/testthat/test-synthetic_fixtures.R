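test_that("synthetic graphs honour the planting contract", {
  spec <- synthetic_graph_spec(n_genes = 10, n_hpo = 5, n_disease = 3,
                               background_edge_prob = 0,
                               planted_genes = c("G001", "G002"),
                               planted_seed_ids = "HP:0000001",
                               layers = c("ppi", "hpo_gene"),
                               n_oligogenic = 0, rng_seed = 1)
  g <- generate_synthetic_graph(spec)
  # with zero background probability only the planted edges exist
  expect_equal(nrow(g$edges), 2)
  expect_setequal(paste(g$edges$source_id, g$edges$target_id),
                  c("GENE:G001 HPO:HP:0000001", "GENE:G002 HPO:HP:0000001"))
})

test_that("generated graphs are deterministic and load back cleanly", {
  spec <- synthetic_graph_spec(rng_seed = 99)
  d <- withr::local_tempdir()
  p1 <- file.path(d, c("e1.tsv", "n1.tsv"))
  p2 <- file.path(d, c("e2.tsv", "n2.tsv"))
  generate_synthetic_graph(spec, p1[1], p1[2])
  generate_synthetic_graph(spec, p2[1], p2[2])
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  expect_identical(readLines(p1[2]), readLines(p2[2]))

  g <- load_graph(p1[1], p1[2])
  expect_s3_class(g, "hetero_graph")
  expect_setequal(unique(g$nodes$node_type),
                  c("gene", "hpo", "disease", "oligogenic"))
  # planted disease genes are adjacent to every planted seed
  for (pg in namespace_gene(spec$planted_genes))
    for (ps in namespace_hpo(spec$planted_seed_ids))
      expect_true(any((g$edges$source_id == ps & g$edges$target_id == pg) |
                        (g$edges$source_id == pg & g$edges$target_id == ps)))
  # preparation removes the oligogenic nodes and the graph still flattens
  tm <- flatten_and_normalize(remove_node_type(g, "oligogenic"))
  expect_lt(max(abs(Matrix::colSums(tm$W) - 1)), 1e-12)
})

test_that("template exomes are byte-deterministic with complete annotation", {
  d <- withr::local_tempdir()
  genes <- sprintf("G%03d", 1:12)
  v1 <- file.path(d, "a.vcf"); a1 <- file.path(d, "a.tsv")
  v2 <- file.path(d, "b.vcf"); a2 <- file.path(d, "b.tsv")
  generate_template_exome(80, genes, rng_seed = 5, vcf_path = v1,
                          annotation_path = a1)
  generate_template_exome(80, genes, rng_seed = 5, vcf_path = v2,
                          annotation_path = a2)
  expect_identical(readLines(v1), readLines(v2))
  expect_identical(readLines(a1), readLines(a2))

  # every VCF record joins an annotation row: nothing is dropped
  v <- expect_no_warning(read_annotated_variants(v1, a1))
  vcf_body <- sum(!startsWith(readLines(v1), "#"))
  expect_equal(nrow(v), vcf_body)
  expect_true(all(v$gene %in% genes))
  expect_true(all(v$consequence %in%
                    c("missense", "synonymous", "intronic", "other")))
  # the filters have real work: some variants fall to each fate
  fl <- apply_variant_filters(v)
  expect_gt(nrow(fl$kept), 0)
  expect_gt(fl$report$n[fl$report$rule == "total_removed"], 0)

  # n_variants = 0 produces a header-only VCF
  v0 <- file.path(d, "empty.vcf"); a0 <- file.path(d, "empty.tsv")
  generate_template_exome(0, genes, rng_seed = 1, vcf_path = v0,
                          annotation_path = a0)
  expect_true(all(startsWith(readLines(v0), "#")))
})

test_that("spike-in inserts the combination and survives the round trip", {
  d <- withr::local_tempdir()
  genes <- sprintf("G%03d", 1:10)
  tmpl_vcf <- file.path(d, "t.vcf"); tmpl_ann <- file.path(d, "t.tsv")
  generate_template_exome(40, genes, rng_seed = 3, vcf_path = tmpl_vcf,
                          annotation_path = tmpl_ann)
  comb <- data.frame(
    chrom = c("chrA", "chrA", "chrB"), pos = c(9000001L, 9000050L, 9000002L),
    ref = c("G", "A", "C"), alt = c("T", "C", "A"),
    gene = c("DG1", "DG1", "DG2"),
    zygosity = c("het", "het", "hom"), consequence = "missense",
    maf = 0.001, exon_edge_distance = 5L, stringsAsFactors = FALSE)
  spec <- spike_in_spec(tmpl_vcf, tmpl_ann, comb,
                        patient_hpo = c("HP:0000001"))
  out_vcf <- file.path(d, "p.vcf"); out_ann <- file.path(d, "p.tsv")
  manifest_path <- file.path(d, "truth.json")
  ins <- insert_combination(spec, out_vcf, out_ann, manifest_path)

  body <- readLines(out_vcf)
  records <- body[!startsWith(body, "#")]
  expect_equal(length(records), 40 + 3)
  expect_true(any(grepl("^chrA\t9000001\t.*0/1$", records)))  # het GT
  expect_true(any(grepl("^chrB\t9000002\t.*1/1$", records)))  # hom GT
  # position-sorted within contig
  pos <- as.integer(sapply(strsplit(records, "\t"), `[`, 2))
  chrom <- sapply(strsplit(records, "\t"), `[`, 1)
  expect_false(is.unsorted(order(chrom, pos)))

  # manifest carries the truth id and the priors
  manifest <- jsonlite::read_json(manifest_path)
  expect_equal(manifest$truth_combination_id, ins$truth_combination_id)
  expect_equal(unlist(manifest$patient_hpo), "HP:0000001")

  # round trip: the truth combination appears in the generated stream
  v <- read_annotated_variants(out_vcf, out_ann)
  fl <- apply_variant_filters(v)
  combos <- generate_combinations(fl$kept)
  expect_true(ins$truth_combination_id %in% combos$combination_id)
})

test_that("spike-in specs reject combinations the filters would remove", {
  d <- withr::local_tempdir()
  tmpl_vcf <- file.path(d, "t.vcf"); tmpl_ann <- file.path(d, "t.tsv")
  generate_template_exome(5, "G001", rng_seed = 1, vcf_path = tmpl_vcf,
                          annotation_path = tmpl_ann)
  bad <- data.frame(chrom = c("chrA", "chrB"), pos = c(1L, 2L),
                    ref = "A", alt = "T", gene = c("DG1", "DG2"),
                    zygosity = "het", consequence = "missense",
                    maf = c(0.2, 0.001),  # first is too common
                    exon_edge_distance = 5L, stringsAsFactors = FALSE)
  expect_error(spike_in_spec(tmpl_vcf, tmpl_ann, bad, patient_hpo = "HP:1"),
               "filters")
  # and a spec with no disease prior at all is rejected
  ok <- bad; ok$maf <- 0.001
  expect_error(spike_in_spec(tmpl_vcf, tmpl_ann, ok), "disease prior")
})

test_that("overlapping template positions are overwritten with a message", {
  d <- withr::local_tempdir()
  tmpl_vcf <- file.path(d, "t.vcf"); tmpl_ann <- file.path(d, "t.tsv")
  write_toy_vcf(tmpl_vcf, "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1")
  write_toy_annotation(tmpl_ann, data.frame(
    chrom = "chr1", pos = 100, ref = "A", alt = "T", gene = "G001",
    consequence = "missense", maf = 0.001, exon_edge_distance = 5))
  comb <- data.frame(chrom = c("chr1", "chr2"), pos = c(100L, 200L),
                     ref = c("A", "C"), alt = c("G", "T"),
                     gene = c("DG1", "DG2"), zygosity = "het",
                     consequence = "missense", maf = 0.001,
                     exon_edge_distance = 5L, stringsAsFactors = FALSE)
  spec <- spike_in_spec(tmpl_vcf, tmpl_ann, comb, patient_hpo = "HP:1")
  expect_message(
    insert_combination(spec, file.path(d, "p.vcf"), file.path(d, "p.tsv")),
    "overwritten")
  records <- grep("^#", readLines(file.path(d, "p.vcf")), value = TRUE,
                  invert = TRUE)
  expect_equal(length(records), 2)  # template record at 100 was replaced
})
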