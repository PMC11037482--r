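ann_row <- function(chrom, pos, ref, alt, gene, consequence = "missense",
                    maf = 0.001, dist = 10) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             consequence = consequence, maf = maf,
             exon_edge_distance = dist, stringsAsFactors = FALSE)
}

test_that("VCF records map to annotated variants with zygosity", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  ann <- withr::local_tempfile(fileext = ".tsv")
  write_toy_vcf(vcf, c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1",
    "chr1\t200\t.\tC\tG\t.\tPASS\t.\tGT\t1/1",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0/1",   # annotated to 2 genes
    "chr1\t400\t.\tT\tC\t.\tPASS\t.\tGT\t0/0",   # ref genotype: skipped
    "chr2\t500\t.\tA\tG,C\t.\tPASS\t.\tGT\t1/2"  # multi-allelic
  ))
  write_toy_annotation(ann, rbind(
    ann_row("chr1", 100, "A", "T", "GENE1"),
    ann_row("chr1", 200, "C", "G", "GENE2"),
    ann_row("chr1", 300, "G", "A", "GENE1"),
    ann_row("chr1", 300, "G", "A", "GENE3"),
    ann_row("chr2", 500, "A", "G", "GENE4"),
    ann_row("chr2", 500, "A", "C", "GENE4")))
  v <- read_annotated_variants(vcf, ann)
  expect_equal(v$zygosity[v$pos == 100], "het")
  expect_equal(v$zygosity[v$pos == 200], "hom")
  expect_setequal(v$gene[v$pos == 300], c("GENE1", "GENE3"))
  expect_false(400 %in% v$pos)
  # each ALT of the multi-allelic record is one het variant
  expect_setequal(v$alt[v$pos == 500], c("G", "C"))
  expect_true(all(v$zygosity[v$pos == 500] == "het"))
})

test_that("multi-sample VCFs require a selector; unannotated records warn", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  ann <- withr::local_tempfile(fileext = ".tsv")
  write_toy_vcf(vcf, c("chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
                       "chr1\t200\t.\tC\tG\t.\tPASS\t.\tGT\t0/1\t0/1"),
                samples = c("S1", "S2"))
  write_toy_annotation(ann, ann_row("chr1", 100, "A", "T", "GENE1"))
  expect_error(read_annotated_variants(vcf, ann), "sample selector")
  expect_warning(v <- read_annotated_variants(vcf, ann, sample = "S2"),
                 "no annotation")
  expect_equal(v$zygosity, "hom")
  expect_error(read_annotated_variants(vcf, ann, sample = "S9"), "S9")
  expect_error(read_annotated_variants(vcf, "missing.tsv"), "not found")
})

test_that("variant filters remove exactly the rule violators", {
  v <- rbind(
    ann_row("chr1", 1, "A", "T", "G1", "missense", maf = 0.05),      # MAF
    ann_row("chr1", 2, "A", "T", "G1", "missense", maf = 0.035),     # kept (boundary)
    ann_row("chr1", 3, "A", "T", "G2", "synonymous", dist = 200),    # syn far
    ann_row("chr1", 4, "A", "T", "G2", "synonymous", dist = 150),    # kept
    ann_row("chr1", 5, "A", "T", "G2", "synonymous", dist = 195),    # kept (boundary)
    ann_row("chr1", 6, "A", "T", "G3", "intronic", maf = 0.001),     # intronic
    ann_row("chr1", 7, "A", "T", "G3", "missense", maf = NA),        # kept: missing MAF
    ann_row("chr1", 8, "A", "T", "G4", "other", maf = 0.01))         # kept
  v$variant_id <- paste0("v", seq_len(nrow(v)))
  fl <- apply_variant_filters(v, filter_config())
  expect_setequal(fl$kept$pos, c(2, 4, 5, 7, 8))
  rep <- setNames(fl$report$n, fl$report$rule)
  expect_equal(rep[["maf_above_max"]], 1)
  expect_equal(rep[["intronic"]], 1)
  expect_equal(rep[["synonymous_far_from_exon"]], 1)
  expect_equal(rep[["total_removed"]], 3)

  # idempotence and order-independence
  fl2 <- apply_variant_filters(fl$kept, filter_config())
  expect_equal(fl2$kept, fl$kept)
  shuffled <- v[rev(seq_len(nrow(v))), ]
  fl3 <- apply_variant_filters(shuffled, filter_config())
  expect_setequal(fl3$kept$variant_id, fl$kept$variant_id)
})

test_that("combination enumeration matches the brute-force subset oracle", {
  # A(1), B(1) -> 1 combination
  expect_equal(nrow(generate_combinations(make_variants(c("A", "B"), c(1, 1)))), 1)
  # A(2), B(3) -> (2 + 1) * (3 + 3) = 18
  kept23 <- make_variants(c("A", "B"), c(2, 3))
  combos23 <- generate_combinations(kept23)
  expect_equal(nrow(combos23), 18)
  expect_identical(sort(combos23$combination_id),
                   brute_force_combinations(kept23))
  # A, B, C with 1 variant each -> 3 combinations over 3 gene pairs
  combos111 <- generate_combinations(make_variants(c("A", "B", "C"), c(1, 1, 1)))
  expect_equal(nrow(combos111), 3)
  expect_equal(length(unique(paste(combos111$gene_a, combos111$gene_b))), 3)
})

test_that("closed-form count equals stream length on random inputs", {
  for (s in 1:30) {
    kept <- withr::with_seed(s, {
      ng <- sample(2:6, 1)
      make_variants(paste0("G", seq_len(ng)), sample(0:6, ng, replace = TRUE))
    })
    if (length(unique(kept$gene)) < 2) {
      expect_equal(count_combinations(kept), 0)
      next
    }
    combos <- generate_combinations(kept)
    expect_equal(count_combinations(kept), nrow(combos))
    expect_identical(sort(combos$combination_id),
                     brute_force_combinations(kept))
  }
})

test_that("streaming emission matches materialized output and is ordered", {
  kept <- make_variants(paste0("G", 1:4), c(2, 1, 3, 2))
  combos <- generate_combinations(kept)
  chunks <- list()
  n <- generate_combinations(kept, callback = function(ch)
    chunks[[length(chunks) + 1]] <<- ch)
  expect_equal(n, nrow(combos))
  expect_setequal(do.call(rbind, chunks)$combination_id,
                  combos$combination_id)
  # deterministic lexicographic emission, unique stable ids
  expect_false(is.unsorted(combos$combination_id))
  expect_false(anyDuplicated(combos$combination_id) > 0)
  expect_identical(combos, generate_combinations(kept))
})

test_that("combination ids are invariant under gene-pair reordering", {
  id1 <- combination_id("GB", c("v2", "v1"), "GA", "v3")
  id2 <- combination_id("GA", "v3", "GB", c("v1", "v2"))
  expect_identical(id1, id2)
  expect_identical(id1, "GA|GB|v3|v1,v2")
})

test_that("degenerate inputs produce empty streams with a warning", {
  one_gene <- make_variants("A", 2)
  expect_warning(combos <- generate_combinations(one_gene), "fewer than 2")
  expect_equal(nrow(combos), 0)
  expect_equal(count_combinations(one_gene), 0)
})
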