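#' Rank of the known truth combination in a ranking
#'
#' Returns the 1-based position of the spiked-in truth combination. Under FS
#' ties the worst (largest) position among the tied records is reported —
#' the conservative reading: a user scanning the list might inspect every
#' tied record before the truth.
#'
#' @param ranking data.frame from [rank_exome()].
#' @param truth_id combination id of the truth.
#' @return Positive integer, or `NA_integer_` when the truth is absent.
#' @export
truth_rank <- function(ranking, truth_id) {
  stopifnot(is.data.frame(ranking))
  hit <- match(truth_id, ranking$combination_id)
  if (is.na(hit)) return(NA_integer_)
  ft <- ranking$FS[hit]
  as.integer(sum(ranking$FS > ft) + sum(ranking$FS == ft))
}

#' Cumulative top-K recovery over benchmark exomes
#'
#' For each K in `1..k_max`, the fraction of exomes whose truth combination
#' ranks at or above K. A truth that was never ranked (`NA`) counts as never
#' recovered.
#'
#' @param results data.frame with one row per exome and a `truth_rank`
#'   column (`NA` = not found), or a vector of truth ranks.
#' @param k_max largest K; default 50.
#' @return list with `cdf` (data.frame `K`, `fraction`) and `summary`
#'   (named fractions at K = 1, 10, 20, 50, restricted to K <= `k_max`).
#' @export
cdf_topk <- function(results, k_max = 50L) {
  ranks <- if (is.data.frame(results)) results$truth_rank else results
  if (length(ranks) == 0) stop("no exome results supplied")
  k <- seq_len(k_max)
  frac <- vapply(k, function(kk) mean(!is.na(ranks) & ranks <= kk),
                 numeric(1))
  ks <- intersect(c(1L, 10L, 20L, 50L), k)
  list(cdf = data.frame(K = k, fraction = frac),
       summary = stats::setNames(frac[ks], paste0("top", ks)))
}

#' Combination rank under a single-variant prioritizer
#'
#' Converts a per-variant rank list (e.g. from a monogenic prioritization
#' tool) into a combination rank: the maximum of the member variants' ranks,
#' i.e. the number of variants a user must examine down the single-variant
#' list before having seen the whole combination. A combination is top-1
#' under this rule only when every member variant is at the top of the list.
#'
#' @param variant_ranks named integer vector: variant id to 1-based rank.
#' @param variant_ids character vector of the combination's variant ids
#'   (a `DigenicCombination`'s `variants_a` and `variants_b`, comma-joined
#'   strings accepted).
#' @return Positive integer, or `NA_integer_` when any member variant is
#'   missing from the rank list.
#' @export
single_variant_combination_rank <- function(variant_ranks, variant_ids) {
  ids <- unlist(strsplit(variant_ids, ",", fixed = TRUE))
  r <- variant_ranks[ids]
  if (any(is.na(r))) return(NA_integer_)
  as.integer(max(r))
}

#' Write benchmark exome results and CDF tables to TSV
#'
#' @param results data.frame with `exome_id`, `truth_rank`,
#'   `total_combinations`.
#' @param path output TSV path.
#' @return Invisibly, the results.
#' @export
write_exome_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(results)
}
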