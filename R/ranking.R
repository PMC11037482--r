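#' Min-max scaling to the unit interval
#'
#' Maps a sequence affinely so the minimum becomes 0 and the maximum 1. When
#' all values are equal (including a length-1 input) every output is 0.5, so
#' a constant score neither dominates nor vanishes when averaged with the
#' other score.
#'
#' @param values non-empty numeric vector of finite values.
#' @return Numeric vector in \[0, 1\].
#' @export
minmax_scale <- function(values) {
  if (length(values) == 0) stop("cannot min-max scale an empty sequence")
  if (any(!is.finite(values))) stop("values must be finite")
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) return(rep(0.5, length(values)))
  (values - lo) / (hi - lo)
}

#' Fuse scaled pathogenicity and disease-relevance scores
#'
#' The default fusion is the arithmetic mean of the scaled scores, giving
#' both evidence types equal weight; `product`, `min` and `max` are
#' available as alternative aggregation operators.
#'
#' @param ps_scaled,ds_scaled numeric vectors in \[0, 1\].
#' @param operator one of `"mean"`, `"product"`, `"min"`, `"max"`.
#' @return Numeric vector of final scores in \[0, 1\].
#' @export
fuse_scores <- function(ps_scaled, ds_scaled,
                        operator = c("mean", "product", "min", "max")) {
  operator <- match.arg(operator)
  stopifnot(all(ps_scaled >= 0 & ps_scaled <= 1),
            all(ds_scaled >= 0 & ds_scaled <= 1))
  switch(operator,
         mean = (ps_scaled + ds_scaled) / 2,
         product = ps_scaled * ds_scaled,
         min = pmin(ps_scaled, ds_scaled),
         max = pmax(ps_scaled, ds_scaled))
}

#' Rank the combinations of one exome
#'
#' Scales PS and DS per exome with [minmax_scale()] (scaling is strictly
#' within one exome, never across a cohort), fuses them with
#' [fuse_scores()], and sorts descending by the final score FS. Ties are
#' broken deterministically: higher `PS_scaled` first, then bytewise
#' lexicographic `combination_id`. Ranks are the permutation `1..N`.
#'
#' @param records data.frame with `combination_id`, `gene_a`, `gene_b`,
#'   `PS`, `DS` (one row per combination of one exome).
#' @param operator fusion operator, see [fuse_scores()].
#' @return data.frame of ranking records: the input columns plus
#'   `PS_scaled`, `DS_scaled`, `FS` and `rank`, sorted by rank.
#' @export
rank_exome <- function(records, operator = "mean") {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("combination_id", "PS", "DS") %in% names(records)))
  out <- records
  out$PS_scaled <- minmax_scale(out$PS)
  out$DS_scaled <- minmax_scale(out$DS)
  out$FS <- fuse_scores(out$PS_scaled, out$DS_scaled, operator = operator)
  ord <- order(-out$FS, -out$PS_scaled, out$combination_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a ranking to TSV
#'
#' @param ranking data.frame from [rank_exome()].
#' @param path output path.
#' @return Invisibly, the ranking.
#' @export
write_ranking <- function(ranking, path) {
  cols <- c("rank", "combination_id", "gene_a", "gene_b",
            "PS", "DS", "PS_scaled", "DS_scaled", "FS")
  cols <- intersect(cols, names(ranking))
  df <- ranking[cols]
  for (nm in intersect(c("PS", "DS", "PS_scaled", "DS_scaled", "FS"), cols))
    df[[nm]] <- sprintf("%.12g", df[[nm]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ranking)
}
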