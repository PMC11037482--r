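#' Pathogenicity scorer contract
#'
#' A scorer maps a digenic combination to a pathogenicity score (PS) in
#' \[0, 1\], deterministically: identical `combination_id` always yields the
#' identical PS. The package ships two scorers behind this contract — a
#' lookup scorer over a precomputed score table ([table_scorer()], e.g. for
#' externally computed VarCoPP-style predictions) and a deterministic
#' surrogate used by the synthetic benchmark ([surrogate_scorer()]). Any
#' model honouring the contract can be plugged in by wrapping it with this
#' constructor.
#'
#' @param name scorer name (character scalar).
#' @param score_fun `function(combination_id, gene_a, gene_b)` returning a
#'   numeric vector of scores in \[0, 1\], vectorized over its arguments.
#' @return An object of class `pathogenicity_scorer`.
#' @export
pathogenicity_scorer <- function(name, score_fun) {
  stopifnot(is.character(name), is.function(score_fun))
  structure(list(name = name, score_fun = score_fun),
            class = "pathogenicity_scorer")
}

#' Score combinations with a scorer
#'
#' @param scorer a [pathogenicity_scorer()].
#' @param combinations data.frame with `combination_id`, `gene_a`, `gene_b`
#'   (as produced by [generate_combinations()]), or a character vector of
#'   combination ids.
#' @return Numeric vector of PS values in \[0, 1\].
#' @export
score_combinations <- function(scorer, combinations) {
  stopifnot(inherits(scorer, "pathogenicity_scorer"))
  if (is.character(combinations)) {
    parts <- strsplit(combinations, "|", fixed = TRUE)
    combinations <- data.frame(
      combination_id = combinations,
      gene_a = vapply(parts, `[`, "", 1L),
      gene_b = vapply(parts, `[`, "", 2L),
      stringsAsFactors = FALSE)
  }
  ps <- scorer$score_fun(combinations$combination_id,
                         combinations$gene_a, combinations$gene_b)
  if (any(is.na(ps) | ps < 0 | ps > 1))
    stop("scorer '", scorer$name, "' returned scores outside [0, 1]")
  ps
}

#' Lookup scorer over a precomputed score table
#'
#' Adapter for externally computed pathogenicity predictions: a TSV keyed by
#' `combination_id` with a `ps` column. In `strict` mode a missing key is an
#' error naming the offending id; in `lenient` mode missing keys score 0
#' with one aggregated warning (absent prediction treated as benign).
#'
#' @param score_table_path path to the TSV (`combination_id`, `ps`).
#' @param mode `"strict"` or `"lenient"`.
#' @return A [pathogenicity_scorer()].
#' @export
table_scorer <- function(score_table_path, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  tab <- utils::read.delim(score_table_path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  if (!all(c("combination_id", "ps") %in% names(tab)))
    stop(score_table_path, ": score table needs columns combination_id, ps")
  ps <- as.numeric(tab$ps)
  if (any(is.na(ps) | ps < 0 | ps > 1))
    stop(score_table_path, ": ps outside [0, 1] (or non-numeric) in ",
         sum(is.na(ps) | ps < 0 | ps > 1), " row(s)")
  lookup <- stats::setNames(ps, tab$combination_id)
  pathogenicity_scorer(
    name = paste0("table[", basename(score_table_path), ",", mode, "]"),
    score_fun = function(combination_id, gene_a, gene_b) {
      out <- lookup[combination_id]
      miss <- is.na(out)
      if (any(miss)) {
        if (mode == "strict")
          stop("no pathogenicity score for combination id(s): ",
               paste(utils::head(combination_id[miss], 5), collapse = ", "))
        warning(sum(miss),
                " combination(s) missing from score table; scored 0")
        out[miss] <- 0
      }
      unname(out)
    }
  )
}

# Deterministic polynomial rolling hash of a string vector onto [0, 1).
# Arithmetic stays below 2^53 so results are exact in doubles and identical
# across platforms: h <- (h * 131 + code) mod (2^31 - 1).
hash_unit_interval <- function(ids, seed) {
  p <- 2147483647  # 2^31 - 1
  chars <- strsplit(intToUtf8(32:126), "")[[1]]
  n <- length(ids)
  h <- rep((as.numeric(seed) * 2654435761) %% p, n)
  maxlen <- if (n == 0) 0L else max(nchar(ids))
  for (i in seq_len(maxlen)) {
    code <- match(substring(ids, i, i), chars, nomatch = 0L)
    code <- ifelse(code > 0L, code + 31L, 0L)
    h <- (h * 131 + code) %% p
  }
  h <- (h * 131 + nchar(ids)) %% p
  # one extra mixing round decorrelates ids sharing long prefixes
  h <- (h * 48271) %% p
  h <- (h * 48271) %% p
  h / p
}

#' Deterministic surrogate pathogenicity scorer
#'
#' Stand-in scorer for benchmarks where no trained combination classifier is
#' available: scores are a deterministic hash of the `combination_id` mapped
#' to \[0, 1) (approximately uniform), so they are reproducible across runs
#' and platforms for a given `seed`. Specific gene pairs can be pinned to a
#' fixed score via `overrides` — the synthetic spike-in benchmark uses this
#' to give the planted pathogenic pair a near-maximal PS.
#'
#' @param seed integer mixed into the hash.
#' @param overrides named numeric vector of scores in \[0, 1\]; names are
#'   gene pairs as `"GENEA|GENEB"` (order-insensitive).
#' @return A [pathogenicity_scorer()].
#' @export
surrogate_scorer <- function(seed = 0L, overrides = NULL) {
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)),
              all(overrides >= 0 & overrides <= 1))
    nm <- vapply(strsplit(names(overrides), "|", fixed = TRUE), function(g) {
      if (length(g) != 2) stop("override names must be 'GENEA|GENEB'")
      paste(sort(g, method = "radix"), collapse = "|")
    }, "")
    names(overrides) <- nm
  }
  pathogenicity_scorer(
    name = paste0("surrogate[seed=", seed, "]"),
    score_fun = function(combination_id, gene_a, gene_b) {
      ps <- hash_unit_interval(combination_id, seed)
      if (!is.null(overrides)) {
        pair <- ifelse(gene_a <= gene_b,
                       paste(gene_a, gene_b, sep = "|"),
                       paste(gene_b, gene_a, sep = "|"))
        hit <- match(pair, names(overrides))
        ps[!is.na(hit)] <- overrides[hit[!is.na(hit)]]
      }
      ps
    }
  )
}

#' Gene-pair-grouped cross-validation fold assignment
#'
#' Assigns combinations to `k` folds while keeping every combination of the
#' same gene pair in the same fold, so that per-fold model retraining never
#' sees the gene pairs it is evaluated on. Gene-pair groups are shuffled
#' with `seed` and then greedily assigned to the currently smallest fold;
#' the resulting fold-size spread is bounded by the largest group size.
#'
#' @param combinations data.frame with `combination_id`, `gene_a`, `gene_b`.
#' @param k number of folds (default 10).
#' @param seed integer shuffle seed.
#' @return Named integer vector: `combination_id` to fold label in `1..k`.
#' @export
assign_grouped_folds <- function(combinations, k = 10L, seed = 1L) {
  stopifnot(is.data.frame(combinations), k >= 2)
  pair <- ifelse(combinations$gene_a <= combinations$gene_b,
                 paste(combinations$gene_a, combinations$gene_b, sep = "|"),
                 paste(combinations$gene_b, combinations$gene_a, sep = "|"))
  groups <- split(combinations$combination_id, pair)
  if (length(groups) < k)
    stop("need at least k = ", k, " distinct gene pairs, got ",
         length(groups))
  order_idx <- withr::with_seed(seed, sample.int(length(groups)))
  groups <- groups[order_idx]
  fold_sizes <- integer(k)
  fold_of <- integer(0)
  ids <- character(0)
  for (g in groups) {
    target <- which.min(fold_sizes)
    fold_sizes[target] <- fold_sizes[target] + length(g)
    fold_of <- c(fold_of, rep(target, length(g)))
    ids <- c(ids, g)
  }
  out <- stats::setNames(fold_of, ids)
  out[combinations$combination_id]
}
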