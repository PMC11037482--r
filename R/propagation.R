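# Namespacing helpers: user-facing inputs are raw HPO ids ("HP:0000118") and
# gene symbols; graph nodes are namespaced by type. Ids that already carry a
# namespace prefix (any node type) pass through unchanged, so seed files may
# also list fully qualified node ids.
has_namespace <- function(ids) grepl("^[A-Z]+:", ids)
namespace_hpo <- function(ids) {
  ifelse(has_namespace(ids) & !startsWith(ids, "HP:"),
         ids, paste0("HPO:", sub("^HPO:", "", ids)))
}
namespace_gene <- function(ids) {
  ifelse(has_namespace(ids), ids, paste0("GENE:", ids))
}

#' Restart-walk configuration
#'
#' @param r restart probability in (0, 1]: at every step the walker teleports
#'   back to the seed distribution with probability `r` and follows an edge
#'   with probability `1 - r`. Small `r` lets the walk explore far from the
#'   seeds; large `r` keeps scores local. Default 0.3.
#' @param tol convergence tolerance on the L1 difference between successive
#'   iterates; default 1e-9.
#' @param max_iter iteration cap; default 1000. Convergence is geometric with
#'   ratio at most `1 - r`, so the cap is never near-binding at default `r`.
#' @return An object of class `rwr_config`.
#' @export
rwr_config <- function(r = 0.3, tol = 1e-9, max_iter = 1000L) {
  stopifnot(is.numeric(r), length(r) == 1, r > 0, r <= 1,
            is.numeric(tol), tol > 0, max_iter >= 1)
  structure(list(r = r, tol = tol, max_iter = as.integer(max_iter)),
            class = "rwr_config")
}

#' Build the seed set and initial probability vector
#'
#' Seeds are the graph nodes that encode what is known about the patient's
#' disease: HPO phenotype terms and/or genes from a clinical gene panel. All
#' resolved seeds receive equal initial probability summing to 1, which is
#' equivalent to starting the walker uniformly at random from any seed.
#' Requested ids absent from the walk index are reported as a warning; if no
#' id resolves, an error lists every unresolved id.
#'
#' @param tm a `transition_matrix` from [flatten_and_normalize()], or a named
#'   node index (node id to column position).
#' @param hpo_ids character vector of HPO term ids (`HP:...`), or NULL.
#' @param panel_genes character vector of gene symbols, or NULL.
#' @return An object of class `seed_set`: `requested_ids`, `resolved_ids`,
#'   `unresolved_ids`, and `p0` (numeric vector over the walk index).
#' @export
build_seed_vector <- function(tm, hpo_ids = NULL, panel_genes = NULL) {
  idx <- if (inherits(tm, "transition_matrix")) tm$node_index else tm
  stopifnot(!is.null(names(idx)))
  if ((is.null(hpo_ids) || length(hpo_ids) == 0) &&
      (is.null(panel_genes) || length(panel_genes) == 0))
    stop("at least one seed source (HPO terms or panel genes) is required")
  requested <- unique(c(
    if (length(hpo_ids) > 0) namespace_hpo(hpo_ids) else character(0),
    if (length(panel_genes) > 0) namespace_gene(panel_genes) else character(0)
  ))
  resolved <- requested[requested %in% names(idx)]
  unresolved <- setdiff(requested, resolved)
  if (length(resolved) == 0)
    stop("no requested seed resolves to a graph node; unresolved ids: ",
         paste(unresolved, collapse = ", "))
  if (length(unresolved) > 0)
    warning(length(unresolved), " seed id(s) not present in the graph: ",
            paste(unresolved, collapse = ", "))
  p0 <- numeric(length(idx))
  names(p0) <- names(idx)
  p0[resolved] <- 1 / length(resolved)
  structure(list(requested_ids = requested, resolved_ids = resolved,
                 unresolved_ids = unresolved, p0 = p0),
            class = "seed_set")
}

#' Random walk with restart over the flattened graph
#'
#' Iterates the propagation update
#' \deqn{p^{t+1} = (1 - r)\, W p^t + r\, p^0}
#' from the seed distribution `p0` until the L1 change between successive
#' iterates falls below `tol` (or `max_iter` is hit, which flags the result
#' and warns but is not fatal). Because `W` is column-stochastic and `p0`
#' sums to one, every iterate is a probability vector; the fixed point scores
#' each node's proximity to the seed set, mixing local and global topology.
#'
#' @param tm a `transition_matrix` from [flatten_and_normalize()].
#' @param seeds a `seed_set` from [build_seed_vector()].
#' @param cfg an [rwr_config()].
#' @return An object of class `node_scores`: `scores` (named numeric over the
#'   walk index), `iterations_used`, `converged`.
#' @export
random_walk_restart <- function(tm, seeds, cfg = rwr_config()) {
  stopifnot(inherits(tm, "transition_matrix"),
            inherits(seeds, "seed_set"),
            inherits(cfg, "rwr_config"))
  p0 <- seeds$p0
  if (length(p0) != ncol(tm$W))
    stop("seed vector length does not match the transition matrix")
  r <- cfg$r
  p <- p0
  converged <- FALSE
  iter <- 0L
  if (r == 1) {
    # walk degenerates to pure restart: fixed point is p0 itself
    p <- p0
    converged <- TRUE
    iter <- 1L
  } else {
    for (iter in seq_len(cfg$max_iter)) {
      p_new <- as.numeric((1 - r) * (tm$W %*% p)) + r * p0
      delta <- sum(abs(p_new - p))
      p <- p_new
      if (delta < cfg$tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    warning("random walk did not converge within ", cfg$max_iter,
            " iterations (returning last iterate)")
  names(p) <- names(seeds$p0)
  structure(list(scores = p, iterations_used = iter, converged = converged),
            class = "node_scores")
}

#' @export
print.node_scores <- function(x, ...) {
  cat("node_scores over", length(x$scores), "nodes;",
      x$iterations_used, "iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Disease-relevance score of a gene pair
#'
#' The pair score is the arithmetic mean of the two genes' walk scores. A
#' gene absent from the walk index (not in the graph, or isolated) carries no
#' disease-relevance evidence and contributes 0, so whole-exome runs never
#' abort on unannotated genes.
#'
#' @param scores a `node_scores` object from [random_walk_restart()].
#' @param gene_a,gene_b gene symbols (raw or `GENE:`-namespaced); vectorized.
#' @return Numeric vector of non-negative pair scores.
#' @export
pair_disease_score <- function(scores, gene_a, gene_b) {
  stopifnot(inherits(scores, "node_scores"))
  ga <- namespace_gene(as.character(gene_a))
  gb <- namespace_gene(as.character(gene_b))
  sa <- scores$scores[ga]
  sb <- scores$scores[gb]
  sa[is.na(sa)] <- 0
  sb[is.na(sb)] <- 0
  unname((sa + sb) / 2)
}
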