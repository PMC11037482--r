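#' @importFrom methods is
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table
NULL

# Canonical undirected edge orientation: endpoints sorted bytewise so that
# (u, v) and (v, u) collapse to one record.
canonical_edges <- function(source_id, target_id) {
  swap <- source_id > target_id
  a <- ifelse(swap, target_id, source_id)
  b <- ifelse(swap, source_id, target_id)
  data.frame(source_id = a, target_id = b, stringsAsFactors = FALSE)
}

#' Construct a heterogeneous knowledge graph
#'
#' A `hetero_graph` is a typed, layered, unweighted node/edge store: every
#' node carries a type (`gene`, `hpo`, `disease`, ...) and every undirected
#' edge belongs to a named layer (e.g. a protein-protein interaction layer or
#' an HPO-to-gene annotation layer). Node identifiers are namespaced by type
#' (`GENE:BRCA1`, `HPO:HP:0000118`) so gene symbols cannot collide with
#' ontology identifiers.
#'
#' Duplicate edges within a layer are collapsed; the same node pair connected
#' in several layers is kept as distinct edge records (the layer field is
#' provenance; propagation flattens layers, see
#' [flatten_and_normalize()]). Self loops are rejected.
#'
#' @param nodes data.frame with columns `node_id`, `node_type`.
#' @param edges data.frame with columns `source_id`, `target_id`, `layer`.
#' @return An object of class `hetero_graph` with elements `nodes`, `edges`
#'   and `layer_names`.
#' @export
hetero_graph <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  need_n <- c("node_id", "node_type")
  need_e <- c("source_id", "target_id", "layer")
  if (!all(need_n %in% names(nodes)))
    stop("node table must have columns: ", paste(need_n, collapse = ", "))
  if (!all(need_e %in% names(edges)))
    stop("edge list must have columns: ", paste(need_e, collapse = ", "))
  nodes <- data.frame(node_id = as.character(nodes$node_id),
                      node_type = as.character(nodes$node_type),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$node_id)) {
    dup <- unique(nodes$node_id[duplicated(nodes$node_id)])
    stop("duplicate node ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  edges <- data.frame(source_id = as.character(edges$source_id),
                      target_id = as.character(edges$target_id),
                      layer = as.character(edges$layer),
                      stringsAsFactors = FALSE)
  if (any(edges$source_id == edges$target_id))
    stop("self-loop edges are not allowed")
  dangling <- setdiff(c(edges$source_id, edges$target_id), nodes$node_id)
  if (length(dangling) > 0)
    stop("edge endpoints not declared in node table: ",
         paste(sort(unique(dangling)), collapse = ", "))
  ce <- canonical_edges(edges$source_id, edges$target_id)
  edges$source_id <- ce$source_id
  edges$target_id <- ce$target_id
  # collapse duplicates within a layer, keep parallel edges across layers
  key <- paste(edges$source_id, edges$target_id, edges$layer, sep = "\t")
  edges <- edges[!duplicated(key), , drop = FALSE]
  ord <- order(edges$source_id, edges$target_id, edges$layer, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  structure(
    list(nodes = nodes, edges = edges,
         layer_names = sort(unique(edges$layer), method = "radix")),
    class = "hetero_graph"
  )
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat("hetero_graph:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edge records,", length(x$layer_names), "layers\n")
  tt <- table(x$nodes$node_type)
  cat("  node types:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Load a heterogeneous graph from edge-list and node-table TSV files
#'
#' The on-disk format mirrors the edge-list export of public knowledge graphs
#' such as BOCK: a node table (`node_id`, `node_type`) and an edge list
#' (`source_id`, `target_id`, `layer`), both tab-separated with a header.
#' See [bock_converter_notes()] for the mapping from the published export.
#'
#' @param edge_list_path path to the edge-list TSV.
#' @param node_table_path path to the node-table TSV.
#' @return A validated [hetero_graph()].
#' @export
load_graph <- function(edge_list_path, node_table_path) {
  for (p in c(edge_list_path, node_table_path))
    if (!file.exists(p)) stop("file not found: ", p)
  nodes <- read_tsv_checked(node_table_path, c("node_id", "node_type"))
  edges <- read_tsv_checked(edge_list_path, c("source_id", "target_id", "layer"))
  hetero_graph(nodes, edges)
}

# TSV reader that reports the 1-based file line of a malformed row.
read_tsv_checked <- function(path, required_cols) {
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      colClasses = "character", quote = "",
                      comment.char = "", na.strings = NULL),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0)
    stop(path, ": missing required columns: ",
         paste(missing, collapse = ", "))
  bad <- which(apply(df[required_cols] == "" | is.na(df[required_cols]), 1, any))
  if (length(bad) > 0)
    stop(path, ": malformed row(s) with empty fields at line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  df
}

#' Remove all nodes of one type from a graph
#'
#' Used to drop node types that would leak label information into the
#' propagation, e.g. curated oligogenic-interaction nodes whose links to
#' genes and diseases encode exactly the associations the prioritizer is
#' later evaluated on. Every edge incident to a removed node is removed as
#' well; removing an absent type is a no-op.
#'
#' @param graph a [hetero_graph()].
#' @param node_type character scalar, the type to remove.
#' @return A `hetero_graph` without any node of `node_type`.
#' @export
remove_node_type <- function(graph, node_type) {
  stopifnot(inherits(graph, "hetero_graph"), is.character(node_type))
  drop_ids <- graph$nodes$node_id[graph$nodes$node_type == node_type]
  if (length(drop_ids) == 0) return(graph)
  nodes <- graph$nodes[!(graph$nodes$node_id %in% drop_ids), , drop = FALSE]
  keep <- !(graph$edges$source_id %in% drop_ids |
              graph$edges$target_id %in% drop_ids)
  edges <- graph$edges[keep, , drop = FALSE]
  hetero_graph(nodes, edges)
}

#' Flatten graph layers and build the column-normalized transition matrix
#'
#' All layers are flattened into one unweighted simple graph: an edge exists
#' between two nodes iff at least one layer connects them, and edge weights
#' (if any existed upstream) are ignored. The adjacency matrix of the
#' flattened graph is then column-normalized so each column of `W` is the
#' uniform distribution over a node's neighbours. Nodes left isolated after
#' flattening carry no probability flow and are dropped from the matrix
#' index; they are reported in the result and later score zero.
#'
#' @param graph a [hetero_graph()].
#' @return An object of class `transition_matrix` with elements:
#'   `W` (sparse `dgCMatrix`, column-stochastic), `node_index` (named integer
#'   vector, node id to column), `node_type` (named character vector over the
#'   index), `dropped` (character vector of isolated node ids).
#' @export
flatten_and_normalize <- function(graph) {
  stopifnot(inherits(graph, "hetero_graph"))
  if (nrow(graph$edges) == 0)
    stop("graph has no edges after flattening; cannot build transition matrix")
  # flatten: unique canonical node pairs across layers
  key <- paste(graph$edges$source_id, graph$edges$target_id, sep = "\t")
  uniq <- !duplicated(key)
  a <- graph$edges$source_id[uniq]
  b <- graph$edges$target_id[uniq]
  connected <- sort(unique(c(a, b)), method = "radix")
  dropped <- setdiff(graph$nodes$node_id, connected)
  idx <- stats::setNames(seq_along(connected), connected)
  i <- c(idx[a], idx[b])
  j <- c(idx[b], idx[a])
  A <- Matrix::sparseMatrix(i = unname(i), j = unname(j), x = 1,
                            dims = c(length(connected), length(connected)))
  deg <- Matrix::colSums(A)
  W <- A %*% Matrix::Diagonal(x = 1 / deg)
  W <- methods::as(W, "CsparseMatrix")
  dimnames(W) <- list(connected, connected)
  ntype <- stats::setNames(graph$nodes$node_type, graph$nodes$node_id)[connected]
  structure(
    list(W = W, node_index = idx, node_type = ntype,
         dropped = sort(dropped, method = "radix")),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("transition_matrix:", length(x$node_index), "nodes in walk index,",
      length(x$dropped), "isolated nodes dropped\n")
  invisible(x)
}

#' Write a graph to edge-list and node-table TSV files
#'
#' @param graph a [hetero_graph()].
#' @param edge_list_path,node_table_path output paths.
#' @return Invisibly, the input graph.
#' @export
write_graph <- function(graph, edge_list_path, node_table_path) {
  stopifnot(inherits(graph, "hetero_graph"))
  nodes <- graph$nodes[order(graph$nodes$node_id, method = "radix"), ,
                       drop = FALSE]
  utils::write.table(nodes, node_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(graph$edges, edge_list_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(graph)
}

#' Mapping notes for the published BOCK knowledge-graph export
#'
#' The package consumes any multiplex-heterogeneous graph expressed as a
#' node-table/edge-list TSV pair. To use the published BOCK export
#' (Zenodo record 7185679) as a drop-in graph: map each node to one row of
#' the node table, namespacing the identifier with its type
#' (`GENE:<symbol>`, `HPO:<hpo id>`, `DISEASE:<disease id>`,
#' `OLIGOGENIC:<combination id>`); map each edge to one edge-list row whose
#' `layer` is the source layer name of the export; drop edge weights and
#' directions. Before propagation, remove the curated oligogenic-interaction
#' nodes with `remove_node_type(graph, "oligogenic")` so the walk cannot see
#' the associations being evaluated.
#'
#' @return A character vector of the expected column headers, invisibly.
#' @export
bock_converter_notes <- function() {
  invisible(c(node_table = "node_id\tnode_type",
              edge_list = "source_id\ttarget_id\tlayer"))
}
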