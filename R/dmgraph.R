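#' Directed multigraphs with typed, multiplicity-weighted edges
#'
#' `dmgraph()` builds the package's universal substrate: a directed multigraph
#' whose edges carry a type label (in enzyme networks, the linking metabolite)
#' and a positive integer multiplicity. Parallel edges with identical
#' (source, target, type) are always merged by summing multiplicities, so two
#' representations of the same multigraph compare `identical()`.
#'
#' @param edges data.frame with columns `source`, `target` and optionally
#'   `edge_type` (default `"metabolic"`) and `multiplicity` (default 1), or
#'   NULL for an edgeless graph.
#' @param nodes character vector of node identifiers; endpoints of `edges` are
#'   added automatically. Stored sorted lexicographically.
#' @return An object of class `dmgraph`: a list with `nodes` (sorted character
#'   vector) and `edges` (canonical data.frame).
#' @examples
#' g <- dmgraph(data.frame(source = c("A", "A"), target = c("B", "B")))
#' g$edges$multiplicity  # 2: parallel records merged
#' @export
dmgraph <- function(edges = NULL, nodes = character()) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        edge_type = character(), multiplicity = integer(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0 && !all(c("source", "target") %in% names(edges)))
    stop("edge table must have 'source' and 'target' columns")
  if (is.null(edges$edge_type)) edges$edge_type <- rep("metabolic", nrow(edges))
  if (is.null(edges$multiplicity)) edges$multiplicity <- rep(1, nrow(edges))
  edges <- edges[c("source", "target", "edge_type", "multiplicity")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$edge_type <- as.character(edges$edge_type)
  edges$multiplicity <- as.numeric(edges$multiplicity)
  if (any(is.na(edges$multiplicity)) || any(edges$multiplicity < 1) ||
      any(edges$multiplicity != round(edges$multiplicity))) {
    bad <- which(is.na(edges$multiplicity) | edges$multiplicity < 1 |
                   edges$multiplicity != round(edges$multiplicity))[1]
    stop(sprintf("invalid multiplicity in edge row %d (%s -> %s): must be a positive integer",
                 bad, edges$source[bad], edges$target[bad]))
  }
  nodes <- sort(unique(c(as.character(nodes), edges$source, edges$target)))
  g <- structure(list(nodes = nodes, edges = edges), class = "dmgraph")
  canonicalize_graph(g)
}

#' Canonicalize a directed multigraph
#'
#' Merges parallel records of identical (source, target, edge_type) by summing
#' multiplicity and sorts edges lexicographically; idempotent.
#' @param g a `dmgraph`
#' @return the canonical `dmgraph`
#' @export
canonicalize_graph <- function(g) {
  stopifnot(inherits(g, "dmgraph"))
  e <- g$edges
  if (nrow(e) > 0) {
    key <- paste(e$source, e$target, e$edge_type, sep = "\r")
    mult <- tapply(e$multiplicity, key, sum)
    parts <- strsplit(names(mult), "\r", fixed = TRUE)
    e <- data.frame(source = vapply(parts, `[`, "", 1),
                    target = vapply(parts, `[`, "", 2),
                    edge_type = vapply(parts, `[`, "", 3),
                    multiplicity = as.numeric(mult),
                    stringsAsFactors = FALSE)
    e <- e[order(e$source, e$target, e$edge_type), , drop = FALSE]
    rownames(e) <- NULL
  }
  g$edges <- e
  g$nodes <- sort(unique(c(g$nodes, e$source, e$target)))
  g
}

#' @export
print.dmgraph <- function(x, ...) {
  cat(sprintf("dmgraph: %d nodes, %d typed edges (total multiplicity %d)\n",
              length(x$nodes), nrow(x$edges), as.integer(sum(x$edges$multiplicity))))
  invisible(x)
}

n_nodes <- function(g) length(g$nodes)

#' Number of edges counted with multiplicity
#' @param g a `dmgraph`
#' @return total edge multiplicity
#' @export
edge_count <- function(g) sum(g$edges$multiplicity)

#' Merge typed parallel edges
#'
#' Collapses edges that differ only in type into a single untyped record whose
#' multiplicity is the sum; used when metabolite identity should be ignored
#' during coloring.
#' @param g a `dmgraph`
#' @return a `dmgraph` with a single edge type
#' @export
collapse_parallel_edges <- function(g) {
  e <- g$edges
  e$edge_type <- rep("collapsed", nrow(e))
  dmgraph(e, nodes = g$nodes)
}

## adjacency matrix A[u, v] = multiplicity of edge u -> v (path counting runs
## occ_{i+1} = A %*% occ_i over this orientation)
adjacency_matrix <- function(g) {
  n <- length(g$nodes)
  A <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  e <- g$edges
  if (nrow(e) > 0) A[cbind(e$source, e$target)] <- e$multiplicity
  A
}

## simple logical adjacency, multiplicities collapsed
simple_adjacency <- function(g) adjacency_matrix(g) > 0

as_igraph <- function(g) {
  e <- g$edges
  igraph::graph_from_data_frame(
    data.frame(from = e$source, to = e$target,
               edge_type = e$edge_type, multiplicity = e$multiplicity,
               stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = g$nodes))
}

#' Induced subgraph on a node subset
#' @param g a `dmgraph`
#' @param nodes node identifiers to keep
#' @return the induced `dmgraph` (all edges of `g` among `nodes`)
#' @export
induced_subgraph_dm <- function(g, nodes) {
  nodes <- intersect(g$nodes, nodes)
  e <- g$edges
  e <- e[e$source %in% nodes & e$target %in% nodes, , drop = FALSE]
  dmgraph(e, nodes = nodes)
}

#' Read a directed multigraph from an edge-list table
#'
#' Reads TSV/CSV with at least `source` and `target` columns; `edge_type` and
#' `multiplicity` columns are optional. Lines starting with `#` are ignored.
#'
#' @param path file path
#' @param sep field separator; `"\t"` default, use `","` for CSV
#' @param dialect optional named character vector remapping column names,
#'   e.g. `c(source = "from", target = "to")`
#' @return a canonical `dmgraph`
#' @export
read_edge_list <- function(path, sep = "\t", dialect = NULL) {
  d <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                      stringsAsFactors = FALSE, quote = ""),
    error = function(e) stop(sprintf("cannot parse edge list '%s': %s", path,
                                     conditionMessage(e))))
  if (nrow(d) == 0 && ncol(d) < 2)
    stop(sprintf("edge list '%s' is empty or lacks a header", path))
  if (!is.null(dialect)) {
    for (std in names(dialect)) names(d)[names(d) == dialect[[std]]] <- std
  }
  if (!all(c("source", "target") %in% names(d)))
    stop(sprintf("edge list '%s' is missing required columns: %s", path,
                 paste(setdiff(c("source", "target"), names(d)), collapse = ", ")))
  dmgraph(d)
}

#' Write a directed multigraph
#'
#' `edge_list_tsv` round-trips through [read_edge_list()]; `graphml` and `dot`
#' are export formats for visualization with multiplicity and edge type stored
#' as edge attributes.
#' @param g a `dmgraph`
#' @param path output path
#' @param format one of `"edge_list_tsv"`, `"graphml"`, `"dot"`
#' @return invisibly, the path
#' @export
write_graph_dm <- function(g, path, format = c("edge_list_tsv", "graphml", "dot")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "dmgraph"))
  if (format == "edge_list_tsv") {
    e <- g$edges
    e$multiplicity <- as.integer(e$multiplicity)
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ig <- as_igraph(g)
    igraph::write_graph(ig, path, format = format)
  }
  invisible(path)
}

#' Strongly connected components
#'
#' @param g a `dmgraph`
#' @return list of node-set character vectors, ordered by decreasing size then
#'   by lexicographic minimum member; each set sorted.
#' @export
strongly_connected_components <- function(g) {
  if (length(g$nodes) == 0) return(list())
  comp <- igraph::components(as_igraph(g), mode = "strong")
  sets <- split(g$nodes, comp$membership[g$nodes])
  sets <- lapply(unname(sets), sort)
  mins <- vapply(sets, `[`, "", 1)
  sizes <- vapply(sets, length, 0L)
  sets[order(-sizes, mins)]
}

#' Node-role decomposition of a directed network
#'
#' Partitions nodes into SCC members (nodes on cycles: components of size >= 2,
#' or singletons carrying a self-loop), connectors (non-SCC nodes sending at
#' least one edge into an SCC) and the k_out shell (everything else: nodes that
#' only receive from the SCCs or from other shell nodes).
#'
#' @param g a `dmgraph`
#' @return data.frame with columns `node`, `role` (factor-free character:
#'   `scc_member`, `connector`, `kout_shell`) and `scc_id` (integer or NA)
#' @export
classify_node_roles <- function(g) {
  nodes <- g$nodes
  sccs <- strongly_connected_components(g)
  selfloop <- unique(g$edges$source[g$edges$source == g$edges$target])
  role <- stats::setNames(rep("kout_shell", length(nodes)), nodes)
  scc_id <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (s in sccs) {
    if (length(s) >= 2 || s[1] %in% selfloop) {
      k <- k + 1L
      role[s] <- "scc_member"
      scc_id[s] <- k
    }
  }
  scc_nodes <- names(role)[role == "scc_member"]
  e <- g$edges
  into_scc <- unique(e$source[e$target %in% scc_nodes])
  role[setdiff(intersect(into_scc, nodes), scc_nodes)] <- "connector"
  data.frame(node = nodes, role = unname(role[nodes]),
             scc_id = unname(scc_id[nodes]), stringsAsFactors = FALSE)
}
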