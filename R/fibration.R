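## In-profile refinement keys: one record per unit of multiplicity, so that a
## node fed twice by color c through one multiplicity-2 edge and a node fed by
## two distinct color-c sources are (correctly) indistinguishable.
in_profile_keys <- function(g, color) {
  e <- g$edges
  if (nrow(e) == 0) return(stats::setNames(rep("", length(g$nodes)), g$nodes))
  rec <- paste(color[e$source], e$edge_type, sep = "\r")
  rec <- rep(rec, e$multiplicity)
  tgt <- rep(e$target, e$multiplicity)
  prof <- vapply(split(rec, factor(tgt, levels = g$nodes)),
                 function(k) paste(sort(k), collapse = "\n"), character(1))
  prof
}

#' Minimal balanced coloring of a directed multigraph
#'
#' Computes the coarsest balanced coloring: starting from a single color, color
#' classes are iteratively split by each node's in-profile — the multiset of
#' (in-neighbor color, edge type) pairs counted with edge multiplicity — until
#' a fixpoint is reached (at most |V| rounds). Nodes sharing a color then have
#' isomorphic input trees; the color classes are the fibers of the minimal
#' symmetry fibration.
#'
#' @param g a `dmgraph`
#' @param collapse_parallel if TRUE, typed parallel edges are merged into a
#'   single multiplicity before refinement (metabolite identity ignored)
#' @return named integer vector node -> color id; ids are assigned by first
#'   occurrence over lexicographically sorted nodes, so the result is
#'   reproducible byte-for-byte
#' @export
minimal_balanced_coloring <- function(g, collapse_parallel = FALSE) {
  stopifnot(inherits(g, "dmgraph"))
  if (collapse_parallel) g <- collapse_parallel_edges(g)
  nodes <- g$nodes
  if (length(nodes) == 0) return(stats::setNames(integer(), character()))
  color <- stats::setNames(rep(1L, length(nodes)), nodes)
  for (round in seq_len(length(nodes) + 1L)) {
    prof <- in_profile_keys(g, color)
    key <- paste(color[nodes], prof[nodes], sep = "|")
    newcol <- stats::setNames(match(key, unique(key)), nodes)
    if (length(unique(newcol)) == length(unique(color))) {
      color <- newcol
      break
    }
    color <- newcol
  }
  stopifnot(length(unique(color)) ==
              length(unique(paste(color[nodes], in_profile_keys(g, color)[nodes]))))
  color
}

#' Fiber partition from a balanced coloring
#'
#' @param coloring named vector node -> color (as from
#'   [minimal_balanced_coloring()]); rejected if not balanced on `g`
#' @param g the `dmgraph` the coloring refers to (used for the balance check)
#' @return a `fiber_partition`: list with `fibers` (list of sorted node sets,
#'   ordered by decreasing size then lexicographic minimum member) and
#'   `trivial` (logical flag per fiber: singleton)
#' @export
fibers <- function(coloring, g = NULL) {
  if (!is.null(g)) {
    p <- partition_from_membership(coloring)
    chk <- is_balanced(g, p)
    if (!chk$balanced)
      stop(sprintf("coloring is not balanced: witness pair (%s, %s)",
                   chk$witness[1], chk$witness[2]))
  }
  partition_from_membership(coloring)
}

partition_from_membership <- function(membership) {
  sets <- lapply(unname(split(names(membership), membership)), sort)
  mins <- vapply(sets, `[`, "", 1)
  sizes <- vapply(sets, length, 0L)
  sets <- sets[order(-sizes, mins)]
  structure(list(fibers = sets,
                 trivial = vapply(sets, length, 0L) == 1L),
            class = "fiber_partition")
}

#' @export
print.fiber_partition <- function(x, ...) {
  cat(sprintf("fiber partition: %d fibers (%d nontrivial)\n",
              length(x$fibers), sum(!x$trivial)))
  for (i in which(!x$trivial))
    cat(sprintf("  [%d] {%s}\n", i, paste(x$fibers[[i]], collapse = ", ")))
  invisible(x)
}

#' Membership vector of a fiber partition
#' @param p a `fiber_partition` (or `fibration`)
#' @return named integer vector node -> fiber index
#' @export
fiber_membership <- function(p) {
  if (inherits(p, "fibration")) p <- p$partition
  m <- integer(0)
  for (i in seq_along(p$fibers))
    m <- c(m, stats::setNames(rep(i, length(p$fibers[[i]])), p$fibers[[i]]))
  m[sort(names(m))]
}

#' Check whether a partition is balanced on a graph
#'
#' Two same-fiber nodes must receive identical multisets of (source fiber,
#' edge type), counted with multiplicity. Used as the independent oracle for
#' the coloring refinement and as the precondition of the quotient.
#' @param g a `dmgraph`
#' @param p a `fiber_partition`, a list of node sets, or a named membership
#'   vector
#' @return list with `balanced` (logical) and, when FALSE, `witness`: the
#'   first violating node pair
#' @export
is_balanced <- function(g, p) {
  memb <- as_membership(p)
  if (!setequal(names(memb), g$nodes))
    stop("partition does not cover the node set of the graph")
  prof <- in_profile_keys(g, stats::setNames(memb[g$nodes], g$nodes))
  for (cls in split(g$nodes, memb[g$nodes])) {
    if (length(cls) < 2) next
    ref <- prof[[cls[1]]]
    for (v in cls[-1]) if (!identical(prof[[v]], ref))
      return(list(balanced = FALSE, witness = c(cls[1], v)))
  }
  list(balanced = TRUE, witness = NULL)
}

as_membership <- function(p) {
  if (inherits(p, "fibration")) p <- p$partition
  if (inherits(p, "fiber_partition")) return(fiber_membership(p))
  if (is.list(p)) {
    m <- integer(0)
    for (i in seq_along(p))
      m <- c(m, stats::setNames(rep(i, length(p[[i]])), p[[i]]))
    return(m)
  }
  stats::setNames(as.integer(factor(p)), names(p))
}

#' Quotient (base) graph of a balanced partition
#'
#' Collapses every fiber to its lexicographically minimal member. The base
#' in-edges of a fiber are the in-edges of that representative with sources
#' mapped through phi; balance makes the member choice immaterial (asserted),
#' which is exactly the lifting property: every edge into an image node lifts
#' uniquely to an edge into each preimage node.
#'
#' @param g a `dmgraph`
#' @param p a balanced partition of `g` (any form accepted by [is_balanced()])
#' @return list of class `base_graph`: `graph` (the base `dmgraph`), `phi`
#'   (named map original node -> base node)
#' @export
build_base <- function(g, p) {
  memb <- as_membership(p)
  chk <- is_balanced(g, p)
  if (!chk$balanced)
    stop(sprintf("partition is not balanced: witness pair (%s, %s)",
                 chk$witness[1], chk$witness[2]))
  reps <- vapply(split(names(memb), memb), function(s) min(s), "")
  phi <- stats::setNames(reps[as.character(memb)], names(memb))
  e <- g$edges
  keep <- e$target %in% reps
  be <- e[keep, , drop = FALSE]
  if (nrow(be) > 0) {
    be$source <- unname(phi[be$source])
    ## target already a representative; parallel lifted edges merge by sum
  }
  base <- dmgraph(be, nodes = unname(reps))
  structure(list(graph = base, phi = phi), class = "base_graph")
}

#' Fibration-symmetry analysis of a directed network
#'
#' The package's central estimator: computes the minimal balanced coloring of
#' `g`, the resulting fiber partition, and the quotient base graph, i.e. the
#' maximal compression of the network that preserves every node's input tree
#' (and hence, under admissible dynamics, the synchronization pattern).
#'
#' @param g a `dmgraph` (see [dmgraph()], [read_edge_list()],
#'   [build_enzyme_network()])
#' @param collapse_parallel merge typed parallel edges before coloring
#' @return object of class `fibration`: list with `graph`, `coloring`,
#'   `partition` (a `fiber_partition`), `base` (a `base_graph`), and the call
#' @seealso [summary.fibration()], [building_blocks()], [branching_ratio()]
#' @examples
#' toy <- make_fig_toy()
#' fit <- fibration(toy$graph)
#' fit$partition$fibers  # {A,B}, {C,D}
#' @export
fibration <- function(g, collapse_parallel = FALSE) {
  stopifnot(inherits(g, "dmgraph"))
  col <- minimal_balanced_coloring(g, collapse_parallel = collapse_parallel)
  gg <- if (collapse_parallel) collapse_parallel_edges(g) else g
  part <- partition_from_membership(col)
  base <- if (length(g$nodes) > 0) build_base(gg, part) else
    structure(list(graph = dmgraph(), phi = character()), class = "base_graph")
  structure(list(graph = g, collapse_parallel = collapse_parallel,
                 coloring = col, partition = part, base = base,
                 call = match.call()),
            class = "fibration")
}

#' @export
print.fibration <- function(x, ...) {
  cat("Fibration symmetry analysis\n")
  cat(sprintf("  network: %d nodes, %d typed edges\n",
              length(x$graph$nodes), nrow(x$graph$edges)))
  cat(sprintf("  fibers: %d total, %d nontrivial; base: %d nodes, %d edges\n",
              length(x$partition$fibers), sum(!x$partition$trivial),
              length(x$base$graph$nodes), nrow(x$base$graph$edges)))
  invisible(x)
}

#' Summary of a fibration analysis
#'
#' Reports network size, node-role decomposition (SCC members, connectors,
#' k_out shell, with in-fiber counts), and the fiber size distribution.
#' @param object a `fibration`
#' @param ... unused
#' @return a `summary.fibration` list, printed as a small table
#' @export
summary.fibration <- function(object, ...) {
  roles <- classify_node_roles(object$graph)
  memb <- fiber_membership(object$partition)
  nontrivial_nodes <- unlist(object$partition$fibers[!object$partition$trivial])
  in_fiber <- roles$node %in% nontrivial_nodes
  tab <- t(vapply(c("scc_member", "connector", "kout_shell"), function(r) {
    sel <- roles$role == r
    c(nodes = sum(sel), in_fibers = sum(sel & in_fiber))
  }, c(nodes = 0, in_fibers = 0)))
  out <- list(n_nodes = length(object$graph$nodes),
              n_edges = nrow(object$graph$edges),
              total_multiplicity = sum(object$graph$edges$multiplicity),
              n_fibers = length(object$partition$fibers),
              n_nontrivial = sum(!object$partition$trivial),
              nodes_in_fibers = length(nontrivial_nodes),
              role_table = tab,
              fiber_sizes = vapply(object$partition$fibers, length, 0L),
              scc_sizes = vapply(strongly_connected_components(object$graph),
                                 length, 0L))
  class(out) <- "summary.fibration"
  out
}

#' @export
print.summary.fibration <- function(x, ...) {
  cat(sprintf("Nodes: %d  Edges: %d (multiplicity %d)\n", x$n_nodes, x$n_edges,
              as.integer(x$total_multiplicity)))
  cat(sprintf("Fibers: %d (%d nontrivial), covering %d nodes (%.1f%%)\n",
              x$n_fibers, x$n_nontrivial, x$nodes_in_fibers,
              if (x$n_nodes) 100 * x$nodes_in_fibers / x$n_nodes else 0))
  cat("Node roles (nodes / of which in nontrivial fibers):\n")
  print(x$role_table)
  invisible(x)
}

#' Plot a fibration analysis
#'
#' Draws the network with nodes colored by fiber (nontrivial fibers colored,
#' singletons grey).
#' @param x a `fibration`
#' @param ... passed to `plot.igraph`
#' @export
plot.fibration <- function(x, ...) {
  ig <- as_igraph(x$graph)
  memb <- fiber_membership(x$partition)
  nt <- which(!x$partition$trivial)
  pal <- grDevices::rainbow(max(1L, length(nt)))
  colv <- rep("grey85", length(x$graph$nodes))
  names(colv) <- x$graph$nodes
  for (i in seq_along(nt)) colv[x$partition$fibers[[nt[i]]]] <- pal[i]
  plot(ig, vertex.color = colv[igraph::V(ig)$name], edge.arrow.size = 0.4, ...)
  invisible(x)
}

#' Write / read a node partition as two-column TSV
#' @param p partition (any form accepted by [is_balanced()]) or `fibration`
#' @param path file path
#' @return `write_partition`: the path, invisibly; `read_partition`: a named
#'   membership vector
#' @export
write_partition <- function(p, path) {
  memb <- as_membership(p)
  utils::write.table(data.frame(node = names(memb), fiber_id = unname(memb)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop(sprintf("partition file '%s' needs two columns", path))
  stats::setNames(d[[2]], as.character(d[[1]]))
}

#' Per-fiber summary as JSON
#' @param fit a `fibration`
#' @param path output path
#' @return the path, invisibly
#' @export
write_fiber_summary <- function(fit, path) {
  p <- fit$partition
  out <- lapply(seq_along(p$fibers), function(i)
    list(fiber = i, members = p$fibers[[i]], size = length(p$fibers[[i]]),
         trivial = p$trivial[i]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
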