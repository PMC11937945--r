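## all nodes lying on any shortest directed path from `from` to `to`
## (unit edge lengths; multiplicity never affects path length)
shortest_path_nodes <- function(g, from, to) {
  if (from == to) return(character())
  adj_out <- split(g$edges$target, factor(g$edges$source, levels = g$nodes))
  adj_in <- split(g$edges$source, factor(g$edges$target, levels = g$nodes))
  dist_from <- bfs_dist(adj_out, from, g$nodes)
  if (is.infinite(dist_from[to])) return(character())
  dist_to <- bfs_dist(adj_in, to, g$nodes)
  d <- dist_from[to]
  g$nodes[dist_from + dist_to == d]
}

bfs_dist <- function(adj, start, nodes) {
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[start] <- 0
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    if (length(nxt) == 0) break
    dist[nxt] <- dist[frontier[1]] + 1
    frontier <- nxt
  }
  dist
}

#' Extract the fibration building block of a fiber
#'
#' A building block is the induced subgraph on the fiber, its regulators
#' (external in-neighbors), and — whenever a fiber node reaches a regulator in
#' the parent graph (the feedback case) — all nodes on all shortest such
#' paths. Regulators that themselves belong to a nontrivial fiber pull in that
#' entire fiber together with its own regulators and feedback paths,
#' recursively: the focal fiber's input tree contains the full input tree of a
#' regulating fiber, so the block must contain the structure that generates it
#' (this is what makes a feed-forward composite inherit the regulator fiber's
#' branching ratio).
#'
#' @param g a `dmgraph`
#' @param p a `fiber_partition` (or `fibration`)
#' @param fiber_id index into `p$fibers`, or a member node name
#' @return object of class `building_block`: list with `focal` (focal fiber
#'   node set), `regulators` (external in-neighbors of the focal fiber),
#'   `members`, `subgraph` (induced `dmgraph`), `ratio` (a `branching_ratio`
#'   for the lexicographically minimal focal node within the subgraph)
#' @export
extract_block <- function(g, p, fiber_id) {
  if (inherits(p, "fibration")) p <- p$partition
  if (is.character(fiber_id)) {
    hit <- which(vapply(p$fibers, function(s) fiber_id %in% s, TRUE))
    if (length(hit) == 0) stop(sprintf("no fiber contains node '%s'", fiber_id))
    fiber_id <- hit[1]
  }
  if (fiber_id < 1 || fiber_id > length(p$fibers))
    stop(sprintf("unknown fiber id %s", fiber_id))
  memb <- fiber_membership(p)
  nontrivial <- which(!p$trivial)
  focal <- p$fibers[[fiber_id]]
  members <- character()
  regulators_of_focal <- NULL
  queue <- fiber_id
  done <- integer()
  while (length(queue) > 0) {
    fid <- queue[1]; queue <- queue[-1]
    if (fid %in% done) next
    done <- c(done, fid)
    fib <- p$fibers[[fid]]
    members <- union(members, fib)
    e <- g$edges
    regs <- sort(setdiff(unique(e$source[e$target %in% fib]), fib))
    if (fid == fiber_id) regulators_of_focal <- regs
    members <- union(members, regs)
    ## feedback inclusion: shortest fiber -> regulator paths in the parent graph
    for (f in fib) for (r in regs)
      members <- union(members, shortest_path_nodes(g, f, r))
    ## recurse through regulator fibers
    for (r in regs) {
      rf <- memb[r]
      if (rf %in% nontrivial && !(rf %in% done)) queue <- c(queue, rf)
    }
  }
  sub <- induced_subgraph_dm(g, members)
  ratio <- branching_ratio(sub, min(focal))
  structure(list(focal = focal, regulators = regulators_of_focal,
                 members = sort(members), subgraph = sub, ratio = ratio),
            class = "building_block")
}

#' @export
print.building_block <- function(x, ...) {
  cat(sprintf("building block of fiber {%s}\n", paste(x$focal, collapse = ", ")))
  cat(sprintf("  regulators: %s\n",
              if (length(x$regulators)) paste(x$regulators, collapse = ", ") else "none"))
  cat(sprintf("  members: %d nodes; r = %.3f (%s)\n", length(x$members),
              x$ratio$value, x$ratio$status))
  invisible(x)
}

## nontrivial fibers of p having >= 2 member nodes inside the block
block_fibers <- function(b, p) {
  idx <- which(!p$trivial)
  idx[vapply(p$fibers[idx],
             function(s) sum(s %in% b$members) >= 2, TRUE)]
}

## TRUE iff some cycle of the block crosses >= 2 nontrivial fibers
has_interfiber_cycle <- function(b, p, fib_idx) {
  if (length(fib_idx) < 2) return(FALSE)
  memb <- fiber_membership(p)
  for (scc in strongly_connected_components(b$subgraph)) {
    if (length(scc) < 2) next
    if (length(unique(memb[scc][memb[scc] %in% fib_idx])) >= 2) return(TRUE)
  }
  FALSE
}

#' Classify a building block
#'
#' Blocks with an integer branching ratio are "fiber number" classes |n,l>:
#' n = 0 for finite (cycle-free) input trees, n = 1 for non-branching infinite
#' chains, n = k for k-ary trees; l counts external regulator classes. Blocks
#' with several integer-class fibers stacked feed-forward are Multi-Layer
#' (composed label such as "|0,3>+|0,1>"). A noninteger r with a single
#' nontrivial fiber is a simple Fibonacci; with two or more fibers it is a
#' Composite Feedforward Fibonacci (the regulating fiber is itself Fibonacci,
#' no inter-fiber cycle). Whenever a cycle of the block crosses two or more
#' fibers the block is a Composite Feedback Fibonacci — this test precedes the
#' integer dichotomy, because feedback composites can land on integer ratios.
#'
#' @param b a `building_block`
#' @param p the `fiber_partition` (or `fibration`) the block came from
#' @param integer_tol tolerance of the integer/noninteger r dichotomy
#' @return object of class `block_class`: list with `family`, `n`, `l`,
#'   `label`, `r`, `n_fibers_involved`
#' @export
classify_block <- function(b, p, integer_tol = 1e-6) {
  if (inherits(p, "fibration")) p <- p$partition
  r <- b$ratio$value
  fib_idx <- block_fibers(b, p)
  nfib <- length(fib_idx)
  memb <- fiber_membership(p)
  l <- length(unique(memb[b$regulators]))
  is_int <- abs(r - round(r)) <= integer_tol
  if (has_interfiber_cycle(b, p, fib_idx)) {
    family <- "composite_feedback_fibonacci"
    n <- NA_integer_
    label <- sprintf("composite feedback (r = %.2f, %d fibers)", r, nfib)
  } else if (!is_int) {
    if (nfib >= 2) {
      family <- "composite_feedforward_fibonacci"
      label <- sprintf("composite feedforward (r = %.2f, %d fibers)", r, nfib)
    } else {
      family <- "fibonacci_simple"
      label <- sprintf("Fibonacci (r = %.2f)", r)
    }
    n <- NA_integer_
  } else if (nfib >= 2) {
    family <- "multilayer"
    n <- NA_integer_
    label <- multilayer_label(b, p, fib_idx, integer_tol)
  } else {
    family <- "n_l"
    n <- as.integer(round(r))
    label <- sprintf("|%d,%d>", n, l)
  }
  structure(list(family = family, n = n, l = l, label = label, r = r,
                 n_fibers_involved = nfib),
            class = "block_class")
}

## ordered per-fiber |n,l> labels (regulating fibers first: topological order
## of the acyclic inter-fiber regulation), joined by "+"
multilayer_label <- function(b, p, fib_idx, integer_tol) {
  memb <- fiber_membership(p)
  e <- b$subgraph$edges
  labs <- character(0)
  depth_of <- vapply(fib_idx, function(fid) {
    ## longest regulation chain above this fiber inside the block
    fib <- intersect(p$fibers[[fid]], b$members)
    d <- 0L; cur <- fib
    repeat {
      regs <- setdiff(unique(e$source[e$target %in% cur]), cur)
      regs <- regs[memb[regs] %in% fib_idx & !(memb[regs] %in% memb[cur])]
      if (length(regs) == 0) break
      d <- d + 1L; cur <- regs
      if (d > length(fib_idx)) break
    }
    d
  }, 0L)
  for (fid in fib_idx[order(-depth_of)]) {
    fib <- intersect(p$fibers[[fid]], b$members)
    regs <- setdiff(unique(e$source[e$target %in% fib]), fib)
    rsub <- branching_ratio(b$subgraph, min(fib))
    nf <- as.integer(round(rsub$value))
    labs <- c(labs, sprintf("|%d,%d>", nf, length(unique(memb[regs]))))
  }
  paste(labs, collapse = "+")
}

#' @export
print.block_class <- function(x, ...) {
  cat(sprintf("%s  %s\n", x$family, x$label))
  invisible(x)
}

#' Fibonacci conditions of a building block
#'
#' A single-fiber block has a fractal (branching) input tree iff (i) a cycle
#' runs between the fiber and at least one regulator, and (ii) a self-loop
#' sits on a node of the fiber or of such a cycle.
#' @param b a `building_block`
#' @return list with logicals `has_fiber_regulator_cycle`,
#'   `has_self_loop_on_cycle`
#' @export
fibonacci_conditions <- function(b) {
  sccs <- strongly_connected_components(b$subgraph)
  cyc <- FALSE
  cyc_nodes <- b$focal
  for (s in sccs) {
    if (length(s) >= 2 && any(s %in% b$focal) && any(s %in% b$regulators)) {
      cyc <- TRUE
      cyc_nodes <- union(cyc_nodes, s)
    }
  }
  e <- b$subgraph$edges
  selfloops <- e$source[e$source == e$target]
  list(has_fiber_regulator_cycle = cyc,
       has_self_loop_on_cycle = any(selfloops %in% cyc_nodes))
}

#' Defining block of every fiber
#'
#' A fiber contained in several building blocks is assigned its member-count
#' smallest one — shortest cycles dominate the dynamics — with ties broken by
#' the lexicographically minimal block member. Larger containing blocks are
#' higher-order.
#'
#' @param blocks list of `building_block`
#' @param p the `fiber_partition` (or `fibration`)
#' @return integer vector: for each nontrivial fiber index of `p`, the index
#'   in `blocks` of its defining block (named by fiber index)
#' @export
assign_defining_blocks <- function(blocks, p) {
  if (inherits(p, "fibration")) p <- p$partition
  nt <- which(!p$trivial)
  out <- stats::setNames(integer(length(nt)), nt)
  for (k in seq_along(nt)) {
    fib <- p$fibers[[nt[k]]]
    containing <- which(vapply(blocks, function(b) all(fib %in% b$members), TRUE))
    if (length(containing) == 0) { out[k] <- NA_integer_; next }
    sizes <- vapply(blocks[containing], function(b) length(b$members), 0L)
    mins <- vapply(blocks[containing], function(b) min(b$members), "")
    out[k] <- containing[order(sizes, mins)][1]
  }
  out
}

#' All building blocks of a fibration analysis
#'
#' Extracts and classifies the building block of every nontrivial fiber and
#' assigns defining blocks.
#' @param fit a `fibration`
#' @param integer_tol passed to [classify_block()]
#' @return data.frame with one row per nontrivial fiber: fiber index, members,
#'   regulators, r, family, label, defining flag; the blocks themselves are
#'   attached as attribute `"blocks"`
#' @export
building_blocks <- function(fit, integer_tol = 1e-6) {
  stopifnot(inherits(fit, "fibration"))
  p <- fit$partition
  nt <- which(!p$trivial)
  blocks <- lapply(nt, function(i) extract_block(fit$graph, p, i))
  classes <- lapply(blocks, classify_block, p = p, integer_tol = integer_tol)
  defining <- assign_defining_blocks(blocks, p)
  d <- data.frame(
    fiber = nt,
    fiber_members = vapply(nt, function(i) paste(p$fibers[[i]], collapse = ","), ""),
    n_members = vapply(blocks, function(b) length(b$members), 0L),
    regulators = vapply(blocks, function(b) paste(b$regulators, collapse = ","), ""),
    r = vapply(blocks, function(b) b$ratio$value, 0),
    status = vapply(blocks, function(b) b$ratio$status, ""),
    family = vapply(classes, function(cl) cl$family, ""),
    label = vapply(classes, function(cl) cl$label, ""),
    defining_block = unname(defining),
    stringsAsFactors = FALSE)
  attr(d, "blocks") <- blocks
  d
}

#' Block report as JSON
#' @param fit a `fibration`
#' @param path output path
#' @param integer_tol passed to [classify_block()]
#' @return the path, invisibly
#' @export
write_block_report <- function(fit, path, integer_tol = 1e-6) {
  d <- building_blocks(fit, integer_tol)
  blocks <- attr(d, "blocks")
  out <- lapply(seq_len(nrow(d)), function(i)
    list(fiber = d$fiber[i],
         members = blocks[[i]]$members,
         regulators = blocks[[i]]$regulators,
         r = d$r[i], status = d$status[i],
         family = d$family[i], label = d$label[i],
         defining = d$defining_block[i] == i))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
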