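#' Construct a block realizing a prescribed layer-count recurrence
#'
#' Each cycle of length d through a node contributes a term a_{i-d} to the
#' recurrence obeyed by its input-tree layer counts, and n parallel cycles of
#' the same length contribute n a_{i-d}. This generator realizes any list of
#' terms (d, n): a self-loop of multiplicity n for d = 1, and for d >= 2 a
#' directed cycle through d-1 fresh nodes whose closing edge into the root
#' carries multiplicity n. The root's layer sequence then satisfies
#' a_i = sum_d n_d a_{i-d}.
#'
#' @param cycle_terms list of `c(d, n)` pairs (or a 2-column matrix): cycle
#'   length d >= 1, coefficient n >= 1
#' @return list with `graph` (a `dmgraph`) and `root` (node id `"root"`)
#' @examples
#' fb <- make_recurrence_block(list(c(1, 1), c(2, 1)))  # golden-ratio block
#' @export
make_recurrence_block <- function(cycle_terms) {
  if (is.matrix(cycle_terms)) cycle_terms <- split(cycle_terms, row(cycle_terms))
  if (length(cycle_terms) == 0) stop("at least one cycle term is required")
  src <- character(); tgt <- character(); mult <- numeric()
  for (k in seq_along(cycle_terms)) {
    term <- cycle_terms[[k]]
    d <- term[1]; n <- term[2]
    if (d < 1 || n < 1 || d != round(d) || n != round(n))
      stop("cycle terms require integer length d >= 1 and coefficient n >= 1")
    if (d == 1) {
      src <- c(src, "root"); tgt <- c(tgt, "root"); mult <- c(mult, n)
    } else {
      chain <- sprintf("c%d_%d", k, seq_len(d - 1))
      path <- c("root", chain, "root")
      for (i in seq_len(d)) {
        src <- c(src, path[i]); tgt <- c(tgt, path[i + 1])
        mult <- c(mult, if (i == d) n else 1)
      }
    }
  }
  g <- dmgraph(data.frame(source = src, target = tgt, edge_type = "metabolic",
                          multiplicity = mult, stringsAsFactors = FALSE))
  list(graph = g, root = "root")
}

#' Synthetic network with planted fibers
#'
#' Plants `n_fibers` groups whose members receive byte-identical in-edge sets
#' (same regulator sources, types and multiplicities), which forces isomorphic
#' input trees within each group. Regulator profiles and per-fiber regulator
#' subsets are kept pairwise distinct so the minimal balanced coloring recovers
#' exactly the planted groups plus regulator singletons.
#'
#' @param n_fibers number of planted fibers
#' @param fiber_sizes integer vector (recycled) of fiber sizes, each >= 1
#' @param n_regulators number of regulator nodes
#' @param seed RNG seed; fixed seed gives a byte-identical graph
#' @return list with `graph` (`dmgraph`) and `partition` — the ground-truth
#'   named membership vector (node -> group id)
#' @export
make_planted_fiber_network <- function(n_fibers, fiber_sizes, n_regulators = 2,
                                       seed = 1) {
  stopifnot(n_fibers >= 1, all(fiber_sizes >= 1), n_regulators >= 1)
  set.seed(seed)
  fiber_sizes <- rep_len(fiber_sizes, n_fibers)
  regs <- sprintf("R%02d", seq_len(n_regulators))
  src <- character(); tgt <- character(); mult <- numeric()
  typ <- character()
  ## regulator j: self-loop of multiplicity j -> pairwise distinct in-profiles;
  ## regulator wiring and fiber feeds use different metabolite types so a
  ## planted member can never share an input tree with a regulator
  for (j in seq_len(n_regulators)) {
    src <- c(src, regs[j]); tgt <- c(tgt, regs[j]); mult <- c(mult, j)
    typ <- c(typ, "reg")
  }
  ## distinct (regulator subset, multiplicity) per fiber
  used <- character()
  membership <- stats::setNames(seq_len(n_regulators) + 1000L, regs)
  for (i in seq_len(n_fibers)) {
    members <- sprintf("F%02d_%02d", i, seq_len(fiber_sizes[i]))
    repeat {
      sub <- sort(sample(regs, sample.int(n_regulators, 1)))
      m <- sample.int(3L, 1)
      key <- paste(paste(sub, collapse = ","), m)
      if (!key %in% used) { used <- c(used, key); break }
      m <- length(used) + 3L  # exhaustively distinct fallback
      key <- paste(paste(sub, collapse = ","), m)
      if (!key %in% used) { used <- c(used, key); break }
    }
    for (node in members) {
      src <- c(src, sub); tgt <- c(tgt, rep(node, length(sub)))
      mult <- c(mult, rep(m, length(sub)))
      typ <- c(typ, rep("fib", length(sub)))
    }
    membership[members] <- i
  }
  g <- dmgraph(data.frame(source = src, target = tgt, edge_type = typ,
                          multiplicity = mult, stringsAsFactors = FALSE))
  list(graph = g, partition = membership[g$nodes])
}

#' The four-node illustrative toy network
#'
#' Two independent self-loop motifs, distinguished by their linking
#' metabolites: A carries a self-loop and feeds B through metabolite m1, C
#' carries a self-loop and feeds D through metabolite m2. The minimal balanced
#' coloring yields the two fibers {A, B} and {C, D}, whose base has two nodes,
#' each with a self-loop.
#'
#' @return list with `graph` (`dmgraph`) and `partition` — expected fibers as a
#'   list of node sets
#' @export
make_fig_toy <- function() {
  g <- dmgraph(data.frame(
    source = c("A", "A", "C", "C"),
    target = c("A", "B", "C", "D"),
    edge_type = c("m1", "m1", "m2", "m2"),
    multiplicity = 1, stringsAsFactors = FALSE))
  list(graph = g, partition = list(c("A", "B"), c("C", "D")))
}

#' Five-step complexity ladder of building blocks
#'
#' Reproduces, as concrete multigraphs with nontrivial fibers, the edge-by-edge
#' progression from a self-regulating fiber to a two-fiber feedback composite:
#' \enumerate{
#'   \item fiber {F1, F2} sustained by a self-loop on F1 (class |1,0>)
#'   \item + external regulator R feeding both members (|1,1>)
#'   \item + feedback edge F1 -> R: the simplest Fibonacci fiber, r = 1.618
#'   \item + second fiber {Y1, Y2} fed by F1: composite feedforward, r unchanged
#'   \item + feedback edges Y1 -> F1, Y2 -> F2: composite feedback, r = 2
#' }
#' @return list of five lists, each `list(graph, focal)` where `focal` is the
#'   fiber whose block is under study at that step
#' @export
make_ladder_steps <- function() {
  ed <- function(type, ...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(source = m[, 1], target = m[, 2], edge_type = type,
               multiplicity = 1, stringsAsFactors = FALSE)
  }
  ## the downstream fiber is linked through a different metabolite (m2) than
  ## the fiber-regulator circuitry (m1), keeping it a distinct fiber from R
  s1 <- ed("m1", "F1", "F1", "F1", "F2")
  s2 <- rbind(s1, ed("m1", "R", "F1", "R", "F2"))
  s3 <- rbind(s2, ed("m1", "F1", "R"))
  s4 <- rbind(s3, ed("m2", "F1", "Y1", "F1", "Y2"))
  s5 <- rbind(s4, ed("m2", "Y1", "F1", "Y2", "F2"))
  list(list(graph = dmgraph(s1), focal = c("F1", "F2")),
       list(graph = dmgraph(s2), focal = c("F1", "F2")),
       list(graph = dmgraph(s3), focal = c("F1", "F2")),
       list(graph = dmgraph(s4), focal = c("Y1", "Y2")),
       list(graph = dmgraph(s5), focal = c("Y1", "Y2")))
}
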