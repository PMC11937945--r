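#' Input-tree layer counts
#'
#' The input tree of a node is the layered tree of all directed paths ending
#' at it; layer i holds the start points of paths of length i-1, counted with
#' edge multiplicity. Layer 1 is the root itself (a_1 = 1) and the occurrence
#' of node u in layer i+1 is sum_v multiplicity(u -> v) x occurrence of v in
#' layer i. Counts are exact integers (held in doubles, exact below 2^53).
#'
#' @param g a `dmgraph`
#' @param root root node id
#' @param depth maximum number of layers (>= 1)
#' @return object of class `layer_sequence`: list with `root`, `a` (layer sums
#'   a_1..a_k; truncated when a layer empties, i.e. the tree is finite) and
#'   `occurrences` (nodes x layers matrix of per-node counts)
#' @examples
#' fb <- make_recurrence_block(list(c(1, 1), c(2, 1)))
#' layer_counts(fb$graph, fb$root, 5)$a  # 1 2 3 5 8
#' @export
layer_counts <- function(g, root, depth) {
  stopifnot(inherits(g, "dmgraph"), depth >= 1)
  if (!root %in% g$nodes) stop(sprintf("root '%s' is not in the graph", root))
  A <- adjacency_matrix(g)
  occ <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  occ[root] <- 1
  layers <- matrix(0, length(g$nodes), 0, dimnames = list(g$nodes, NULL))
  a <- numeric(0)
  for (i in seq_len(depth)) {
    if (all(occ == 0)) break
    layers <- cbind(layers, occ)
    a <- c(a, sum(occ))
    occ <- drop(A %*% occ)
  }
  colnames(layers) <- NULL
  structure(list(root = root, a = a, occurrences = layers),
            class = "layer_sequence")
}

#' @export
print.layer_sequence <- function(x, ...) {
  cat(sprintf("input tree of '%s': a_i = %s%s\n", x$root,
              paste(format(x$a, scientific = FALSE, trim = TRUE), collapse = ", "),
              if (length(x$a) && x$a[length(x$a)] > 0) ", ..." else " (finite)"))
  invisible(x)
}

#' Branching ratio of an input tree
#'
#' Iterates the layer occurrence vector (normalized each step by its sup-norm
#' to avoid overflow) and tracks the ratio of consecutive layer sums
#' r_i = a_{i+1}/a_i. Iteration stops when the ratio changes by less than
#' `tol` for three consecutive steps (ratio sequences oscillate around their
#' limit, so first-touch stopping is not used), when the layers empty (finite
#' input tree: r = 0), or at `max_iter` (converged = FALSE).
#'
#' @param g a `dmgraph`
#' @param root root node id
#' @param tol convergence tolerance on successive ratios (> 0)
#' @param max_iter iteration cap
#' @return object of class `branching_ratio`: list with `value` (r, full
#'   precision), `status` (`finite_tree`, `chain` for r = 1, or `branching`),
#'   `iterations`, `converged`
#' @examples
#' fb <- make_recurrence_block(list(c(1, 1), c(2, 1)))
#' branching_ratio(fb$graph, fb$root)$value  # golden ratio 1.6180...
#' @export
branching_ratio <- function(g, root, tol = 1e-9, max_iter = 10000) {
  stopifnot(inherits(g, "dmgraph"))
  if (!root %in% g$nodes) stop(sprintf("root '%s' is not in the graph", root))
  if (tol <= 0) stop("tol must be > 0")
  A <- adjacency_matrix(g)
  occ <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  occ[root] <- 1
  r_prev <- NA_real_
  r <- NA_real_
  streak <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    nxt <- drop(A %*% occ)
    s_cur <- sum(occ)
    s_nxt <- sum(nxt)
    if (s_nxt == 0) {
      return(structure(list(value = 0, status = "finite_tree",
                            iterations = iter, converged = TRUE),
                       class = "branching_ratio"))
    }
    r <- s_nxt / s_cur
    if (!is.na(r_prev) && abs(r - r_prev) < tol) {
      streak <- streak + 1L
      if (streak >= 3L) { converged <- TRUE; break }
    } else streak <- 0L
    r_prev <- r
    occ <- nxt / max(nxt)
  }
  status <- if (abs(r - 1) < 1e-6) "chain" else "branching"
  structure(list(value = r, status = status, iterations = iter,
                 converged = converged),
            class = "branching_ratio")
}

#' @export
print.branching_ratio <- function(x, ...) {
  cat(sprintf("branching ratio r = %.2f (%s, %d iterations%s)\n", x$value,
              x$status, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Limiting ratio of a linear layer-count recurrence
#'
#' Evaluates the limit of a_{i+1}/a_i for a_i = sum_d n_d a_{i-d}, seeded with
#' a_1 = 1 and absent earlier terms 0 — the recurrence contributed by cycles of
#' length d with total multiplicity n_d through the root. The limit equals the
#' dominant root of the characteristic polynomial
#' x^D = sum_d n_d x^(D-d).
#'
#' @param coefficients list of `c(d, n)` pairs: lag d >= 1, coefficient n >= 1
#' @param tol convergence tolerance on successive ratios
#' @param max_iter iteration cap
#' @return the limiting ratio (full precision)
#' @examples
#' recurrence_ratio(list(c(1, 1), c(2, 1)))  # 1.618...
#' @export
recurrence_ratio <- function(coefficients, tol = 1e-9, max_iter = 10000) {
  if (length(coefficients) == 0) stop("empty coefficient list")
  lag <- vapply(coefficients, `[`, 0, 1)
  cf <- vapply(coefficients, `[`, 0, 2)
  if (any(lag < 1) || any(cf < 1)) stop("lags and coefficients must be >= 1")
  D <- max(lag)
  coef_by_lag <- numeric(D)
  for (k in seq_along(lag)) coef_by_lag[lag[k]] <- coef_by_lag[lag[k]] + cf[k]
  a <- c(numeric(D - 1), 1)  # window a_{i-D+1} .. a_i, seeded a_1 = 1
  r_prev <- NA_real_
  streak <- 0L
  for (iter in seq_len(max_iter)) {
    nxt <- sum(coef_by_lag * rev(a))
    r <- nxt / a[D]
    a <- c(a[-1], nxt)
    if (max(a) > 1e100) a <- a / max(a)  # rescale, ratio unaffected
    if (!is.na(r_prev) && abs(r - r_prev) < tol) {
      streak <- streak + 1L
      if (streak >= 3L) return(r)
    } else streak <- 0L
    r_prev <- r
  }
  warning("recurrence ratio did not converge within max_iter")
  r
}

#' Depth-bounded input-tree isomorphism
#'
#' Two input trees match at depth d iff the multisets of (edge type, child
#' subtree at depth d-1) over in-edges, counted with multiplicity, match.
#' Comparison at depth |V| decides full (infinite-depth) isomorphism, because
#' the refinement of depth-k signatures stabilizes within |V| rounds.
#'
#' @param g a `dmgraph`
#' @param u,v node ids
#' @param depth comparison depth (>= 0; depth 0 trees are always isomorphic)
#' @return logical
#' @export
input_tree_isomorphic <- function(g, u, v, depth) {
  stopifnot(u %in% g$nodes, v %in% g$nodes, depth >= 0)
  sig <- input_tree_signatures(g, depth)
  identical(sig[[u]], sig[[v]])
}

## depth-k signatures for all nodes, re-encoded to integers each level to keep
## strings bounded (Weisfeiler-Lehman style, in-edges only)
input_tree_signatures <- function(g, depth) {
  nodes <- g$nodes
  sig <- stats::setNames(rep(1L, length(nodes)), nodes)
  e <- g$edges
  for (k in seq_len(depth)) {
    rec <- rep(paste(sig[e$source], e$edge_type, sep = "\r"), e$multiplicity)
    tgt <- rep(e$target, e$multiplicity)
    prof <- vapply(split(rec, factor(tgt, levels = nodes)),
                   function(x) paste(sort(x), collapse = "\n"), character(1))
    sig <- stats::setNames(match(prof[nodes], unique(prof[nodes])), nodes)
  }
  as.list(sig)
}
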