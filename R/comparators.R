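#' Adjusted Rand index of two groupings
#'
#' Permutation-model ARI over the contingency table n_ij = |X_i ∩ Y_j|:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - [\sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}]/\binom{n}{2}}
#' {\frac12[\sum_i\binom{a_i}{2}+\sum_j\binom{b_j}{2}] - [\sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}]/\binom{n}{2}}}
#' Identical partitions score 1; independent ones score ~0.
#'
#' @param x,y groupings over the same node universe: named membership vectors,
#'   lists of node sets, or `fiber_partition`/`fibration` objects
#' @param complete if TRUE, nodes present in only one grouping are placed in
#'   singletons of the other (partial covers, e.g. motif members vs a full
#'   module partition); if FALSE mismatched universes are an error
#' @return the ARI (real)
#' @export
adjusted_rand_index <- function(x, y, complete = FALSE) {
  mx <- as_membership(x); my <- as_membership(y)
  if (length(mx) == 0 || length(my) == 0) stop("empty grouping")
  if (!setequal(names(mx), names(my))) {
    if (!complete)
      stop("groupings cover different node sets (set complete = TRUE to fill singletons)")
    univ <- union(names(mx), names(my))
    fill <- function(m) {
      miss <- setdiff(univ, names(m))
      c(m, stats::setNames(seq_along(miss) + max(m), miss))
    }
    mx <- fill(mx); my <- fill(my)
  }
  my <- my[names(mx)]
  tab <- table(mx, my)
  n <- sum(tab)
  choose2 <- function(v) sum(choose(v, 2))
  sij <- choose2(tab)
  sa <- choose2(rowSums(tab))
  sb <- choose2(colSums(tab))
  expected <- sa * sb / choose(n, 2)
  denom <- (sa + sb) / 2 - expected
  if (denom == 0) return(if (sij == expected) 1 else 0)
  (sij - expected) / denom
}

#' Directed modularity of a partition
#'
#' \deqn{Q = \frac1m \sum_{u,v}\left[A_{uv} - \frac{d_u^{in} d_v^{out}}{m}\right]\delta(C_u, C_v)}
#' with multiplicities counted in m, in A and in the degrees.
#' @param g a `dmgraph` with at least one edge
#' @param membership named vector node -> community (or `fiber_partition`)
#' @return Q (real)
#' @export
directed_modularity <- function(g, membership) {
  memb <- as_membership(membership)
  if (!all(g$nodes %in% names(memb)))
    stop("membership does not cover the node set")
  m <- sum(g$edges$multiplicity)
  if (m < 1) stop("modularity of an edgeless graph is undefined")
  e <- g$edges
  din <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  dout <- din
  agg_in <- tapply(e$multiplicity, e$target, sum)
  agg_out <- tapply(e$multiplicity, e$source, sum)
  din[names(agg_in)] <- agg_in
  dout[names(agg_out)] <- agg_out
  same <- memb[e$source] == memb[e$target]
  a_term <- sum(e$multiplicity[same])
  null_term <- 0
  for (cls in split(g$nodes, memb[g$nodes]))
    null_term <- null_term + sum(din[cls]) * sum(dout[cls]) / m
  (a_term - null_term) / m
}

#' Greedy directed-modularity community detection
#'
#' Louvain-style optimization of the directed modularity: repeated local-move
#' sweeps (each node greedily relocated to the in/out-neighboring community
#' with the best modularity gain) followed by graph aggregation, until no move
#' improves Q. Deterministic under a fixed seed (the seed sets the node sweep
#' order).
#'
#' @param g a `dmgraph` with at least one edge
#' @param seed RNG seed for the sweep order
#' @return list of class `module_partition`: `membership` (named node ->
#'   community, ids renumbered by first occurrence), `Q` (achieved modularity)
#' @export
louvain_partition <- function(g, seed = 1) {
  if (sum(g$edges$multiplicity) < 1) stop("edgeless graph")
  set.seed(seed)
  cur <- g
  map <- stats::setNames(g$nodes, g$nodes)  # original node -> current supernode
  repeat {
    res <- louvain_local_moves(cur)
    map <- stats::setNames(unname(res$membership[map]), names(map))
    if (res$n_moves == 0) break
    ## aggregate communities into supernodes
    comm <- res$membership
    e <- cur$edges
    agg <- data.frame(source = unname(comm[e$source]),
                      target = unname(comm[e$target]),
                      edge_type = "agg", multiplicity = e$multiplicity,
                      stringsAsFactors = FALSE)
    cur <- dmgraph(agg, nodes = unique(unname(comm)))
  }
  ids <- match(map[g$nodes], unique(map[g$nodes]))
  membership <- stats::setNames(ids, g$nodes)
  structure(list(membership = membership,
                 Q = directed_modularity(g, membership)),
            class = "module_partition")
}

## one full local-move phase on graph `cur`; returns membership (node name ->
## community id given as a node name of cur) and number of moves made
louvain_local_moves <- function(cur) {
  nodes <- cur$nodes
  m <- sum(cur$edges$multiplicity)
  e <- cur$edges
  ## weights between node pairs (summed over types)
  win <- split(seq_len(nrow(e)), e$target)
  wout <- split(seq_len(nrow(e)), e$source)
  din <- stats::setNames(numeric(length(nodes)), nodes)
  dout <- din
  if (nrow(e)) {
    ai <- tapply(e$multiplicity, e$target, sum); din[names(ai)] <- ai
    ao <- tapply(e$multiplicity, e$source, sum); dout[names(ao)] <- ao
  }
  comm <- stats::setNames(nodes, nodes)  # community labelled by a node name
  Din <- din; Dout <- dout               # community degree totals
  names(Din) <- names(Dout) <- nodes
  total_moves <- 0L
  repeat {
    moves <- 0L
    for (v in sample(nodes)) {
      cv <- comm[[v]]
      ## weights from v to each community and vice versa
      idx_out <- wout[[v]]; idx_in <- win[[v]]
      w_to <- tapply(e$multiplicity[idx_out], comm[e$target[idx_out]], sum)
      w_from <- tapply(e$multiplicity[idx_in], comm[e$source[idx_in]], sum)
      cand <- unique(c(names(w_to), names(w_from), cv))
      self_w <- sum(e$multiplicity[idx_out][e$target[idx_out] == v])
      gain <- function(cc) {
        ## modularity change of placing v (alone) into community cc
        k_vc <- (if (cc %in% names(w_to)) w_to[[cc]] else 0) +
          (if (cc %in% names(w_from)) w_from[[cc]] else 0)
        if (cc == cv) k_vc <- k_vc - 2 * self_w
        Dic <- Din[[cc]]; Doc <- Dout[[cc]]
        if (cc == cv) { Dic <- Dic - din[[v]]; Doc <- Doc - dout[[v]] }
        k_vc / m - (din[[v]] * Doc + dout[[v]] * Dic) / m^2
      }
      g_stay <- gain(cv)
      best <- cv; best_gain <- g_stay
      for (cc in setdiff(cand, cv)) {
        gc <- gain(cc)
        if (gc > best_gain + 1e-12 ||
            (abs(gc - best_gain) <= 1e-12 && cc < best)) {
          best <- cc; best_gain <- gc
        }
      }
      if (best != cv && best_gain > g_stay + 1e-12) {
        Din[[cv]] <- Din[[cv]] - din[[v]]; Dout[[cv]] <- Dout[[cv]] - dout[[v]]
        Din[[best]] <- Din[[best]] + din[[v]]
        Dout[[best]] <- Dout[[best]] + dout[[v]]
        comm[[v]] <- best
        moves <- moves + 1L
      }
    }
    total_moves <- total_moves + moves
    if (moves == 0L) break
  }
  list(membership = comm, n_moves = total_moves)
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module partition: %d communities, Q = %.4f\n",
              length(unique(x$membership)), x$Q))
  invisible(x)
}
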