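## Independent oracles and random-instance generators shared by the suite.
## Everything here is deliberately brute-force and kept apart from the
## package's own algorithms.

random_dmgraph <- function(n_nodes, n_edges, n_types = 2, max_mult = 2,
                           seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  src <- sample(nodes, n_edges, replace = TRUE)
  tgt <- sample(nodes, n_edges, replace = TRUE)
  dmgraph(data.frame(
    source = src, target = tgt,
    edge_type = sample(sprintf("t%d", seq_len(n_types)), n_edges, TRUE),
    multiplicity = sample.int(max_mult, n_edges, TRUE),
    stringsAsFactors = FALSE), nodes = nodes)
}

## mutual-reachability SCCs via boolean transitive closure
oracle_scc <- function(g) {
  n <- length(g$nodes)
  R <- diag(TRUE, n)
  dimnames(R) <- list(g$nodes, g$nodes)
  e <- g$edges
  if (nrow(e)) R[cbind(e$source, e$target)] <- TRUE
  for (k in seq_len(n)) R <- R | (R %*% R > 0)
  mutual <- R & t(R)
  groups <- unique(apply(mutual, 1, function(r) paste(which(r), collapse = ",")))
  lapply(groups, function(gr) sort(g$nodes[as.integer(strsplit(gr, ",")[[1]])]))
}

## recursive input-tree signature: depth-d trees equal iff strings equal;
## memoized on (node, depth)
oracle_tree_sig <- function(g, node, depth, memo = new.env(parent = emptyenv())) {
  key <- paste(node, depth)
  if (!is.null(memo[[key]])) return(memo[[key]])
  if (depth == 0) return("*")
  e <- g$edges
  ins <- which(e$target == node)
  parts <- character(0)
  for (i in ins) {
    child <- oracle_tree_sig(g, e$source[i], depth - 1, memo)
    parts <- c(parts, rep(paste0(e$edge_type[i], "(", child, ")"),
                          e$multiplicity[i]))
  }
  out <- paste0("[", paste(sort(parts), collapse = ","), "]")
  memo[[key]] <- out
  out
}

oracle_iso <- function(g, u, v, depth) {
  memo <- new.env(parent = emptyenv())
  identical(oracle_tree_sig(g, u, depth, memo),
            oracle_tree_sig(g, v, depth, memo))
}

## exhaustive subset motif counts ("contains" semantics)
oracle_motif_counts <- function(g) {
  M <- fibnet:::simple_adjacency(g)
  diag(M) <- FALSE
  n <- nrow(M)
  pats <- fibnet:::motif_patterns()
  counts <- setNames(integer(length(pats)), names(pats))
  for (k in c(3L, 4L)) {
    if (n < k) next
    perms <- fibnet:::perms_of(k)
    subs <- utils::combn(n, k)
    pk <- pats[vapply(pats, function(p) p$size, 0L) == k]
    for (j in seq_len(ncol(subs))) {
      s <- subs[, j]
      sub <- M[s, s, drop = FALSE]
      for (nm in names(pk))
        if (fibnet:::subset_matches(sub, pk[[nm]], perms))
          counts[nm] <- counts[nm] + 1L
    }
  }
  counts
}

## pair-counting adjusted Rand index (independent of the contingency formula)
oracle_ari <- function(mx, my) {
  my <- my[names(mx)]
  n <- length(mx)
  pairs <- utils::combn(n, 2)
  same_x <- mx[pairs[1, ]] == mx[pairs[2, ]]
  same_y <- my[pairs[1, ]] == my[pairs[2, ]]
  a <- sum(same_x & same_y); b <- sum(same_x & !same_y)
  c_ <- sum(!same_x & same_y); d <- sum(!same_x & !same_y)
  np <- choose(n, 2)
  expected <- (a + b) * (a + c_) / np
  maxi <- ((a + b) + (a + c_)) / 2
  if (maxi == expected) return(if (a == expected) 1 else 0)
  (a - expected) / (maxi - expected)
}

## all set partitions of 1..n as membership vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, m) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(m + 1)) rec(c(prefix, v), max(m, v))
  }
  rec(integer(0), 0L)
  out
}

## random block with a guaranteed aperiodic root class: cycles through a root,
## always including a length-1 term
random_recurrence_terms <- function(seed) {
  set.seed(seed)
  n_terms <- sample(1:3, 1)
  terms <- list(c(1, sample(1:3, 1)))
  if (n_terms > 1)
    for (k in seq_len(n_terms - 1))
      terms[[k + 1]] <- c(sample(2:4, 1), sample(1:3, 1))
  terms
}
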