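## motif edge patterns over subset positions (1-based role indices)
motif_patterns <- function() {
  list(
    feed_forward_loop = list(size = 3L,
                             edges = rbind(c(1, 2), c(1, 3), c(2, 3))),
    bifan = list(size = 4L,
                 edges = rbind(c(1, 3), c(1, 4), c(2, 3), c(2, 4))),
    biparallel = list(size = 4L,
                      edges = rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4))),
    cycle4 = list(size = 4L,
                  edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))))
}

perms_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

## does the induced adjacency `sub` (k x k logical) contain / exactly match
## the pattern under some role permutation?
subset_matches <- function(sub, pat, perms, strict = FALSE) {
  k <- nrow(sub)
  for (p in seq_len(nrow(perms))) {
    perm <- perms[p, ]
    idx <- cbind(perm[pat$edges[, 1]], perm[pat$edges[, 2]])
    if (all(sub[idx])) {
      if (!strict) return(TRUE)
      diag_free <- sub
      diag(diag_free) <- FALSE
      if (sum(diag_free) == nrow(pat$edges)) return(TRUE)
    }
  }
  FALSE
}

## ESU (Wernicke) enumeration of all weakly connected k-subsets, each exactly
## once; returns a list of integer vectors
enumerate_connected_subsets <- function(nbr, n, k) {
  out <- vector("list", 0L)
  emit <- function(s) out[[length(out) + 1L]] <<- s
  extend <- function(sub, ext, v) {
    if (length(sub) == k) { emit(sub); return() }
    while (length(ext) > 0) {
      w <- ext[1]; ext <- ext[-1]
      excl <- setdiff(nbr[[w]], c(sub, unlist(nbr[sub], use.names = FALSE)))
      extend(c(sub, w), c(ext, excl[excl > v]), v)
    }
  }
  for (v in seq_len(n)) {
    ext0 <- nbr[[v]][nbr[[v]] > v]
    extend(v, ext0, v)
  }
  out
}

#' Census of 3- and 4-node network motifs
#'
#' Counts node subsets whose induced connectivity contains the motif's edges
#' (extra edges allowed, the common mfinder-style convention; set
#' `strict_induced = TRUE` to require an exact edge match). Motifs:
#' feed-forward loop (A→B, A→C, B→C), bi-fan (A→C, A→D, B→C, B→D),
#' bi-parallel (A→B, A→C, B→D, C→D) and the 4-cycle. Multiplicities are
#' collapsed and self-loops ignored for motif matching.
#'
#' @param g a `dmgraph`
#' @param strict_induced require the induced subgraph to equal the pattern
#' @return named integer vector of counts per motif type
#' @export
motif_census <- function(g, strict_induced = FALSE) {
  M <- simple_adjacency(g)
  diag(M) <- FALSE
  n <- nrow(M)
  pats <- motif_patterns()
  counts <- stats::setNames(integer(length(pats)), names(pats))
  if (n < 3) return(counts)
  und <- M | t(M)
  nbr <- lapply(seq_len(n), function(i) which(und[i, ]))
  perms <- list(`3` = perms_of(3L), `4` = perms_of(4L))
  for (k in c(3L, 4L)) {
    if (n < k) next
    subsets <- enumerate_connected_subsets(nbr, n, k)
    pk <- pats[vapply(pats, function(p) p$size, 0L) == k]
    for (s in subsets) {
      sub <- M[s, s, drop = FALSE]
      for (nm in names(pk))
        if (subset_matches(sub, pk[[nm]], perms[[as.character(k)]],
                           strict = strict_induced))
          counts[nm] <- counts[nm] + 1L
    }
  }
  counts
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Rewires the simple view of the graph (multiplicities collapsed) by repeated
#' double-edge swaps (a→b, c→d) => (a→d, c→b), each attempt rejected if it
#' would create a self-loop or duplicate an existing edge. Every node's in-
#' and out-degree and the edge count are conserved. Self-loops are held fixed
#' and never swapped.
#'
#' @param g a `dmgraph`
#' @param n_swaps number of attempted swaps (default 10 x edge count)
#' @param seed RNG seed
#' @return a randomized `dmgraph` (unit multiplicities; original self-loops
#'   kept)
#' @export
degree_preserving_randomize <- function(g, n_swaps = NULL, seed = 1) {
  M <- simple_adjacency(g)
  selfloops <- g$nodes[diag(M)]
  diag(M) <- FALSE
  idx <- which(M, arr.ind = TRUE)
  ne <- nrow(idx)
  if (is.null(n_swaps)) n_swaps <- 10L * ne
  set.seed(seed)
  if (ne >= 2 && n_swaps > 0) {
    src <- idx[, 1]; tgt <- idx[, 2]
    for (s in seq_len(n_swaps)) {
      ij <- sample.int(ne, 2)
      a <- src[ij[1]]; b <- tgt[ij[1]]
      c_ <- src[ij[2]]; d <- tgt[ij[2]]
      if (a == d || c_ == b) next          # would create a self-loop
      if (M[a, d] || M[c_, b]) next        # would duplicate an edge
      M[a, b] <- FALSE; M[c_, d] <- FALSE
      M[a, d] <- TRUE; M[c_, b] <- TRUE
      tgt[ij[1]] <- d; tgt[ij[2]] <- b
    }
    idx <- cbind(src, tgt)
  }
  e <- data.frame(source = g$nodes[idx[, 1]], target = g$nodes[idx[, 2]],
                  edge_type = "metabolic", multiplicity = 1,
                  stringsAsFactors = FALSE)
  if (length(selfloops) > 0)
    e <- rbind(e, data.frame(source = selfloops, target = selfloops,
                             edge_type = "metabolic", multiplicity = 1,
                             stringsAsFactors = FALSE))
  dmgraph(e, nodes = g$nodes)
}

#' Motif Z-scores against a degree-preserving null ensemble
#'
#' Compares observed motif counts with `n_random` randomized replicas of the
#' network: Z_i = (N_i - <N_i>) / sigma_i, motif significant iff Z_i > 2. A
#' degenerate null (sigma = 0) reports Z = +Inf when the observed count
#' exceeds the null mean and 0 otherwise.
#'
#' @param g a `dmgraph`
#' @param n_random size of the null ensemble (>= 2)
#' @param n_swaps attempted swaps per draw (default 10 x edge count)
#' @param seed base RNG seed (draw k uses seed + k)
#' @param strict_induced passed to [motif_census()]
#' @return data.frame of class `motif_census`: per motif, observed count N,
#'   null mean, null sd, Z, significant flag
#' @export
motif_zscores <- function(g, n_random = 1000, n_swaps = NULL, seed = 1,
                          strict_induced = FALSE) {
  stopifnot(n_random >= 2)
  obs <- motif_census(g, strict_induced)
  nulls <- matrix(0, n_random, length(obs),
                  dimnames = list(NULL, names(obs)))
  for (k in seq_len(n_random)) {
    rg <- degree_preserving_randomize(g, n_swaps, seed = seed + k)
    stopifnot(identical(degree_table(rg), degree_table(g)))  # swap invariant
    nulls[k, ] <- motif_census(rg, strict_induced)
  }
  mu <- colMeans(nulls)
  sdev <- apply(nulls, 2, stats::sd)
  z <- ifelse(sdev > 0, (obs - mu) / sdev, ifelse(obs > mu, Inf, 0))
  out <- data.frame(motif = names(obs), N = as.integer(obs),
                    null_mean = unname(mu), null_sd = unname(sdev),
                    Z = unname(z), significant = unname(z > 2),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("motif_census", class(out))
  out
}

## in/out degree table of the simple (collapsed) view, self-loops included
degree_table <- function(g) {
  M <- simple_adjacency(g)
  list(din = colSums(M), dout = rowSums(M))
}
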