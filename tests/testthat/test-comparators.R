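test_that("adjusted Rand index matches direct contingency evaluation", {
  x <- c(n1 = 1, n2 = 1, n3 = 2, n4 = 2)
  expect_equal(adjusted_rand_index(x, x), 1)

  y <- c(n1 = 1, n2 = 1, n3 = 1, n4 = 2)  # {1,2,3},{4}
  expect_equal(adjusted_rand_index(x, y), 0)

  singles <- c(n1 = 1, n2 = 2, n3 = 3, n4 = 4)
  block <- c(n1 = 1, n2 = 1, n3 = 1, n4 = 1)
  expect_equal(adjusted_rand_index(singles, block), 0)

  ## symmetry and pair-counting oracle on random partitions
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:12, 1)
    mx <- setNames(sample.int(3, n, TRUE), paste0("v", 1:n))
    my <- setNames(sample.int(4, n, TRUE), paste0("v", 1:n))
    got <- adjusted_rand_index(mx, my)
    expect_equal(got, adjusted_rand_index(my, mx))
    expect_equal(got, oracle_ari(mx, my), tolerance = 1e-12)
    expect_lte(got, 1)
  }
})

test_that("ARI universe completion places missing nodes in singletons", {
  part <- c(a = 1, b = 1, c = 2)
  cover <- c(a = 1, b = 1)
  expect_error(adjusted_rand_index(part, cover), "different node sets")
  got <- adjusted_rand_index(part, cover, complete = TRUE)
  expect_equal(got, adjusted_rand_index(part, c(cover, c = 99)))
  expect_error(adjusted_rand_index(c(x = 1), integer(0)), "empty")
})

test_that("directed modularity reproduces hand-evaluated values", {
  cyc2 <- dmgraph(data.frame(source = c("A", "B"), target = c("B", "A")))
  expect_equal(directed_modularity(cyc2, c(A = 1, B = 1)), 0)
  expect_equal(directed_modularity(cyc2, c(A = 1, B = 2)), -0.5)

  two <- dmgraph(data.frame(source = c("A", "B", "C", "D"),
                            target = c("B", "A", "D", "C")))
  expect_equal(directed_modularity(two, c(A = 1, B = 1, C = 2, D = 2)), 0.5)
  expect_error(directed_modularity(dmgraph(nodes = "A"), c(A = 1)), "edgeless")
})

test_that("greedy modularity optimization finds known community structure", {
  ## two dense directed 4-cliques joined by one edge
  clique <- function(nodes) {
    pr <- expand.grid(source = nodes, target = nodes, stringsAsFactors = FALSE)
    pr[pr$source != pr$target, ]
  }
  e <- rbind(clique(c("a1", "a2", "a3", "a4")), clique(c("b1", "b2", "b3", "b4")),
             data.frame(source = "a1", target = "b1"))
  g <- dmgraph(e)
  mp <- louvain_partition(g, seed = 4)
  memb <- mp$membership
  expect_length(unique(memb), 2)
  expect_length(unique(memb[c("a1", "a2", "a3", "a4")]), 1)
  expect_length(unique(memb[c("b1", "b2", "b3", "b4")]), 1)

  ## exhaustive optimum over all partitions of 8 nodes
  best <- max(vapply(all_partitions(8), function(pp)
    directed_modularity(g, setNames(pp, g$nodes)), 0))
  expect_equal(mp$Q, best, tolerance = 1e-9)

  cyc2 <- dmgraph(data.frame(source = c("A", "B"), target = c("B", "A")))
  m2 <- louvain_partition(cyc2, seed = 1)
  expect_length(unique(m2$membership), 1)  # Q = 0 beats singletons' -0.5
  expect_equal(m2$Q, 0)

  expect_identical(louvain_partition(g, seed = 9)$membership,
                   louvain_partition(g, seed = 9)$membership)
})

test_that("greedy optimizer stays near the exhaustive optimum on random graphs", {
  for (seed in 1:6) {
    g <- random_dmgraph(sample(4:6, 1), sample(5:10, 1), n_types = 1,
                        max_mult = 1, seed = 500 + seed)
    if (sum(g$edges$multiplicity) < 1) next
    best <- max(vapply(all_partitions(length(g$nodes)), function(pp)
      directed_modularity(g, setNames(pp, g$nodes)), 0))
    got <- louvain_partition(g, seed = seed)$Q
    if (best > 0) expect_gte(got, 0.95 * best)
    expect_lte(got, best + 1e-12)
  }
})

test_that("motif census counts node subsets containing each pattern", {
  ffl <- dmgraph(data.frame(source = c("A", "A", "B"), target = c("B", "C", "C")))
  expect_equal(unname(motif_census(ffl)),
               c(1L, 0L, 0L, 0L))

  bifan <- dmgraph(data.frame(source = c("A", "A", "B", "B"),
                              target = c("C", "D", "C", "D")))
  cb <- motif_census(bifan)
  expect_equal(cb[["bifan"]], 1L)
  expect_equal(sum(cb), 1L)

  bp <- dmgraph(data.frame(source = c("A", "A", "B", "C"),
                           target = c("B", "C", "D", "D")))
  expect_equal(motif_census(bp)[["biparallel"]], 1L)

  c4 <- dmgraph(data.frame(source = c("A", "B", "C", "D"),
                           target = c("B", "C", "D", "A")))
  expect_equal(motif_census(c4)[["cycle4"]], 1L)

  ## a full bidirectional triangle contains the FFL but is not an exact match
  tri <- dmgraph(data.frame(source = c("A", "B", "B", "C", "A", "C"),
                            target = c("B", "A", "C", "B", "C", "A")))
  expect_equal(motif_census(tri)[["feed_forward_loop"]], 1L)
  expect_equal(motif_census(tri, strict_induced = TRUE)[["feed_forward_loop"]], 0L)

  for (seed in 1:8) {
    g <- random_dmgraph(sample(5:8, 1), sample(6:16, 1), seed = 600 + seed)
    expect_equal(motif_census(g), oracle_motif_counts(g), info = paste("seed", seed))
  }
})

test_that("degree-preserving randomization conserves degrees and is seeded", {
  g <- random_dmgraph(8, 16, seed = 55)
  r1 <- degree_preserving_randomize(g, seed = 7)
  expect_identical(fibnet:::degree_table(r1), fibnet:::degree_table(g))
  expect_identical(degree_preserving_randomize(g, seed = 7), r1)

  r0 <- degree_preserving_randomize(g, n_swaps = 0, seed = 7)
  expect_identical(fibnet:::simple_adjacency(r0), fibnet:::simple_adjacency(g))

  ## self-loops are preserved untouched
  sl <- dmgraph(data.frame(source = c("A", "A", "B", "C"),
                           target = c("A", "B", "C", "A")))
  rs <- degree_preserving_randomize(sl, seed = 3)
  expect_true(any(rs$edges$source == "A" & rs$edges$target == "A"))
})

test_that("motif Z-scores flag planted enrichment and handle degenerate nulls", {
  ## rigid FFL: every randomization is identical, so Z = 0, not significant
  ffl <- dmgraph(data.frame(source = c("A", "A", "B"), target = c("B", "C", "C")))
  z <- motif_zscores(ffl, n_random = 5, seed = 2)
  expect_equal(z$Z[z$motif == "feed_forward_loop"], 0)
  expect_false(any(z$significant))

  ## planted FFLs on a sparse background are significantly enriched
  k <- 8
  e <- do.call(rbind, lapply(seq_len(k), function(i) {
    n <- sprintf(c("x%d", "y%d", "z%d"), i)
    data.frame(source = c(n[1], n[1], n[2]), target = c(n[2], n[3], n[3]))
  }))
  set.seed(99)
  bg_nodes <- sprintf("b%d", 1:8)
  bg <- data.frame(source = sample(bg_nodes, 10, TRUE),
                   target = sample(bg_nodes, 10, TRUE))
  bg <- bg[bg$source != bg$target, ]
  g <- dmgraph(rbind(e, bg))
  z2 <- motif_zscores(g, n_random = 60, seed = 11)
  expect_gt(z2$Z[z2$motif == "feed_forward_loop"], 2)
  expect_true(z2$significant[z2$motif == "feed_forward_loop"])
})
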