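test_that("block extraction collects fiber, regulators and feedback paths", {
  ## golden-ratio base: focal node with self-loop in a 2-cycle with a regulator
  fb <- make_recurrence_block(list(c(1, 1), c(2, 1)))
  fit <- fibration(fb$graph)
  b <- extract_block(fb$graph, fit$partition, "root")
  expect_setequal(b$members, c("root", "c2_1"))
  expect_equal(b$regulators, "c2_1")
  expect_equal(b$ratio$value, (1 + sqrt(5)) / 2, tolerance = 1e-7)

  ## feed-forward fiber with two regulators: no feedback, finite trees all
  ## around (R2 -> R1 keeps the two regulators distinguishable singletons)
  ff <- dmgraph(data.frame(source = c("R1", "R1", "R2", "R2", "R2"),
                           target = c("A1", "A2", "A1", "A2", "R1")))
  pff <- fibration(ff)$partition
  bff <- extract_block(ff, pff, "A1")
  expect_setequal(bff$members, c("A1", "A2", "R1", "R2"))
  expect_equal(bff$ratio$value, 0)
  clff <- classify_block(bff, pff)
  expect_equal(clff$family, "n_l")
  expect_equal(clff$label, "|0,2>")

  ## feedback through an intermediate node: it must be a member
  gi <- dmgraph(data.frame(source = c("R", "R", "A1", "X"),
                           target = c("A1", "A2", "X", "R")))
  pi <- fibration(gi)$partition
  bi <- extract_block(gi, pi, "A1")
  expect_true("X" %in% bi$members)
  ## BFS oracle: X lies on the unique shortest A1 -> R path
  expect_setequal(fibnet:::shortest_path_nodes(gi, "A1", "R"), c("A1", "X", "R"))

  expect_error(extract_block(gi, pi, 99), "unknown fiber")
  expect_error(extract_block(gi, pi, "nope"), "no fiber contains")
})

test_that("the complexity ladder reproduces its five classes and ratios", {
  steps <- make_ladder_steps()
  want_family <- c("n_l", "n_l", "fibonacci_simple",
                   "composite_feedforward_fibonacci",
                   "composite_feedback_fibonacci")
  want_r <- c(1, 1, (1 + sqrt(5)) / 2, (1 + sqrt(5)) / 2, 2)
  for (k in seq_along(steps)) {
    s <- steps[[k]]
    fit <- fibration(s$graph)
    b <- extract_block(s$graph, fit$partition, s$focal[1])
    cl <- classify_block(b, fit$partition)
    expect_equal(cl$family, want_family[k], info = paste("step", k))
    expect_equal(b$ratio$value, want_r[k], tolerance = 1e-6,
                 info = paste("step", k))
  }
  ## the two n_l steps carry the right fiber numbers
  fit1 <- fibration(steps[[1]]$graph)
  cl1 <- classify_block(extract_block(steps[[1]]$graph, fit1$partition, "F1"),
                        fit1$partition)
  expect_equal(cl1$label, "|1,0>")
  fit2 <- fibration(steps[[2]]$graph)
  cl2 <- classify_block(extract_block(steps[[2]]$graph, fit2$partition, "F1"),
                        fit2$partition)
  expect_equal(cl2$label, "|1,1>")
})

test_that("fibonacci conditions flag feedback cycles and self-loops", {
  fb <- make_recurrence_block(list(c(1, 1), c(2, 1)))
  fitfb <- fibration(fb$graph)
  bfb <- extract_block(fb$graph, fitfb$partition, "root")
  expect_equal(fibonacci_conditions(bfb),
               list(has_fiber_regulator_cycle = TRUE,
                    has_self_loop_on_cycle = TRUE))

  ## |1,1>: self-loop on the fiber, regulator without feedback
  g11 <- dmgraph(data.frame(source = c("F", "R"), target = c("F", "F")))
  p11 <- fibration(g11)$partition
  b11 <- extract_block(g11, p11, "F")
  expect_equal(fibonacci_conditions(b11),
               list(has_fiber_regulator_cycle = FALSE,
                    has_self_loop_on_cycle = TRUE))
  expect_equal(branching_ratio(g11, "F")$value, 1)

  ## |0,1>: no cycles at all
  g01 <- dmgraph(data.frame(source = "R", target = "F"))
  p01 <- fibration(g01)$partition
  b01 <- extract_block(g01, p01, "F")
  expect_equal(fibonacci_conditions(b01),
               list(has_fiber_regulator_cycle = FALSE,
                    has_self_loop_on_cycle = FALSE))
  expect_equal(b01$ratio$status, "finite_tree")
})

test_that("integer ratios get n_l classes, noninteger ratios Fibonacci classes", {
  fit <- fibration(make_planted_fiber_network(2, c(2, 2), 2, seed = 8)$graph)
  d <- building_blocks(fit)
  for (i in seq_len(nrow(d))) {
    is_int <- abs(d$r[i] - round(d$r[i])) <= 1e-6
    if (grepl("fibonacci", d$family[i]) && d$family[i] != "composite_feedback_fibonacci")
      expect_false(is_int)
    if (d$family[i] == "n_l") expect_true(is_int)
  }
})

test_that("classification is stable under node relabeling", {
  steps <- make_ladder_steps()
  for (s in steps[c(3, 5)]) {
    g <- s$graph
    relab <- setNames(sprintf("zz%02d", seq_along(g$nodes)), g$nodes)
    e <- g$edges
    g2 <- dmgraph(data.frame(source = unname(relab[e$source]),
                             target = unname(relab[e$target]),
                             edge_type = e$edge_type,
                             multiplicity = e$multiplicity))
    f1 <- fibration(g)
    f2 <- fibration(g2)
    c1 <- classify_block(extract_block(g, f1$partition, s$focal[1]), f1$partition)
    c2 <- classify_block(extract_block(g2, f2$partition, relab[[s$focal[1]]]),
                         f2$partition)
    expect_equal(c1$family, c2$family)
    expect_equal(c1$r, c2$r, tolerance = 1e-9)
  }
})

test_that("defining blocks pick the smallest containing block", {
  ## two nested blocks around the same fiber: size 3 beats size 6
  mk <- function(members) structure(list(members = members), class = "building_block")
  blocks <- list(mk(c("a", "b", "c", "d", "e", "f")), mk(c("a", "b", "r")))
  p <- fibers(c(a = 1, b = 1, c = 2, d = 2, e = 3, f = 4, r = 5))
  map <- assign_defining_blocks(blocks, p)
  fib_ab <- which(vapply(p$fibers, function(s) "a" %in% s, TRUE))
  fib_cd <- which(vapply(p$fibers, function(s) "c" %in% s, TRUE))
  expect_equal(unname(map[as.character(fib_ab)]), 2L)  # smaller block wins
  expect_equal(unname(map[as.character(fib_cd)]), 1L)  # only containing block

  ## two fibers joined only in one composite block both map to it
  steps <- make_ladder_steps()
  fit5 <- fibration(steps[[5]]$graph)
  d5 <- building_blocks(fit5)
  blocks5 <- attr(d5, "blocks")
  nt <- which(!fit5$partition$trivial)
  map5 <- assign_defining_blocks(blocks5, fit5$partition)
  expect_true(all(!is.na(map5)))
  expect_length(map5, length(nt))
})

test_that("building_blocks table is total over nontrivial fibers", {
  pf <- make_planted_fiber_network(3, c(2, 3, 2), 2, seed = 17)
  fit <- fibration(pf$graph)
  d <- building_blocks(fit)
  expect_equal(nrow(d), sum(!fit$partition$trivial))
  expect_true(all(!is.na(d$defining_block)))
  jf <- tempfile(fileext = ".json")
  write_block_report(fit, jf)
  parsed <- jsonlite::fromJSON(jf, simplifyDataFrame = FALSE)
  expect_length(parsed, nrow(d))
})
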