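test_that("free-size search keeps the strong edge rather than diluting it", {
  net <- path_network(5)
  w <- c(e01 = 1, e02 = 3, e03 = 2, e04 = -5, e05 = 4)
  s <- greedy_search(net, w, mode = "subgraph")
  expect_s3_class(s, "subnetwork")
  expect_identical(sort(s$edges), "e05")
  expect_equal(s$score, 4)
})

test_that("fixed-size search finds the best connected pair", {
  net <- path_network(5)
  w <- c(e01 = 1, e02 = 3, e03 = 2, e04 = -5, e05 = 4)
  s <- greedy_search(net, w, mode = "subgraph", k_fixed = 2)
  expect_setequal(s$edges, c("e02", "e03"))
  expect_equal(s$score, 5 / sqrt(2))
})

test_that("a single negative edge is still reported with all-edge seeds", {
  net <- path_network(1)
  s <- greedy_search(net, c(e01 = -2), mode = "subgraph")
  expect_identical(s$edges, "e01")
  expect_equal(s$score, -2)
})

test_that("positive-edge seeding returns empty when nothing is positive", {
  net <- path_network(3)
  w <- c(e01 = -1, e02 = -2, e03 = -0.5)
  s <- greedy_search(net, w, mode = "subgraph", seeds = "positive_edges")
  expect_equal(s$k, 0L)
  expect_identical(s$score, -Inf)
  # all-edge seeding picks the least bad single edge
  s2 <- greedy_search(net, w, mode = "subgraph", seeds = "all_edges")
  expect_identical(s2$edges, "e03")
})

test_that("empty networks yield the explicit empty subnetwork", {
  s <- greedy_search(path_network(0), numeric(), mode = "subgraph")
  expect_equal(s$k, 0L)
  expect_identical(s$score, -Inf)
})

test_that("aggregate score is the weight sum over sqrt(k)", {
  net <- path_network(4)
  w <- c(e01 = 2, e02 = 2, e03 = 2, e04 = 2)
  s <- greedy_search(net, w, mode = "subgraph", k_fixed = 3)
  expect_equal(s$score, 6 / sqrt(3))
  expect_equal(s$score, sum(w[s$edges]) / sqrt(s$k))
})

test_that("ties are broken toward the lexicographically smaller reaction", {
  # two disconnected components with identical weight
  net <- tibble::tibble(
    reaction_id = c("b_edge", "a_edge"),
    source = c("C1", "C3"), target = c("C2", "C4"),
    reversible = FALSE
  )
  s <- greedy_search(net, c(b_edge = 1, a_edge = 1), mode = "subgraph")
  expect_identical(s$edges, "a_edge")
})

test_that("repeated runs are byte-identical", {
  set.seed(71)
  net <- random_network(6, 10)
  w <- stats::setNames(rnorm(10), net$reaction_id)
  a <- greedy_search(net, w, mode = "subgraph")
  b <- greedy_search(net, w, mode = "subgraph")
  expect_identical(a, b)
})

test_that("chains obey reaction direction and reversibility", {
  # C1 -> C2 <- C3, second edge reversible: valid chain uses it backwards
  net <- tibble::tibble(
    reaction_id = c("e1", "e2"),
    source = c("C1", "C3"), target = c("C2", "C2"),
    reversible = c(FALSE, TRUE)
  )
  s <- greedy_search(net, c(e1 = 2, e2 = 3), mode = "chain", k_fixed = 2)
  expect_setequal(s$edges, c("e1", "e2"))
  expect_true(is_valid_chain(net, s$edges))

  # same topology but irreversible: no 2-chain exists
  net$reversible <- FALSE
  s2 <- greedy_search(net, c(e1 = 2, e2 = 3), mode = "chain", k_fixed = 2)
  expect_equal(s2$k, 0L)
  expect_false(is_valid_chain(net, c("e1", "e2")))
})

test_that("self-loops never enter chains but may enter subgraphs", {
  net <- tibble::tibble(
    reaction_id = c("loop", "e1"),
    source = c("C1", "C1"), target = c("C1", "C2"),
    reversible = FALSE
  )
  w <- c(loop = 10, e1 = 1)
  sc <- greedy_search(net, w, mode = "chain")
  expect_false("loop" %in% sc$edges)
  sg <- greedy_search(net, w, mode = "subgraph")
  expect_true("loop" %in% sg$edges)
})

test_that("two-ended extension can rescue a weak middle seed", {
  # 5 - 1 - 5 path: one-ended growth from the ends stops at a single edge,
  # two-ended growth from the middle assembles the full path
  net <- path_network(3)
  w <- c(e01 = 5, e02 = 1, e03 = 5)
  one <- greedy_search(net, w, mode = "chain", chain_extend = "one")
  expect_equal(one$score, 5)
  both <- greedy_search(net, w, mode = "chain", chain_extend = "both")
  expect_setequal(both$edges, c("e01", "e02", "e03"))
  expect_equal(both$score, 11 / sqrt(3))
})

test_that("brute force enumerates the true optimum on a hand-checked case", {
  net <- path_network(4)
  w <- c(e01 = 1, e02 = -1, e03 = 3, e04 = 2)
  b <- brute_force_search(net, w, k = 2, mode = "subgraph")
  expect_setequal(b$edges, c("e03", "e04"))
  expect_equal(b$score, 5 / sqrt(2))
  bc <- brute_force_search(net, w, k = 2, mode = "chain")
  expect_setequal(bc$edges, c("e03", "e04"))
})

test_that("brute force returns empty when no feasible set exists", {
  b <- brute_force_search(path_network(2), c(e01 = 1, e02 = 1), k = 3)
  expect_equal(b$k, 0L)
  expect_error(
    brute_force_search(random_network(10, 20), rep(1, 20), k = 2),
    "<= 16 edges"
  )
})

test_that("greedy never beats brute force and always returns valid sets", {
  set.seed(81)
  for (rep in 1:60) {
    net <- random_network(sample(4:7, 1), sample(4:9, 1))
    w <- stats::setNames(rnorm(nrow(net)), net$reaction_id)
    k <- sample(2:4, 1)
    for (mode in c("subgraph", "chain")) {
      g <- greedy_search(net, w, mode = mode, k_fixed = k)
      b <- brute_force_search(net, w, k = k, mode = mode)
      expect_lte(g$score, b$score + 1e-9)
      if (g$k > 0L) {
        expect_equal(g$k, k)
        if (mode == "subgraph") {
          expect_true(is_connected_edge_set(net, g$edges))
        } else {
          expect_true(is_valid_chain(net, g$edges))
        }
        expect_equal(g$score, sum(w[g$edges]) / sqrt(k))
      } else if (mode == "subgraph") {
        # subgraph growth cannot dead-end, so empty means infeasible;
        # chain growth may legitimately dead-end short of k
        expect_equal(b$k, 0L)
      }
    }
  }
})

test_that("free-size results are valid and never below the best single edge", {
  set.seed(91)
  for (rep in 1:40) {
    net <- random_network(sample(4:7, 1), sample(4:10, 1))
    w <- stats::setNames(rnorm(nrow(net)), net$reaction_id)
    for (mode in c("subgraph", "chain")) {
      g <- greedy_search(net, w, mode = mode)
      # best single eligible edge is always a candidate (chains bar self-loops)
      eligible <- if (mode == "chain") w[net$source != net$target] else w
      if (length(eligible) == 0L) next
      expect_gte(g$score, max(eligible))
      if (mode == "subgraph") {
        expect_true(is_connected_edge_set(net, g$edges))
      } else {
        expect_true(is_valid_chain(net, g$edges))
      }
    }
  }
})

test_that("edge adjacency is symmetric and excludes the edge itself", {
  net <- path_network(4)
  adj <- edge_adjacency(net)
  expect_named(adj, net$reaction_id)
  for (e in names(adj)) {
    expect_false(e %in% adj[[e]])
    for (f in adj[[e]]) expect_true(e %in% adj[[f]])
  }
  expect_identical(adj$e01, "e02")
  expect_identical(adj$e02, c("e01", "e03"))
})

test_that("weight handling: missing ids get 0, unnamed vectors map by order", {
  net <- path_network(3)
  s <- greedy_search(net, c(e02 = 2), mode = "subgraph")
  expect_identical(s$edges, "e02")
  s2 <- greedy_search(net, c(0, 2, 0), mode = "subgraph")
  expect_identical(s2$edges, "e02")
  expect_error(
    greedy_search(net, c(e01 = Inf, e02 = 1, e03 = 1), mode = "subgraph"),
    "finite"
  )
})

test_that("validity checkers reject malformed member sets", {
  net <- path_network(4)
  expect_false(is_connected_edge_set(net, character()))
  expect_false(is_connected_edge_set(net, c("e01", "e03"))) # gap
  expect_true(is_connected_edge_set(net, c("e01", "e02")))
  expect_false(is_connected_edge_set(net, c("e01", "nope")))
  expect_true(is_valid_chain(net, c("e02", "e01"))) # order-free
  expect_false(is_valid_chain(net, c("e01", "e03")))
  expect_false(is_valid_chain(net, character()))
})

test_that("subnetwork objects print and tidy", {
  net <- path_network(3)
  s <- greedy_search(net, c(e01 = 1, e02 = 2, e03 = 3), mode = "subgraph")
  expect_output(print(s), "<subnetwork>")
  td <- generics::tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("reaction_id", "position"))
  expect_equal(nrow(td), s$k)
})
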