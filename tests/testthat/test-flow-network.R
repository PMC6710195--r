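test_that("the worked three-node example routes 5 units from A to C", {
  expect_equal(max_flow_value(fig1_graph(), "A", "C"), 5)
})

test_that("flow is zero without a source-to-sink path", {
  g <- capacity_graph(c("A", "B", "C"),
                      data.frame(from = "B", to = "A", capacity = 2))
  expect_equal(max_flow_value(g, "A", "C"), 0)
  expect_error(max_flow_value(g, "A", "A"), "differ")
  expect_error(max_flow_value(g, "A", "Z"), "not in graph")
})

test_that("max flow equals the brute-force minimum cut on random graphs", {
  set.seed(77)
  for (r in 1:50) {
    n <- sample(3:6, 1)
    g <- random_small_graph(n)
    nodes <- g$nodes
    st <- sample(nodes, 2)
    expect_equal(max_flow_value(g, st[1], st[2]),
                 brute_force_min_cut(g, st[1], st[2]))
  }
})

test_that("raising one capacity never lowers any flow", {
  set.seed(91)
  for (r in 1:10) {
    g <- random_small_graph(5)
    if (!nrow(g$edges)) next
    before <- max_flow_value(g, "v1", "v5")
    e <- sample(nrow(g$edges), 1)
    g$edges$capacity[e] <- g$edges$capacity[e] + 3
    expect_gte(max_flow_value(g, "v1", "v5"), before)
  }
})

test_that("capacity graphs reject self-edges and negative capacities", {
  expect_error(capacity_graph("a", data.frame(from = "a", to = "a",
                                              capacity = 1)), "self-edges")
  expect_error(capacity_graph(c("a", "b"),
                              data.frame(from = "a", to = "b",
                                         capacity = -1)), "nonnegative")
  # zero-capacity edges are dropped
  g <- capacity_graph(c("a", "b"),
                      data.frame(from = "a", to = "b", capacity = 0))
  expect_identical(nrow(g$edges), 0L)
})

sparse_fixture <- function(n, seed, density = 0.7) {
  set.seed(seed)
  vals <- matrix(runif(n * n), n) * (runif(n * n) < density)
  diag(vals) <- 0
  te_matrix(vals, sparse_flag = TRUE)
}

test_that("within-group restriction keeps the complete within-group digraph", {
  te <- sparse_fixture(3, 101, density = 1)
  sch <- block_scheme(3, 1)
  g <- restricted_edge_set(te, sch, "n1", "n2")
  expect_identical(nrow(g$edges), 6L) # all ordered pairs of 3 nodes
})

test_that("cross-group restriction keeps only tail-in-X head-in-Y edges", {
  te <- sparse_fixture(6, 102, density = 1)
  sch <- block_scheme(6, 2) # n1-n3 -> g1, n4-n6 -> g2
  g <- restricted_edge_set(te, sch, "n2", "n5")
  expect_true(all(g$edges$from %in% c("n1", "n2", "n3")))
  expect_true(all(g$edges$to %in% c("n4", "n5", "n6")))
  expect_identical(nrow(g$edges), 9L)
})

test_that("an all-zero sparse matrix yields empty edges and zero flow", {
  te <- te_matrix(matrix(0, 4, 4), sparse_flag = TRUE)
  sch <- block_scheme(4, 2)
  g <- restricted_edge_set(te, sch, "n1", "n3")
  expect_identical(nrow(g$edges), 0L)
  iff <- compute_full_if_matrix(te, sch, restricted = TRUE)
  expect_true(all(iff$values == 0))
})

test_that("unrestricted flow dominates the direct TE edge", {
  te <- sparse_fixture(5, 103)
  iff <- compute_full_if_matrix(te, restricted = FALSE)
  expect_true(all(iff$values >= te$values - 1e-12))
  expect_true(all(diag(iff$values) == 0))
})

test_that("restriction can only reduce flow", {
  te <- sparse_fixture(6, 104)
  sch <- block_scheme(6, 3)
  un <- compute_full_if_matrix(te, restricted = FALSE)
  re <- compute_full_if_matrix(te, sch, restricted = TRUE)
  expect_true(all(re$values <= un$values + 1e-9))
  expect_error(compute_full_if_matrix(te, restricted = TRUE),
               "scheme")
})

test_that("flow matrices are equivariant under node relabeling", {
  te <- sparse_fixture(5, 105)
  perm <- c(4, 2, 5, 1, 3)
  te_p <- te_matrix(te$values[perm, perm],
                    node_ids = te$node_ids[perm], sparse_flag = TRUE)
  un <- compute_full_if_matrix(te, restricted = FALSE)
  un_p <- compute_full_if_matrix(te_p, restricted = FALSE)
  expect_equal(un_p$values, un$values[perm, perm], tolerance = 1e-9)
})

test_that("flow values are reproducible across runs", {
  te <- sparse_fixture(6, 106)
  f1 <- compute_full_if_matrix(te, restricted = FALSE)$values
  f2 <- compute_full_if_matrix(te, restricted = FALSE)$values
  expect_true(all(abs(f1 - f2) <= 1e-9 * pmax(abs(f1), 1)))
})

test_that("reduction matches an explicit double-loop summation", {
  te <- sparse_fixture(4, 107, density = 1)
  sch <- block_scheme(4, 2)
  re <- compute_full_if_matrix(te, sch, restricted = TRUE)
  red <- reduce_if_matrix(re, sch)
  grp <- sch$node_to_group[re$labels]
  for (x in sch$group_ids) for (y in sch$group_ids) {
    acc <- 0
    for (i in seq_along(re$labels)) for (j in seq_along(re$labels)) {
      if (i != j && grp[i] == x && grp[j] == y) {
        acc <- acc + re$values[i, j]
      }
    }
    expect_equal(red$values[x, y], acc)
  }
  expect_error(reduce_if_matrix(compute_full_if_matrix(te, restricted = FALSE),
                                sch), "restricted")
})

test_that("a zero full matrix reduces to a zero matrix", {
  te <- te_matrix(matrix(0, 6, 6), sparse_flag = TRUE)
  sch <- block_scheme(6, 3)
  red <- reduce_if_matrix(compute_full_if_matrix(te, sch, TRUE), sch)
  expect_true(all(red$values == 0))
  expect_identical(dim(red$values), c(3L, 3L))
})

test_that("reduced matrices are equivariant under group relabeling", {
  te <- sparse_fixture(6, 108)
  sch <- block_scheme(6, 3)
  re <- compute_full_if_matrix(te, sch, restricted = TRUE)
  red <- reduce_if_matrix(re, sch)
  sch2 <- group_scheme(sch$node_to_group, group_ids = c("g3", "g1", "g2"))
  red2 <- reduce_if_matrix(re, sch2)
  expect_equal(red2$values[sch$group_ids, sch$group_ids], red$values)
})

test_that("feature flattening is row-major with stable labels", {
  vals <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("a", "b")))
  red <- if_matrix(vals, variant = "reduced")
  v <- flatten_reduced(red)
  expect_identical(unname(v), c(1, 2, 3, 4))
  expect_identical(names(v), c("a->a", "a->b", "b->a", "b->b"))
})

test_that("a single-node group has zero within-group flow", {
  te <- sparse_fixture(3, 109, density = 1)
  sch <- group_scheme(c(n1 = "solo", n2 = "pair", n3 = "pair"))
  re <- compute_full_if_matrix(te, sch, restricted = TRUE)
  red <- reduce_if_matrix(re, sch)
  expect_identical(red$values["solo", "solo"], 0)
})
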