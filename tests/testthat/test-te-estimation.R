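test_that("parcellation averages voxel time courses", {
  vox2 <- rbind(c(1, 2, 3), c(3, 4, 5), c(7, 7, 7))
  p2 <- parcellate(vox2, c("a1", "a1", "b1"))
  expect_equal(unname(p2$data["a1", ]), c(2, 3, 4))
  expect_equal(unname(p2$data["b1", ]), c(7, 7, 7))
})

test_that("one voxel per node reproduces the input in sorted order", {
  vox <- matrix(rnorm(12), 3)
  p <- parcellate(vox, c("c", "a", "b"))
  expect_identical(p$node_ids, c("a", "b", "c"))
  expect_equal(unname(p$data), unname(vox[c(2, 3, 1), ]))
})

test_that("parcellation matches a brute-force mean on random labels", {
  set.seed(14)
  vox <- matrix(rnorm(100 * 30), 100)
  labels <- sample(paste0("r", 1:5), 100, replace = TRUE)
  p <- parcellate(vox, labels)
  for (nd in sort(unique(labels))) {
    manual <- rep(0, 30)
    cnt <- 0
    for (v in which(labels == nd)) {
      manual <- manual + vox[v, ]
      cnt <- cnt + 1
    }
    expect_equal(unname(p$data[nd, ]), manual / cnt)
  }
  expect_error(parcellate(vox[1:2, ], c("a", "a")), "at least 2 nodes")
})

test_that("KSG estimate is near zero for independent series", {
  ests <- vapply(1:10, function(s) {
    with_seed_local <- function() {
      set.seed(1000 + s)
      list(x = rnorm(5000), y = rnorm(5000))
    }
    d <- with_seed_local()
    ksg_transfer_entropy(d$x, d$y, ksg_config(seed = s))
  }, numeric(1))
  expect_lt(abs(mean(ests)), 0.02)
})

test_that("KSG estimate approaches the Gaussian closed form", {
  m <- var_model(matrix(c(0.3, 0.4, 0, 0.3), 2, 2, byrow = TRUE))
  truth <- analytic_gaussian_te(m, 1, 2)
  ests <- vapply(1:4, function(s) {
    p <- simulate_var_panel(m, 4000, seed = 200 + s)
    ksg_transfer_entropy(p$data[1, ], p$data[2, ], ksg_config(seed = s))
  }, numeric(1))
  expect_lt(abs(mean(ests) - truth), 0.03)
})

test_that("perfect lagged copying dominates both null and VAR coupling", {
  set.seed(55)
  x <- rnorm(3000)
  y <- c(0, x[-3000]) # y_t = x_{t-1}
  te_copy <- ksg_transfer_entropy(x, y, ksg_config(seed = 1))
  m <- var_model(matrix(c(0.3, 0.4, 0, 0.3), 2, 2, byrow = TRUE))
  p <- simulate_var_panel(m, 3000, seed = 9)
  te_var <- ksg_transfer_entropy(p$data[1, ], p$data[2, ], ksg_config(seed = 1))
  te_null <- ksg_transfer_entropy(rnorm(3000), rnorm(3000),
                                  ksg_config(seed = 1))
  expect_gt(te_copy, te_var)
  expect_gt(te_var, te_null)
  expect_gt(te_copy, 1) # near-deterministic transfer carries many bits
})

test_that("estimator is deterministic given the config seed", {
  set.seed(2)
  x <- rnorm(800); y <- rnorm(800)
  e1 <- ksg_transfer_entropy(x, y, ksg_config(seed = 42))
  e2 <- ksg_transfer_entropy(x, y, ksg_config(seed = 42))
  expect_identical(e1, e2)
})

test_that("estimator rejects bad inputs", {
  cfg <- ksg_config()
  expect_error(ksg_transfer_entropy(rnorm(10), rnorm(11), cfg), "equal length")
  expect_error(ksg_transfer_entropy(rnorm(5), rnorm(5), cfg), "too short")
  expect_error(ksg_transfer_entropy(c(rnorm(99), NA), rnorm(100), cfg),
               "non-finite")
})

test_that("TE matrix has the right structure and directionality", {
  m <- var_model(matrix(c(0.3, 0.5, 0, 0.3), 2, 2, byrow = TRUE))
  p <- simulate_var_panel(m, 4000, seed = 66)
  M <- build_te_matrix(p, ksg_config(seed = 3))
  expect_false(M$sparse_flag)
  expect_identical(diag(M$values), c(n1 = 0, n2 = 0))
  # one-way coupling: forward TE exceeds reverse TE
  expect_gt(M$values[1, 2], M$values[2, 1])
})

test_that("3-node TE matrix populates all ordered pairs", {
  m <- random_var_model(3, density = 0.6, seed = 8)
  p <- simulate_var_panel(m, 400, seed = 12)
  M <- build_te_matrix(p, ksg_config(seed = 4))
  off <- M$values[row(M$values) != col(M$values)]
  expect_length(off, 6)
  expect_true(all(off != 0)) # estimates are continuous, never exactly 0
  expect_true(all(diag(M$values) == 0))
})

test_that("TE matrix is equivariant under node permutation", {
  m <- random_var_model(4, density = 0.5, seed = 19)
  p <- simulate_var_panel(m, 2000, seed = 23)
  M <- build_te_matrix(p, ksg_config(seed = 5))
  perm <- c(3, 1, 4, 2)
  pp <- timeseries_panel(p$data[perm, ], node_ids = p$node_ids[perm])
  Mp <- build_te_matrix(pp, ksg_config(seed = 5))
  # jitter realizations differ between runs, so equality is approximate
  expect_equal(Mp$values, M$values[perm, perm], tolerance = 1e-4)
})

test_that("truncating one timepoint barely changes the TE matrix", {
  m <- random_var_model(3, density = 0.6, seed = 28)
  p <- simulate_var_panel(m, 5000, seed = 29)
  M1 <- build_te_matrix(p, ksg_config(seed = 6))
  p2 <- timeseries_panel(p$data[, -5000], node_ids = p$node_ids)
  M2 <- build_te_matrix(p2, ksg_config(seed = 6))
  expect_lt(max(abs(M1$values - M2$values)), 0.05)
})

test_that("sparsification clips negatives and is idempotent", {
  vals <- matrix(c(0, -0.2, 0.3,
                   0.1, 0, -0.4,
                   -0.1, 0.2, 0), 3, 3, byrow = TRUE)
  full <- te_matrix(vals, sparse_flag = FALSE)
  sp <- sparsify_te_matrix(full)
  expect_true(sp$sparse_flag)
  expect_true(all(sp$values >= 0))
  expect_identical(sum(sp$values == 0), sum(vals < 0) + 3L)
  expect_identical(sparsify_te_matrix(sp)$values, sp$values)
  # all-negative and all-nonnegative corner cases
  neg <- te_matrix(matrix(-abs(rnorm(9)), 3) * (1 - diag(3)))
  expect_true(all(sparsify_te_matrix(neg)$values == 0))
  pos <- te_matrix(matrix(abs(rnorm(9)), 3) * (1 - diag(3)))
  expect_identical(sparsify_te_matrix(pos)$values, pos$values)
})

test_that("estimator error shrinks as the series grows", {
  m <- var_model(matrix(c(0.3, 0.4, 0, 0.3), 2, 2, byrow = TRUE))
  truth <- analytic_gaussian_te(m, 1, 2)
  mae_at <- function(T) {
    errs <- vapply(1:3, function(s) {
      p <- simulate_var_panel(m, T, seed = 300 + s)
      ksg_transfer_entropy(p$data[1, ], p$data[2, ],
                           ksg_config(seed = s)) - truth
    }, numeric(1))
    mean(abs(errs))
  }
  maes <- c(mae_at(1000), mae_at(4000), mae_at(16000))
  # allow Monte-Carlo slack at adjacent sizes, require a clear overall drop
  expect_lt(maes[2], maes[1] + 0.01)
  expect_lt(maes[3], maes[2] + 0.005)
  expect_lt(maes[3], maes[1])
})
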