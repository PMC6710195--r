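# Shared fixtures and independent oracles. Everything is generated in
# code; no stored data.

# The introductory worked max-flow example: direct edge A->C of
# capacity 2 plus a two-edge alternative path through B of bottleneck 3.
fig1_graph <- function() {
  capacity_graph(c("A", "B", "C"),
                 data.frame(from = c("A", "A", "B"),
                            to = c("C", "B", "C"),
                            capacity = c(2, 3, 3)))
}

# Round-robin node->group scheme (group sizes may differ by one).
round_robin_scheme <- function(n_nodes, n_groups,
                               node_ids = paste0("n", seq_len(n_nodes)),
                               group_ids = paste0("g", seq_len(n_groups))) {
  grp <- rep_len(group_ids, n_nodes)
  group_scheme(stats::setNames(grp, node_ids))
}

# Scheme with contiguous equal-size groups (nodes 1..k -> g1, ...).
block_scheme <- function(n_nodes, n_groups,
                         node_ids = paste0("n", seq_len(n_nodes)),
                         group_ids = paste0("g", seq_len(n_groups))) {
  stopifnot(n_nodes %% n_groups == 0)
  grp <- rep(group_ids, each = n_nodes / n_groups)
  group_scheme(stats::setNames(grp, node_ids))
}

# Independent max-flow oracle: enumerate every source/sink cut of a
# small directed graph and take the minimum cut capacity
# (max-flow = min-cut).
brute_force_min_cut <- function(graph, source, sink) {
  nodes <- graph$nodes
  others <- setdiff(nodes, c(source, sink))
  best <- Inf
  for (mask in 0:(2^length(others) - 1)) {
    side <- c(source, others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0])
    cut <- sum(graph$edges$capacity[graph$edges$from %in% side &
                                      !(graph$edges$to %in% side)])
    if (cut < best) best <- cut
  }
  if (length(others) == 0) {
    best <- sum(graph$edges$capacity[graph$edges$from == source &
                                       graph$edges$to == sink])
  }
  best
}

# Random small directed graph with integer capacities.
random_small_graph <- function(n_nodes, max_capacity = 9) {
  nodes <- paste0("v", seq_len(n_nodes))
  pairs <- expand.grid(from = nodes, to = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < 0.5
  edges <- pairs[keep, , drop = FALSE]
  edges$capacity <- sample(0:max_capacity, nrow(edges), replace = TRUE)
  capacity_graph(nodes, edges)
}

# Independent stationary-covariance oracle: iterate the Lyapunov
# recursion to convergence instead of solving the vectorized system.
iterate_stationary_cov <- function(coupling, noise_sd = 1, iters = 500) {
  B <- t(coupling)
  n <- nrow(coupling)
  Q <- diag(rep_len(noise_sd, n)^2, n)
  S <- Q
  for (i in seq_len(iters)) S <- B %*% S %*% t(B) + Q
  S
}

# Standard planted-effect cohort used across CPM tests: 12 nodes in 4
# groups, behavior driven by the g1->g2 reduced flow cell.
planted_cohort <- function(seed, n_subjects = 20, noise_rel = 0.1,
                           n_timepoints = 250) {
  sch <- block_scheme(12, 4)
  tmpl <- random_var_model(12, density = 0.3, spectral_radius = 0.7,
                           seed = seed)
  W <- matrix(0, 4, 4)
  W[1, 2] <- 1
  spec <- cohort_spec(n_subjects, tmpl, W, behavior_noise_sd = noise_rel,
                      noise_relative = TRUE, seed = seed + 1L)
  simulate_cohort(spec, sch, n_timepoints = n_timepoints)
}

# Null cohort: same generator, zero planted weights, unit score noise.
null_cohort <- function(seed, n_subjects = 20, n_nodes = 8,
                        n_timepoints = 150) {
  sch <- block_scheme(n_nodes, 4)
  tmpl <- random_var_model(n_nodes, density = 0.3, spectral_radius = 0.7,
                           seed = seed)
  spec <- cohort_spec(n_subjects, tmpl, matrix(0, 4, 4),
                      behavior_noise_sd = 1, seed = seed + 1L)
  simulate_cohort(spec, sch, n_timepoints = n_timepoints)
}

# Quick synthetic feature cohort (no time series): k signal features
# carrying a latent score plus pure-noise features.
feature_cohort <- function(seed, n = 20, n_signal = 3, n_noise = 13,
                           noise_sd = 0.1) {
  set.seed(seed)
  latent <- rnorm(n)
  X <- cbind(outer(latent, runif(n_signal, 0.5, 1.5)) +
               matrix(rnorm(n * n_signal, sd = 0.3), n),
             matrix(rnorm(n * n_noise), n))
  colnames(X) <- paste0("f", seq_len(n_signal + n_noise))
  rownames(X) <- sprintf("sub%02d", seq_len(n))
  list(features = X, behavior = latent + rnorm(n, sd = noise_sd),
       latent = latent)
}
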