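#' Lag-1 vector autoregressive (VAR) ground-truth model
#'
#' Defines the stationary linear-Gaussian process
#' \deqn{x_t = C^\top x_{t-1} + \epsilon_t, \quad
#'       \epsilon_t \sim N(0, \mathrm{diag}(\sigma^2))}
#' where entry \code{coupling[i, j]} is the lag-1 influence of node
#' \code{i} on node \code{j}. Because the process is Gaussian, the
#' transfer entropy between any pair of nodes has a closed form
#' (\code{\link{analytic_gaussian_te}}), which makes this family the
#' ground truth against which the nearest-neighbor estimator is checked.
#'
#' @param coupling square numeric matrix; \code{coupling[i, j]} is the
#'   lag-1 coefficient from node \code{i} to node \code{j}.
#' @param noise_sd innovation standard deviation, recycled to one value
#'   per node; all must be > 0.
#' @param node_ids optional character vector of node names; defaults to
#'   \code{"n1".."nN"}.
#' @return An object of class \code{var_model} with fields
#'   \code{n_nodes}, \code{coupling}, \code{noise_sd}, \code{node_ids}
#'   and \code{max_abs_eigenvalue} (the spectral radius of the coupling
#'   matrix).
#' @details Construction fails unless the spectral radius of
#'   \code{coupling} is strictly below 1, the stationarity condition for
#'   a lag-1 VAR.
#' @seealso \code{\link{simulate_var_panel}}, \code{\link{analytic_gaussian_te}}
#' @export
var_model <- function(coupling, noise_sd = 1, node_ids = NULL) {
  check_matrix_finite(coupling, "coupling")
  n <- nrow(coupling)
  if (ncol(coupling) != n || n < 1L) {
    stop("`coupling` must be a square matrix", call. = FALSE)
  }
  noise_sd <- rep_len(as.numeric(noise_sd), n)
  if (any(!is.finite(noise_sd)) || any(noise_sd <= 0)) {
    stop("`noise_sd` must be positive for every node", call. = FALSE)
  }
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n || anyDuplicated(node_ids)) {
    stop("`node_ids` must be unique and one per node", call. = FALSE)
  }
  rho <- max(Mod(eigen(coupling, only.values = TRUE)$values))
  if (rho >= 1) {
    stop(sprintf(paste0(
      "non-stationary model: spectral radius of the coupling matrix is ",
      "%.4f but must be < 1 for the VAR(1) process to be stationary"),
      rho), call. = FALSE)
  }
  structure(
    list(n_nodes = n, coupling = coupling, noise_sd = noise_sd,
         node_ids = node_ids, max_abs_eigenvalue = rho),
    class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> %d nodes, spectral radius %.3f\n",
              x$n_nodes, x$max_abs_eigenvalue))
  invisible(x)
}

#' Random sparse stable VAR model
#'
#' Draws a coupling matrix with a given off-diagonal density and uniform
#' self-coupling, then rescales it to a target spectral radius. Used as
#' the panel template behind synthetic cohorts.
#'
#' @param n_nodes number of nodes.
#' @param density probability that each off-diagonal coupling entry is
#'   nonzero (default 0.25).
#' @param self_coupling lag-1 self-coefficient shared by all nodes
#'   (default 0.3).
#' @param spectral_radius target spectral radius after rescaling
#'   (default 0.7; must be < 1).
#' @param seed integer seed.
#' @return A \code{\link{var_model}}.
#' @export
random_var_model <- function(n_nodes, density = 0.25, self_coupling = 0.3,
                             spectral_radius = 0.7, seed) {
  check_scalar_number(n_nodes, "n_nodes", lower = 2, integer = TRUE)
  check_scalar_number(spectral_radius, "spectral_radius",
                      lower = 0.05, upper = 0.999)
  C <- with_local_seed(seed, {
    C <- matrix(0, n_nodes, n_nodes)
    off <- which(row(C) != col(C))
    on <- off[runif(length(off)) < density]
    C[on] <- runif(length(on), 0.2, 0.5) * sample(c(-1, 1), length(on),
                                                  replace = TRUE)
    diag(C) <- self_coupling
    C
  })
  rho <- max(Mod(eigen(C, only.values = TRUE)$values))
  if (rho > 0) C <- C * (spectral_radius / rho)
  var_model(C, noise_sd = 1)
}

# Stationary covariance of the VAR(1) process: solves the discrete
# Lyapunov equation Sigma = B Sigma B' + Q with B = t(coupling),
# Q = diag(noise_sd^2), via vectorization.
stationary_covariance <- function(model) {
  B <- t(model$coupling)
  n <- model$n_nodes
  Q <- diag(model$noise_sd^2, n)
  vecS <- solve(diag(n * n) - kronecker(B, B), as.vector(Q))
  S <- matrix(vecS, n, n)
  (S + t(S)) / 2
}

#' Simulate a time-series panel from a VAR model
#'
#' Generates one subject's node-by-time matrix from the lag-1
#' linear-Gaussian recurrence. The chain is initialized from the exact
#' stationary distribution and a short burn-in is discarded, so every
#' retained sample is drawn from the stationary law.
#'
#' @param model a \code{\link{var_model}}.
#' @param n_timepoints number of retained timepoints (at least 10 times
#'   the node count is recommended for downstream estimation).
#' @param seed integer seed; the same seed reproduces the panel exactly.
#' @param subject_id,condition metadata stored on the panel.
#' @param burn_in discarded initial steps (default 100).
#' @return A \code{\link{timeseries_panel}}.
#' @export
simulate_var_panel <- function(model, n_timepoints, seed,
                               subject_id = "sim", condition = "other",
                               burn_in = 100L) {
  stopifnot(inherits(model, "var_model"))
  check_scalar_number(n_timepoints, "n_timepoints", lower = 2,
                      integer = TRUE)
  n <- model$n_nodes
  B <- t(model$coupling)
  S <- stationary_covariance(model)
  total <- n_timepoints + burn_in
  X <- with_local_seed(seed, {
    L <- t(chol(S + diag(1e-12, n)))
    x <- as.vector(L %*% rnorm(n))
    E <- matrix(rnorm(n * total), n, total) * model$noise_sd
    X <- matrix(0, n, total)
    for (t in seq_len(total)) {
      x <- as.vector(B %*% x) + E[, t]
      X[, t] <- x
    }
    X
  })
  timeseries_panel(X[, (burn_in + 1L):total, drop = FALSE],
                   node_ids = model$node_ids,
                   subject_id = subject_id, condition = condition)
}

#' Closed-form Gaussian transfer entropy of a VAR model
#'
#' For a stationary Gaussian process the lag-1 transfer entropy from
#' \code{source} to \code{target} is
#' \deqn{TE = \frac{1}{2}\log_2
#'   \frac{\mathrm{var}(x^{tgt}_t \mid x^{tgt}_{t-1})}
#'        {\mathrm{var}(x^{tgt}_t \mid x^{tgt}_{t-1}, x^{src}_{t-1})}}
#' with the conditional variances obtained from the process's stationary
#' covariance by Schur complements. This is the exact value the KSG
#' estimator converges to on panels simulated from the same model, and
#' serves as the estimator's analytic oracle.
#'
#' @param model a \code{\link{var_model}}.
#' @param source,target node ids (or 1-based indices); must differ.
#' @return Transfer entropy in bits (nonnegative).
#' @export
analytic_gaussian_te <- function(model, source, target) {
  stopifnot(inherits(model, "var_model"))
  src <- resolve_node(model$node_ids, source)
  tgt <- resolve_node(model$node_ids, target)
  if (src == tgt) {
    stop("`source` and `target` must be different nodes", call. = FALSE)
  }
  S <- stationary_covariance(model)
  B <- t(model$coupling)
  CS <- B %*% S                     # Cov(x_t, x_{t-1})
  # Joint covariance of (x_t[tgt], x_{t-1}[tgt], x_{t-1}[src])
  v_y <- S[tgt, tgt]
  cond_var <- function(past_idx) {
    c_yp <- CS[tgt, past_idx]
    V_pp <- S[past_idx, past_idx, drop = FALSE]
    v_y - as.numeric(c_yp %*% solve(V_pp, c_yp))
  }
  te_nats <- 0.5 * log(cond_var(tgt) / cond_var(c(tgt, src)))
  max(te_nats, 0) / log(2)
}

resolve_node <- function(node_ids, x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (x < 1L || x > length(node_ids)) {
      stop("node index out of range", call. = FALSE)
    }
    return(x)
  }
  i <- match(as.character(x), node_ids)
  if (is.na(i)) stop(sprintf("unknown node id '%s'", x), call. = FALSE)
  i
}

#' Threshold-coupled nonlinear pair
#'
#' Simulates a source/target pair whose coupling is purely nonlinear:
#' the source is Gaussian white noise and the target responds to whether
#' the source's previous value exceeded a threshold in magnitude,
#' \deqn{y_t = c \cdot 1\{|x_{t-1}| > \theta\} + \sigma \eta_t.}
#' Because the response is an even function of a symmetric source, the
#' linear (Pearson) correlation between the series is zero at every lag,
#' while the directed information transfer is substantial -- the fixture
#' demonstrates that transfer entropy detects coupling invisible to
#' correlation-based connectivity.
#'
#' @param n_timepoints series length.
#' @param seed integer seed.
#' @param coupling response amplitude \code{c} (default 1).
#' @param threshold magnitude threshold \code{theta} (default 1).
#' @param noise_sd target innovation sd \code{sigma} (default 0.25).
#' @return A two-node \code{\link{timeseries_panel}} with nodes
#'   \code{"src"} and \code{"tgt"}.
#' @export
simulate_threshold_pair <- function(n_timepoints, seed, coupling = 1,
                                    threshold = 1, noise_sd = 0.25) {
  check_scalar_number(n_timepoints, "n_timepoints", lower = 10,
                      integer = TRUE)
  with_local_seed(seed, {
    x <- rnorm(n_timepoints + 1L)
    y <- coupling * as.numeric(abs(x[seq_len(n_timepoints)]) > threshold) +
      noise_sd * rnorm(n_timepoints)
    timeseries_panel(rbind(x[-1L], y), node_ids = c("src", "tgt"),
                     subject_id = "threshold_pair", condition = "other")
  })
}
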