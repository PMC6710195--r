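#' KSG estimator configuration
#'
#' Parameters of the Kraskov-Stogbauer-Grassberger nearest-neighbor
#' transfer-entropy estimator.
#'
#' @param k_neighbors nearest-neighbor count of the KSG estimator
#'   (default 4, the common toolkit default).
#' @param history_target embedding length of the target's own past
#'   (default 1).
#' @param history_source embedding length of the source's past
#'   (default 1).
#' @param jitter_sd amplitude of the seeded tie-breaking noise added to
#'   each series before neighbor search, as an absolute sd; \code{NULL}
#'   (default) scales it to \code{1e-8} times each series' sd. Must be
#'   tiny relative to the data scale.
#' @param units \code{"bits"} (default) or \code{"nats"}. Estimation is
#'   carried out in nats and divided by \code{log(2)} when bits are
#'   requested.
#' @param seed integer seed driving the jitter (default 1).
#' @return An object of class \code{ksg_config}.
#' @export
ksg_config <- function(k_neighbors = 4L, history_target = 1L,
                       history_source = 1L, jitter_sd = NULL,
                       units = c("bits", "nats"), seed = 1L) {
  check_scalar_number(k_neighbors, "k_neighbors", lower = 1, integer = TRUE)
  check_scalar_number(history_target, "history_target", lower = 1,
                      integer = TRUE)
  check_scalar_number(history_source, "history_source", lower = 1,
                      integer = TRUE)
  if (!is.null(jitter_sd)) {
    check_scalar_number(jitter_sd, "jitter_sd", lower = 0)
  }
  structure(
    list(k_neighbors = as.integer(k_neighbors),
         history_target = as.integer(history_target),
         history_source = as.integer(history_source),
         jitter_sd = jitter_sd, units = match.arg(units),
         seed = as.integer(seed)),
    class = "ksg_config")
}

#' Transfer entropy between two series (KSG estimator)
#'
#' Estimates the transfer entropy from \code{source} to \code{target} as
#' the conditional mutual information
#' \eqn{I(\mathrm{target}_{t+1};\ \mathrm{source\ past}\mid
#'      \mathrm{target\ past})}
#' with the KSG algorithm-1 nearest-neighbor estimator (max-norm
#' neighborhoods in the joint embedding space). The estimate may be
#' negative: the true quantity is nonnegative, but the estimator has
#' finite-sample variance, so values near zero can come out below it.
#' A seeded micro-jitter breaks distance ties, making the result
#' deterministic given \code{config$seed}.
#'
#' @param source,target numeric series of equal length.
#' @param config a \code{\link{ksg_config}}.
#' @return Transfer entropy estimate in the configured units.
#' @examples
#' cfg <- ksg_config(seed = 7)
#' x <- rnorm(500)
#' y <- c(0, 0.8 * x[-500]) + rnorm(500, sd = 0.5)
#' ksg_transfer_entropy(x, y, cfg) # positive: y copies x with lag 1
#' @export
ksg_transfer_entropy <- function(source, target, config = ksg_config()) {
  stopifnot(inherits(config, "ksg_config"))
  source <- as.numeric(source)
  target <- as.numeric(target)
  if (length(source) != length(target)) {
    stop("`source` and `target` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(source)) || any(!is.finite(target))) {
    stop("series contain non-finite values", call. = FALSE)
  }
  h <- max(config$history_target, config$history_source)
  min_len <- config$k_neighbors + h + 2L
  if (length(source) <= min_len) {
    stop(sprintf("series too short: need length > %d for k = %d, history %d",
                 min_len, config$k_neighbors, h), call. = FALSE)
  }
  ser <- jitter_series(list(source, target), config, config$seed)
  te_nats <- ksg_te_nats(ser[[1]], ser[[2]], config)
  if (config$units == "bits") te_nats / log(2) else te_nats
}

# Core estimate in nats on already-jittered series.
ksg_te_nats <- function(source, target, config) {
  ht <- config$history_target
  hs <- config$history_source
  h <- max(ht, hs)
  T <- length(target)
  idx <- h:(T - 1L)                  # present times with full history
  embed_past <- function(x, len) {
    vapply(seq_len(len) - 1L, function(lag) x[idx - lag], numeric(length(idx)))
  }
  x_future <- target[idx + 1L]
  Z <- embed_past(target, ht)
  Y <- embed_past(source, hs)
  .ksg_cmi_cpp(x_future, Y, Z, config$k_neighbors)
}

# Seeded micro-jitter: breaks exact distance ties in the neighbor
# search; amplitude 1e-8 x sd unless configured.
jitter_series <- function(series_list, config, seed) {
  with_local_seed(seed, lapply(series_list, function(s) {
    amp <- config$jitter_sd %||% (1e-8 * max(sd(s), .Machine$double.eps))
    s + rnorm(length(s), sd = amp)
  }))
}

#' Directed transfer-entropy matrix container
#'
#' @param values numeric n-by-n matrix; entry (i, j) is the TE from node
#'   i to node j. The diagonal must be exactly 0.
#' @param node_ids node labels (row/column order).
#' @param sparse_flag \code{TRUE} once negatives have been clipped; a
#'   sparse matrix must be entry-wise nonnegative.
#' @param units \code{"bits"} or \code{"nats"}.
#' @return An object of class \code{te_matrix}.
#' @export
te_matrix <- function(values, node_ids = rownames(values),
                      sparse_flag = FALSE, units = "bits") {
  check_matrix_finite(values, "values")
  n <- nrow(values)
  if (ncol(values) != n) stop("`values` must be square", call. = FALSE)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n || anyDuplicated(node_ids)) {
    stop("`node_ids` must be unique, one per row", call. = FALSE)
  }
  if (any(diag(values) != 0)) {
    stop("diagonal of a TE matrix must be exactly 0", call. = FALSE)
  }
  if (isTRUE(sparse_flag) && any(values < 0)) {
    stop("a sparse TE matrix cannot contain negative entries",
         call. = FALSE)
  }
  dimnames(values) <- list(node_ids, node_ids)
  structure(
    list(values = values, node_ids = node_ids,
         sparse_flag = isTRUE(sparse_flag), units = units),
    class = "te_matrix")
}

#' @export
print.te_matrix <- function(x, ...) {
  cat(sprintf("<te_matrix> %d nodes, %s, %s\n", length(x$node_ids),
              if (x$sparse_flag) "sparse (clipped)" else "full", x$units))
  invisible(x)
}

#' Full pairwise transfer-entropy matrix of a panel
#'
#' Estimates TE for every ordered node pair of the panel with
#' \code{\link{ksg_transfer_entropy}}. The diagonal (self-TE) is defined
#' as 0 and never estimated. Per-pair jitter seeds are derived from
#' \code{config$seed} by pair position, so the result is independent of
#' evaluation order and pair computations could run in parallel.
#'
#' @param panel a \code{\link{timeseries_panel}}.
#' @param config a \code{\link{ksg_config}}.
#' @return A full (unclipped) \code{\link{te_matrix}}; entries may be
#'   negative.
#' @export
build_te_matrix <- function(panel, config = ksg_config()) {
  stopifnot(inherits(panel, "timeseries_panel"),
            inherits(config, "ksg_config"))
  n <- nrow(panel$data)
  vals <- matrix(0, n, n)
  pair_seeds <- matrix(derive_seeds(config$seed, n * n), n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      est <- tryCatch({
        ser <- jitter_series(list(panel$data[i, ], panel$data[j, ]),
                             config, pair_seeds[i, j])
        te <- ksg_te_nats(ser[[1]], ser[[2]], config)
        if (config$units == "bits") te / log(2) else te
      }, error = function(e) {
        stop(sprintf("TE estimation failed for pair %s -> %s: %s",
                     panel$node_ids[i], panel$node_ids[j],
                     conditionMessage(e)), call. = FALSE)
      })
      vals[i, j] <- est
    }
  }
  te_matrix(vals, node_ids = panel$node_ids, sparse_flag = FALSE,
            units = config$units)
}

#' Clip negative transfer entropies to zero
#'
#' Negative TE estimates are finite-sample measurement error (the true
#' quantity is nonnegative), so they are set to 0; the result is the
#' sparse TE matrix used as the capacity (adjacency) matrix for the flow
#' computation. Idempotent.
#'
#' @param full a \code{\link{te_matrix}} with \code{sparse_flag = FALSE}
#'   (an already-sparse matrix passes through unchanged).
#' @return The sparse \code{\link{te_matrix}}.
#' @export
sparsify_te_matrix <- function(full) {
  stopifnot(inherits(full, "te_matrix"))
  te_matrix(pmax(full$values, 0), node_ids = full$node_ids,
            sparse_flag = TRUE, units = full$units)
}
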