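#' Node-to-group assignment scheme
#'
#' Maps every node to exactly one macroscale group. The standard brain
#' scheme has 20 groups: 10 lobes (prefrontal, motor, insula, parietal,
#' temporal, occipital, limbic, cerebellum, subcortical, brainstem) in
#' each hemisphere; see \code{\link{default_lobe_labels}}. Any covering
#' scheme is accepted.
#'
#' @param node_to_group named character vector: names are node ids,
#'   values are group ids.
#' @param group_ids optional ordered group-id vector; defaults to the
#'   sorted distinct groups. Every listed group must be nonempty.
#' @return An object of class \code{group_scheme}.
#' @export
group_scheme <- function(node_to_group, group_ids = NULL) {
  if (is.null(names(node_to_group)) || anyDuplicated(names(node_to_group))) {
    stop("`node_to_group` must be named by unique node ids", call. = FALSE)
  }
  node_to_group <- vapply(node_to_group, as.character, character(1))
  if (any(is.na(node_to_group)) || any(!nzchar(node_to_group))) {
    stop("every node must be assigned a group", call. = FALSE)
  }
  if (is.null(group_ids)) {
    group_ids <- sort(unique(unname(node_to_group)))
  } else {
    group_ids <- as.character(group_ids)
    if (anyDuplicated(group_ids)) stop("duplicated group ids", call. = FALSE)
    missing_g <- setdiff(unname(node_to_group), group_ids)
    if (length(missing_g)) {
      stop(sprintf("nodes mapped to undeclared group(s): %s",
                   paste(missing_g, collapse = ", ")), call. = FALSE)
    }
    empty <- setdiff(group_ids, unname(node_to_group))
    if (length(empty)) {
      stop(sprintf("empty group(s): %s", paste(empty, collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(list(node_to_group = node_to_group, group_ids = group_ids),
            class = "group_scheme")
}

#' @export
print.group_scheme <- function(x, ...) {
  cat(sprintf("<group_scheme> %d nodes in %d groups\n",
              length(x$node_to_group), length(x$group_ids)))
  invisible(x)
}

#' Standard hemisphere-by-lobe group labels
#'
#' The 20 group labels of the standard macroscale brain scheme:
#' \{L, R\} crossed with the 10 lobes.
#'
#' @return Character vector of 20 labels, hemisphere-major order.
#' @export
default_lobe_labels <- function() {
  lobes <- c("prefrontal", "motor", "insula", "parietal", "temporal",
             "occipital", "limbic", "cerebellum", "subcortical",
             "brainstem")
  as.vector(t(outer(c("L", "R"), lobes, paste, sep = "_")))
}

#' Directed capacity graph
#'
#' A set of directed edges with nonnegative capacities over a fixed node
#' list. Self-edges are forbidden; zero-capacity edges are dropped at
#' construction (they can never carry flow).
#'
#' @param nodes ordered character vector of node ids.
#' @param edges data frame with columns \code{from}, \code{to},
#'   \code{capacity}.
#' @return An object of class \code{capacity_graph}.
#' @export
capacity_graph <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicated node ids", call. = FALSE)
  edges <- as.data.frame(edges)
  if (!all(c("from", "to", "capacity") %in% names(edges))) {
    stop("`edges` needs columns from, to, capacity", call. = FALSE)
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  bad <- setdiff(c(edges$from, edges$to), nodes)
  if (length(bad)) {
    stop(sprintf("edge endpoint(s) not in node list: %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  if (any(edges$from == edges$to)) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  if (any(!is.finite(edges$capacity)) || any(edges$capacity < 0)) {
    stop("capacities must be finite and nonnegative", call. = FALSE)
  }
  edges <- edges[edges$capacity > 0, c("from", "to", "capacity"),
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "capacity_graph")
}

#' Capacity graph from a sparse TE matrix
#'
#' Interprets the sparse TE matrix as the adjacency matrix of a directed
#' graph: every strictly positive entry (i, j) becomes an edge i -> j
#' whose capacity is that transfer entropy (in bits).
#'
#' @param te_sparse a sparse \code{\link{te_matrix}}.
#' @return A \code{\link{capacity_graph}}.
#' @export
te_capacity_graph <- function(te_sparse) {
  stopifnot(inherits(te_sparse, "te_matrix"))
  if (!te_sparse$sparse_flag) {
    stop("capacities must come from a sparse (clipped) TE matrix; ",
         "call sparsify_te_matrix() first", call. = FALSE)
  }
  pos <- which(te_sparse$values > 0, arr.ind = TRUE)
  capacity_graph(
    te_sparse$node_ids,
    data.frame(from = te_sparse$node_ids[pos[, 1]],
               to = te_sparse$node_ids[pos[, 2]],
               capacity = te_sparse$values[pos]))
}

# igraph representation, cached construction point for repeated queries.
as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = length(graph$nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = graph$nodes)
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(
      g, rbind(match(graph$edges$from, graph$nodes),
               match(graph$edges$to, graph$nodes)))
    g <- igraph::set_edge_attr(g, "capacity", value = graph$edges$capacity)
  }
  g
}

#' Maximum flow between two nodes
#'
#' The largest amount routable from \code{source} to \code{sink} given
#' the edge capacities; by the max-flow/min-cut theorem this value
#' equals the capacity of the minimum source/sink cut and is unique even
#' though optimal flow assignments need not be.
#'
#' @param graph a \code{\link{capacity_graph}}.
#' @param source,sink node ids; must differ and be present in the graph.
#' @return Nonnegative flow value (same units as the capacities).
#' @examples
#' g <- capacity_graph(c("A", "B", "C"),
#'                     data.frame(from = c("A", "A", "B"),
#'                                to = c("C", "B", "C"),
#'                                capacity = c(2, 3, 3)))
#' max_flow_value(g, "A", "C") # 5: direct edge (2) plus the A->B->C path (3)
#' @export
max_flow_value <- function(graph, source, sink) {
  stopifnot(inherits(graph, "capacity_graph"))
  source <- as.character(source)
  sink <- as.character(sink)
  if (!source %in% graph$nodes) {
    stop(sprintf("source node '%s' not in graph", source), call. = FALSE)
  }
  if (!sink %in% graph$nodes) {
    stop(sprintf("sink node '%s' not in graph", sink), call. = FALSE)
  }
  if (source == sink) {
    stop("`source` and `sink` must differ", call. = FALSE)
  }
  if (!nrow(graph$edges) ||
      !any(graph$edges$from == source) || !any(graph$edges$to == sink)) {
    return(0)
  }
  max_flow_on_igraph(as_igraph(graph), graph$edges$capacity, source, sink)
}

# Same computation on a prebuilt igraph (used by the matrix drivers to
# avoid rebuilding the graph for every node pair).
max_flow_on_igraph <- function(g, caps, source, sink) {
  igraph::max_flow(g, source = source, target = sink,
                   capacity = caps)$value
}

#' Anatomically restricted edge set for one node pair
#'
#' When computing flow from node A to node C under the anatomical
#' restriction, only edges whose tail lies in A's group and whose head
#' lies in C's group are eligible. If both endpoints share a group the
#' edge set is all (positive-TE) edges inside that group.
#'
#' @param te_sparse sparse \code{\link{te_matrix}}.
#' @param scheme \code{\link{group_scheme}} covering all nodes.
#' @param source,sink node ids.
#' @return A \code{\link{capacity_graph}} on the union of the two groups'
#'   nodes containing only the eligible edges.
#' @export
restricted_edge_set <- function(te_sparse, scheme, source, sink) {
  stopifnot(inherits(te_sparse, "te_matrix"),
            inherits(scheme, "group_scheme"))
  check_scheme_covers(scheme, te_sparse$node_ids)
  source <- as.character(source)
  sink <- as.character(sink)
  if (!source %in% te_sparse$node_ids || !sink %in% te_sparse$node_ids) {
    stop("source/sink must be nodes of the TE matrix", call. = FALSE)
  }
  g_src <- scheme$node_to_group[[source]]
  g_snk <- scheme$node_to_group[[sink]]
  ids <- te_sparse$node_ids
  in_src <- ids[scheme$node_to_group[ids] == g_src]
  in_snk <- ids[scheme$node_to_group[ids] == g_snk]
  nodes <- union(in_src, in_snk)
  sub <- te_sparse$values[in_src, in_snk, drop = FALSE]
  pos <- which(sub > 0, arr.ind = TRUE)
  edges <- data.frame(from = in_src[pos[, 1]], to = in_snk[pos[, 2]],
                      capacity = sub[pos])
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  capacity_graph(nodes, edges)
}

check_scheme_covers <- function(scheme, node_ids) {
  missing_n <- setdiff(node_ids, names(scheme$node_to_group))
  if (length(missing_n)) {
    stop(sprintf("node(s) absent from group scheme: %s",
                 paste(missing_n, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Information-flow matrix container
#'
#' @param values nonnegative numeric matrix in bits: node-by-node for
#'   the full variants (zero diagonal) or group-by-group for the reduced
#'   variant (the diagonal holds within-group flow sums).
#' @param labels node or group ids.
#' @param variant \code{"full_unrestricted"}, \code{"full_restricted"}
#'   or \code{"reduced"}.
#' @return An object of class \code{if_matrix}.
#' @export
if_matrix <- function(values, labels = rownames(values),
                      variant = c("full_unrestricted", "full_restricted",
                                  "reduced")) {
  variant <- match.arg(variant)
  check_matrix_finite(values, "values")
  if (nrow(values) != ncol(values)) {
    stop("`values` must be square", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("information flow cannot be negative", call. = FALSE)
  }
  if (variant != "reduced" && any(diag(values) != 0)) {
    stop("full information-flow matrices have zero diagonal",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("n", seq_len(nrow(values)))
  labels <- as.character(labels)
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, variant = variant),
            class = "if_matrix")
}

#' @export
print.if_matrix <- function(x, ...) {
  cat(sprintf("<if_matrix> %s, %d x %d, total flow %.3f bits\n",
              x$variant, nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

#' Full information-flow matrix (max flow for every node pair)
#'
#' Entry (i, j) is the maximum flow from node i to node j over the
#' capacity graph defined by the sparse TE matrix -- either the whole
#' graph (\code{restricted = FALSE}) or, under the anatomical
#' restriction, only edges from i's group to j's group
#' (\code{\link{restricted_edge_set}}). The diagonal is 0. Pair
#' computations are independent, so the result does not depend on
#' evaluation order.
#'
#' @param te_sparse sparse \code{\link{te_matrix}}.
#' @param scheme \code{\link{group_scheme}}; required when
#'   \code{restricted = TRUE}.
#' @param restricted apply the anatomical edge restriction?
#' @return An \code{\link{if_matrix}} with variant
#'   \code{"full_restricted"} or \code{"full_unrestricted"}.
#' @export
compute_full_if_matrix <- function(te_sparse, scheme = NULL,
                                   restricted = FALSE) {
  stopifnot(inherits(te_sparse, "te_matrix"))
  if (!te_sparse$sparse_flag) {
    stop("flow requires the sparse TE matrix (negatives clipped)",
         call. = FALSE)
  }
  if (restricted && is.null(scheme)) {
    stop("`scheme` is required for the restricted variant", call. = FALSE)
  }
  ids <- te_sparse$node_ids
  n <- length(ids)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  if (any(te_sparse$values > 0)) {
    if (restricted) {
      out <- restricted_flow_matrix(te_sparse, scheme)
    } else {
      graph <- te_capacity_graph(te_sparse)
      g <- as_igraph(graph)
      caps <- graph$edges$capacity
      has_out <- ids %in% graph$edges$from
      has_in <- ids %in% graph$edges$to
      for (i in seq_len(n)) {
        if (!has_out[i]) next
        for (j in seq_len(n)) {
          if (i == j || !has_in[j]) next
          out[i, j] <- max_flow_on_igraph(g, caps, ids[i], ids[j])
        }
      }
    }
  }
  if_matrix(out, labels = ids,
            variant = if (restricted) "full_restricted"
                      else "full_unrestricted")
}

# Restricted variant: all node pairs with the same (source group, sink
# group) share one edge set, so one subgraph per ordered group pair is
# built and reused for all its node pairs.
restricted_flow_matrix <- function(te_sparse, scheme) {
  ids <- te_sparse$node_ids
  check_scheme_covers(scheme, ids)
  n <- length(ids)
  grp <- scheme$node_to_group[ids]
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (gx in unique(grp)) {
    for (gy in unique(grp)) {
      in_x <- which(grp == gx)
      in_y <- which(grp == gy)
      sub <- te_sparse$values[in_x, in_y, drop = FALSE]
      pos <- which(sub > 0, arr.ind = TRUE)
      edges <- data.frame(from = ids[in_x][pos[, 1]],
                          to = ids[in_y][pos[, 2]],
                          capacity = sub[pos])
      edges <- edges[edges$from != edges$to, , drop = FALSE]
      if (!nrow(edges)) next
      graph <- capacity_graph(union(ids[in_x], ids[in_y]), edges)
      g <- as_igraph(graph)
      caps <- graph$edges$capacity
      for (i in in_x) {
        if (!ids[i] %in% edges$from) next
        for (j in in_y) {
          if (i == j || !ids[j] %in% edges$to) next
          out[i, j] <- max_flow_on_igraph(g, caps, ids[i], ids[j])
        }
      }
    }
  }
  out
}

#' Reduce a full flow matrix over groups
#'
#' Group-level flow: entry (x, y) is the sum of the full-matrix flows
#' over all ordered node pairs with the source node in group x and the
#' sink node in group y (self-pairs excluded; the full matrix's diagonal
#' is zero). The result is directed -- flow from x to y generally
#' differs from flow from y to x -- and its diagonal holds the summed
#' within-group flows. With the standard 20-group scheme this reduces
#' the feature space from 71,824 node-pair cells to 400 group-pair
#' cells.
#'
#' @param if_full_restricted an \code{\link{if_matrix}} of variant
#'   \code{"full_restricted"}.
#' @param scheme \code{\link{group_scheme}} covering all nodes.
#' @return An \code{\link{if_matrix}} of variant \code{"reduced"} with
#'   one row/column per group, in \code{scheme$group_ids} order.
#' @export
reduce_if_matrix <- function(if_full_restricted, scheme) {
  stopifnot(inherits(if_full_restricted, "if_matrix"),
            inherits(scheme, "group_scheme"))
  if (if_full_restricted$variant != "full_restricted") {
    stop("reduction expects the anatomically restricted full matrix",
         call. = FALSE)
  }
  ids <- if_full_restricted$labels
  check_scheme_covers(scheme, ids)
  G <- outer(scheme$node_to_group[ids], scheme$group_ids, "==") * 1
  red <- t(G) %*% if_full_restricted$values %*% G
  if_matrix(red, labels = scheme$group_ids, variant = "reduced")
}

#' Flatten a reduced flow matrix into a feature vector
#'
#' Row-major flattening (all sink groups for the first source group,
#' then the second, ...), including the within-group diagonal, giving a
#' stable feature order shared by training and prediction. Labels are
#' \code{"<from>-><to>"}.
#'
#' @param reduced an \code{\link{if_matrix}} of variant \code{"reduced"}.
#' @return Named numeric vector of length \code{g^2}.
#' @export
flatten_reduced <- function(reduced) {
  stopifnot(inherits(reduced, "if_matrix"))
  if (reduced$variant != "reduced") {
    stop("expected a reduced flow matrix", call. = FALSE)
  }
  v <- as.vector(t(reduced$values))
  names(v) <- as.vector(t(outer(reduced$labels, reduced$labels, paste,
                                sep = "->")))
  v
}
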