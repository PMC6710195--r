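#' Time-series panel: one subject's node-by-time matrix
#'
#' The basic data container: rows are nodes (regions), columns are
#' timepoints. Values must be finite, node ids unique and aligned with
#' rows, and at least two nodes present.
#'
#' @param data numeric node-by-time matrix.
#' @param node_ids character vector, one id per row.
#' @param subject_id subject label (default \code{"s1"}).
#' @param condition one of \code{"task"}, \code{"rest"}, \code{"other"}.
#' @return An object of class \code{timeseries_panel}.
#' @export
timeseries_panel <- function(data, node_ids = rownames(data),
                             subject_id = "s1", condition = "other") {
  check_matrix_finite(data, "data")
  if (nrow(data) < 2L) stop("a panel needs at least 2 nodes", call. = FALSE)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(nrow(data)))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != nrow(data)) {
    stop("`node_ids` must have one entry per row of `data`", call. = FALSE)
  }
  if (anyDuplicated(node_ids)) {
    stop(sprintf("duplicated node id: '%s'",
                 node_ids[anyDuplicated(node_ids)]), call. = FALSE)
  }
  condition <- match.arg(condition, c("task", "rest", "other"))
  rownames(data) <- node_ids
  structure(
    list(subject_id = as.character(subject_id), condition = condition,
         data = data, node_ids = node_ids),
    class = "timeseries_panel")
}

#' @export
print.timeseries_panel <- function(x, ...) {
  cat(sprintf("<timeseries_panel> subject '%s' (%s): %d nodes x %d timepoints\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Average voxel time courses into node time courses
#'
#' Parcellation step: each node's time course is the unweighted mean of
#' the time courses of its constituent voxels. Nodes are emitted in
#' sorted id order.
#'
#' @param voxel_matrix numeric voxel-by-time matrix.
#' @param labels vector assigning each voxel (row) to a node id.
#' @param subject_id,condition metadata for the returned panel.
#' @return A \code{\link{timeseries_panel}} with one row per distinct label.
#' @export
parcellate <- function(voxel_matrix, labels, subject_id = "s1",
                       condition = "other") {
  check_matrix_finite(voxel_matrix, "voxel_matrix")
  labels <- as.character(labels)
  if (length(labels) != nrow(voxel_matrix)) {
    stop("`labels` must have one entry per voxel row", call. = FALSE)
  }
  nodes <- sort(unique(labels))
  empty <- setdiff(nodes, labels)
  if (length(empty)) {
    stop(sprintf("node(s) with zero voxels: %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  out <- t(vapply(nodes, function(nd) {
    colMeans(voxel_matrix[labels == nd, , drop = FALSE])
  }, numeric(ncol(voxel_matrix))))
  timeseries_panel(out, node_ids = nodes, subject_id = subject_id,
                   condition = condition)
}
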