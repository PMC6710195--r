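# Delimited-text interchange formats. Matrices and panels travel as
# tab-separated text with a label header row/column, preceded by "#"
# comment lines carrying units and producing parameters; numbers are
# written with 17 significant digits so round-trips are exact.

fmt_num <- function(x) sprintf("%.17g", x)

write_header_comments <- function(con, meta) {
  for (key in names(meta)) {
    writeLines(sprintf("# %s: %s", key, as.character(meta[[key]])), con)
  }
}

read_header_comments <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

#' Write / read a time-series panel as delimited text
#'
#' Format: optional \code{#} comment header (subject, condition, units),
#' then a tab-separated table whose header row is \code{node_id}
#' followed by timepoint indices and whose first column holds node ids.
#'
#' @param panel a \code{\link{timeseries_panel}}.
#' @param path file path.
#' @return \code{write_timeseries_panel} returns \code{path} invisibly;
#'   \code{read_timeseries_panel} returns a
#'   \code{\link{timeseries_panel}}.
#' @export
write_timeseries_panel <- function(panel, path) {
  stopifnot(inherits(panel, "timeseries_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  write_header_comments(con, list(
    subject = panel$subject_id, condition = panel$condition,
    units = "arbitrary"))
  writeLines(paste(c("node_id", seq_len(ncol(panel$data))),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(panel$data))) {
    writeLines(paste(c(panel$node_ids[i], fmt_num(panel$data[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_timeseries_panel
#' @export
read_timeseries_panel <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  meta <- read_header_comments(lines)
  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body_idx) < 3L) {
    stop("panel file needs a header row and at least 2 node rows",
         call. = FALSE)
  }
  parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  ncols <- length(parts[[1]])
  node_ids <- character(length(parts) - 1L)
  data <- matrix(NA_real_, length(parts) - 1L, ncols - 1L)
  for (r in seq_along(parts)[-1L]) {
    row <- parts[[r]]
    line_no <- body_idx[r]
    if (length(row) != ncols) {
      stop(sprintf("ragged row at line %d: %d fields, expected %d",
                   line_no, length(row), ncols), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(row[-1L]))
    if (any(is.na(vals))) {
      stop(sprintf("non-numeric cell at line %d", line_no), call. = FALSE)
    }
    node_ids[r - 1L] <- row[1L]
    data[r - 1L, ] <- vals
  }
  dup <- node_ids[duplicated(node_ids)]
  if (length(dup)) {
    stop(sprintf("duplicated node id: '%s'", dup[1]), call. = FALSE)
  }
  timeseries_panel(data, node_ids = node_ids,
                   subject_id = meta$subject %||% "s1",
                   condition = meta$condition %||% "other")
}

#' Write / read a labeled square matrix as delimited text
#'
#' \code{#} comment header (units plus caller-supplied parameters), then
#' a tab-separated table with a label header row and a label first
#' column. Values are written with full precision.
#'
#' @param values numeric matrix with dimnames, or a
#'   \code{\link{te_matrix}} / \code{\link{if_matrix}}.
#' @param path file path.
#' @param meta named list of extra header fields.
#' @return \code{write_matrix} returns \code{path} invisibly;
#'   \code{read_matrix} returns the labeled matrix with the header
#'   fields in \code{attr(, "meta")}.
#' @export
write_matrix <- function(values, path, meta = list()) {
  if (inherits(values, "te_matrix")) {
    meta <- c(list(type = "te_matrix", units = values$units,
                   sparse = values$sparse_flag), meta)
    values <- values$values
  } else if (inherits(values, "if_matrix")) {
    meta <- c(list(type = "if_matrix", units = "bits",
                   variant = values$variant), meta)
    values <- values$values
  }
  if (is.null(meta$units)) meta$units <- "bits"
  labels <- rownames(values) %||% paste0("n", seq_len(nrow(values)))
  con <- file(path, "w")
  on.exit(close(con))
  write_header_comments(con, meta)
  writeLines(paste(c("label", labels), collapse = "\t"), con)
  for (i in seq_len(nrow(values))) {
    writeLines(paste(c(labels[i], fmt_num(values[i, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  meta <- read_header_comments(lines)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  labels <- vapply(parts[-1L], `[[`, character(1), 1L)
  vals <- t(vapply(parts[-1L], function(r) as.numeric(r[-1L]),
                   numeric(length(parts[[1]]) - 1L)))
  dimnames(vals) <- list(labels, parts[[1L]][-1L])
  attr(vals, "meta") <- meta
  vals
}

#' Read a node-to-group scheme file
#'
#' Tab-separated text with a header line and columns \code{node_id},
#' \code{hemisphere}, \code{lobe} (extra columns rejected). Group ids
#' are formed as \code{hemisphere_lobe} and canonically sorted, so files
#' listing the same assignments in any order give identical schemes.
#'
#' @param path file path.
#' @return A \code{\link{group_scheme}}.
#' @export
read_group_scheme <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", comment.char = "#")
  expected <- c("node_id", "hemisphere", "lobe")
  if (!identical(sort(names(df)), sort(expected))) {
    stop(sprintf("scheme file must have exactly columns %s (got: %s)",
                 paste(expected, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  if (any(!nzchar(df$hemisphere)) || any(!nzchar(df$lobe)) ||
      any(is.na(df$hemisphere)) || any(is.na(df$lobe))) {
    stop("every node needs a hemisphere and a lobe entry", call. = FALSE)
  }
  if (anyDuplicated(df$node_id)) {
    stop(sprintf("node mapped twice: '%s'",
                 df$node_id[duplicated(df$node_id)][1]), call. = FALSE)
  }
  map <- stats::setNames(paste(df$hemisphere, df$lobe, sep = "_"),
                         df$node_id)
  map <- map[sort(names(map))]
  group_scheme(map, group_ids = sort(unique(unname(map))))
}

#' @rdname read_group_scheme
#' @param scheme a \code{\link{group_scheme}} whose group ids have the
#'   form \code{hemisphere_lobe}.
#' @export
write_group_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "group_scheme"))
  parts <- strsplit(unname(scheme$node_to_group), "_", fixed = TRUE)
  hemi <- vapply(parts, `[[`, character(1), 1L)
  lobe <- vapply(parts, function(p) paste(p[-1L], collapse = "_"),
                 character(1))
  df <- data.frame(node_id = names(scheme$node_to_group),
                   hemisphere = hemi, lobe = lobe)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a trained CPM model as JSON
#'
#' Plain-text schema holding the feature mask, PCA center and loadings,
#' regression coefficients, component count and the z-score reference
#' statistics, at full numeric precision.
#'
#' @param model a \code{\link{fit_cpm}} model.
#' @param path file path.
#' @return \code{write_cpm_model} returns \code{path} invisibly;
#'   \code{read_cpm_model} returns the restored \code{cpm_model}.
#' @export
write_cpm_model <- function(model, path) {
  stopifnot(inherits(model, "cpm_model"))
  obj <- list(
    schema = "infoflow_cpm_model_v1",
    feature_labels = model$feature_labels,
    selected_mask = unname(model$selected_mask),
    pca_center = unname(model$pca_center),
    pca_loadings = model$pca_loadings,
    n_components = model$n_components,
    regression_intercept = model$regression_intercept,
    regression_coefficients = model$regression_coefficients,
    train_pred_mean = model$train_pred_mean,
    train_pred_sd = model$train_pred_sd,
    selection_alpha = model$selection_alpha)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cpm_model
#' @export
read_cpm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "infoflow_cpm_model_v1")) {
    stop("not an infoflow CPM model file", call. = FALSE)
  }
  loadings <- matrix(obj$pca_loadings, nrow = obj$n_components)
  structure(
    list(selected_mask = stats::setNames(as.logical(obj$selected_mask),
                                         obj$feature_labels),
         pca_center = obj$pca_center,
         pca_loadings = loadings,
         n_components = as.integer(obj$n_components),
         regression_intercept = obj$regression_intercept,
         regression_coefficients = obj$regression_coefficients,
         train_pred_mean = obj$train_pred_mean,
         train_pred_sd = obj$train_pred_sd,
         selection_alpha = obj$selection_alpha,
         feature_labels = obj$feature_labels),
    class = "cpm_model")
}

#' Pipeline run configuration
#'
#' Bundles the parameters of a full run. An explicit seed is mandatory:
#' stochastic stages never fall back to a silent default.
#'
#' @param ksg a \code{\link{ksg_config}}.
#' @param scheme a \code{\link{group_scheme}}.
#' @param alpha Spearman selection threshold.
#' @param flow_variant \code{"reduced"}, \code{"full_restricted"} or
#'   \code{"full_unrestricted"}; which flow matrix supplies the features.
#' @param permutation_iterations permutations for the significance test
#'   (0 disables it).
#' @param seed integer seed; required.
#' @param output_dir directory for artifacts (created if absent).
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(ksg = ksg_config(), scheme, alpha = 0.05,
                       flow_variant = c("reduced", "full_restricted",
                                        "full_unrestricted"),
                       permutation_iterations = 1000L, seed, output_dir) {
  stopifnot(inherits(ksg, "ksg_config"), inherits(scheme, "group_scheme"))
  if (missing(seed)) {
    stop("an explicit `seed` is required", call. = FALSE)
  }
  check_scalar_number(seed, "seed", integer = TRUE)
  check_scalar_number(permutation_iterations, "permutation_iterations",
                      lower = 0, integer = TRUE)
  structure(
    list(ksg = ksg, scheme = scheme, alpha = alpha,
         flow_variant = match.arg(flow_variant),
         permutation_iterations = as.integer(permutation_iterations),
         seed = as.integer(seed), output_dir = output_dir),
    class = "run_config")
}

#' Run the full pipeline: panels to predictions
#'
#' For every subject panel: estimate the full TE matrix, clip it,
#' compute the configured information-flow variant, and flatten it into
#' features; then run leave-one-out internal validation of the CPM and
#' (optionally) the permutation test. All matrices, features,
#' predictions, the trained full-cohort model and a manifest (versions,
#' seed, parameters, md5 checksums of every artifact) are written under
#' \code{config$output_dir}.
#'
#' @param config a \code{\link{run_config}}.
#' @param panels list of \code{\link{timeseries_panel}}, one per subject.
#' @param behavior numeric score per subject, aligned with panels.
#' @return Invisibly, a list with \code{features}, \code{loocv},
#'   \code{permutation} (or NULL), \code{model} and \code{manifest}.
#' @export
run_pipeline <- function(config, panels, behavior) {
  stopifnot(inherits(config, "run_config"))
  if (!length(panels) || !all(vapply(panels, inherits, logical(1),
                                     "timeseries_panel"))) {
    stop("`panels` must be a non-empty list of timeseries_panel",
         call. = FALSE)
  }
  check_behavior(behavior, length(panels))
  out <- config$output_dir
  dir.create(file.path(out, "subjects"), recursive = TRUE,
             showWarnings = FALSE)
  scheme <- config$scheme
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage: %s] %s", what, conditionMessage(e)),
           call. = FALSE)
    })
  }

  sub_seeds <- derive_seeds(config$seed, length(panels) + 1L)
  feats <- NULL
  files <- character(0)
  for (s in seq_along(panels)) {
    p <- panels[[s]]
    sid <- p$subject_id
    sdir <- file.path(out, "subjects", sid)
    dir.create(sdir, showWarnings = FALSE)
    cfg <- config$ksg
    cfg$seed <- sub_seeds[s]
    te_full <- stage(sprintf("te (%s)", sid), build_te_matrix(p, cfg))
    te_sp <- sparsify_te_matrix(te_full)
    restricted <- config$flow_variant != "full_unrestricted"
    if_full <- stage(sprintf("flow (%s)", sid),
                     compute_full_if_matrix(
                       te_sp, scheme = if (restricted) scheme else NULL,
                       restricted = restricted))
    meta <- list(seed = cfg$seed, k_neighbors = cfg$k_neighbors,
                 history_target = cfg$history_target,
                 history_source = cfg$history_source)
    files <- c(files,
      write_matrix(te_full, file.path(sdir, "te_full.tsv"), meta),
      write_matrix(te_sp, file.path(sdir, "te_sparse.tsv"), meta))
    if (config$flow_variant == "reduced") {
      if_red <- stage(sprintf("reduce (%s)", sid),
                      reduce_if_matrix(if_full, scheme))
      files <- c(files,
        write_matrix(if_full, file.path(sdir, "if_full_restricted.tsv"),
                     meta),
        write_matrix(if_red, file.path(sdir, "if_reduced.tsv"), meta))
      v <- flatten_reduced(if_red)
    } else {
      files <- c(files,
        write_matrix(if_full, file.path(sdir, "if_full.tsv"), meta))
      v <- as.vector(t(if_full$values))
      names(v) <- as.vector(t(outer(if_full$labels, if_full$labels,
                                    paste, sep = "->")))
    }
    feats <- rbind(feats, v)
    rownames(feats)[nrow(feats)] <- sid
  }
  features <- cohort_features(feats)

  loocv <- stage("loocv", loocv_internal_validation(
    features, behavior, alpha = config$alpha))
  model <- stage("fit", fit_cpm(features, behavior, alpha = config$alpha))
  perm <- NULL
  if (config$permutation_iterations > 0) {
    perm <- stage("permutation", permutation_test(
      features, behavior, alpha = config$alpha,
      n_iterations = config$permutation_iterations,
      seed = sub_seeds[length(sub_seeds)]))
  }

  feat_path <- file.path(out, "features.tsv")
  write_matrix(features$features, feat_path,
               meta = list(units = "bits",
                           flow_variant = config$flow_variant))
  pred <- data.frame(subject = features$subjects, raw = loocv$raw,
                     z = loocv$z, behavior = behavior)
  pred_path <- file.path(out, "predictions.tsv")
  con <- file(pred_path, "w")
  write_header_comments(con, list(
    units = "z-score (raw in behavior units)", seed = config$seed,
    alpha = config$alpha, spearman_rho = fmt_num(loocv$rho)))
  close(con)
  suppressWarnings(write.table(pred, pred_path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  model_path <- file.path(out, "model.json")
  write_cpm_model(model, model_path)
  files <- c(files, feat_path, pred_path, model_path)

  manifest <- list(
    package = "infoflow",
    version = as.character(utils::packageVersion("infoflow")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = list(
      alpha = config$alpha, flow_variant = config$flow_variant,
      permutation_iterations = config$permutation_iterations,
      k_neighbors = config$ksg$k_neighbors,
      history_target = config$ksg$history_target,
      history_source = config$ksg$history_source,
      units = config$ksg$units),
    results = list(
      loocv_rho = loocv$rho,
      permutation_p = if (is.null(perm)) NULL else perm$p_value),
    files = as.list(tools::md5sum(sort(unname(files)))))
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(features = features, loocv = loocv, permutation = perm,
                 model = model, manifest = manifest))
}
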