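#' Cohort specification for synthetic subjects
#'
#' Describes a cohort whose behavior score is a noisy linear function of
#' designated cells of the reduced information-flow matrix. Each subject
#' is an independently perturbed copy of the template VAR model
#' (multiplicative Gaussian jitter of the coupling entries), which
#' creates the inter-subject flow variance that the predictive model can
#' exploit.
#'
#' @param n_subjects number of subjects (at least 3; leave-one-out
#'   validation needs at least that many).
#' @param panel_template a \code{\link{var_model}} shared by the cohort.
#' @param planted_weights group-by-group numeric matrix of weights: the
#'   noiseless behavior score is the weighted sum of the subject's
#'   reduced flow cells. All-zero weights give a null cohort.
#' @param behavior_noise_sd sd of the Gaussian noise added to the
#'   score; interpreted as an absolute sd, or as a multiple of the
#'   across-subject signal sd when \code{noise_relative = TRUE}.
#' @param noise_relative scale the noise sd by the realized signal sd?
#'   (default \code{FALSE}).
#' @param coupling_jitter_sd sd of the per-subject multiplicative
#'   coupling jitter (default 0.1, i.e. 10\%).
#' @param seed integer master seed for the whole cohort.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects, panel_template, planted_weights,
                        behavior_noise_sd = 0, noise_relative = FALSE,
                        coupling_jitter_sd = 0.1, seed) {
  check_scalar_number(n_subjects, "n_subjects", lower = 3, integer = TRUE)
  stopifnot(inherits(panel_template, "var_model"))
  check_matrix_finite(planted_weights, "planted_weights")
  if (nrow(planted_weights) != ncol(planted_weights)) {
    stop("`planted_weights` must be square (group x group)", call. = FALSE)
  }
  check_scalar_number(behavior_noise_sd, "behavior_noise_sd", lower = 0)
  check_scalar_number(coupling_jitter_sd, "coupling_jitter_sd", lower = 0)
  check_scalar_number(seed, "seed", integer = TRUE)
  structure(
    list(n_subjects = as.integer(n_subjects),
         panel_template = panel_template,
         planted_weights = planted_weights,
         behavior_noise_sd = behavior_noise_sd,
         noise_relative = isTRUE(noise_relative),
         coupling_jitter_sd = coupling_jitter_sd,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Simulate a subject cohort with a planted flow-behavior association
#'
#' For each subject: perturb the template coupling matrix, simulate a
#' panel, then run the real connectivity pipeline (KSG transfer-entropy
#' matrix, negative clipping, anatomically restricted max flow, group
#' reduction) to obtain the subject's reduced flow matrix. The behavior
#' score is the planted weighted sum of flow cells plus Gaussian noise.
#' Entirely reproducible from \code{spec$seed}.
#'
#' @param spec a \code{\link{cohort_spec}}; \code{planted_weights} must
#'   be group-by-group in \code{scheme$group_ids} order.
#' @param scheme \code{\link{group_scheme}} covering the template's
#'   nodes.
#' @param n_timepoints timepoints per subject panel.
#' @param config \code{\link{ksg_config}} used for TE estimation (its
#'   seed is rederived per subject from the cohort seed).
#' @param max_redraws attempts to rejitter a subject whose perturbed
#'   coupling loses stationarity (default 50).
#' @return An object of class \code{if_cohort}: list with \code{panels}
#'   (one \code{\link{timeseries_panel}} per subject), \code{behavior}
#'   (named numeric vector), \code{flows} (subject-by-feature matrix of
#'   flattened reduced flows, see \code{\link{flatten_reduced}}),
#'   \code{signal} (the noiseless scores) and \code{scheme}.
#' @export
simulate_cohort <- function(spec, scheme, n_timepoints,
                            config = ksg_config(), max_redraws = 50L) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(scheme, "group_scheme"))
  tmpl <- spec$panel_template
  check_scheme_covers(scheme, tmpl$node_ids)
  g <- length(scheme$group_ids)
  if (nrow(spec$planted_weights) != g) {
    stop(sprintf("`planted_weights` is %d x %d but the scheme has %d groups",
                 nrow(spec$planted_weights), ncol(spec$planted_weights), g),
         call. = FALSE)
  }
  n_sub <- spec$n_subjects
  seeds <- matrix(derive_seeds(spec$seed, 4L * n_sub), ncol = 4L)

  panels <- vector("list", n_sub)
  flows <- matrix(NA_real_, n_sub, g * g)
  for (s in seq_len(n_sub)) {
    model_s <- jitter_model(tmpl, spec$coupling_jitter_sd,
                            seeds[s, 1L], max_redraws)
    panels[[s]] <- simulate_var_panel(
      model_s, n_timepoints, seed = seeds[s, 2L],
      subject_id = sprintf("sub%03d", s), condition = "task")
    cfg_s <- config
    cfg_s$seed <- seeds[s, 3L]
    te_sp <- sparsify_te_matrix(build_te_matrix(panels[[s]], cfg_s))
    if_red <- reduce_if_matrix(
      compute_full_if_matrix(te_sp, scheme, restricted = TRUE), scheme)
    flows[s, ] <- flatten_reduced(if_red)
  }
  colnames(flows) <- as.vector(t(outer(scheme$group_ids, scheme$group_ids,
                                       paste, sep = "->")))
  rownames(flows) <- vapply(panels, `[[`, character(1), "subject_id")

  w <- as.vector(t(spec$planted_weights))   # row-major, matches flows
  signal <- as.vector(flows %*% w)
  noise_sd <- spec$behavior_noise_sd
  if (spec$noise_relative) noise_sd <- noise_sd * sd(signal)
  noise <- with_local_seed(seeds[1L, 4L], rnorm(n_sub, sd = noise_sd))
  behavior <- signal + noise
  names(behavior) <- rownames(flows)

  structure(
    list(panels = panels, behavior = behavior, flows = flows,
         signal = signal, scheme = scheme, spec = spec),
    class = "if_cohort")
}

#' @export
print.if_cohort <- function(x, ...) {
  cat(sprintf("<if_cohort> %d subjects, %d flow features\n",
              length(x$panels), ncol(x$flows)))
  invisible(x)
}

# Multiplicative Gaussian jitter of the coupling entries, redrawing
# until the perturbed model stays stationary.
jitter_model <- function(model, jitter_sd, seed, max_redraws) {
  if (jitter_sd == 0) return(model)
  sub_seeds <- derive_seeds(seed, max_redraws)
  for (a in seq_len(max_redraws)) {
    C <- with_local_seed(sub_seeds[a], {
      model$coupling * (1 + rnorm(length(model$coupling), sd = jitter_sd))
    })
    if (max(Mod(eigen(C, only.values = TRUE)$values)) < 0.98) {
      return(var_model(C, noise_sd = model$noise_sd,
                       node_ids = model$node_ids))
    }
  }
  stop("could not draw a stationary perturbed coupling matrix; ",
       "reduce `coupling_jitter_sd` or the template's spectral radius",
       call. = FALSE)
}

#' Feature container for a subject cohort
#'
#' Subject-by-feature matrix wrapper used by the predictive-modeling
#' layer; rows are subjects, columns are (typically) flattened reduced
#' flow cells.
#'
#' @param features numeric subject-by-feature matrix, no missing values.
#' @param subjects subject ids (default from rownames).
#' @param feature_labels feature labels (default from colnames).
#' @return An object of class \code{cohort_features}.
#' @export
cohort_features <- function(features, subjects = rownames(features),
                            feature_labels = colnames(features)) {
  check_matrix_finite(features, "features")
  if (nrow(features) < 3L) {
    stop("a cohort needs at least 3 subjects", call. = FALSE)
  }
  if (is.null(subjects)) subjects <- sprintf("sub%03d", seq_len(nrow(features)))
  if (is.null(feature_labels)) {
    feature_labels <- sprintf("f%d", seq_len(ncol(features)))
  }
  subjects <- as.character(subjects)
  feature_labels <- as.character(feature_labels)
  if (length(subjects) != nrow(features) || anyDuplicated(subjects)) {
    stop("`subjects` must be unique, one per row", call. = FALSE)
  }
  if (length(feature_labels) != ncol(features)) {
    stop("`feature_labels` must have one entry per column", call. = FALSE)
  }
  dimnames(features) <- list(subjects, feature_labels)
  structure(
    list(subjects = subjects, features = features,
         feature_labels = feature_labels),
    class = "cohort_features")
}

#' @rdname cohort_features
#' @param cohort an \code{\link{if_cohort}}.
#' @export
as_cohort_features <- function(cohort) {
  stopifnot(inherits(cohort, "if_cohort"))
  cohort_features(cohort$flows)
}
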