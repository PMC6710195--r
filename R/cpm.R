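# Connectome-based predictive modeling (CPM) over flow features:
# Spearman feature selection at a p threshold, PCA aggregation with the
# component count chosen by an inner leave-one-out loop, ordinary least
# squares on the component scores, and z-scored predictions whose
# reference population is the training subjects' own nested-LOOCV
# predictions.

# ---- rank-correlation internals ------------------------------------------

rank_cols <- function(X) {
  R <- apply(X, 2L, rank)
  if (!is.matrix(R)) R <- matrix(R, nrow = nrow(X))
  R
}

# Vectorized Spearman rho and two-sided asymptotic-t p-value of every
# column of `feat_ranks` (precomputed column ranks) against `y`.
# Constant columns yield NA.
spearman_cols <- function(feat_ranks, y) {
  n <- length(y)
  ry <- rank(y)
  ryc <- ry - mean(ry)
  deny <- sqrt(sum(ryc^2))
  Rc <- feat_ranks - (n + 1) / 2
  denx <- sqrt(colSums(Rc^2))
  rho <- as.vector(crossprod(Rc, ryc)) / (denx * deny)
  rho[!is.finite(rho)] <- NA_real_
  rho <- pmin(pmax(rho, -1), 1)
  tt <- abs(rho) * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-tt, df = n - 2)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p = p)
}

spearman_rho <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(rank(a), rank(b))
}

# ---- feature selection ----------------------------------------------------

#' Select behavior-correlated features
#'
#' A feature is retained iff the two-sided Spearman rank correlation
#' between its values and the behavior score is significant at
#' \code{alpha} (asymptotic t approximation). Constant features are
#' never selected.
#'
#' @param features \code{\link{cohort_features}} or subject-by-feature
#'   matrix.
#' @param behavior numeric score per subject, aligned with rows.
#' @param alpha selection threshold (default 0.05).
#' @return Logical mask, one entry per feature.
#' @export
select_features <- function(features, behavior, alpha = 0.05) {
  X <- feature_matrix(features)
  check_behavior(behavior, nrow(X))
  check_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  if (nrow(X) < 4L) {
    stop("feature selection needs at least 4 subjects", call. = FALSE)
  }
  sp <- spearman_cols(rank_cols(X), behavior)
  mask <- !is.na(sp$p) & sp$p <= alpha
  names(mask) <- colnames(X)
  mask
}

#' Exclude features correlated with nuisance covariates
#'
#' A feature is dropped iff it correlates (two-sided Spearman, same
#' approximation as \code{\link{select_features}}) with \emph{any}
#' covariate column at \code{alpha}. Used, e.g., to remove flows related
#' to head-motion summaries before behavioral selection.
#'
#' @param features \code{\link{cohort_features}} or matrix.
#' @param covariates subject-by-covariate numeric matrix aligned with
#'   the feature rows; zero columns mean no exclusion.
#' @param alpha exclusion threshold (default 0.05).
#' @return Logical keep-mask, one entry per feature.
#' @export
exclude_covariate_correlated <- function(features, covariates,
                                         alpha = 0.05) {
  X <- feature_matrix(features)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != nrow(X)) {
    stop("`covariates` rows must align with the feature rows",
         call. = FALSE)
  }
  keep <- rep(TRUE, ncol(X))
  if (ncol(covariates)) {
    fr <- rank_cols(X)
    for (k in seq_len(ncol(covariates))) {
      sp <- spearman_cols(fr, covariates[, k])
      keep <- keep & !(!is.na(sp$p) & sp$p <= alpha)
    }
  }
  names(keep) <- colnames(X)
  keep
}

# ---- component selection --------------------------------------------------

# Leave-one-out predictions for every candidate component count
# (compiled kernel); column c = predictions using c components.
cv_component_predictions <- function(X, y, cmax) {
  .cv_component_predictions_cpp(as.matrix(X), as.numeric(y),
                                as.integer(cmax))
}

#' Choose the PCA component count by inner leave-one-out validation
#'
#' For each candidate count c in 1..min(n_subjects - 1, n_features),
#' every subject is predicted by a PCA-plus-regression model fit on the
#' remaining subjects (feature set held fixed), and the candidate whose
#' leave-one-out predictions have the highest Spearman correlation with
#' the behavior score wins; ties go to the smallest count. Candidates
#' beyond the rank of a training block reuse its full-rank model.
#'
#' @param features selected-feature matrix (or
#'   \code{\link{cohort_features}}).
#' @param behavior numeric score per subject.
#' @return The chosen component count (positive integer).
#' @export
choose_n_components <- function(features, behavior) {
  X <- feature_matrix(features)
  check_behavior(behavior, nrow(X))
  if (nrow(X) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (ncol(X) < 1L) {
    stop("no selected features; relax the selection threshold",
         call. = FALSE)
  }
  cmax <- min(nrow(X) - 1L, ncol(X))
  P <- cv_component_predictions(X, behavior, cmax)
  scores <- apply(P, 2L, spearman_rho, b = behavior)
  scores[is.na(scores)] <- -Inf
  which.max(scores)   # first index at the maximum = smallest count
}

# ---- core fit -------------------------------------------------------------

# Fit the CPM stages on a feature matrix: selection -> component choice
# -> PCA (centered, unscaled) -> OLS on component scores; also the
# nested-LOOCV training predictions that define the z-score reference.
# `feat_ranks` may carry precomputed column ranks of X.
# empty_action: "error" rejects when no feature passes selection;
# "fallback" keeps the single best-ranked feature instead.
fit_cpm_core <- function(X, y, alpha, empty_action = "error",
                         feat_ranks = NULL, fixed_components = NULL) {
  n <- nrow(X)
  if (is.null(feat_ranks)) feat_ranks <- rank_cols(X)
  sp <- spearman_cols(feat_ranks, y)
  mask <- !is.na(sp$p) & sp$p <= alpha
  if (!any(mask)) {
    if (identical(empty_action, "fallback") && any(!is.na(sp$p))) {
      mask[which.min(sp$p)] <- TRUE
    } else {
      stop("no feature passed Spearman selection; relax `alpha` ",
           "(or use empty_action = \"fallback\")", call. = FALSE)
    }
  }
  Xs <- X[, mask, drop = FALSE]
  m <- ncol(Xs)
  cmax <- min(n - 1L, m)
  P <- cv_component_predictions(Xs, y, cmax)
  if (is.null(fixed_components)) {
    scores <- apply(P, 2L, spearman_rho, b = y)
    scores[is.na(scores)] <- -Inf
    n_comp <- which.max(scores)
  } else {
    n_comp <- min(as.integer(fixed_components), cmax)
  }

  mu <- colMeans(Xs)
  Xc <- sweep(Xs, 2L, mu)
  sv <- La.svd(Xc)
  tol <- sv$d[1] * 1e-10
  rank_f <- min(sum(sv$d > tol), n - 1L, m)
  c_use <- min(n_comp, rank_f)
  U <- sv$u[, seq_len(c_use), drop = FALSE]
  d <- sv$d[seq_len(c_use)]
  loadings <- sv$vt[seq_len(c_use), , drop = FALSE]  # components x features
  coef <- as.vector(crossprod(U, y)) / d
  train_pred <- P[, n_comp]

  list(mask = mask, n_components = c_use,
       pca_center = mu, pca_loadings = loadings,
       regression_intercept = mean(y), regression_coefficients = coef,
       train_pred = train_pred,
       train_pred_mean = mean(train_pred), train_pred_sd = sd(train_pred),
       selection_alpha = alpha)
}

predict_core <- function(core, Xnew) {
  Xc <- sweep(Xnew, 2L, core$pca_center)
  scores <- Xc %*% t(core$pca_loadings)
  as.vector(core$regression_intercept +
              scores %*% core$regression_coefficients)
}

#' Fit a CPM model on a training cohort
#'
#' Pipeline: optional covariate-based feature exclusion
#' (\code{\link{exclude_covariate_correlated}}), Spearman selection
#' (\code{\link{select_features}}), component-count choice by inner
#' leave-one-out validation (\code{\link{choose_n_components}}), then a
#' centered (unscaled) PCA of the selected features and an ordinary
#' least-squares regression of behavior on the component scores. The
#' z-score reference population (\code{train_pred_mean},
#' \code{train_pred_sd}) is formed by the leave-one-out predictions of
#' every training subject under the final feature mask and component
#' count, each fit without that subject.
#'
#' @param features \code{\link{cohort_features}} or subject-by-feature
#'   matrix.
#' @param behavior numeric score per subject.
#' @param alpha Spearman selection threshold (default 0.05).
#' @param covariates optional subject-by-covariate matrix for nuisance
#'   exclusion before selection.
#' @param empty_action what to do when no feature passes selection:
#'   \code{"error"} (default) or \code{"fallback"} (keep the single
#'   best-ranked feature).
#' @return An object of class \code{cpm_model} with fields
#'   \code{selected_mask}, \code{pca_center}, \code{pca_loadings}
#'   (components x selected features), \code{n_components},
#'   \code{regression_intercept}, \code{regression_coefficients},
#'   \code{train_pred_mean}, \code{train_pred_sd},
#'   \code{selection_alpha}, \code{feature_labels}.
#' @export
fit_cpm <- function(features, behavior, alpha = 0.05, covariates = NULL,
                    empty_action = c("error", "fallback")) {
  empty_action <- match.arg(empty_action)
  X <- feature_matrix(features)
  check_behavior(behavior, nrow(X))
  if (nrow(X) < 4L) stop("fitting needs at least 4 subjects", call. = FALSE)
  keep <- if (is.null(covariates)) rep(TRUE, ncol(X)) else
    exclude_covariate_correlated(X, covariates, alpha)
  if (!any(keep)) {
    stop("covariate exclusion removed every feature", call. = FALSE)
  }
  core <- fit_cpm_core(X[, keep, drop = FALSE], behavior, alpha,
                       empty_action)
  selected <- rep(FALSE, ncol(X))
  selected[which(keep)[core$mask]] <- TRUE
  labels <- colnames(X) %||% sprintf("f%d", seq_len(ncol(X)))
  structure(
    list(selected_mask = stats::setNames(selected, labels),
         pca_center = core$pca_center,
         pca_loadings = core$pca_loadings,
         n_components = core$n_components,
         regression_intercept = core$regression_intercept,
         regression_coefficients = core$regression_coefficients,
         train_pred_mean = core$train_pred_mean,
         train_pred_sd = core$train_pred_sd,
         selection_alpha = alpha,
         feature_labels = labels),
    class = "cpm_model")
}

#' @export
print.cpm_model <- function(x, ...) {
  cat(sprintf(paste0("<cpm_model> %d/%d features selected, %d component(s), ",
                     "z reference %.3f +/- %.3f\n"),
              sum(x$selected_mask), length(x$selected_mask),
              x$n_components, x$train_pred_mean, x$train_pred_sd))
  invisible(x)
}

#' Predict behavior scores with a frozen CPM model
#'
#' Applies the stored feature mask, PCA transform and regression
#' coefficients -- no refitting -- and z-scores the raw prediction
#' against the model's training-prediction population:
#' \code{z = (raw - train_pred_mean) / train_pred_sd}.
#'
#' @param model a \code{\link{fit_cpm}} model.
#' @param features feature vector, matrix or
#'   \code{\link{cohort_features}}; when labeled, columns are matched to
#'   the training feature labels (all must be present).
#' @return Data frame with columns \code{subject}, \code{raw}, \code{z}.
#' @export
predict_cpm <- function(model, features) {
  stopifnot(inherits(model, "cpm_model"))
  if (inherits(features, "cohort_features")) features <- features$features
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list("s1", names(features)))
  }
  features <- as.matrix(features)
  if (!is.null(colnames(features))) {
    miss <- setdiff(model$feature_labels, colnames(features))
    if (length(miss)) {
      stop(sprintf("missing feature label(s): %s",
                   paste(head(miss, 5), collapse = ", ")), call. = FALSE)
    }
    features <- features[, model$feature_labels, drop = FALSE]
  } else if (ncol(features) != length(model$feature_labels)) {
    stop("unlabeled features must match the training feature count",
         call. = FALSE)
  }
  Xs <- features[, model$selected_mask, drop = FALSE]
  core <- list(pca_center = model$pca_center,
               pca_loadings = model$pca_loadings,
               regression_intercept = model$regression_intercept,
               regression_coefficients = model$regression_coefficients)
  raw <- predict_core(core, Xs)
  if (!is.finite(model$train_pred_sd) || model$train_pred_sd <= 0) {
    stop("degenerate model: train_pred_sd must be positive", call. = FALSE)
  }
  data.frame(subject = rownames(features) %||% paste0("s", seq_along(raw)),
             raw = raw,
             z = (raw - model$train_pred_mean) / model$train_pred_sd,
             row.names = NULL)
}

# ---- leave-one-out validation --------------------------------------------

# Shared LOOCV engine. Per fold: refit the entire pipeline (selection,
# component choice, PCA, regression) on the other subjects, predict the
# left-out one. fold_ranks may carry precomputed per-fold feature ranks
# (they do not depend on the behavior vector, so the permutation test
# reuses them across iterations).
loocv_engine <- function(X, y, alpha, empty_action, fold_ranks = NULL,
                         fixed_components = NULL, want_z = TRUE,
                         want_details = FALSE) {
  n <- nrow(X)
  raw <- numeric(n)
  zs <- numeric(n)
  details <- if (want_details) vector("list", n) else NULL
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    core <- tryCatch(
      fit_cpm_core(Xtr, y[-i], alpha, empty_action,
                   feat_ranks = fold_ranks[[i]],
                   fixed_components = fixed_components),
      error = function(e) {
        stop(sprintf("fold %d (subject '%s'): %s", i,
                     rownames(X)[i] %||% i, conditionMessage(e)),
             call. = FALSE)
      })
    raw[i] <- predict_core(core, X[i, core$mask, drop = FALSE])
    if (want_z) {
      zs[i] <- (raw[i] - core$train_pred_mean) / core$train_pred_sd
    }
    if (want_details) details[[i]] <- c(core, list(train_index = setdiff(
      seq_len(n), i)))
  }
  rho <- spearman_rho(raw, y)
  list(raw = raw, z = if (want_z) zs else NULL, rho = rho,
       details = details)
}

#' Internal validation by leave-one-out cross-validation
#'
#' Each subject is predicted exactly once by a model trained without
#' them; the whole pipeline (covariate exclusion if requested, Spearman
#' selection, nested component choice, PCA, regression) is redone inside
#' every fold, so no information from the left-out subject reaches the
#' trained model. Predictions are additionally z-scored against each
#' fold's nested training predictions. The procedure is deterministic.
#'
#' @param features \code{\link{cohort_features}} or matrix.
#' @param behavior numeric score per subject.
#' @param alpha Spearman selection threshold (default 0.05).
#' @param covariates optional covariate matrix; exclusion is recomputed
#'   per fold from the training subjects only.
#' @param empty_action per-fold behavior when selection comes up empty:
#'   \code{"error"} (default; the run aborts naming the fold) or
#'   \code{"fallback"} (the fold keeps its single best-ranked feature).
#' @param return_details also return each fold's fitted parameters
#'   (mask, component count, transform, coefficients) for auditing.
#' @return List with \code{z}, \code{raw} (one prediction per subject,
#'   named), \code{rho} (Spearman correlation of predictions with
#'   behavior), and \code{details} when requested.
#' @export
loocv_internal_validation <- function(features, behavior, alpha = 0.05,
                                      covariates = NULL,
                                      empty_action = c("error", "fallback"),
                                      return_details = FALSE) {
  empty_action <- match.arg(empty_action)
  X <- feature_matrix(features)
  check_behavior(behavior, nrow(X))
  if (nrow(X) < 4L) stop("LOOCV needs at least 4 subjects", call. = FALSE)
  n <- nrow(X)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) {
      stop("`covariates` rows must align with subjects", call. = FALSE)
    }
    # fold-specific exclusion, then pooled engine call per fold
    raw <- numeric(n); zs <- numeric(n)
    details <- if (return_details) vector("list", n) else NULL
    for (i in seq_len(n)) {
      keep <- exclude_covariate_correlated(X[-i, , drop = FALSE],
                                           covariates[-i, , drop = FALSE],
                                           alpha)
      if (!any(keep)) {
        stop(sprintf("fold %d: covariate exclusion removed every feature", i),
             call. = FALSE)
      }
      core <- fit_cpm_core(X[-i, keep, drop = FALSE], behavior[-i], alpha,
                           empty_action)
      raw[i] <- predict_core(core, X[i, keep, drop = FALSE][, core$mask,
                                                            drop = FALSE])
      zs[i] <- (raw[i] - core$train_pred_mean) / core$train_pred_sd
      if (return_details) {
        details[[i]] <- c(core, list(keep_mask = keep,
                                     train_index = setdiff(seq_len(n), i)))
      }
    }
    res <- list(raw = raw, z = zs, rho = spearman_rho(raw, behavior),
                details = details)
  } else {
    res <- loocv_engine(X, behavior, alpha, empty_action,
                        want_details = return_details)
  }
  names(res$raw) <- rownames(X)
  if (!is.null(res$z)) names(res$z) <- rownames(X)
  res
}

#' Permutation test of the LOOCV prediction performance
#'
#' Repeatedly permutes the behavior scores across subjects, reruns the
#' full prediction pipeline (selection, component choice, LOOCV) on each
#' permuted cohort, and reports
#' \deqn{p = \frac{1 + \#\{\rho_{perm} \ge \rho_{obs}\}}{1 + B}}
#' (one-sided in the direction of the trained association;
#' \code{alternative = "two.sided"} compares absolute values). The
#' add-one correction keeps p away from zero at finite B. Reproducible
#' given \code{seed}.
#'
#' @param features \code{\link{cohort_features}} or matrix.
#' @param behavior numeric score per subject.
#' @param alpha Spearman selection threshold (default 0.05).
#' @param n_iterations number of permutations B (at least 100 advised
#'   for reporting).
#' @param seed integer seed for the permutations.
#' @param empty_action per-fold empty-selection handling; default
#'   \code{"fallback"} so that null permutations (where often nothing
#'   passes selection) remain scoreable and exchangeable with the
#'   observed statistic, which is computed under the same rule.
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}.
#' @param component_selection \code{"nested"} (default; the component
#'   count is rechosen inside every fold of every permutation) or
#'   \code{"fixed"} (reuse \code{n_components}).
#' @param n_components component count when
#'   \code{component_selection = "fixed"}.
#' @return List with \code{p_value}, \code{observed_rho},
#'   \code{permuted_rho} (length B) and \code{n_iterations}.
#' @export
permutation_test <- function(features, behavior, alpha = 0.05,
                             n_iterations = 1000L, seed,
                             empty_action = c("fallback", "error"),
                             alternative = c("greater", "two.sided"),
                             component_selection = c("nested", "fixed"),
                             n_components = NULL) {
  empty_action <- match.arg(empty_action)
  alternative <- match.arg(alternative)
  component_selection <- match.arg(component_selection)
  X <- feature_matrix(features)
  check_behavior(behavior, nrow(X))
  check_scalar_number(n_iterations, "n_iterations", lower = 1,
                      integer = TRUE)
  n <- nrow(X)
  fixed <- if (component_selection == "fixed") {
    if (is.null(n_components)) {
      stop("`n_components` required when component_selection = \"fixed\"",
           call. = FALSE)
    }
    as.integer(n_components)
  } else NULL
  # per-fold feature ranks are behavior-independent: compute once
  fold_ranks <- lapply(seq_len(n), function(i) {
    rank_cols(X[-i, , drop = FALSE])
  })
  obs <- loocv_engine(X, behavior, alpha, empty_action,
                      fold_ranks = fold_ranks, fixed_components = fixed,
                      want_z = FALSE)$rho
  perms <- with_local_seed(seed, {
    replicate(n_iterations, sample.int(n), simplify = FALSE)
  })
  perm_rho <- vapply(perms, function(pp) {
    loocv_engine(X, behavior[pp], alpha, empty_action,
                 fold_ranks = fold_ranks, fixed_components = fixed,
                 want_z = FALSE)$rho
  }, numeric(1))
  perm_rho[is.na(perm_rho)] <- 0
  obs_cmp <- if (is.na(obs)) 0 else obs
  extreme <- if (alternative == "greater") perm_rho >= obs_cmp
             else abs(perm_rho) >= abs(obs_cmp)
  list(p_value = (1 + sum(extreme)) / (1 + n_iterations),
       observed_rho = obs, permuted_rho = perm_rho,
       n_iterations = as.integer(n_iterations))
}

#' Apply a model trained on one cohort to an external cohort
#'
#' Fits the CPM once on the full training cohort (no test-set
#' information enters any stage) and predicts each external subject with
#' the frozen model; the z-scores are relative to the training cohort's
#' nested-LOOCV prediction population.
#'
#' @param train_features,train_behavior training cohort.
#' @param test_features external cohort features (labels must match the
#'   training labels).
#' @param test_behavior optional external scores; when given with more
#'   than one subject, the Spearman correlation between predictions and
#'   scores is reported.
#' @param alpha Spearman selection threshold (default 0.05).
#' @param covariates optional training-cohort covariates.
#' @return List with \code{predictions} (data frame: subject, raw, z),
#'   \code{rho} (or NA), and the fitted \code{model}.
#' @export
external_validation <- function(train_features, train_behavior,
                                test_features, test_behavior = NULL,
                                alpha = 0.05, covariates = NULL) {
  model <- fit_cpm(train_features, train_behavior, alpha = alpha,
                   covariates = covariates)
  preds <- predict_cpm(model, test_features)
  rho <- NA_real_
  if (!is.null(test_behavior) && length(test_behavior) > 1L) {
    if (length(test_behavior) != nrow(preds)) {
      stop("`test_behavior` must align with the test subjects",
           call. = FALSE)
    }
    rho <- spearman_rho(preds$z, test_behavior)
  }
  list(predictions = preds, rho = rho, model = model)
}

# ---- shared checks --------------------------------------------------------

feature_matrix <- function(features) {
  if (inherits(features, "cohort_features")) return(features$features)
  check_matrix_finite(as.matrix(features), "features")
}

check_behavior <- function(behavior, n) {
  if (!is.numeric(behavior) || length(behavior) != n ||
      any(!is.finite(behavior))) {
    stop("`behavior` must be a finite numeric vector aligned with subjects",
         call. = FALSE)
  }
  invisible(behavior)
}
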