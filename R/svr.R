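#' SVR hyperparameters
#'
#' Linear epsilon-insensitive support vector regression with box constraint
#' C = 1 and epsilon set per fit to IQR(response)/13.49 — the divisor
#' (about 2 x 0.6745) turns the interquartile range into a robust estimate of
#' twice the residual sigma. `gamma` is recorded for fidelity to the original
#' configuration but has no effect under a linear kernel; a note is logged
#' once per session when a model is fit.
#'
#' @param box_constraint positive regularization constant C (default 1).
#' @param epsilon fixed epsilon, or NULL (default) to apply the IQR rule per
#'   training set.
#' @param gamma inert under the linear kernel; recorded only.
#' @return An `svr_hyperparams` list.
#' @export
svr_hyperparams <- function(box_constraint = 1, epsilon = NULL, gamma = 1) {
  if (!is.numeric(box_constraint) || box_constraint <= 0) {
    stop("`box_constraint` must be positive", call. = FALSE)
  }
  if (!is.null(epsilon) && (!is.numeric(epsilon) || epsilon < 0)) {
    stop("`epsilon` must be nonnegative or NULL (IQR rule)", call. = FALSE)
  }
  structure(list(box_constraint = box_constraint, epsilon = epsilon,
                 kernel = "linear", gamma = gamma),
            class = "svr_hyperparams")
}

#' Epsilon from the response interquartile range
#'
#' `IQR(response) / 13.49`, with quantiles computed by linear interpolation
#' between order statistics (R type 7). A constant response gives epsilon 0
#' with a warning.
#'
#' @param response numeric vector, length >= 2.
#' @return nonnegative scalar.
#' @export
compute_epsilon <- function(response) {
  if (length(response) < 2L || anyNA(response)) {
    stop("`response` needs >= 2 non-missing values", call. = FALSE)
  }
  iqr <- stats::IQR(response, type = 7)
  if (iqr == 0) {
    warning("constant response: epsilon set to 0", call. = FALSE)
  }
  iqr / 13.49
}

.gamma_note_logged <- new.env(parent = emptyenv())

#' Fit linear epsilon-insensitive SVR
#'
#' Solves the epsilon-insensitive SVR problem with a linear kernel (via the
#' libsvm solver in e1071, deterministic for fixed inputs) and extracts the
#' primal weights and intercept, which reproduce the solver's decision
#' function to within 1e-6. Inputs are used as given: scaling is the caller's
#' responsibility (see [minmax_scale()] and [loocv_predict()]).
#'
#' @param x numeric predictor matrix (no missing entries, >= 2 rows).
#' @param y numeric response.
#' @param hyperparams an [svr_hyperparams()].
#' @return A `fitted_model`: `weights`, `intercept`, `epsilon_used`,
#'   `hyperparams`, `column_names`.
#' @export
fit_svr <- function(x, y, hyperparams = svr_hyperparams()) {
  stopifnot(is.matrix(x), inherits(hyperparams, "svr_hyperparams"))
  if (nrow(x) < 2L) {
    stop("cannot fit SVR on fewer than 2 cases", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y) || length(y) != nrow(x)) {
    stop("`x`/`y` must be complete and conformable", call. = FALSE)
  }
  if (!identical(hyperparams$gamma, 1) &&
      is.null(.gamma_note_logged$done)) {
    message("note: `gamma` is recorded but inert under the linear kernel")
    .gamma_note_logged$done <- TRUE
  }
  eps <- if (is.null(hyperparams$epsilon)) compute_epsilon(y) else
    hyperparams$epsilon
  fit <- e1071::svm(x, y, type = "eps-regression", kernel = "linear",
                    cost = hyperparams$box_constraint, epsilon = eps,
                    scale = FALSE)
  if (is.null(fit$coefs) || nrow(fit$coefs) == 0L) {
    w <- numeric(ncol(x))
  } else {
    w <- drop(t(fit$coefs) %*% fit$SV)
  }
  # recover the intercept from the solver's own decision function
  b <- mean(stats::predict(fit, x) - drop(x %*% w))
  structure(
    list(weights = stats::setNames(as.numeric(w), colnames(x)),
         intercept = b, epsilon_used = eps, hyperparams = hyperparams,
         column_names = colnames(x), n_train = nrow(x)),
    class = "fitted_model"
  )
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("<fitted_model> linear SVR, ", length(x$weights), " weights, C = ",
      x$hyperparams$box_constraint, ", epsilon = ",
      signif(x$epsilon_used, 4), "\n", sep = "")
  invisible(x)
}

#' Predict with range capping
#'
#' Raw linear predictions `x %*% w + b` clamped to the score range \[0, 10\].
#'
#' @param model a `fitted_model`.
#' @param x predictor matrix with the model's columns.
#' @return numeric predictions in \[0, 10\].
#' @export
predict_capped <- function(model, x) {
  stopifnot(inherits(model, "fitted_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$weights)) {
    stop("predictor width (", ncol(x), ") does not match model (",
         length(model$weights), ")", call. = FALSE)
  }
  raw <- drop(x %*% model$weights) + model$intercept
  pmin(pmax(raw, 0), 10)
}

#' Leave-one-out cross-validated predictions for one model cell
#'
#' Each case is held out in turn and its score predicted from a model fit on
#' the remaining cases. Min-max scaling parameters and the epsilon rule are
#' recomputed on each training fold, so no statistic of the held-out case's
#' response or features influences its own model. Predictions are capped to
#' \[0, 10\].
#'
#' @param cohort an `mlsm_cohort`, or a pre-built `feature_matrix`.
#' @param outcome,timepoint,family cell identity (ignored when `cohort` is a
#'   `feature_matrix`).
#' @param hyperparams an [svr_hyperparams()].
#' @return A `cv_prediction_set` data.frame: `patient_id`, `observed`,
#'   `predicted`, `outcome`, `timepoint`, `family`.
#' @export
loocv_predict <- function(cohort, outcome = NULL, timepoint = NULL,
                          family = NULL, hyperparams = svr_hyperparams()) {
  fm <- if (inherits(cohort, "feature_matrix")) cohort else
    assemble_features(cohort, outcome, timepoint, family)
  n <- nrow(fm$x)
  if (n < 3L) {
    stop("leave-one-out evaluation needs >= 3 eligible cases (got ", n, ")",
         call. = FALSE)
  }
  pred <- numeric(n)
  for (i in seq_len(n)) {
    sc <- minmax_scale(fm$x[-i, , drop = FALSE],
                       newdata = fm$x[i, , drop = FALSE],
                       cols = fm$scale_cols)
    model <- suppressWarnings(
      fit_svr(sc$train, fm$response[-i], hyperparams))
    pred[i] <- predict_capped(model, sc$newdata)
  }
  structure(
    data.frame(patient_id = fm$patient_ids, observed = fm$response,
               predicted = pred, outcome = fm$outcome,
               timepoint = fm$timepoint, family = fm$family,
               stringsAsFactors = FALSE),
    class = c("cv_prediction_set", "data.frame")
  )
}

#' Fit one model cell on all eligible cases
#'
#' Full-sample refit used for feature-weight mapping (not for accuracy
#' claims): scaling and epsilon are computed on the complete eligible case
#' set. The returned model is tagged `refit = "full_sample"` so downstream
#' weight maps carry their provenance.
#'
#' @inheritParams loocv_predict
#' @return A `fitted_model` with scaling parameters and cell identity
#'   attached.
#' @export
fit_family_model <- function(cohort, outcome, timepoint, family,
                             hyperparams = svr_hyperparams()) {
  fm <- if (inherits(cohort, "feature_matrix")) cohort else
    assemble_features(cohort, outcome, timepoint, family)
  sc <- minmax_scale(fm$x, cols = fm$scale_cols)
  model <- fit_svr(sc$train, fm$response, hyperparams)
  model$scaling <- sc$params
  model$outcome <- fm$outcome
  model$timepoint <- fm$timepoint
  model$family <- fm$family
  model$llv_cols <- fm$llv_cols
  model$refit <- "full_sample"
  model
}
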