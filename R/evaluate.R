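#' Prediction r-squared
#'
#' `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`: the improvement of
#' the out-of-sample predictions over simply guessing the mean of the
#' observed values in the evaluated set. Unlike a squared correlation it is
#' penalised for bias and scale errors and can be negative when the model
#' underperforms the mean predictor — which epsilon-insensitive SVR can do
#' when predictors are uninformative.
#'
#' @param observed,predicted equal-length numeric vectors (>= 2 values).
#' @return scalar, at most 1, possibly negative.
#' @export
prediction_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop("`observed` and `predicted` must be equal-length, >= 2", call. = FALSE)
  }
  if (anyNA(observed) || anyNA(predicted)) {
    stop("missing values in predictions", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("prediction r^2 undefined: observed values are constant",
         call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Root mean squared error
#'
#' @inheritParams prediction_r2
#' @return nonnegative scalar, in score units.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1L) {
    stop("`observed` and `predicted` must be equal-length, >= 1", call. = FALSE)
  }
  sqrt(mean((observed - predicted)^2))
}

#' Summarise one cross-validated prediction set
#'
#' @param cvset a `cv_prediction_set` from [loocv_predict()].
#' @return one-row data.frame: cell identity, `n`, `prediction_r2`, `rmse`,
#'   `low_n` flag (n < 10).
#' @export
evaluate_predictions <- function(cvset) {
  stopifnot(inherits(cvset, "cv_prediction_set"))
  data.frame(
    outcome = cvset$outcome[1], timepoint = cvset$timepoint[1],
    family = cvset$family[1], n = nrow(cvset),
    prediction_r2 = prediction_r2(cvset$observed, cvset$predicted),
    rmse = rmse(cvset$observed, cvset$predicted),
    low_n = nrow(cvset) < 10L,
    stringsAsFactors = FALSE
  )
}

#' Build the model-family x outcome x timepoint comparison grid
#'
#' Runs a fresh leave-one-out evaluation for every requested cell. Cells that
#' cannot be computed are kept in the grid with a machine-readable status:
#' `"skipped"` for structurally undefined cells (initial-presentation
#' families at the acute timepoint) and `"error"` for per-cell failures
#' (e.g. no eligible cases); neither aborts the remaining cells. The
#' improvement count — in how many (outcome, timepoint) cells the LLV-bearing
#' family beats its no-LLV reduction — is available via
#' [improvement_count()].
#'
#' @param cohort an `mlsm_cohort`.
#' @param families,outcomes,timepoints subsets of the closed vocabularies.
#' @param hyperparams an [svr_hyperparams()].
#' @param keep_predictions logical; attach the per-cell prediction sets as
#'   an attribute.
#' @param verbose logical; log one line per cell (stage, cell identity,
#'   case count).
#' @return A `comparison_grid` data.frame with columns `outcome`,
#'   `timepoint`, `family`, `status`, `reason`, `n`, `prediction_r2`,
#'   `rmse`, `low_n`.
#' @export
build_comparison_grid <- function(cohort,
                                  families = c("llv", "reduced_no_llv",
                                               "reduced_no_llv_no_extent"),
                                  outcomes = mlsm_outcomes(),
                                  timepoints = mlsm_timepoints(),
                                  hyperparams = svr_hyperparams(),
                                  keep_predictions = FALSE,
                                  verbose = FALSE) {
  families <- match.arg(families, mlsm_families(), several.ok = TRUE)
  outcomes <- match.arg(outcomes, mlsm_outcomes(), several.ok = TRUE)
  timepoints <- match.arg(timepoints, mlsm_timepoints(), several.ok = TRUE)
  cells <- expand.grid(outcome = outcomes, timepoint = timepoints,
                       family = families, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  preds <- if (keep_predictions) vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    cell <- cells[k, ]
    base <- data.frame(outcome = cell$outcome, timepoint = cell$timepoint,
                       family = cell$family, status = "ok", reason = NA_character_,
                       n = NA_integer_, prediction_r2 = NA_real_,
                       rmse = NA_real_, low_n = NA, stringsAsFactors = FALSE)
    if (family_has_ip(cell$family) && cell$timepoint == "acute") {
      base$status <- "skipped"
      base$reason <- "ip_undefined_at_acute"
      rows[[k]] <- base
      next
    }
    res <- tryCatch({
      cv <- loocv_predict(cohort, cell$outcome, cell$timepoint, cell$family,
                          hyperparams = hyperparams)
      if (keep_predictions) preds[[k]] <- cv
      ev <- evaluate_predictions(cv)
      base[c("n", "prediction_r2", "rmse", "low_n")] <-
        ev[c("n", "prediction_r2", "rmse", "low_n")]
      base
    }, error = function(e) {
      base$status <- "error"
      base$reason <- conditionMessage(e)
      base
    })
    if (verbose) {
      message(sprintf("[grid] %s @ %s [%s]: %s (n = %s)", cell$outcome,
                      cell$timepoint, cell$family, res$status,
                      ifelse(is.na(res$n), "-", res$n)))
    }
    rows[[k]] <- res
  }
  grid <- do.call(rbind, rows)
  class(grid) <- c("comparison_grid", "data.frame")
  if (keep_predictions) {
    attr(grid, "predictions") <- do.call(rbind, preds[!vapply(preds, is.null,
                                                              logical(1))])
  }
  grid
}

#' Count cells where lesion location improves prediction
#'
#' Pairs each LLV-bearing family with its no-LLV reduction (`llv` vs
#' `reduced_no_llv`, `llv_ip` vs `reduced_no_llv_ip`) within each (outcome,
#' timepoint) cell and counts how often the LLV family achieves the higher
#' prediction r-squared.
#'
#' @param grid a `comparison_grid`.
#' @return list with `improved`, `total` and the per-cell comparison table.
#' @export
improvement_count <- function(grid) {
  stopifnot(inherits(grid, "comparison_grid"))
  pairs <- list(c("llv", "reduced_no_llv"), c("llv_ip", "reduced_no_llv_ip"))
  comp <- list()
  for (p in pairs) {
    full <- grid[grid$family == p[1] & grid$status == "ok", ]
    red <- grid[grid$family == p[2] & grid$status == "ok", ]
    if (!nrow(full) || !nrow(red)) next
    m <- merge(full[c("outcome", "timepoint", "prediction_r2")],
               red[c("outcome", "timepoint", "prediction_r2")],
               by = c("outcome", "timepoint"),
               suffixes = c("_llv", "_reduced"))
    if (!nrow(m)) next
    m$family_pair <- paste(p, collapse = " vs ")
    m$improved <- m$prediction_r2_llv > m$prediction_r2_reduced
    comp[[length(comp) + 1L]] <- m
  }
  comp <- if (length(comp)) do.call(rbind, comp) else
    data.frame(improved = logical())
  list(improved = sum(comp$improved), total = nrow(comp), cells = comp)
}
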