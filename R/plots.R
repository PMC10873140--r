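#' Observed-versus-predicted scatter for one model cell
#'
#' Observed scores against out-of-sample predictions with the identity line;
#' perfect prediction falls on the diagonal.
#'
#' @param cvset a `cv_prediction_set`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the cvset.
#' @export
plot_predictions <- function(cvset, ...) {
  stopifnot(inherits(cvset, "cv_prediction_set"))
  r2 <- prediction_r2(cvset$observed, cvset$predicted)
  graphics::plot(cvset$predicted, cvset$observed, xlim = c(0, 10),
                 ylim = c(0, 10), xlab = "Predicted score",
                 ylab = "Observed score",
                 main = sprintf("%s @ %s [%s]  n = %d, prediction r2 = %.2f",
                                cvset$outcome[1], cvset$timepoint[1],
                                cvset$family[1], nrow(cvset), r2), ...)
  graphics::abline(0, 1, col = "grey60")
  invisible(cvset)
}

#' Grouped prediction-r2 bars across timepoints and families
#'
#' One group of bars per timepoint, one bar per model family, for a single
#' outcome — the standard layout for comparing nested predictor sets (the
#' no-LLV reductions against the full lesion-load models).
#'
#' @param grid a `comparison_grid`.
#' @param outcome outcome to display.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the plotted matrix of r2 values.
#' @export
plot_grid_bars <- function(grid, outcome = "overall", ...) {
  stopifnot(inherits(grid, "comparison_grid"))
  g <- grid[grid$outcome == outcome & grid$status == "ok", ]
  if (!nrow(g)) stop("no evaluated cells for outcome ", outcome, call. = FALSE)
  fams <- intersect(mlsm_families(), unique(g$family))
  tps <- intersect(mlsm_timepoints(), unique(g$timepoint))
  m <- matrix(NA_real_, length(fams), length(tps),
              dimnames = list(fams, tps))
  for (i in seq_len(nrow(g))) m[g$family[i], g$timepoint[i]] <- g$prediction_r2[i]
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "prediction r2", xlab = "timepoint",
                    main = outcome, ...)
  invisible(m)
}
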