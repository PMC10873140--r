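#' Tabulate model feature weights with their ROI linkage
#'
#' Extracts every coefficient of a full-sample refit (see
#' [fit_family_model()]) into a table flagging the lesion-load columns and
#' linking each to its atlas label. The model's LLV columns must match the
#' atlas `roi_table` one-to-one and in order.
#'
#' @param model a `fitted_model` from an LLV-bearing family.
#' @param atlas the `atlas_definition` the model's LLVs were computed from.
#' @return A `weight_table` data.frame: `column_name`, `weight`, `is_llv`,
#'   `roi_label` (NA for non-LLV columns), with the refit provenance in
#'   `attr(, "refit")`.
#' @export
extract_weights <- function(model, atlas) {
  stopifnot(inherits(model, "fitted_model"),
            inherits(atlas, "atlas_definition"))
  expected <- paste0("llv_", atlas$roi_table$label)
  llv_cols <- if (!is.null(model$llv_cols)) model$llv_cols else
    grep("^llv_", model$column_names, value = TRUE)
  if (!identical(llv_cols, expected)) {
    stop("model LLV columns do not match the atlas ROI table ",
         "(order and labels must agree one-to-one)", call. = FALSE)
  }
  is_llv <- model$column_names %in% llv_cols
  roi_label <- rep(NA_integer_, length(is_llv))
  roi_label[is_llv] <- as.integer(sub("^llv_", "", model$column_names[is_llv]))
  tab <- data.frame(
    column_name = model$column_names,
    weight = as.numeric(model$weights),
    is_llv = is_llv,
    roi_label = roi_label,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("weight_table", "data.frame")
  attr(tab, "refit") <- model$refit
  attr(tab, "cell") <- list(outcome = model$outcome,
                            timepoint = model$timepoint,
                            family = model$family)
  tab
}

#' Select strongly negative lesion-load weights
#'
#' Keeps ROIs in which more damage predicts a *lower* score, thresholded at
#' one standard deviation beyond the mean: weight < mu - sigma and
#' weight < 0. By default mu and sigma (population SD) are computed over the
#' LLV weights only, since the map is spatial; set `scope = "all"` to pool
#' every model coefficient instead.
#'
#' @param weight_table a `weight_table` with >= 2 LLV rows.
#' @param scope `"llv"` (default) or `"all"`: which weights define mu/sigma.
#' @return the selected subset of `weight_table` (possibly empty; empty with
#'   a warning when the weights are degenerate, sigma = 0).
#' @export
threshold_negative_weights <- function(weight_table, scope = c("llv", "all")) {
  stopifnot(inherits(weight_table, "weight_table"))
  scope <- match.arg(scope)
  pool <- if (scope == "llv") weight_table$weight[weight_table$is_llv] else
    weight_table$weight
  if (length(pool) < 2L) {
    stop("need >= 2 weights to threshold", call. = FALSE)
  }
  mu <- mean(pool)
  sigma <- sqrt(mean((pool - mu)^2))
  if (sigma == 0) {
    warning("all weights identical (sigma = 0): empty selection",
            call. = FALSE)
    return(weight_table[integer(0), ])
  }
  sel <- weight_table$is_llv & weight_table$weight < mu - sigma &
    weight_table$weight < 0
  weight_table[sel, ]
}

#' Paint selected ROI weights back into brain space
#'
#' Voxels of each selected ROI are set to the absolute weight magnitude
#' (brighter = damage predicting larger score reductions); all other voxels
#' are 0.
#'
#' @param selected a `weight_table` subset whose rows are all LLV weights.
#' @param atlas the matching `atlas_definition`.
#' @return A `brain_volume` weight map.
#' @export
project_to_volume <- function(selected, atlas) {
  stopifnot(inherits(atlas, "atlas_definition"))
  if (nrow(selected) && !all(selected$is_llv)) {
    stop("only LLV weights can be projected to brain space", call. = FALSE)
  }
  unknown <- setdiff(selected$roi_label, atlas$roi_table$label)
  if (length(unknown)) {
    stop("unknown ROI label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  values <- array(0, atlas$grid$dims)
  for (i in seq_len(nrow(selected))) {
    values[atlas$labels == selected$roi_label[i]] <- abs(selected$weight[i])
  }
  brain_volume(values, atlas$grid)
}
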