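#' Closed vocabularies: timepoints, outcomes, model families
#'
#' Timepoints follow the longitudinal design (acute = first days post-stroke,
#' then 1 month, 3 months and 12 months). Outcomes are the overall language
#' score plus eight subdomain scores, each on a 0 (complete impairment) to 10
#' (normal) scale. Model families are the nested predictor sets: `llv` uses
#' lesion load vectors + lesion extent + demographics; `reduced_no_llv` drops
#' the lesion load columns; `reduced_no_llv_no_extent` additionally drops
#' lesion extent; the `_ip` variants add the acute overall score ("initial
#' presentation") and exist only at follow-up timepoints.
#'
#' @return character vector of valid values.
#' @export
mlsm_timepoints <- function() c("acute", "1mo", "3mo", "12mo")

#' @rdname mlsm_timepoints
#' @export
mlsm_outcomes <- function() {
  c("overall", "word_comprehension", "sentence_comprehension",
    "word_finding", "grammatical_construction", "speech_motor_programming",
    "speech_motor_execution", "repetition", "reading")
}

#' @rdname mlsm_timepoints
#' @export
mlsm_families <- function() {
  c("llv", "llv_ip", "reduced_no_llv", "reduced_no_llv_ip",
    "reduced_no_llv_no_extent", "reduced_no_llv_no_extent_ip")
}

family_has_llv <- function(family) family %in% c("llv", "llv_ip")
family_has_extent <- function(family) {
  family %in% c("llv", "llv_ip", "reduced_no_llv", "reduced_no_llv_ip")
}
family_has_ip <- function(family) grepl("_ip$", family)

#' Compute a lesion load vector
#'
#' For each atlas ROI `r`, the load is the mean (smoothed) lesion value over
#' the voxels labelled `r` — i.e. the proportion of that ROI that is lesioned,
#' a value in \[0, 1\]. Entries follow the atlas `roi_table` row order and are
#' named `llv_<label>`.
#'
#' @param lesion a `lesion_volume` (typically smoothed; see
#'   [gaussian_smooth()]).
#' @param atlas an `atlas_definition` on the same grid.
#' @return Named numeric vector of length `atlas$n_rois`.
#' @export
compute_llv <- function(lesion, atlas) {
  stopifnot(inherits(lesion, "lesion_volume"),
            inherits(atlas, "atlas_definition"))
  if (!check_same_grid(lesion, atlas)) {
    stop("lesion and atlas are not on the same voxel grid", call. = FALSE)
  }
  lab <- atlas$labels
  pos <- lab > 0L
  sums <- rowsum(lesion$data[pos], lab[pos])
  loads <- numeric(atlas$n_rois)
  idx <- match(atlas$roi_table$label, as.integer(rownames(sums)))
  loads[!is.na(idx)] <- sums[idx[!is.na(idx)], 1]
  loads <- loads / atlas$voxel_counts
  loads <- pmin(pmax(loads, 0), 1)
  names(loads) <- paste0("llv_", atlas$roi_table$label)
  loads
}

#' Lesion extent in cubic centimetres
#'
#' Voxel count of the binary (pre-smoothing) mask times the voxel volume.
#'
#' @param lesion a binary `lesion_volume`.
#' @return Lesion volume in cm^3.
#' @export
lesion_extent_cm3 <- function(lesion) {
  stopifnot(inherits(lesion, "lesion_volume"))
  if (!isTRUE(lesion$is_binary) || any(lesion$data != 0 & lesion$data != 1)) {
    stop("lesion extent is defined on the binary pre-smoothing mask",
         call. = FALSE)
  }
  sum(lesion$data) * prod(lesion$grid$voxel_size_mm) / 1000
}

#' Encode categorical covariates as single numeric columns
#'
#' sex: M = 0, F = 1; stroke type: ischaemic = 0, haemorrhagic = 1;
#' handedness (ordinal): R = 1, A = 0.5, L = 0. Single-column encodings keep
#' the predictor count aligned with the model families' feature lists.
#'
#' @param covariates data.frame with columns `patient_id`, `age`, `sex`,
#'   `handedness`, `education`, `stroke_type` and `lesion_extent_cm3`.
#' @return data.frame of numeric columns (plus `patient_id`).
#' @export
encode_covariates <- function(covariates) {
  required <- c("patient_id", "age", "sex", "handedness", "education",
                "stroke_type", "lesion_extent_cm3")
  missing_cols <- setdiff(required, names(covariates))
  if (length(missing_cols)) {
    stop("covariate table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  code <- function(x, map, what) {
    x <- as.character(x)
    bad <- !x %in% names(map) & !is.na(x)
    if (any(bad)) {
      stop("invalid ", what, " value(s): ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
    unname(map[x])
  }
  data.frame(
    patient_id = as.character(covariates$patient_id),
    age = as.numeric(covariates$age),
    sex = code(covariates$sex, c(M = 0, F = 1), "sex"),
    handedness = code(covariates$handedness, c(R = 1, A = 0.5, L = 0),
                      "handedness"),
    education = as.numeric(covariates$education),
    stroke_type = code(covariates$stroke_type,
                       c(ischaemic = 0, haemorrhagic = 1), "stroke type"),
    lesion_extent_cm3 = as.numeric(covariates$lesion_extent_cm3),
    stringsAsFactors = FALSE
  )
}

#' Min-max scale columns using training-set ranges
#'
#' Each selected column is scaled by `(x - min_train) / (max_train -
#' min_train)`. Constant training columns map to 0. Rows in `newdata` are
#' scaled with the training parameters and clipped to \[0, 1\], preserving
#' train/test independence when nested in cross-validation.
#'
#' @param train numeric matrix used to derive ranges.
#' @param newdata optional matrix to transform with the training ranges.
#' @param cols column names to scale; others pass through untouched.
#' @return list with `train`, `newdata` (or NULL) and `params` (per-column
#'   min/max).
#' @export
minmax_scale <- function(train, newdata = NULL, cols = colnames(train)) {
  stopifnot(is.matrix(train))
  cols <- intersect(cols, colnames(train))
  lo <- apply(train[, cols, drop = FALSE], 2, min)
  hi <- apply(train[, cols, drop = FALSE], 2, max)
  rng <- hi - lo
  scale_one <- function(m, clip) {
    for (j in seq_along(cols)) {
      cn <- cols[j]
      if (rng[j] == 0) {
        m[, cn] <- 0
      } else {
        v <- (m[, cn] - lo[j]) / rng[j]
        if (clip) v <- pmin(pmax(v, 0), 1)
        m[, cn] <- v
      }
    }
    m
  }
  list(
    train = scale_one(train, clip = FALSE),
    newdata = if (!is.null(newdata)) scale_one(newdata, clip = TRUE),
    params = data.frame(column = cols, min = unname(lo), max = unname(hi))
  )
}

#' Bundle featurized cohort data
#'
#' The modelling container: the lesion load matrix, encoded covariates and
#' the long score table, with optional atlas and simulation ground truth.
#'
#' @param llv numeric matrix, patients x ROIs; rownames are patient ids.
#' @param covariates raw covariate data.frame (see [encode_covariates()]).
#' @param scores long data.frame: `patient_id`, `timepoint`, `outcome`,
#'   `value` (NA = missing).
#' @param atlas optional `atlas_definition`.
#' @param ground_truth optional list (simulation sidecar).
#' @return An `mlsm_cohort`.
#' @export
mlsm_cohort <- function(llv, covariates, scores, atlas = NULL,
                        ground_truth = NULL) {
  stopifnot(is.matrix(llv), !is.null(rownames(llv)))
  scores <- as.data.frame(scores)
  req <- c("patient_id", "timepoint", "outcome", "value")
  if (!all(req %in% names(scores))) {
    stop("score table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!all(scores$timepoint %in% mlsm_timepoints())) {
    stop("invalid timepoint(s) in score table", call. = FALSE)
  }
  if (!all(scores$outcome %in% mlsm_outcomes())) {
    stop("invalid outcome(s) in score table", call. = FALSE)
  }
  v <- scores$value
  if (any(!is.na(v) & (v < 0 | v > 10))) {
    stop("scores must lie in [0, 10] or be missing", call. = FALSE)
  }
  enc <- encode_covariates(covariates)
  if (!all(rownames(llv) %in% enc$patient_id)) {
    stop("every LLV row needs a covariate row", call. = FALSE)
  }
  structure(
    list(llv = llv, covariates = covariates, covariates_encoded = enc,
         scores = scores, atlas = atlas, ground_truth = ground_truth),
    class = "mlsm_cohort"
  )
}

#' @export
print.mlsm_cohort <- function(x, ...) {
  cat("<mlsm_cohort> ", nrow(x$llv), " patients x ", ncol(x$llv),
      " ROIs; score rows: ", nrow(x$scores), "\n", sep = "")
  invisible(x)
}

#' Featurize raw cohort data (lesions + atlas + tables) into an `mlsm_cohort`
#'
#' Lesion extent is computed from each binary mask before smoothing; lesion
#' load vectors from the smoothed mask, in that order.
#'
#' @param atlas an `atlas_definition`.
#' @param lesions named list of binary `lesion_volume`s (names = patient ids).
#' @param covariates covariate data.frame (without `lesion_extent_cm3`; it is
#'   computed here, but a pre-existing column is accepted and overwritten).
#' @param scores long score data.frame.
#' @param fwhm_mm smoothing kernel FWHM in mm (default 8).
#' @return An `mlsm_cohort`.
#' @export
featurize_cohort <- function(atlas, lesions, covariates, scores, fwhm_mm = 8) {
  stopifnot(inherits(atlas, "atlas_definition"), length(lesions) > 0)
  ids <- names(lesions)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("`lesions` must be a named list with unique patient ids",
         call. = FALSE)
  }
  llv <- matrix(0, nrow = length(ids), ncol = atlas$n_rois,
                dimnames = list(ids, paste0("llv_", atlas$roi_table$label)))
  extent <- numeric(length(ids))
  for (i in seq_along(ids)) {
    les <- lesions[[i]]
    extent[i] <- lesion_extent_cm3(les)
    llv[i, ] <- compute_llv(gaussian_smooth(les, fwhm_mm), atlas)
  }
  covariates <- as.data.frame(covariates)
  covariates$lesion_extent_cm3 <-
    extent[match(covariates$patient_id, ids)]
  mlsm_cohort(llv, covariates, scores, atlas = atlas)
}

#' Read cohort score tables
#'
#' `read_scores_long()` expects columns `patient_id`, `timepoint`, `outcome`,
#' `value` (empty field = missing). `read_scores_wide()` expects one row per
#' patient x timepoint with one column per outcome and melts it to long form.
#'
#' @param path delimited file (tab- or comma-separated; inferred from
#'   extension, `.tsv` = tab).
#' @return long-format data.frame.
#' @export
read_scores_long <- function(path) {
  tab <- read_delim_auto(path)
  req <- c("patient_id", "timepoint", "outcome", "value")
  if (!all(req %in% names(tab))) {
    stop("long score table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  tab$patient_id <- as.character(tab$patient_id)
  tab$value <- as.numeric(tab$value)
  tab[req]
}

#' @rdname read_scores_long
#' @export
read_scores_wide <- function(path) {
  tab <- read_delim_auto(path)
  req <- c("patient_id", "timepoint")
  if (!all(req %in% names(tab))) {
    stop("wide score table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  outs <- intersect(mlsm_outcomes(), names(tab))
  if (!length(outs)) stop("no outcome columns found", call. = FALSE)
  long <- do.call(rbind, lapply(outs, function(o) {
    data.frame(patient_id = as.character(tab$patient_id),
               timepoint = tab$timepoint, outcome = o,
               value = as.numeric(tab[[o]]), stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' Assemble the predictor matrix for one model cell
#'
#' Restricts to patients with a non-missing response at the requested
#' outcome/timepoint (and a non-missing acute overall score for `_ip`
#' families), sorts rows by patient id, and lays out columns as: LLV block
#' (if the family includes it), lesion extent (if included), then age, sex,
#' handedness, education, stroke type, then acute overall for `_ip`
#' families. LLV columns are natively in \[0, 1\] and are never min-max
#' scaled; the remaining columns are listed in `scale_cols` and scaled inside
#' cross-validation (or by the full-sample fitter), not here.
#'
#' @param cohort an `mlsm_cohort`.
#' @param outcome one of [mlsm_outcomes()].
#' @param timepoint one of [mlsm_timepoints()].
#' @param family one of [mlsm_families()].
#' @return A `feature_matrix`: list with `x` (unscaled matrix), `response`,
#'   `patient_ids`, `scale_cols`, `llv_cols` and the cell identity.
#' @export
assemble_features <- function(cohort, outcome, timepoint, family) {
  stopifnot(inherits(cohort, "mlsm_cohort"))
  outcome <- match.arg(outcome, mlsm_outcomes())
  timepoint <- match.arg(timepoint, mlsm_timepoints())
  family <- match.arg(family, mlsm_families())
  if (family_has_ip(family) && timepoint == "acute") {
    stop("initial-presentation families are undefined at the acute ",
         "timepoint (acute overall is a predictor)", call. = FALSE)
  }
  sc <- cohort$scores
  resp <- sc[sc$outcome == outcome & sc$timepoint == timepoint &
               !is.na(sc$value), c("patient_id", "value")]
  ids <- resp$patient_id
  if (family_has_ip(family)) {
    ip <- sc[sc$outcome == "overall" & sc$timepoint == "acute" &
               !is.na(sc$value), c("patient_id", "value")]
    ids <- intersect(ids, ip$patient_id)
  }
  enc <- cohort$covariates_encoded
  complete <- enc$patient_id[stats::complete.cases(enc)]
  ids <- sort(intersect(intersect(ids, rownames(cohort$llv)), complete))
  if (!length(ids)) {
    stop("no eligible cases for outcome '", outcome, "' at timepoint '",
         timepoint, "' (family ", family, ")", call. = FALSE)
  }
  demo_cols <- c("age", "sex", "handedness", "education", "stroke_type")
  enc <- enc[match(ids, enc$patient_id), , drop = FALSE]
  blocks <- list()
  if (family_has_llv(family)) {
    blocks$llv <- cohort$llv[ids, , drop = FALSE]
  }
  if (family_has_extent(family)) {
    blocks$extent <- matrix(enc$lesion_extent_cm3, ncol = 1,
                            dimnames = list(NULL, "lesion_extent_cm3"))
  }
  blocks$demo <- as.matrix(enc[, demo_cols, drop = FALSE])
  if (family_has_ip(family)) {
    ipv <- ip$value[match(ids, ip$patient_id)]
    blocks$ip <- matrix(ipv, ncol = 1,
                        dimnames = list(NULL, "acute_overall"))
  }
  x <- do.call(cbind, blocks)
  rownames(x) <- ids
  llv_cols <- if (family_has_llv(family)) colnames(cohort$llv) else character()
  structure(
    list(x = x,
         response = resp$value[match(ids, resp$patient_id)],
         patient_ids = ids,
         scale_cols = setdiff(colnames(x), llv_cols),
         llv_cols = llv_cols,
         outcome = outcome, timepoint = timepoint, family = family),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", x$outcome, "@", x$timepoint, " [", x$family,
      "]: ", nrow(x$x), " cases x ", ncol(x$x), " predictors\n", sep = "")
  invisible(x)
}
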