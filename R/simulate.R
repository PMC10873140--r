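#' Simulation configuration for synthetic cohorts
#'
#' Defaults emulate the reference cohort's study conditions: 217 patients
#' with heavy-tailed lesion sizes (log-normal matched to mean 53.6, SD 60.4,
#' truncated to 0.6-376.4 cm^3), a 150-ROI left-hemisphere-style atlas
#' (123 grey / 21 white / 6 commissural parcels), bounded 0-10 scores driven
#' by a sparse ground-truth ROI weight map plus noise, longitudinal recovery
#' toward ceiling with severity-dependent fractions, untestable-acute
#' patients (overall 0, subscores missing) and independent follow-up dropout
#' shrinking the cohort to roughly 102 / 98 / 74 cases.
#'
#' @param n_patients cohort size.
#' @param grid_dims,voxel_size_mm synthetic volume geometry.
#' @param n_rois number of atlas parcels.
#' @param lesion_mean_cm3,lesion_sd_cm3,lesion_range_cm3 log-normal lesion
#'   size scale (cm^3) and truncation range.
#' @param fwhm_mm smoothing kernel FWHM applied before LLV computation.
#' @param dropout named probabilities of losing a patient at each follow-up
#'   timepoint, independent of severity.
#' @param untestable_threshold,untestable_prob patients whose acute latent
#'   score falls below the threshold become untestable (overall 0, subscores
#'   missing) with this probability.
#' @param baseline intercept of the latent score (near ceiling; an intact
#'   brain scores `min(baseline, 10)` plus noise).
#' @param noise_sd named per-timepoint latent noise SD (> 0).
#' @param severity_cut latent acute score splitting severe from mild strata.
#' @param recovery_fractions list with numeric vectors `severe` and `mild`
#'   (one entry per timepoint, nondecreasing, in \[0, 1\]): the fraction of
#'   the distance to ceiling recovered at each timepoint per stratum.
#' @param n_informative,informative_weight_range sparse ground truth: how
#'   many ROIs carry signal and the (negative) weight range they are drawn
#'   from.
#' @param truth_mode `"location"` (deficit from specific ROIs) or `"size"`
#'   (deficit proportional to total lesioned volume, i.e. carried entirely by
#'   lesion extent).
#' @param size_slope deficit per cm^3 of lesion in `"size"` mode. The default
#'   keeps even the largest truncation-range lesion's deficit near the score
#'   scale (0.03 x 376 cm^3 is about 11 points), so floor censoring stays
#'   rare and the size-only regime genuinely contains no signal beyond
#'   lesion extent.
#' @param subscore_cor target correlation between subscores and the overall
#'   score.
#' @param seed mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 217,
                       grid_dims = c(48, 48, 48),
                       voxel_size_mm = c(3, 3, 3),
                       n_rois = 150,
                       lesion_mean_cm3 = 53.6,
                       lesion_sd_cm3 = 60.4,
                       lesion_range_cm3 = c(0.6, 376.4),
                       fwhm_mm = 8,
                       dropout = c("1mo" = 1 - 102 / 217,
                                   "3mo" = 1 - 98 / 217,
                                   "12mo" = 1 - 74 / 217),
                       untestable_threshold = 1,
                       untestable_prob = 0.9,
                       baseline = 8.5,
                       noise_sd = c(acute = 0.8, "1mo" = 0.5, "3mo" = 0.5,
                                    "12mo" = 0.5),
                       severity_cut = 5,
                       recovery_fractions = list(
                         severe = c(acute = 0, "1mo" = 0.15, "3mo" = 0.25,
                                    "12mo" = 0.35),
                         mild = c(acute = 0, "1mo" = 0.3, "3mo" = 0.45,
                                  "12mo" = 0.55)),
                       n_informative = 5,
                       informative_weight_range = c(-8, -4),
                       truth_mode = c("location", "size"),
                       size_slope = 0.03,
                       subscore_cor = 0.8,
                       seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("`seed` is mandatory in a simulation config", call. = FALSE)
  }
  truth_mode <- match.arg(truth_mode)
  stopifnot(n_patients >= 1, n_rois >= 2, length(grid_dims) == 3,
            length(voxel_size_mm) == 3, all(voxel_size_mm > 0),
            lesion_mean_cm3 > 0, lesion_sd_cm3 > 0,
            length(lesion_range_cm3) == 2,
            lesion_range_cm3[1] > 0,
            diff(lesion_range_cm3) > 0,
            fwhm_mm > 0, all(noise_sd > 0),
            untestable_prob >= 0, untestable_prob <= 1,
            subscore_cor > 0, subscore_cor <= 1)
  fu <- c("1mo", "3mo", "12mo")
  if (!all(fu %in% names(dropout)) || any(dropout < 0) || any(dropout > 1)) {
    stop("`dropout` must name probabilities in [0, 1] for ",
         paste(fu, collapse = ", "), call. = FALSE)
  }
  if (!all(mlsm_timepoints() %in% names(noise_sd))) {
    stop("`noise_sd` must name every timepoint", call. = FALSE)
  }
  for (stratum in c("severe", "mild")) {
    rf <- recovery_fractions[[stratum]]
    if (is.null(rf) || length(rf) != 4L || any(rf < 0) || any(rf > 1) ||
        any(diff(rf) < 0)) {
      stop("`recovery_fractions$", stratum, "` must be 4 nondecreasing ",
           "fractions in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(n_patients = as.integer(n_patients), grid_dims = as.integer(grid_dims),
         voxel_size_mm = voxel_size_mm, n_rois = as.integer(n_rois),
         lesion_mean_cm3 = lesion_mean_cm3, lesion_sd_cm3 = lesion_sd_cm3,
         lesion_range_cm3 = lesion_range_cm3, fwhm_mm = fwhm_mm,
         dropout = dropout[fu], untestable_threshold = untestable_threshold,
         untestable_prob = untestable_prob, baseline = baseline,
         noise_sd = noise_sd[mlsm_timepoints()], severity_cut = severity_cut,
         recovery_fractions = recovery_fractions,
         n_informative = as.integer(n_informative),
         informative_weight_range = informative_weight_range,
         truth_mode = truth_mode, size_slope = size_slope,
         subscore_cor = subscore_cor, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate a synthetic parcellated atlas
#'
#' Partitions an interior ellipsoidal "brain" mask (leaving a background
#' margin) into `n_rois` contiguous parcels by seeded Voronoi assignment:
#' parcel seeds are placed by greedy farthest-point sampling over the mask,
#' then every mask voxel takes the label of its nearest seed. Parcel tissue
#' classes follow the 123/21/6 grey/white/commissural proportions of the
#' reference 150-ROI atlas. Deterministic for a fixed RNG state.
#'
#' @param grid_dims integer triple.
#' @param n_rois number of parcels (>= 2; every parcel must end up with >= 8
#'   voxels).
#' @param voxel_size_mm voxel edge lengths.
#' @param seed optional integer; when given, seeds the RNG.
#' @param margin background margin in voxels around the ellipsoid.
#' @return An `atlas_definition`.
#' @export
make_synthetic_atlas <- function(grid_dims, n_rois, voxel_size_mm = c(1, 1, 1),
                                 seed = NULL, margin = 2) {
  if (!is.null(seed)) set.seed(seed)
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3, n_rois >= 2)
  ctr <- (grid_dims + 1) / 2
  semi <- pmax(grid_dims / 2 - margin, 1)
  ax <- (seq_len(grid_dims[1]) - ctr[1]) / semi[1]
  ay <- (seq_len(grid_dims[2]) - ctr[2]) / semi[2]
  az <- (seq_len(grid_dims[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  mask <- r2 <= 1
  m <- sum(mask)
  if (m < 8 * n_rois) {
    stop("grid too small: ", n_rois, " parcels need >= ", 8 * n_rois,
         " interior voxels, mask has ", m, call. = FALSE)
  }
  coords <- which(mask, arr.ind = TRUE)
  mm <- sweep(coords, 2, voxel_size_mm, `*`)
  for (attempt in 1:5) {
    # greedy farthest-point seed placement over a candidate subsample
    n_cand <- min(m, 4000L)
    cand <- sort(sample.int(m, n_cand))
    seeds <- integer(n_rois)
    seeds[1] <- cand[sample.int(n_cand, 1L)]
    mind <- colSums((t(mm[cand, , drop = FALSE]) - mm[seeds[1], ])^2)
    for (k in 2:n_rois) {
      seeds[k] <- cand[which.max(mind)]
      mind <- pmin(mind,
                   colSums((t(mm[cand, , drop = FALSE]) - mm[seeds[k], ])^2))
    }
    best_d <- rep(Inf, m)
    lab_mask <- integer(m)
    for (k in seq_len(n_rois)) {
      d <- colSums((t(mm) - mm[seeds[k], ])^2)
      upd <- d < best_d
      best_d[upd] <- d[upd]
      lab_mask[upd] <- k
    }
    if (min(tabulate(lab_mask, n_rois)) >= 8L) break
    if (attempt == 5L) {
      stop("could not place ", n_rois, " parcels of >= 8 voxels on this grid",
           call. = FALSE)
    }
  }
  labels <- array(0L, grid_dims)
  labels[mask] <- lab_mask
  n_com <- max(0L, round(n_rois * 6 / 150))
  n_wm <- max(0L, round(n_rois * 21 / 150))
  if (n_com + n_wm >= n_rois) { n_com <- 0L; n_wm <- min(1L, n_rois - 1L) }
  n_gm <- n_rois - n_wm - n_com
  tissue <- c(rep("grey", n_gm), rep("white", n_wm), rep("commissural", n_com))
  prefix <- c(grey = "gm", white = "wm", commissural = "cc")[tissue]
  roi_table <- data.frame(
    label = seq_len(n_rois),
    name = paste0(prefix, "_", sprintf("%03d", seq_len(n_rois))),
    tissue_class = tissue, stringsAsFactors = FALSE
  )
  atlas_definition(labels, voxel_grid(grid_dims, voxel_size_mm), roi_table)
}

neighbours_6 <- function(idx, dims, eligible) {
  co <- arrayInd(idx, dims)
  out <- integer(0)
  for (axis in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- co
      nb[, axis] <- nb[, axis] + s
      ok <- nb[, axis] >= 1L & nb[, axis] <= dims[axis]
      if (any(ok)) {
        lin <- (nb[ok, 3L] - 1L) * dims[1L] * dims[2L] +
          (nb[ok, 2L] - 1L) * dims[1L] + nb[ok, 1L]
        out <- c(out, lin[eligible[lin]])
      }
    }
  }
  unique(out)
}

#' Grow one contiguous synthetic lesion
#'
#' Region growing from a random seed voxel inside the labelled brain mask:
#' at each step a uniform random batch of the current 6-connected frontier is
#' absorbed, with the final batch trimmed so the achieved volume matches the
#' target voxel count exactly (within one voxel of the requested cm^3
#' volume). Growth never leaves the labelled mask.
#'
#' @param atlas an `atlas_definition` defining the brain mask.
#' @param size_cm3 target lesion volume (> 0; at most 80% of the labelled
#'   volume). A minimum of one voxel is enforced.
#' @param seed optional RNG seed.
#' @param patient_id identifier attached to the mask.
#' @return A binary `lesion_volume`.
#' @export
simulate_lesion <- function(atlas, size_cm3, seed = NULL,
                            patient_id = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(atlas, "atlas_definition"), size_cm3 >= 0)
  dims <- atlas$grid$dims
  voxvol <- prod(atlas$grid$voxel_size_mm) / 1000
  target <- max(1L, as.integer(round(size_cm3 / voxvol)))
  eligible <- atlas$labels > 0L
  n_elig <- sum(eligible)
  if (target > 0.8 * n_elig) {
    stop("target lesion volume (", target, " voxels) exceeds 80% of the ",
         "labelled volume (", n_elig, " voxels)", call. = FALSE)
  }
  inreg <- array(FALSE, dims)
  elig_idx <- which(eligible)
  start <- elig_idx[sample.int(n_elig, 1L)]
  inreg[start] <- TRUE
  count <- 1L
  frontier <- neighbours_6(start, dims, eligible)
  while (count < target) {
    frontier <- frontier[!inreg[frontier]]
    if (!length(frontier)) {
      stop("lesion growth exhausted the reachable mask before reaching ",
           target, " voxels", call. = FALSE)
    }
    nadd <- min(target - count, max(1L, as.integer(ceiling(length(frontier) * 0.5))))
    pick <- if (nadd == length(frontier)) frontier else
      frontier[sample.int(length(frontier), nadd)]
    inreg[pick] <- TRUE
    count <- count + nadd
    frontier <- unique(c(frontier, neighbours_6(pick, dims, eligible)))
  }
  lesion_volume(inreg + 0, atlas$grid, patient_id = patient_id,
                is_binary = TRUE)
}

#' Draw demographic and clinical covariates
#'
#' Marginal distributions follow the reference cohort table: age ~ N(62.5,
#' 13.6) truncated to 21-90; sex 117M:100F; handedness 193R:19L:5A; education
#' ~ N(12.9, 3.2) truncated to 0-20; stroke type 174 ischaemic : 43
#' haemorrhagic. Covariates are generated independently of the lesion, so
#' carry no true outcome signal.
#'
#' @param n number of patients.
#' @param seed optional RNG seed.
#' @return data.frame of raw (unencoded) covariates, without lesion extent.
#' @export
simulate_covariates <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("p%0*d", max(3L, nchar(n)), seq_len(n))
  data.frame(
    patient_id = ids,
    age = pmin(pmax(round(stats::rnorm(n, 62.5, 13.6)), 21), 90),
    sex = sample(c("M", "F"), n, TRUE, prob = c(117, 100)),
    handedness = sample(c("R", "L", "A"), n, TRUE, prob = c(193, 19, 5)),
    education = pmin(pmax(round(stats::rnorm(n, 12.9, 3.2)), 0), 20),
    stroke_type = sample(c("ischaemic", "haemorrhagic"), n, TRUE,
                         prob = c(174, 43)),
    stringsAsFactors = FALSE
  )
}

#' Construct the ground-truth ROI weight map
#'
#' In `"location"` mode a sparse map: `n_informative` randomly chosen ROIs
#' get weights drawn uniformly from `informative_weight_range`, all others 0
#' — the deficit depends on *where* the lesion falls. In `"size"` mode every
#' ROI's weight is `-size_slope x its volume in cm^3`, so the summed deficit
#' equals `-size_slope x` the lesioned volume: the deficit depends only on
#' *how large* the lesion is, and lesion extent carries all the signal.
#'
#' @param atlas an `atlas_definition`.
#' @param config a [sim_config()].
#' @param seed optional RNG seed.
#' @return list with `roi_weights` (named by atlas label), `informative_labels`
#'   and `mode`.
#' @export
make_ground_truth <- function(atlas, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- stats::setNames(numeric(atlas$n_rois),
                       paste0("llv_", atlas$roi_table$label))
  if (config$truth_mode == "location") {
    pick <- sort(sample.int(atlas$n_rois, config$n_informative))
    w[pick] <- stats::runif(config$n_informative,
                            min(config$informative_weight_range),
                            max(config$informative_weight_range))
    informative <- atlas$roi_table$label[pick]
  } else {
    voxvol <- prod(atlas$grid$voxel_size_mm) / 1000
    w[] <- -config$size_slope * atlas$voxel_counts * voxvol
    informative <- integer(0)
  }
  list(roi_weights = w, informative_labels = informative,
       mode = config$truth_mode)
}

#' Simulate longitudinal scores from lesion load vectors
#'
#' The acute latent score is `baseline + llv %*% roi_weights + noise`; each
#' follow-up latent is the acute latent pulled toward the ceiling of 10 by
#' the stratum's recovery fraction, plus fresh timepoint noise. All scores
#' are clipped to \[0, 10\]. Subscores are correlated perturbations of the
#' overall latent (target correlation `subscore_cor`). Patients whose acute
#' latent falls below `untestable_threshold` become untestable with
#' probability `untestable_prob`: acute overall is recorded as 0 and acute
#' subscores as missing. The noiseless clipped trajectory is returned
#' alongside for noise-ceiling computations.
#'
#' @param llv patients x ROIs lesion load matrix (rownames = patient ids).
#' @param truth output of [make_ground_truth()].
#' @param config a [sim_config()].
#' @param seed optional RNG seed.
#' @return list: `scores` (long data.frame), `noiseless` (patients x
#'   timepoints matrix of clipped noiseless overall scores), `untestable`
#'   (logical per patient), `signal` (noiseless unclipped acute latent).
#' @export
simulate_scores <- function(llv, truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (ncol(llv) != length(truth$roi_weights)) {
    stop("LLV width (", ncol(llv), ") does not match ground-truth weights (",
         length(truth$roi_weights), ")", call. = FALSE)
  }
  n <- nrow(llv)
  ids <- rownames(llv)
  tps <- mlsm_timepoints()
  signal <- config$baseline + drop(llv %*% truth$roi_weights)
  stratum <- ifelse(signal < config$severity_cut, "severe", "mild")
  acute_latent <- signal + stats::rnorm(n, 0, config$noise_sd["acute"])
  latent <- matrix(NA_real_, n, 4, dimnames = list(ids, tps))
  noiseless <- latent
  latent[, "acute"] <- acute_latent
  noiseless[, "acute"] <- pmin(pmax(signal, 0), 10)
  for (t in tps[-1]) {
    rf <- vapply(stratum, function(s) config$recovery_fractions[[s]][[t]],
                 numeric(1))
    latent[, t] <- acute_latent + rf * (10 - acute_latent) +
      stats::rnorm(n, 0, config$noise_sd[t])
    noiseless[, t] <- pmin(pmax(signal + rf * (10 - signal), 0), 10)
  }
  clipped <- pmin(pmax(latent, 0), 10)
  untestable <- acute_latent < config$untestable_threshold &
    stats::runif(n) < config$untestable_prob
  sub_outcomes <- setdiff(mlsm_outcomes(), "overall")
  rows <- vector("list", 4 * (1 + length(sub_outcomes)))
  k <- 0
  for (t in tps) {
    overall_t <- clipped[, t]
    if (t == "acute") overall_t[untestable] <- 0
    k <- k + 1
    rows[[k]] <- data.frame(patient_id = ids, timepoint = t,
                            outcome = "overall", value = unname(overall_t),
                            stringsAsFactors = FALSE)
    sd_lat <- stats::sd(latent[, t])
    sub_sd <- if (sd_lat > 0) sd_lat * sqrt(1 / config$subscore_cor^2 - 1)
      else config$noise_sd[t]
    for (o in sub_outcomes) {
      v <- pmin(pmax(latent[, t] + stats::rnorm(n, 0, sub_sd), 0), 10)
      if (t == "acute") v[untestable] <- NA_real_
      k <- k + 1
      rows[[k]] <- data.frame(patient_id = ids, timepoint = t, outcome = o,
                              value = unname(v), stringsAsFactors = FALSE)
    }
  }
  list(scores = do.call(rbind, rows), noiseless = noiseless,
       untestable = stats::setNames(untestable, ids),
       signal = stats::setNames(signal, ids))
}

#' Apply severity-independent follow-up dropout
#'
#' Each patient is independently retained at each follow-up timepoint with
#' probability `1 - dropout`; rows of dropped patient-timepoints are removed.
#' Retention is independent of the acute score, so severity distributions of
#' retained and dropped patients match in expectation (no follow-up sampling
#' bias). Acute rows are never dropped.
#'
#' @param scores long score data.frame.
#' @param dropout named dropout probabilities for `1mo`, `3mo`, `12mo`.
#' @param seed optional RNG seed.
#' @return the score table with follow-up missingness applied.
#' @export
apply_dropout <- function(scores, dropout, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sort(unique(scores$patient_id))
  keep <- rep(TRUE, nrow(scores))
  for (t in c("1mo", "3mo", "12mo")) {
    p <- dropout[[t]]
    if (is.null(p) || p <= 0) next
    dropped <- ids[stats::runif(length(ids)) < p]
    keep <- keep & !(scores$timepoint == t & scores$patient_id %in% dropped)
  }
  scores[keep, , drop = FALSE]
}

#' Generate a complete synthetic cohort
#'
#' Runs the whole generator under a single RNG stream seeded from
#' `config$seed`: atlas, lesion sizes and masks, covariates, ground truth,
#' longitudinal scores and dropout. Lesion extent is taken from the binary
#' masks and lesion load vectors from the smoothed masks. With `dir` set,
#' the raw dataset is also written to disk
#' (`lesions/<id>.nii.gz`, `atlas.nii.gz`, `atlas_rois.tsv`,
#' `covariates.tsv`, `scores.tsv`, `ground_truth.json`) in a layout that
#' [load_cohort()] re-featurizes with no special-casing.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory (created if needed).
#' @param keep_lesions logical; retain the binary masks in the returned
#'   object (memory-heavy for large cohorts).
#' @return An `mlsm_cohort` with `ground_truth` attached.
#' @export
generate_cohort <- function(config, dir = NULL, keep_lesions = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  atlas <- make_synthetic_atlas(config$grid_dims, config$n_rois,
                                config$voxel_size_mm)
  sigma2 <- log(1 + (config$lesion_sd_cm3 / config$lesion_mean_cm3)^2)
  meanlog <- log(config$lesion_mean_cm3) - sigma2 / 2
  sizes <- numeric(config$n_patients)
  for (i in seq_len(config$n_patients)) {
    repeat {
      s <- stats::rlnorm(1, meanlog, sqrt(sigma2))
      if (s >= config$lesion_range_cm3[1] && s <= config$lesion_range_cm3[2]) {
        sizes[i] <- s
        break
      }
    }
  }
  covariates <- simulate_covariates(config$n_patients)
  ids <- covariates$patient_id
  llv <- matrix(0, config$n_patients, atlas$n_rois,
                dimnames = list(ids, paste0("llv_", atlas$roi_table$label)))
  extent <- numeric(config$n_patients)
  lesions <- if (keep_lesions || !is.null(dir)) vector("list",
                                                       config$n_patients)
  for (i in seq_len(config$n_patients)) {
    les <- simulate_lesion(atlas, sizes[i], patient_id = ids[i])
    extent[i] <- lesion_extent_cm3(les)
    llv[i, ] <- compute_llv(gaussian_smooth(les, config$fwhm_mm), atlas)
    if (!is.null(lesions)) lesions[[i]] <- les
  }
  covariates$lesion_extent_cm3 <- extent
  truth <- make_ground_truth(atlas, config)
  sim <- simulate_scores(llv, truth, config)
  scores <- apply_dropout(sim$scores, config$dropout)
  rownames(scores) <- NULL
  ground_truth <- list(
    mode = truth$mode, roi_weights = truth$roi_weights,
    informative_labels = truth$informative_labels,
    baseline = config$baseline, noise_sd = config$noise_sd,
    noiseless = sim$noiseless, untestable = sim$untestable,
    signal = sim$signal, config = config
  )
  cohort <- mlsm_cohort(llv, covariates, scores, atlas = atlas,
                        ground_truth = ground_truth)
  if (keep_lesions) cohort$lesions <- stats::setNames(lesions, ids)
  if (!is.null(dir)) {
    write_cohort(cohort, dir, lesions = stats::setNames(lesions, ids))
  }
  cohort
}

write_cohort <- function(cohort, dir, lesions) {
  dir.create(file.path(dir, "lesions"), recursive = TRUE, showWarnings = FALSE)
  atlas <- cohort$atlas
  write_volume(brain_volume(atlas$labels, atlas$grid),
               file.path(dir, "atlas.nii.gz"))
  write_roi_table(atlas$roi_table, file.path(dir, "atlas_rois.tsv"))
  for (id in names(lesions)) {
    write_volume(lesions[[id]], file.path(dir, "lesions",
                                          paste0(id, ".nii.gz")))
  }
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$scores, file.path(dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(mode = gt$mode, roi_weights = as.list(gt$roi_weights),
         informative_labels = gt$informative_labels,
         baseline = gt$baseline, noise_sd = as.list(gt$noise_sd),
         untestable = names(gt$untestable)[gt$untestable],
         noiseless = as.data.frame(gt$noiseless),
         seed = gt$config$seed),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a cohort dataset from disk
#'
#' Reads the layout written by [generate_cohort()] (or any dataset following
#' it) and featurizes it: lesions are smoothed and converted to lesion load
#' vectors, lesion extent is recomputed from the binary masks.
#'
#' @param dir dataset directory.
#' @param fwhm_mm smoothing FWHM in mm (default 8).
#' @return An `mlsm_cohort` (with ground truth attached when the sidecar is
#'   present).
#' @export
load_cohort <- function(dir, fwhm_mm = 8) {
  atlas <- load_atlas(file.path(dir, "atlas.nii.gz"),
                      file.path(dir, "atlas_rois.tsv"))
  files <- sort(list.files(file.path(dir, "lesions"),
                           pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  if (!length(files)) stop("no lesion volumes under ", dir, call. = FALSE)
  ids <- sub("\\.nii(\\.gz)?$", "", basename(files))
  lesions <- stats::setNames(
    lapply(seq_along(files), function(i)
      load_volume(files[i], expect_binary = TRUE, patient_id = ids[i])),
    ids)
  covariates <- read_delim_auto(file.path(dir, "covariates.tsv"))
  scores <- read_scores_long(file.path(dir, "scores.tsv"))
  cohort <- featurize_cohort(atlas, lesions, covariates, scores,
                             fwhm_mm = fwhm_mm)
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    gt$roi_weights <- unlist(gt$roi_weights)
    gt$noiseless <- as.matrix(gt$noiseless)
    rownames(gt$noiseless) <- rownames(cohort$llv)
    cohort$ground_truth <- gt
  }
  cohort
}

#' Analytic noise ceiling of a simulated cohort
#'
#' The prediction r-squared an oracle predictor knowing the noiseless clipped
#' trajectory would achieve on the evaluated case set: `1 - sum((obs -
#' noiseless)^2) / sum((obs - mean(obs))^2)` over patients with a non-missing
#' overall score at the timepoint. Residual variance here is measurement
#' noise plus the untestable-zeroing convention, neither of which any
#' lesion-based model can predict exactly.
#'
#' @param cohort an `mlsm_cohort` with simulation ground truth.
#' @param timepoint one of [mlsm_timepoints()].
#' @return scalar ceiling estimate.
#' @export
noise_ceiling <- function(cohort, timepoint = "acute") {
  stopifnot(inherits(cohort, "mlsm_cohort"))
  gt <- cohort$ground_truth
  if (is.null(gt$noiseless)) {
    stop("cohort carries no simulation ground truth", call. = FALSE)
  }
  timepoint <- match.arg(timepoint, mlsm_timepoints())
  sc <- cohort$scores
  obs <- sc[sc$outcome == "overall" & sc$timepoint == timepoint &
              !is.na(sc$value), ]
  nl <- gt$noiseless[obs$patient_id, timepoint]
  1 - sum((obs$value - nl)^2) / sum((obs$value - mean(obs$value))^2)
}
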