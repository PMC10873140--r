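# Independent brute-force oracles and small fixture builders.
# Oracles deliberately avoid the package's vectorised code paths.

# Direct 3-D convolution with an explicitly assembled truncated Gaussian
# kernel, zero padding outside the volume: one R-level loop per output voxel.
conv3_oracle <- function(values, voxel_size_mm, fwhm_mm) {
  sigma <- fwhm_mm / (voxel_size_mm * 2 * sqrt(2 * log(2)))
  r <- pmax(1L, as.integer(ceiling(4 * sigma)))
  k1 <- lapply(1:3, function(a) {
    k <- dnorm(seq(-r[a], r[a]), sd = sigma[a])
    k / sum(k)
  })
  K <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  d <- dim(values)
  out <- array(0, d)
  for (x in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      for (z in seq_len(d[3])) {
        xs <- (x - r[1]):(x + r[1])
        ys <- (y - r[2]):(y + r[2])
        zs <- (z - r[3]):(z + r[3])
        okx <- xs >= 1 & xs <= d[1]
        oky <- ys >= 1 & ys <= d[2]
        okz <- zs >= 1 & zs <= d[3]
        out[x, y, z] <- sum(K[okx, oky, okz] *
                              values[xs[okx], ys[oky], zs[okz]])
      }
    }
  }
  out
}

# Per-voxel accumulation of ROI sums and counts.
llv_oracle <- function(lesion_values, labels, roi_labels) {
  sums <- setNames(numeric(length(roi_labels)), roi_labels)
  counts <- setNames(numeric(length(roi_labels)), roi_labels)
  for (i in seq_along(labels)) {
    l <- labels[i]
    if (l > 0) {
      key <- as.character(l)
      sums[key] <- sums[key] + lesion_values[i]
      counts[key] <- counts[key] + 1
    }
  }
  unname(sums / counts)
}

# Grid-search minimiser of the epsilon-insensitive loss for a constant
# predictor (the zero-feature SVR limit).
eps_loss <- function(const, y, eps) sum(pmax(0, abs(y - const) - eps))

# Deterministic block atlas: grid split into 4 axis-aligned slabs.
make_block_atlas <- function(dims = c(12, 12, 12), voxel_size = c(2, 2, 2)) {
  labels <- array(0L, dims)
  cut <- floor(dims[1] / 4)
  for (k in 1:4) {
    lo <- (k - 1) * cut + 1
    hi <- if (k == 4) dims[1] else k * cut
    labels[lo:hi, , ] <- k
  }
  roi <- data.frame(label = 1:4,
                    name = paste0("gm_", sprintf("%03d", 1:4)),
                    tissue_class = c("grey", "grey", "white", "commissural"))
  atlas_definition(labels, voxel_grid(dims, voxel_size), roi)
}

# Small simulated cohort for modelling tests (fast: coarse grid, few ROIs).
make_tiny_cohort <- function(n = 25, seed = 42, ...) {
  generate_cohort(sim_config(
    n_patients = n, grid_dims = c(20, 20, 20), voxel_size_mm = c(5, 5, 5),
    n_rois = 12, n_informative = 3, lesion_mean_cm3 = 40,
    lesion_sd_cm3 = 30, lesion_range_cm3 = c(1, 150), seed = seed, ...))
}

# LOOCV prediction r2 for one model cell.
prediction_r2_of <- function(cohort, family, outcome = "overall",
                             timepoint = "acute") {
  cv <- loocv_predict(cohort, outcome, timepoint, family)
  prediction_r2(cv$observed, cv$predicted)
}

# Hand-built cohort with a known 150-column LLV matrix and explicit scores;
# no volumes involved, so featurization arithmetic is fully controlled.
make_table_cohort <- function(n = 12, n_rois = 150, seed = 99) {
  set.seed(seed)
  ids <- sprintf("p%03d", seq_len(n))
  llv <- matrix(runif(n * n_rois), n, n_rois,
                dimnames = list(ids, paste0("llv_", seq_len(n_rois))))
  covariates <- data.frame(
    patient_id = ids,
    age = sample(30:85, n, TRUE), sex = sample(c("M", "F"), n, TRUE),
    handedness = sample(c("R", "L", "A"), n, TRUE),
    education = sample(8:20, n, TRUE),
    stroke_type = sample(c("ischaemic", "haemorrhagic"), n, TRUE),
    lesion_extent_cm3 = runif(n, 1, 300))
  scores <- expand.grid(patient_id = ids, timepoint = mlsm_timepoints(),
                        outcome = mlsm_outcomes(), stringsAsFactors = FALSE)
  scores$value <- round(runif(nrow(scores), 0, 10), 2)
  mlsm_cohort(llv, covariates, scores)
}
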