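make_weight_table <- function(weights, atlas,
                              extra = c(lesion_extent_cm3 = 0.2, age = -0.1)) {
  cols <- c(paste0("llv_", atlas$roi_table$label), names(extra))
  model <- structure(
    list(weights = setNames(c(weights, unname(extra)), cols),
         intercept = 5, hyperparams = svr_hyperparams(),
         column_names = cols,
         llv_cols = paste0("llv_", atlas$roi_table$label),
         refit = "full_sample"),
    class = "fitted_model")
  extract_weights(model, atlas)
}

test_that("weight extraction links every coefficient to its ROI", {
  cohort <- make_tiny_cohort(n = 18, seed = 19)
  model <- fit_family_model(cohort, "overall", "acute", "llv")
  wt <- extract_weights(model, cohort$atlas)
  expect_identical(nrow(wt), length(model$weights))
  expect_identical(sum(wt$is_llv), cohort$atlas$n_rois)
  expect_identical(wt$roi_label[wt$is_llv], cohort$atlas$roi_table$label)
  expect_true(all(is.na(wt$roi_label[!wt$is_llv])))
  expect_identical(attr(wt, "refit"), "full_sample")

  # zero-weight model tabulates zeros
  wt0 <- make_weight_table(rep(0, cohort$atlas$n_rois), cohort$atlas,
                           extra = c(age = 0))
  expect_true(all(wt0$weight == 0))

  # column/atlas mismatch is a mapping error
  shuffled <- cohort$atlas
  shuffled$roi_table <- shuffled$roi_table[rev(seq_len(nrow(shuffled$roi_table))), ]
  expect_error(extract_weights(model, shuffled), "do not match")
})

test_that("1-SD negative thresholding selects the hand-computed subset", {
  labels <- array(0L, c(10, 10, 10))
  labels[1:5, , ] <- slice.index(labels, 1)[1:5, , ]
  atlas5 <- atlas_definition(
    labels, voxel_grid(c(10, 10, 10), c(2, 2, 2)),
    data.frame(label = 1:5, name = paste0("gm_", 1:5),
               tissue_class = "grey"))

  wt <- make_weight_table(c(-3, -1, 0, 1, 3), atlas5, extra = c(age = -9))
  sel <- threshold_negative_weights(wt)  # mu = 0, population sd = 2
  expect_identical(sel$roi_label, 1L)
  expect_identical(sel$weight, -3)

  # scale equivariance: positive scaling keeps the selected set
  wt_scaled <- make_weight_table(10 * c(-3, -1, 0, 1, 3), atlas5,
                                 extra = c(age = -90))
  expect_identical(threshold_negative_weights(wt_scaled)$roi_label,
                   sel$roi_label)

  # all weights equal: sigma = 0, empty selection with warning
  wt_const <- make_weight_table(rep(2, 5), atlas5)
  expect_warning(sel0 <- threshold_negative_weights(wt_const), "sigma = 0")
  expect_identical(nrow(sel0), 0L)

  # all positive: the negativity requirement empties the selection
  wt_pos <- make_weight_table(c(0.1, 1, 2, 3, 10), atlas5)
  expect_identical(nrow(threshold_negative_weights(wt_pos)), 0L)
})

test_that("thresholded weights recover the truly deficit-driving ROIs", {
  # parcels large enough that ROI-level signal is identifiable
  cohort <- generate_cohort(sim_config(
    n_patients = 300, seed = 4, n_rois = 30, untestable_prob = 0,
    noise_sd = c(acute = 1, "1mo" = 1, "3mo" = 1, "12mo" = 1)))
  model <- fit_family_model(cohort, "overall", "acute", "llv")
  sel <- threshold_negative_weights(extract_weights(model, cohort$atlas))
  truth <- cohort$ground_truth$informative_labels
  jaccard <- length(intersect(sel$roi_label, truth)) /
    length(union(sel$roi_label, truth))
  expect_gt(jaccard, 0.5)

  # under the fine 150-parcel default the threshold stays fully sensitive
  # (every true ROI selected), though spatially correlated neighbours can
  # enter the selection too
  fine <- generate_cohort(sim_config(
    n_patients = 300, seed = 4, untestable_prob = 0,
    noise_sd = c(acute = 1, "1mo" = 1, "3mo" = 1, "12mo" = 1)))
  model_f <- fit_family_model(fine, "overall", "acute", "llv")
  sel_f <- threshold_negative_weights(extract_weights(model_f, fine$atlas))
  expect_true(all(fine$ground_truth$informative_labels %in% sel_f$roi_label))
})

test_that("projection paints constant |weight| patches and round-trips", {
  labels <- array(0L, c(10, 10, 10))
  labels[1:2, 1:5, 1:4] <- 1L   # 40 voxels
  labels[5:6, 1:5, 1:4] <- 2L
  atlas <- atlas_definition(
    labels, voxel_grid(c(10, 10, 10), c(2, 2, 2)),
    data.frame(label = 1:2, name = c("gm_1", "gm_2"),
               tissue_class = "grey"))

  wt <- make_weight_table(c(-2.5, -4), atlas)
  wt <- wt[wt$is_llv, ]
  vol <- project_to_volume(wt, atlas)
  expect_identical(sum(vol$data == 2.5), 40L)
  expect_identical(sum(vol$data == 4), 40L)
  expect_identical(sum(vol$data != 0), 80L)

  # per-ROI voxel-scan recovery of |weights|
  for (i in 1:2) {
    patch <- vol$data[atlas$labels == wt$roi_label[i]]
    expect_true(all(patch == abs(wt$weight[i])))
  }

  empty <- wt[integer(0), ]
  expect_true(all(project_to_volume(empty, atlas)$data == 0))

  bad <- wt
  bad$roi_label <- c(1L, 99L)
  expect_error(project_to_volume(bad, atlas), "unknown ROI")
})
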