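test_that("synthetic atlases partition the brain mask into valid parcels", {
  atlas <- make_synthetic_atlas(c(16, 16, 16), n_rois = 4, seed = 50)
  expect_identical(atlas$n_rois, 4L)
  expect_identical(sort(unique(as.vector(atlas$labels[atlas$labels > 0]))),
                   1:4)
  expect_true(all(atlas$voxel_counts >= 8))

  # same seed twice: identical label volumes
  atlas2 <- make_synthetic_atlas(c(16, 16, 16), n_rois = 4, seed = 50)
  expect_identical(atlas$labels, atlas2$labels)

  # parcels are 6-connected (BFS reaches every parcel voxel)
  for (lab in 1:4) {
    vox <- which(atlas$labels == lab)
    reached <- vox[1]
    frontier <- vox[1]
    elig <- atlas$labels == lab
    while (length(frontier)) {
      nb <- mlsm:::neighbours_6(frontier, dim(atlas$labels), elig)
      frontier <- setdiff(nb, reached)
      reached <- c(reached, frontier)
    }
    expect_identical(sort(reached), sort(vox))
  }

  expect_error(make_synthetic_atlas(c(6, 6, 6), n_rois = 150, seed = 1),
               "too small")
})

test_that("a 150-parcel atlas fits the reference grey/white/commissural split", {
  atlas <- make_synthetic_atlas(c(48, 48, 48), n_rois = 150,
                                voxel_size_mm = c(3, 3, 3), seed = 60)
  expect_identical(sum(atlas$roi_table$tissue_class == "grey"), 123L)
  expect_identical(sum(atlas$roi_table$tissue_class == "white"), 21L)
  expect_identical(sum(atlas$roi_table$tissue_class == "commissural"), 6L)
  expect_identical(length(unique(atlas$roi_table$label)), 150L)
  expect_true(min(atlas$voxel_counts) >= 8)
})

test_that("simulated lesions are contiguous and hit the target volume", {
  atlas <- make_synthetic_atlas(c(20, 20, 20), n_rois = 6,
                                voxel_size_mm = c(4, 4, 4), seed = 70)
  voxvol <- prod(atlas$grid$voxel_size_mm) / 1000

  les1 <- simulate_lesion(atlas, voxvol, seed = 71)  # one-voxel target
  expect_identical(sum(les1$data), 1)

  les0 <- simulate_lesion(atlas, 0, seed = 72)  # minimum one voxel enforced
  expect_identical(sum(les0$data), 1)

  les <- simulate_lesion(atlas, 30, seed = 73)
  expect_identical(sum(les$data), round(30 / voxvol))
  expect_true(all(atlas$labels[les$data == 1] > 0))  # confined to the mask

  # contiguity: BFS from one lesion voxel reaches all of it
  vox <- which(les$data == 1)
  elig <- les$data == 1
  reached <- vox[1]
  frontier <- vox[1]
  while (length(frontier)) {
    nb <- mlsm:::neighbours_6(frontier, dim(les$data), elig)
    frontier <- setdiff(nb, reached)
    reached <- c(reached, frontier)
  }
  expect_identical(sort(reached), sort(vox))

  expect_error(simulate_lesion(atlas, 1e5, seed = 74), "80%")
})

test_that("scores respect bounds, ceilings and the untestable convention", {
  # no-deficit, (near) noise-free: every timepoint scores min(baseline, 10)
  # (recovery pulls toward the ceiling, so an intact patient stays there)
  quiet_cfg <- sim_config(n_patients = 2, grid_dims = c(20, 20, 20),
                          voxel_size_mm = c(5, 5, 5), n_rois = 12,
                          baseline = 10,
                          noise_sd = c(acute = 1e-9, "1mo" = 1e-9,
                                       "3mo" = 1e-9, "12mo" = 1e-9),
                          untestable_prob = 0, seed = 5)
  llv0 <- matrix(0, 2, 12, dimnames = list(c("p1", "p2"),
                                           paste0("llv_", 1:12)))
  truth <- list(roi_weights = setNames(rep(-5, 12), paste0("llv_", 1:12)),
                informative_labels = 1:12, mode = "location")
  sim <- simulate_scores(llv0, truth, quiet_cfg, seed = 6)
  ov <- sim$scores[sim$scores$outcome == "overall", ]
  expect_true(all(abs(ov$value - min(quiet_cfg$baseline, 10)) < 1e-6))

  # full recovery: follow-up scores reach the ceiling
  full_cfg <- sim_config(n_patients = 2, grid_dims = c(20, 20, 20),
                         voxel_size_mm = c(5, 5, 5), n_rois = 12,
                         noise_sd = c(acute = 1e-9, "1mo" = 1e-9,
                                      "3mo" = 1e-9, "12mo" = 1e-9),
                         recovery_fractions = list(
                           severe = c(acute = 0, "1mo" = 1, "3mo" = 1,
                                      "12mo" = 1),
                           mild = c(acute = 0, "1mo" = 1, "3mo" = 1,
                                    "12mo" = 1)),
                         untestable_prob = 0, seed = 5)
  llv1 <- llv0; llv1[1, 1] <- 0.5
  sim2 <- simulate_scores(llv1, truth, full_cfg, seed = 6)
  fu <- sim2$scores[sim2$scores$outcome == "overall" &
                      sim2$scores$timepoint != "acute", ]
  expect_true(all(abs(fu$value - 10) < 1e-6))

  # severe patients become untestable: overall 0, subscores missing at acute
  cohort <- make_tiny_cohort(n = 60, seed = 91, untestable_prob = 1,
                             untestable_threshold = 3)
  unt <- names(which(cohort$ground_truth$untestable))
  expect_gt(length(unt), 0)
  sc <- cohort$scores
  acute_overall <- sc[sc$outcome == "overall" & sc$timepoint == "acute", ]
  expect_true(all(acute_overall$value[acute_overall$patient_id %in% unt] == 0))
  acute_sub <- sc[sc$outcome != "overall" & sc$timepoint == "acute" &
                    sc$patient_id %in% unt, ]
  expect_true(all(is.na(acute_sub$value)))

  # every generated score is inside [0, 10]
  expect_true(all(is.na(sc$value) | (sc$value >= 0 & sc$value <= 10)))
})

test_that("dropout is severity-independent with the configured rate", {
  cohort <- make_tiny_cohort(n = 10, seed = 33)
  sc <- cohort$scores[cohort$scores$timepoint == "acute", ]

  none <- apply_dropout(sc, c("1mo" = 0, "3mo" = 0, "12mo" = 0), seed = 1)
  expect_identical(none, sc)

  full_sc <- make_tiny_cohort(n = 10, seed = 34,
                              dropout = c("1mo" = 0, "3mo" = 0,
                                          "12mo" = 0))$scores
  all_gone <- apply_dropout(full_sc, c("1mo" = 1, "3mo" = 1, "12mo" = 1),
                            seed = 2)
  expect_identical(sort(unique(all_gone$timepoint)), "acute")

  # retained count at 55% dropout stays inside the binomial 99% interval
  ids <- sprintf("p%03d", 1:217)
  big <- data.frame(patient_id = rep(ids, 2),
                    timepoint = rep(c("acute", "12mo"), each = 217),
                    outcome = "overall", value = 5)
  kept <- apply_dropout(big, c("1mo" = 0, "3mo" = 0, "12mo" = 0.55), seed = 3)
  n12 <- sum(kept$timepoint == "12mo")
  bounds <- qbinom(c(0.005, 0.995), 217, 0.45)
  expect_gte(n12, bounds[1])
  expect_lte(n12, bounds[2])
})

test_that("cohort generation is deterministic and round-trips through disk", {
  tmp <- withr::local_tempdir()
  cfg <- sim_config(n_patients = 8, grid_dims = c(20, 20, 20),
                    voxel_size_mm = c(5, 5, 5), n_rois = 10,
                    n_informative = 3, lesion_mean_cm3 = 40,
                    lesion_sd_cm3 = 30, lesion_range_cm3 = c(1, 150),
                    seed = 77)
  a <- generate_cohort(cfg, dir = file.path(tmp, "cohort"))
  b <- generate_cohort(cfg)
  expect_identical(a$llv, b$llv)
  expect_identical(a$scores, b$scores)
  expect_identical(a$covariates, b$covariates)

  # and twice to disk gives byte-identical tables
  cfg2 <- sim_config(n_patients = 8, grid_dims = c(20, 20, 20),
                     voxel_size_mm = c(5, 5, 5), n_rois = 10,
                     n_informative = 3, lesion_mean_cm3 = 40,
                     lesion_sd_cm3 = 30, lesion_range_cm3 = c(1, 150),
                     seed = 77)
  generate_cohort(cfg2, dir = file.path(tmp, "cohort2"))
  for (f in c("covariates.tsv", "scores.tsv", "atlas_rois.tsv",
              "ground_truth.json")) {
    expect_identical(readLines(file.path(tmp, "cohort", f)),
                     readLines(file.path(tmp, "cohort2", f)))
  }

  # reloading from disk reproduces the featurized cohort
  back <- load_cohort(file.path(tmp, "cohort"))
  expect_lt(max(abs(back$llv - a$llv)), 1e-12)
  expect_equal(back$covariates$lesion_extent_cm3,
               a$covariates$lesion_extent_cm3)
  expect_equal(back$scores$value, a$scores$value, tolerance = 1e-12)
  expect_identical(back$ground_truth$mode, "location")
})

test_that("lesion sizes track the configured log-normal scale", {
  cohort <- generate_cohort(sim_config(
    n_patients = 100, grid_dims = c(32, 32, 32), voxel_size_mm = c(4.5, 4.5, 4.5),
    n_rois = 30, seed = 123))
  m <- mean(cohort$covariates$lesion_extent_cm3)
  expect_lt(abs(m - 53.6) / 53.6, 0.25)
  expect_true(all(cohort$covariates$lesion_extent_cm3 > 0))
})
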