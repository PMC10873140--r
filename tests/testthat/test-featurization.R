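test_that("lesion load vectors match per-voxel accumulation", {
  atlas <- make_block_atlas()
  grid <- atlas$grid

  empty <- lesion_volume(array(0, grid$dims), grid)
  expect_identical(unname(compute_llv(empty, atlas)), rep(0, 4))

  # binary lesion exactly covering ROI 3 (no smoothing)
  full3 <- array(0, grid$dims)
  full3[atlas$labels == 3L] <- 1
  llv <- compute_llv(lesion_volume(full3, grid), atlas)
  expect_equal(unname(llv), c(0, 0, 1, 0))

  set.seed(11)
  for (rep in 1:5) {
    vals <- array(runif(prod(grid$dims)), grid$dims)
    got <- compute_llv(lesion_volume(vals, grid), atlas)
    want <- llv_oracle(as.vector(vals), as.vector(atlas$labels),
                       atlas$roi_table$label)
    expect_lt(max(abs(got - want)), 1e-12)
  }

  other <- lesion_volume(array(0, c(8, 8, 8)), voxel_grid(c(8, 8, 8), c(2, 2, 2)))
  expect_error(compute_llv(other, atlas), "same voxel grid")
})

test_that("growing a lesion never decreases any load (no smoothing)", {
  atlas <- make_block_atlas()
  set.seed(5)
  base <- array(0, atlas$grid$dims)
  inside <- which(atlas$labels > 0)
  lesioned <- sample(inside, 80)
  base[lesioned] <- 1
  small <- compute_llv(lesion_volume(base, atlas$grid), atlas)
  grown <- base
  grown[sample(setdiff(inside, lesioned), 120)] <- 1
  large <- compute_llv(lesion_volume(grown, atlas$grid), atlas)
  expect_true(all(large >= small))
})

test_that("lesion extent converts voxel counts to cm3", {
  grid1 <- voxel_grid(c(10, 10, 10), c(1, 1, 1))
  m <- array(1, grid1$dims)  # 1000 voxels of 1 mm3
  expect_equal(lesion_extent_cm3(lesion_volume(m, grid1)), 1.0)

  expect_equal(lesion_extent_cm3(lesion_volume(array(0, grid1$dims), grid1)), 0)

  grid2 <- voxel_grid(c(20, 20, 20), c(2, 2, 2))
  m2 <- array(0, grid2$dims)
  m2[seq_len(790)] <- 1
  expect_equal(lesion_extent_cm3(lesion_volume(m2, grid2)), 6.32)

  soft <- lesion_volume(array(0.5, grid1$dims), grid1, is_binary = FALSE)
  expect_error(lesion_extent_cm3(soft), "binary")
})

test_that("covariate encoding and min-max scaling follow the train-only rule", {
  enc <- encode_covariates(data.frame(
    patient_id = c("a", "b"), age = c(20, 90), sex = c("M", "F"),
    handedness = c("R", "A"), education = c(12, 16),
    stroke_type = c("ischaemic", "haemorrhagic"),
    lesion_extent_cm3 = c(10, 20)))
  expect_equal(enc$sex, c(0, 1))
  expect_equal(enc$handedness, c(1, 0.5))
  expect_equal(enc$stroke_type, c(0, 1))
  expect_error(encode_covariates(data.frame(
    patient_id = "a", age = 50, sex = "X", handedness = "R",
    education = 12, stroke_type = "ischaemic", lesion_extent_cm3 = 1)),
    "invalid sex")

  train <- cbind(age = c(20, 90), sex = c(0, 0))
  new <- cbind(age = c(55, 95), sex = c(1, 0))
  sc <- minmax_scale(train, newdata = new)
  expect_equal(unname(sc$newdata[1, "age"]), 0.5)   # midpoint of train range
  expect_equal(unname(sc$newdata[2, "age"]), 1.0)   # clipped above train max
  expect_true(all(sc$train[, "sex"] == 0))          # constant column -> 0
  expect_true(all(sc$newdata[, "sex"] == 0))
})

test_that("assembled feature matrices have the documented column layout", {
  cohort <- make_table_cohort(n = 12, n_rois = 150)
  fm <- assemble_features(cohort, "overall", "3mo", "llv")
  expect_identical(ncol(fm$x), 156L)  # 150 LLV + extent + 5 demographic
  expect_identical(
    colnames(fm$x)[151:156],
    c("lesion_extent_cm3", "age", "sex", "handedness", "education",
      "stroke_type"))

  fm_ip <- assemble_features(cohort, "overall", "3mo", "llv_ip")
  expect_identical(ncol(fm_ip$x), 157L)
  expect_identical(colnames(fm_ip$x)[157], "acute_overall")

  fm_red <- assemble_features(cohort, "overall", "3mo",
                              "reduced_no_llv_no_extent")
  expect_identical(ncol(fm_red$x), 5L)

  # LLV columns are never min-max scaled; everything else is
  expect_identical(fm$scale_cols,
                   setdiff(colnames(fm$x), paste0("llv_", 1:150)))

  # deterministic: identical inputs give bit-identical output, rows sorted
  fm2 <- assemble_features(cohort, "overall", "3mo", "llv")
  expect_identical(fm, fm2)
  expect_identical(fm$patient_ids, sort(fm$patient_ids))

  expect_error(assemble_features(cohort, "overall", "acute", "llv_ip"),
               "acute")
})

test_that("untestable-acute patients enter overall models but no subscore model", {
  cohort <- make_table_cohort(n = 10)
  sc <- cohort$scores
  # mark two patients untestable at acute: overall 0, subscores missing
  unt <- c("p001", "p002")
  sc$value[sc$patient_id %in% unt & sc$timepoint == "acute" &
             sc$outcome == "overall"] <- 0
  sc$value[sc$patient_id %in% unt & sc$timepoint == "acute" &
             sc$outcome != "overall"] <- NA
  cohort <- mlsm_cohort(cohort$llv, cohort$covariates, sc)

  fm_overall <- assemble_features(cohort, "overall", "acute", "llv")
  expect_true(all(unt %in% fm_overall$patient_ids))
  expect_true(all(fm_overall$response[match(unt, fm_overall$patient_ids)] == 0))

  fm_sub <- assemble_features(cohort, "word_finding", "acute", "llv")
  expect_false(any(unt %in% fm_sub$patient_ids))
  expect_identical(nrow(fm_sub$x), 8L)

  # empty case set raises an informative error naming the cell
  sc2 <- sc[!(sc$outcome == "reading" & sc$timepoint == "12mo"), ]
  cohort2 <- mlsm_cohort(cohort$llv, cohort$covariates, sc2)
  expect_error(assemble_features(cohort2, "reading", "12mo", "llv"),
               "reading.*12mo")
})

test_that("wide and long score readers agree", {
  tmp <- withr::local_tempdir()
  wide <- data.frame(patient_id = c("a", "b"), timepoint = "acute",
                     overall = c(5, NA), reading = c(2.5, 10))
  write.table(wide, file.path(tmp, "wide.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE, na = "")
  long <- read_scores_wide(file.path(tmp, "wide.tsv"))
  expect_identical(sort(unique(long$outcome)), c("overall", "reading"))
  expect_true(is.na(long$value[long$patient_id == "b" &
                                 long$outcome == "overall"]))
  write.table(long, file.path(tmp, "long.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE, na = "")
  back <- read_scores_long(file.path(tmp, "long.tsv"))
  expect_identical(back$value, long$value)
})
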