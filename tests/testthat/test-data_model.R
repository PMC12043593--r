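test_that("motor score derivation and binarisation follow the clinical coding", {
  expect_identical(derive_motor_score(0, 0), 10L)  # no impairment
  expect_identical(derive_motor_score(4, 4), 2L)   # major impairment
  expect_identical(derive_motor_score(2, 1), 7L)
  expect_identical(derive_motor_score(c(0, 4), c(0, 4)), c(10L, 2L))
  expect_error(derive_motor_score(5, 0), "\\[0, 4\\]")
  expect_error(derive_motor_score(0, -1), "\\[0, 4\\]")
  expect_error(derive_motor_score(0.5, 1), "\\[0, 4\\]")

  expect_identical(binarize_performance(10), 1L)
  expect_identical(binarize_performance(9), 0L)
  expect_identical(binarize_performance(2), 0L)
  expect_error(binarize_performance(1), "\\[2, 10\\]")
  expect_error(binarize_performance(11), "\\[2, 10\\]")

  # ability is 1 iff both limb items are 0, over the whole item grid
  grid <- expand.grid(u = 0:4, l = 0:4)
  got <- binarize_performance(derive_motor_score(grid$u, grid$l))
  expect_identical(got, as.integer(grid$u == 0 & grid$l == 0))
})

test_that("region_set enforces its invariants", {
  expect_error(region_set(c("a", "a", "RoB"), c(1, 2, 3), rob_id = "RoB"),
               "unique")
  expect_error(region_set(c("a", "b"), c(1, 2), rob_id = "zz"), "rob_id")
  expect_error(region_set(c("a", "RoB"), c(0, 5), rob_id = "RoB"),
               "positive")
  expect_error(region_set(c("a", "b", "RoB"), c(1, 1, 1),
                          atlas_label = c(7L, 7L, NA), rob_id = "RoB"),
               "atlas labels")
  rs <- toy_region_set(2)
  expect_s3_class(rs, "region_set")
  expect_identical(rob_id(rs), "RoB")
})

test_that("lesion loads are extracted by voxel overlap and conserve voxels", {
  atlas <- toy_atlas()
  rs <- toy_two_region_set()

  # empty lesion
  res <- extract_lesion_loads(array(0, dim(atlas)), atlas, rs)
  expect_identical(unname(res$relative), c(0, 0, 0))

  # mask hits 2 of label 1's 5 voxels -> 40%, others 0
  mask <- array(0, dim(atlas)); mask[1:2] <- 1
  res <- extract_lesion_loads(mask, atlas, rs)
  expect_equal(unname(res$absolute), c(2, 0, 0))
  expect_equal(unname(res$relative), c(40, 0, 0))

  # complete ablation of region b
  mask_b <- array(as.numeric(atlas == 2), dim(atlas))
  res <- extract_lesion_loads(mask_b, atlas, rs)
  expect_equal(unname(res$relative), c(0, 100, 0))

  # unclaimed non-background voxels go to the RoB; counts are conserved
  atlas2 <- array(c(1, 1, 0, 2, 2, 3, 3, 3, 4), dim = c(3, 3, 1))
  rs2 <- region_set(c("a", "b", "RoB"), voxel_count = c(2, 2, 4),
                    atlas_label = c(1L, 2L, NA), rob_id = "RoB")
  for (seed in 1:5) {
    mask <- with_test_seed(seed,
                           array(rbinom(9, 1, 0.5), dim = c(3, 3, 1)))
    res <- extract_lesion_loads(mask, atlas2, rs2)
    expect_equal(sum(res$absolute), sum(mask == 1 & atlas2 != 0))
  }

  expect_error(extract_lesion_loads(array(0, c(2, 2)), atlas, rs),
               "different grids")
  expect_error(extract_lesion_loads(array(2, dim(atlas)), atlas, rs),
               "binary")
  rs3 <- region_set(c("a", "ghost", "RoB"), voxel_count = c(5, 3, 4),
                    atlas_label = c(1L, 99L, NA), rob_id = "RoB")
  atlas3 <- array(c(1, 1, 1, 1, 1, 3, 3, 3, 3), dim = c(3, 3, 1))
  expect_warning(res <- extract_lesion_loads(mask_b * 0 + 1, atlas3, rs3),
                 "absent")
  expect_equal(unname(res$absolute["ghost"]), 0)
})

test_that("lesion-pattern correlations match direct Pearson computation", {
  # 5-patient toy table checked against the closed-form estimate and
  # cor.test's t-based p-value
  loads <- cbind(a = c(0, 10, 20, 40, 80),
                 b = c(5, 0, 30, 35, 90),
                 c = c(0, 20, 40, 80, 160) / 2,   # = 2*a scaled: r(a,c)=1
                 RoB = c(1, 2, 3, 4, 5))
  rs_abc <- region_set(c("a", "b", "c", "RoB"), voxel_count = rep(10, 4),
                       atlas_label = c(1L, 2L, 3L, NA), rob_id = "RoB")
  ds <- lesion_dataset(loads, rep(10L, 5), rs_abc)
  cm <- lesion_correlations(ds)
  pearson <- function(x, y)
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm$r["a", "b"], pearson(loads[, "a"], loads[, "b"]))
  expect_equal(cm$r["a", "c"], 1)
  ct <- cor.test(loads[, "a"], loads[, "b"])
  expect_equal(cm$p["a", "b"], ct$p.value)
  expect_equal(unname(diag(cm$r)), rep(1, 4))
  expect_equal(cm$r, t(cm$r))
  expect_true(all(cm$p >= 0 & cm$p <= 1, na.rm = TRUE))

  # constant column: undefined, reported missing, not zero
  loads2 <- loads; loads2[, "b"] <- 7
  ds2 <- lesion_dataset(loads2, rep(10L, 5), rs_abc)
  expect_warning(cm2 <- lesion_correlations(ds2), "zero-variance")
  expect_true(all(is.na(cm2$r["b", ])))
  expect_identical(cm2$constant, "b")

  expect_error(lesion_correlations(
    lesion_dataset(loads[1:2, ], rep(10L, 2), rs_abc)),
    "3 patients")
})

test_that("merging into the RoB pools voxels and conserves lesion mass", {
  # voxel counts (100, 300), loads (50, 10), RoB 600 voxels at 0%
  rs <- region_set(c("a", "b", "RoB"), voxel_count = c(100, 300, 600),
                   atlas_label = c(1L, 2L, NA), rob_id = "RoB")
  ds <- lesion_dataset(matrix(c(50, 10, 0), 1), 10L, rs)
  merged <- merge_into_rob(ds, c("a", "b"))
  expect_equal(unname(merged$loads[1, "RoB"]), 100 * (50 + 30 + 0) / 1000)
  expect_equal(merged$region_set$voxel_count, 1000)

  # discarding an all-zero region only dilutes the RoB
  ds0 <- lesion_dataset(matrix(c(0, 10, 20), 1), 10L, rs)
  m0 <- merge_into_rob(ds0, "a")
  expect_equal(unname(m0$loads[1, "RoB"]), 20 * 600 / (600 + 100))

  # pooled lesioned-voxel counts are conserved per patient, and merging is
  # associative
  ds_multi <- lesion_dataset(matrix(runif(5 * 3, 0, 100), 5), rep(10L, 5), rs)
  before <- pooled_lesion_voxels(ds_multi)
  both <- merge_into_rob(ds_multi, c("a", "b"))
  oneatatime <- merge_into_rob(merge_into_rob(ds_multi, "a"), "b")
  expect_equal(pooled_lesion_voxels(both), before)
  expect_equal(both$loads, oneatatime$loads)
  expect_identical(both$motor_score, ds_multi$motor_score)
  expect_identical(both$patient_id, ds_multi$patient_id)

  expect_error(merge_into_rob(ds, "RoB"), "cannot be discarded")
  expect_error(merge_into_rob(ds, "zz"), "unknown")
})

test_that("cohort subsetting supports the leave-out analyses", {
  ds <- threshold_cohort(n = 20)
  ds$metadata <- data.frame(bilateral = rep(c(TRUE, FALSE), 10),
                            recurrent = rep(c(FALSE, TRUE), each = 10))
  uni <- filter_cohort(ds, exclude_bilateral = TRUE)
  expect_equal(n_patients(uni), 10)
  first <- filter_cohort(ds, exclude_recurrent = TRUE)
  expect_equal(n_patients(first), 10)
  both <- filter_cohort(ds, TRUE, TRUE)
  expect_equal(n_patients(both), 5)
  expect_error(filter_cohort(threshold_cohort(n = 5), TRUE), "bilateral")
})
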