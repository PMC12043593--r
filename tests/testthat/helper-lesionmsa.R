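# in-code fixtures shared across the suite: tiny region sets, toy volumes,
# and small cohorts with known outcome rules

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_region_set <- function(p = 3, vox = rep(10, p), rob_vox = 100) {
  region_set(c(sprintf("r%d", seq_len(p)), "RoB"),
             voxel_count = c(vox, rob_vox),
             atlas_label = c(seq_len(p), NA_integer_),
             rob_id = "RoB")
}

# cohort whose deficit is a deterministic threshold on region 1's load
threshold_cohort <- function(n = 60, p = 3, cut = 50, seed = 1) {
  loads <- with_test_seed(seed, {
    m <- matrix(round(runif(n * (p + 1), 0, 100), 2), n, p + 1)
    m[, p + 1] <- round(runif(n, 0, 5), 2)  # small incidental RoB loads
    m
  })
  score <- ifelse(loads[, 1] >= cut, 5L, 10L)
  lesion_dataset(loads, score, toy_region_set(p))
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# 3x3x1 grid: label 1 on 5 voxels, label 2 on 4 voxels (fully claimed atlas)
toy_atlas <- function() {
  array(c(1, 1, 1,
          1, 1, 2,
          2, 2, 2), dim = c(3, 3, 1))
}

toy_two_region_set <- function(rob_vox = 50) {
  region_set(c("a", "b", "RoB"), voxel_count = c(5, 4, rob_vox),
             atlas_label = c(1L, 2L, NA_integer_), rob_id = "RoB")
}
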