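#' Specification of a synthetic lesion cohort
#'
#' Describes a stroke-like cohort with known ground truth: sparse graded
#' lesions whose occurrence is correlated within vascular-territory blocks
#' (a Gaussian copula on block-level occurrence), a small planted set of
#' causal regions whose weighted damage drives a thresholded deficit, and a
#' binarised motor outcome. Defaults are a 1/5-scale analogue of a ~270
#' patient, 151-ROI clinical cohort: 300 patients, 30 regions plus RoB,
#' 3 causal regions spread across different territories, and a ~70/30
#' normal/pathological split.
#'
#' @param n_patients cohort size.
#' @param n_regions number of regions excluding the RoB.
#' @param block_size regions per territory block.
#' @param rho within-block occurrence correlation in `[0, 1)`.
#' @param prevalence probability a patient's lesion touches a given region's
#'   territory draw (per region, before the copula).
#' @param causal_weights named or positional non-negative weights over the
#'   non-RoB regions; default plants weights 1.0 / 0.85 / 0.7 on the first
#'   region of blocks 1-3.
#' @param load_shape Beta shape parameters of the graded severity draw on
#'   `[0, 100]`.
#' @param theta deficit threshold: performance is 0 when
#'   `sum(weight * load) / 100 >= theta`.
#' @param label_noise probability of flipping the binary outcome.
#' @param voxel_counts per-region voxel counts (default log-spaced
#'   750-4,500); the RoB voxel count is `rob_voxels`.
#' @param rob_voxels voxels of the rest-of-brain element.
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients = 300, n_regions = 30, block_size = 5,
                           rho = 0.5, prevalence = 0.35,
                           causal_weights = NULL,
                           load_shape = c(1.2, 3), theta = 0.3,
                           label_noise = 0.02, voxel_counts = NULL,
                           rob_voxels = 8e5, seed = 1) {
  stopifnot(n_patients >= 2, n_regions >= 2, rho >= 0, rho < 1,
            prevalence > 0, prevalence < 1, theta > 0,
            label_noise >= 0, label_noise < 0.5)
  if (is.null(causal_weights)) {
    causal_weights <- numeric(n_regions)
    heads <- 1 + block_size * (0:2)
    heads <- heads[heads <= n_regions]
    causal_weights[heads] <- c(1.0, 0.85, 0.7)[seq_along(heads)]
  }
  if (length(causal_weights) != n_regions || any(causal_weights < 0))
    stop("causal_weights must be non-negative, one per non-RoB region")
  if (is.null(voxel_counts))
    voxel_counts <- round(exp(seq(log(750), log(4500),
                                  length.out = n_regions)))
  stopifnot(length(voxel_counts) == n_regions, all(voxel_counts > 0))
  structure(list(n_patients = n_patients, n_regions = n_regions,
                 block_size = block_size, rho = rho,
                 prevalence = prevalence, causal_weights = causal_weights,
                 load_shape = load_shape, theta = theta,
                 label_noise = label_noise, voxel_counts = voxel_counts,
                 rob_voxels = rob_voxels, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic lesion cohort with planted ground truth
#'
#' Per patient: block-correlated lesion-occurrence indicators (latent
#' equicorrelated normals thresholded at the prevalence quantile), graded
#' Beta severities for hit regions, a weighted-threshold deficit rule,
#' optional label flips, and a motor score consistent with the binary
#' outcome (10 when normal; a graded 2-9 score scaling with latent damage
#' when pathological). The RoB column receives small incidental loads and
#' carries no causal weight.
#'
#' When the spec is noise-free the generator re-derives every outcome from
#' the threshold rule and stops if any label disagrees (a self-check of the
#' stated world).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (a [lesion_dataset()] whose last column is
#'   the RoB) and `truth` (list: `causal_ids`, `weights`, `latent`,
#'   `pre_noise_performance`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_patients
  p <- spec$n_regions
  with_seed(spec$seed, {
    block <- rep(seq_len(ceiling(p / spec$block_size)),
                 each = spec$block_size)[seq_len(p)]
    u <- matrix(rnorm(n * max(block)), n, max(block))  # shared block factor
    e <- matrix(rnorm(n * p), n, p)
    z <- sqrt(spec$rho) * u[, block] + sqrt(1 - spec$rho) * e
    hit <- z < qnorm(spec$prevalence)
    sev <- matrix(100 * rbeta(n * p, spec$load_shape[1], spec$load_shape[2]),
                  n, p)
    loads <- hit * sev
    latent <- as.numeric(loads %*% spec$causal_weights) / 100
    deficit <- as.integer(latent >= spec$theta)
    pre_noise <- 1L - deficit
    if (spec$label_noise > 0) {
      flip <- runif(n) < spec$label_noise
      deficit <- ifelse(flip, 1L - deficit, deficit)
    }
    performance <- 1L - deficit
    if (all(spec$causal_weights == 0) && spec$label_noise == 0)
      warning("degenerate spec: all weights zero and no noise, ",
              "every patient is normal")
    # motor score consistent with the binary coding: normal -> 10,
    # pathological -> 2..9 scaled by latent damage
    severity <- pmin(7L, 1L + as.integer(round(6 * pmin(latent / spec$theta,
                                                        2) / 2)))
    score <- ifelse(performance == 1L, 10L, 10L - severity - 1L)
    score <- pmax(2L, pmin(9L, score))
    score[performance == 1L] <- 10L
    # small incidental RoB loads, causally null
    rob_load <- (runif(n) < 0.9) * 100 * rbeta(n, 1.5, 60)
    rs <- region_set(c(sprintf("roi_%02d", seq_len(p)), "RoB"),
                     voxel_count = c(spec$voxel_counts, spec$rob_voxels),
                     atlas_label = c(seq_len(p), NA_integer_),
                     rob_id = "RoB")
    ds <- lesion_dataset(cbind(loads, rob_load), score, rs)
    if (spec$label_noise == 0 &&
        !identical(ds$performance, pre_noise))
      stop("internal error: outcomes inconsistent with the threshold rule")
    causal <- which(spec$causal_weights > 0)
    list(dataset = ds,
         truth = list(causal_ids = rs$region_id[causal],
                      weights = structure(spec$causal_weights[causal],
                                          names = rs$region_id[causal]),
                      latent = latent,
                      pre_noise_performance = pre_noise))
  })
}

#' Ground-truth recovery metrics for an iterative MSA trace
#'
#' Compares the final significant (non-RoB) set against the planted causal
#' regions: recall (fraction of causal regions recovered), precision
#' (fraction of the recovered set that is causal; `NA` when the set is
#' empty), and rank agreement (Spearman correlation between planted weights
#' and final-iteration contributions over the causal regions still present;
#' `NA` with fewer than 3 comparable regions).
#'
#' @param trace an `msa_trace`.
#' @param truth the `truth` element of [generate_cohort()].
#' @return list with `recall`, `precision`, `rank_agreement`,
#'   `final_significant`.
#' @export
recovery_metrics <- function(trace, truth) {
  stopifnot(inherits(trace, "msa_trace"))
  found <- final_significant_set(trace)
  causal <- truth$causal_ids
  recall <- if (length(causal)) mean(causal %in% found) else NA_real_
  precision <- if (length(found)) mean(found %in% causal) else NA_real_
  res <- trace$final_result
  present <- intersect(causal, res$region_id)
  rank_agreement <- if (length(present) >= 3L) {
    suppressWarnings(cor(truth$weights[present],
                         res$contribution[match(present, res$region_id)],
                         method = "spearman"))
  } else NA_real_
  list(recall = recall, precision = precision,
       rank_agreement = rank_agreement, final_significant = found)
}
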