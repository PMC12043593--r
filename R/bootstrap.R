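#' Bootstrap-aggregated estimated MSA
#'
#' The robustness layer of the analysis: for each of `B` bootstrap resamples
#' of patients (with replacement, at the original cohort size) the surrogate
#' forest is retrained and the estimated Shapley values are recomputed from
#' `R` sampled permutations. The reported contribution of a region is the
#' mean over resamples, its uncertainty the standard deviation over
#' resamples (the bootstrap SE), with a two-sided percentile confidence
#' interval; a region is flagged significant when that interval excludes 0.
#' Resamples that happen to contain a single outcome class are redrawn (and
#' counted), so all `B` replicates are effective.
#'
#' The resample/retrain/permute loop runs in compiled code; coalition values
#' are memoised within each replicate.
#'
#' @param dataset a [lesion_dataset()].
#' @param spec a `predictor_spec` (its chosen hyperparameters are used for
#'   every retrain).
#' @param B bootstrap replicates (reference analyses use 1,000).
#' @param R permutations per replicate (reference analyses use 1,000).
#' @param seed integer seed.
#' @param level confidence level of the percentile interval.
#' @param output_mode characteristic-function output, `"class"` or
#'   `"prob"`.
#' @param embedding binary-configuration embedding, `"ablation"` or
#'   `"mean_load"` (see [train_surrogate()]).
#' @param significance `"ci"` (percentile interval excludes 0, default) or
#'   `"z"` (`|mean|/se` beyond the normal quantile).
#' @return object of class `shapley_result`: list with `region_id`,
#'   `contribution`, `se`, `ci_low`, `ci_high`, `significant`, `boot`
#'   (the `B x p` replicate matrix), `B`, `R`, `seed`, `level`,
#'   `redraws`.
#' @export
bootstrap_msa <- function(dataset, spec, B = 1000, R = 1000, seed = 1,
                          level = 0.95, output_mode = c("class", "prob"),
                          embedding = c("ablation", "mean_load"),
                          significance = c("ci", "z")) {
  stopifnot(inherits(dataset, "lesion_dataset"),
            inherits(spec, "predictor_spec"), B >= 1, R >= 1)
  output_mode <- match.arg(output_mode)
  embedding <- match.arg(embedding)
  significance <- match.arg(significance)
  y <- dataset$performance
  if (length(unique(y)) < 2L)
    stop("bootstrap MSA requires both outcome classes")
  ch <- spec$chosen
  p <- ncol(dataset$loads)
  res <- boot_shapley_cpp(dataset$loads, y, as.integer(ch$n_trees),
                          depth_code(ch$max_depth),
                          mtry_of(ch$max_features, p),
                          isTRUE(ch$bootstrap), as.integer(ch$min_leaf),
                          as.integer(ch$min_split), as.integer(B),
                          as.integer(R),
                          lesioned_embedding(dataset, embedding),
                          output_mode == "class", as.integer(seed))
  boot <- res$boot
  colnames(boot) <- dataset$region_set$region_id
  contribution <- colMeans(boot)
  se <- if (B == 1L) rep(0, ncol(boot)) else apply(boot, 2L, sd)
  alpha <- 1 - level
  ci <- apply(boot, 2L, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)
  significant <- if (significance == "ci") {
    ci[1, ] > 0 | ci[2, ] < 0
  } else {
    abs(contribution) / pmax(se, .Machine$double.eps) > qnorm(1 - alpha / 2)
  }
  structure(list(region_id = dataset$region_set$region_id,
                 contribution = contribution, se = se,
                 ci_low = ci[1, ], ci_high = ci[2, ],
                 significant = significant, boot = boot,
                 B = B, R = R, seed = seed, level = level,
                 significance = significance, output_mode = output_mode,
                 redraws = res$redraws),
            class = "shapley_result")
}

#' @export
print.shapley_result <- function(x, ...) {
  cat(sprintf("shapley_result: %d regions, B = %d bootstrap x R = %d permutations\n",
              length(x$region_id), x$B, x$R))
  df <- as.data.frame(x)
  df <- df[order(-df$contribution), ]
  print.data.frame(head(df, 12L), row.names = FALSE, digits = 3)
  if (nrow(df) > 12L) cat(sprintf("... and %d more regions\n", nrow(df) - 12L))
  invisible(x)
}

#' @export
as.data.frame.shapley_result <- function(x, ...) {
  data.frame(region_id = x$region_id, contribution = x$contribution,
             se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
             significant = x$significant, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a Shapley result to CSV and JSON
#'
#' @param x a `shapley_result`.
#' @param csv,json output paths (either may be `NULL` to skip).
#' @return `x`, invisibly.
#' @export
write_shapley_result <- function(x, csv = NULL, json = NULL) {
  stopifnot(inherits(x, "shapley_result"))
  df <- as.data.frame(x)
  if (!is.null(csv)) write.csv(df, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(c(as.list(df),
                           list(B = x$B, R = x$R, seed = x$seed,
                                level = x$level)),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(x)
}
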