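#' Configuration of an iterative MSA run
#'
#' Defaults follow the reference analysis scale: 1,000 permutations per
#' Shapley estimate and 1,000 bootstrap replicates. `negligible_fraction`
#' controls the batch discard: besides the single weakest region, every
#' region whose absolute contribution falls below this fraction of the total
#' absolute contribution is folded into the RoB in the same iteration (0
#' reproduces strict one-at-a-time elimination).
#'
#' @param R permutations per Shapley estimate.
#' @param B bootstrap replicates.
#' @param alpha significance level of the bootstrap interval.
#' @param negligible_fraction batch-discard threshold in `[0, 1)`.
#' @param max_iterations safety cap on the elimination loop.
#' @param seed master seed; all stage seeds derive from it.
#' @param grid hyperparameter grid for the surrogate search.
#' @param output_mode,embedding,significance forwarded to
#'   [bootstrap_msa()].
#' @param reoptimize re-run the hyperparameter search each iteration
#'   (the feature space changes as regions merge); `FALSE` freezes the
#'   iteration-1 choice for speed.
#' @return list of class `run_config`.
#' @export
run_config <- function(R = 1000, B = 1000, alpha = 0.05,
                       negligible_fraction = 0.01, max_iterations = 100,
                       seed = 1, grid = default_predictor_grid(),
                       output_mode = "class", embedding = "ablation",
                       significance = "ci", reoptimize = TRUE) {
  stopifnot(R >= 1, B >= 1, alpha > 0, alpha < 1,
            negligible_fraction >= 0, negligible_fraction < 1,
            max_iterations >= 1)
  structure(list(R = R, B = B, alpha = alpha,
                 negligible_fraction = negligible_fraction,
                 max_iterations = max_iterations, seed = seed,
                 grid = check_grid(grid), output_mode = output_mode,
                 embedding = embedding, significance = significance,
                 reoptimize = reoptimize),
            class = "run_config")
}

#' Run the iterative estimated MSA
#'
#' Each iteration (i) selects surrogate hyperparameters on the current
#' dataset, (ii) runs [bootstrap_msa()], and (iii) discards the non-RoB
#' region with the smallest absolute contribution — plus all regions below
#' the negligible-contribution threshold — into the RoB via
#' [merge_into_rob()]. The loop keeps discarding while the RoB contribution
#' is non-significant; if a discard makes the RoB significant, that discard
#' is rolled back and the previous region set is returned (a significant RoB
#' signals that the discarded tissue carried real function). It also stops
#' when only one non-RoB region remains or when all remaining non-RoB
#' regions are significant positive contributors.
#'
#' Ties on the smallest contribution are broken towards the smaller voxel
#' count.
#'
#' @param dataset a [lesion_dataset()] with at least 2 non-RoB regions.
#' @param config a [run_config()].
#' @return object of class `msa_trace`: list with `iterations` (each with
#'   `region_ids`, `result`, `spec`, `discarded_ids`, `rob_significant`),
#'   `final_region_ids`, `final_result`, `stopping_reason`
#'   (`"rob_significant_next"`, `"min_set_reached"` or `"max_iter"`),
#'   `config`.
#' @export
run_iterative_msa <- function(dataset, config = run_config()) {
  stopifnot(inherits(dataset, "lesion_dataset"),
            inherits(config, "run_config"))
  rob <- rob_id(dataset)
  if (nrow(dataset$region_set) < 3L)
    stop("iterative MSA needs at least 2 non-RoB regions")
  seeds <- derive_seeds(config$seed, 2L * config$max_iterations)
  current <- dataset
  iterations <- list()
  stopping_reason <- NULL
  final <- NULL
  spec <- NULL
  t <- 0L
  repeat {
    t <- t + 1L
    if (config$reoptimize || is.null(spec))
      spec <- optimize_hyperparameters(current, grid = config$grid,
                                       seed = seeds[2L * t - 1L])
    res <- bootstrap_msa(current, spec, B = config$B, R = config$R,
                         seed = seeds[2L * t], level = 1 - config$alpha,
                         output_mode = config$output_mode,
                         embedding = config$embedding,
                         significance = config$significance)
    rob_sig <- unname(res$significant[res$region_id == rob])
    it <- list(region_ids = current$region_set$region_id, result = res,
               spec = spec, discarded_ids = character(0),
               rob_significant = rob_sig)
    if (rob_sig) {
      iterations[[t]] <- it
      if (t == 1L) {
        warning("RoB contribution significant before any discard; ",
                "the region set may be missing relevant structures")
        final <- iterations[[1L]]
      } else {
        final <- iterations[[t - 1L]]   # roll back the discard
      }
      stopping_reason <- "rob_significant_next"
      break
    }
    non_rob <- res$region_id != rob
    contr <- res$contribution
    if (sum(non_rob) <= 1L ||
        all(res$significant[non_rob] & contr[non_rob] > 0)) {
      iterations[[t]] <- it
      final <- it
      stopping_reason <- "min_set_reached"
      break
    }
    # mandatory single weakest discard (ties -> smaller voxel count) ...
    vox <- current$region_set$voxel_count
    ord <- order(abs(contr), vox, seq_along(contr))
    weakest <- res$region_id[ord[ord %in% which(non_rob)][1L]]
    # ... plus the negligible batch
    negligible <- res$region_id[non_rob &
      abs(contr) < config$negligible_fraction * sum(abs(contr))]
    discard <- union(weakest, negligible)
    # never empty the non-RoB set
    if (length(discard) >= sum(non_rob)) {
      keep_order <- order(-abs(contr))
      keep_one <- res$region_id[keep_order[keep_order %in%
                                             which(non_rob)][1L]]
      discard <- setdiff(discard, keep_one)
    }
    it$discarded_ids <- discard
    iterations[[t]] <- it
    if (t >= config$max_iterations) {
      warning("iterative MSA hit max_iterations before convergence")
      final <- it
      stopping_reason <- "max_iter"
      break
    }
    current <- merge_into_rob(current, discard)
  }
  structure(list(iterations = iterations,
                 final_region_ids = final$region_ids,
                 final_result = final$result,
                 stopping_reason = stopping_reason, config = config,
                 rob_id = rob),
            class = "msa_trace")
}

#' Regions flagged significant in the final set
#'
#' @param trace an `msa_trace`.
#' @param include_rob keep the RoB in the answer (default drops it).
#' @return character vector of region ids.
#' @export
final_significant_set <- function(trace, include_rob = FALSE) {
  res <- trace$final_result
  ids <- res$region_id[res$significant]
  if (!include_rob) ids <- setdiff(ids, trace$rob_id)
  ids
}

#' Summarise an iterative MSA trace
#'
#' Prints the per-iteration elimination history and the final contribution
#' table sorted by contribution, with bootstrap SE and significance
#' markers. An explicit banner is emitted when no region outside the RoB is
#' significant.
#'
#' @param trace an `msa_trace`.
#' @param ... unused.
#' @return invisibly, a list with `per_iteration` and `final` data frames.
#' @export
summarize_trace <- function(trace, ...) {
  stopifnot(inherits(trace, "msa_trace"))
  per_it <- data.frame(
    iteration = seq_along(trace$iterations),
    n_regions = vapply(trace$iterations, function(i)
      length(i$region_ids), integer(1)),
    rob_significant = vapply(trace$iterations, `[[`, logical(1),
                             "rob_significant"),
    n_discarded = vapply(trace$iterations, function(i)
      length(i$discarded_ids), integer(1)),
    discarded = vapply(trace$iterations, function(i)
      paste(i$discarded_ids, collapse = ";"), character(1)))
  final <- as.data.frame(trace$final_result)
  final <- final[order(-final$contribution), ]
  rownames(final) <- NULL
  cat(sprintf("iterative MSA: %d iteration(s), stopped on '%s'\n",
              nrow(per_it), trace$stopping_reason))
  print.data.frame(per_it, row.names = FALSE)
  cat(sprintf("\nfinal set (%d regions):\n", nrow(final)))
  marked <- final
  marked$sig <- ifelse(final$significant, "*", "")
  print.data.frame(marked, row.names = FALSE, digits = 3)
  if (!any(final$significant[final$region_id != trace$rob_id]))
    cat("\nNOTE: no significant contributors outside the RoB ",
        "(degenerate/null result)\n", sep = "")
  invisible(list(per_iteration = per_it, final = final))
}

#' @export
print.msa_trace <- function(x, ...) {
  cat(sprintf(paste0("msa_trace: %d iteration(s), final set of %d regions, ",
                     "stopping reason '%s'\n"),
              length(x$iterations), length(x$final_region_ids),
              x$stopping_reason))
  invisible(x)
}

#' Serialise a trace to JSON (results only, no models)
#'
#' @param trace an `msa_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  iters <- lapply(trace$iterations, function(it)
    list(region_ids = it$region_ids,
         contributions = as.data.frame(it$result),
         chosen_hyperparameters = as.list(it$spec$chosen),
         discarded_ids = it$discarded_ids,
         rob_significant = it$rob_significant))
  cfg <- unclass(trace$config)
  cfg$grid <- NULL
  jsonlite::write_json(
    list(iterations = iters,
         final_region_ids = trace$final_region_ids,
         final_contributions = as.data.frame(trace$final_result),
         stopping_reason = trace$stopping_reason,
         config = cfg),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
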