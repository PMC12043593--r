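#' Pairwise Pearson correlation of regional lesion patterns
#'
#' Correlates graded lesion-load columns across patients. High correlations
#' flag regions whose lesions co-occur, typically because they share a
#' vascular territory; such collinearity is what motivates multivariate
#' (game-theoretic) inference over mass-univariate mapping. Two-sided
#' p-values come from the t distribution with `n - 2` degrees of freedom.
#' Constant columns have no defined correlation and are reported as `NA`
#' (not coerced to zero), with a warning.
#'
#' @param dataset a [lesion_dataset()].
#' @param regions optional character vector restricting to a region subset.
#' @return object of class `correlation_matrix`: list with `r`, `p`
#'   (matrices with unit/`NA` diagonal handling as above), `region_id`,
#'   `n` (patients) and `constant` (ids of zero-variance columns).
#' @export
lesion_correlations <- function(dataset, regions = NULL) {
  stopifnot(inherits(dataset, "lesion_dataset"))
  x <- dataset$loads
  if (!is.null(regions)) {
    miss <- setdiff(regions, colnames(x))
    if (length(miss)) stop("unknown regions: ", paste(miss, collapse = ", "))
    x <- x[, regions, drop = FALSE]
  }
  n <- nrow(x)
  if (n < 3L) stop("at least 3 patients are required for correlations")
  sds <- apply(x, 2L, sd)
  constant <- colnames(x)[sds == 0]
  if (length(constant))
    warning("zero-variance lesion columns, correlations undefined: ",
            paste(constant, collapse = ", "))
  r <- suppressWarnings(cor(x))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r)[!colnames(x) %in% constant] <- 1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, region_id = colnames(x), n = n,
                 constant = constant),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf(paste0("correlation_matrix: %d regions, %d patients\n",
                     "  off-diagonal r: median %.3f, max %.3f; ",
                     "%d undefined column(s)\n"),
              length(x$region_id), x$n,
              stats::median(off, na.rm = TRUE), max(off, na.rm = TRUE),
              length(x$constant)))
  invisible(x)
}

#' Write a correlation matrix to CSV (wide and long form)
#'
#' @param x a `correlation_matrix`.
#' @param dir output directory; writes `correlations_r.csv`,
#'   `correlations_p.csv` and `correlations_long.csv`
#'   (`region_i, region_j, r, p`).
#' @return the directory, invisibly.
#' @export
write_correlations <- function(x, dir) {
  stopifnot(inherits(x, "correlation_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(x$r, file.path(dir, "correlations_r.csv"))
  write.csv(x$p, file.path(dir, "correlations_p.csv"))
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  long <- data.frame(region_i = x$region_id[idx[, 1]],
                     region_j = x$region_id[idx[, 2]],
                     r = x$r[idx], p = x$p[idx])
  write.csv(long, file.path(dir, "correlations_long.csv"), row.names = FALSE)
  invisible(dir)
}
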