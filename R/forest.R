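#' Fit a random-forest classifier on lesion loads
#'
#' Bagged Gini CART trees with per-split feature subsampling; the compiled
#' backend implements the six tunable dimensions used for surrogate
#' selection: number of trees, tree depth, feature fraction per split,
#' bootstrap flag, minimum leaf size and minimum split size.
#'
#' @param x numeric feature matrix (patients x regions, percent loads).
#' @param y integer 0/1 outcome (1 = intact performance).
#' @param n_trees number of trees.
#' @param max_depth maximum split depth; `NA` = unlimited.
#' @param max_features fraction of features tried per split in `(0, 1]`;
#'   `NA` = `sqrt(p)/p` (the usual classification default).
#' @param bootstrap draw a bootstrap sample per tree?
#' @param min_leaf,min_split minimum samples per leaf / to attempt a split.
#' @param seed integer seed for the forest's RNG.
#' @return object of class `rf_model` (tree arrays plus the settings used).
#' @export
rf_fit <- function(x, y, n_trees = 100, max_depth = NA, max_features = NA,
                   bootstrap = TRUE, min_leaf = 1, min_split = 2, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("x and y sizes differ")
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  p <- ncol(x)
  forest <- rf_train_cpp(x, y, as.integer(n_trees), depth_code(max_depth),
                         mtry_of(max_features, p), isTRUE(bootstrap),
                         as.integer(min_leaf), as.integer(min_split),
                         as.integer(seed))
  structure(list(forest = forest, p = p, feature_names = colnames(x),
                 params = list(n_trees = n_trees, max_depth = max_depth,
                               max_features = max_features,
                               bootstrap = bootstrap, min_leaf = min_leaf,
                               min_split = min_split, seed = seed)),
            class = "rf_model")
}

#' @param object an `rf_model`.
#' @param newdata feature matrix.
#' @param type `"prob"` for the class-1 probability (fraction of tree leaf
#'   votes), `"class"` for the hard 0/1 label.
#' @param ... unused.
#' @rdname rf_fit
#' @export
predict.rf_model <- function(object, newdata, type = c("prob", "class"),
                             ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$p)
    stop("newdata must have ", object$p, " columns")
  pr <- rf_predict_cpp(object$forest, newdata)
  if (type == "class") as.integer(pr >= 0.5) else pr
}

depth_code <- function(max_depth) {
  if (is.na(max_depth) || is.infinite(max_depth)) 0L
  else as.integer(max_depth)
}

mtry_of <- function(max_features, p) {
  if (is.na(max_features)) return(max(1L, as.integer(floor(sqrt(p)))))
  if (max_features <= 0 || max_features > 1)
    stop("max_features must be a fraction in (0, 1] or NA for sqrt")
  max(1L, as.integer(round(max_features * p)))
}
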