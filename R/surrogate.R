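#' F1 score from confusion counts
#'
#' `Precision = TP/(TP+FP)`, `Recall = TP/(TP+FN)`,
#' `F1 = 2 * Precision * Recall / (Precision + Recall)`. When `tp` is zero
#' (precision or recall undefined or zero) the score is 0 by convention.
#'
#' @param tp,fp,fn non-negative counts (vectorised).
#' @return F1 value(s) in `[0, 1]`.
#' @export
f1_score <- function(tp, fp, fn) {
  if (any(tp < 0) || any(fp < 0) || any(fn < 0))
    stop("confusion counts must be non-negative")
  ifelse(tp == 0, 0, 2 * tp / (2 * tp + fp + fn))
}

confusion_of <- function(truth, pred, positive) {
  c(tp = sum(pred == positive & truth == positive),
    fp = sum(pred == positive & truth != positive),
    tn = sum(pred != positive & truth != positive),
    fn = sum(pred != positive & truth == positive))
}

#' Default hyperparameter grid for the surrogate forest
#'
#' A deliberately modest grid spanning the six tuned dimensions. The
#' candidate values are package defaults (the source method fixes the
#' dimensions, not the values) sized for desk-scale cohorts; pass a larger
#' [expand.grid()] for heavier searches.
#'
#' @return data frame with columns `n_trees`, `max_depth`, `max_features`,
#'   `bootstrap`, `min_leaf`, `min_split`.
#' @export
default_predictor_grid <- function() {
  expand.grid(n_trees = 100, max_depth = c(5, 12), max_features = NA_real_,
              bootstrap = TRUE, min_leaf = c(1, 4), min_split = 2,
              KEEP.OUT.ATTRS = FALSE)
}

check_grid <- function(grid) {
  need <- c("n_trees", "max_depth", "max_features", "bootstrap", "min_leaf",
            "min_split")
  miss <- setdiff(need, names(grid))
  if (length(miss)) stop("grid lacks columns: ", paste(miss, collapse = ", "))
  if (any(grid$n_trees < 1) || any(grid$min_leaf < 1) ||
      any(grid$min_split < 2))
    stop("invalid grid entries")
  bad <- !is.na(grid$max_features) &
    (grid$max_features <= 0 | grid$max_features > 1)
  if (any(bad)) stop("max_features must be in (0, 1] or NA")
  grid[need]
}

#' Select surrogate hyperparameters by cross-validated F1
#'
#' Evaluates every grid point by stratified k-fold cross-validation on
#' (loads -> binary performance) and keeps the configuration with the best
#' pooled F1 on the deficit class (ties broken by grid order, so the search
#' is deterministic given the seed).
#'
#' @param dataset a [lesion_dataset()] containing both outcome classes.
#' @param grid hyperparameter data frame (see [default_predictor_grid()]).
#' @param seed integer seed (fold assignment and tree RNG).
#' @param k folds (reduced automatically if a class is rarer than `k`).
#' @param positive_class class the F1 targets; default `0`, the deficit
#'   class, usually the rarer and clinically relevant one.
#' @return object of class `predictor_spec`: list with `grid`, `chosen`
#'   (1-row data frame), `cv_f1` per grid row, `k`, `positive_class`,
#'   `seed`.
#' @export
optimize_hyperparameters <- function(dataset, grid = default_predictor_grid(),
                                     seed = 1, k = 5, positive_class = 0) {
  stopifnot(inherits(dataset, "lesion_dataset"))
  grid <- check_grid(grid)
  y <- dataset$performance
  if (length(unique(y)) < 2L)
    stop("hyperparameter search requires both outcome classes")
  k <- max(2L, min(k, min(table(y))))
  folds <- with_seed(seed, stratified_folds(y, k))
  sub_seeds <- derive_seeds(seed, nrow(grid))
  x <- dataset$loads
  cv_f1 <- vapply(seq_len(nrow(grid)), function(g) {
    pred <- integer(length(y))
    for (f in seq_len(k)) {
      test <- folds == f
      fit <- do.call(rf_fit, c(list(x = x[!test, , drop = FALSE],
                                    y = y[!test],
                                    seed = sub_seeds[g] + f),
                               as.list(grid[g, ])))
      pred[test] <- predict(fit, x[test, , drop = FALSE], type = "class")
    }
    cm <- confusion_of(y, pred, positive_class)
    f1_score(cm["tp"], cm["fp"], cm["fn"])
  }, numeric(1))
  structure(list(grid = grid, chosen = grid[which.max(cv_f1), , drop = FALSE],
                 cv_f1 = cv_f1, k = k, positive_class = positive_class,
                 seed = seed),
            class = "predictor_spec")
}

#' @export
print.predictor_spec <- function(x, ...) {
  cat(sprintf("predictor_spec: %d grid points, %d-fold CV, best F1 = %.3f\n",
              nrow(x$grid), x$k, max(x$cv_f1)))
  print.data.frame(x$chosen, row.names = FALSE)
  invisible(x)
}

#' A predictor spec with fixed hyperparameters (grid of size one)
#'
#' @param ... hyperparameter values overriding the forest defaults
#'   (`n_trees`, `max_depth`, `max_features`, `bootstrap`, `min_leaf`,
#'   `min_split`).
#' @return a `predictor_spec` whose chosen point is the given configuration.
#' @export
fixed_predictor_spec <- function(...) {
  defaults <- list(n_trees = 100, max_depth = NA, max_features = NA_real_,
                   bootstrap = TRUE, min_leaf = 1, min_split = 2)
  args <- utils::modifyList(defaults, list(...))
  grid <- check_grid(as.data.frame(args))
  structure(list(grid = grid, chosen = grid, cv_f1 = NA_real_, k = NA,
                 positive_class = 0, seed = NA),
            class = "predictor_spec")
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Train the surrogate performance predictor
#'
#' Fits the forest on graded loads (percent units) against the binary
#' ability score, with the feature order bound to the dataset's region set
#' (the RoB is an ordinary feature). The fitted model realises the game's
#' characteristic function via [evaluate_configuration()].
#'
#' @param dataset a [lesion_dataset()] with both classes present.
#' @param spec a `predictor_spec` (its `chosen` row is used).
#' @param seed integer seed.
#' @param output_mode `"class"` (default): v(config) is the hard predicted
#'   class; `"prob"`: the class-1 probability, a smoother characteristic
#'   function.
#' @param embedding how a binary configuration maps to graded features:
#'   `"ablation"` (lesioned -> 100% load) or `"mean_load"` (lesioned -> the
#'   region's mean observed load among lesioned patients).
#' @return object of class `surrogate_model`.
#' @export
train_surrogate <- function(dataset, spec, seed = 1,
                            output_mode = c("class", "prob"),
                            embedding = c("ablation", "mean_load")) {
  stopifnot(inherits(dataset, "lesion_dataset"),
            inherits(spec, "predictor_spec"))
  output_mode <- match.arg(output_mode)
  embedding <- match.arg(embedding)
  y <- dataset$performance
  if (length(unique(y)) < 2L)
    stop("surrogate training requires both outcome classes")
  fit <- do.call(rf_fit, c(list(x = dataset$loads, y = y, seed = seed),
                           as.list(spec$chosen)))
  structure(list(fit = fit, region_id = dataset$region_set$region_id,
                 spec = spec, output_mode = output_mode,
                 embedding = embedding,
                 lesioned_values = lesioned_embedding(dataset, embedding),
                 seed = seed),
            class = "surrogate_model")
}

lesioned_embedding <- function(dataset, embedding) {
  if (embedding == "ablation") {
    v <- rep(100, n_regions(dataset))
  } else {
    v <- apply(dataset$loads, 2L, function(col) {
      hit <- col > 0
      if (any(hit)) mean(col[hit]) else 100
    })
  }
  names(v) <- dataset$region_set$region_id
  v
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf(paste0("surrogate_model: forest over %d regions ",
                     "(output: %s, embedding: %s)\n"),
              length(x$region_id), x$output_mode, x$embedding))
  invisible(x)
}

#' Evaluate the surrogate on binary lesion configurations
#'
#' A configuration assigns each region 1 = intact or 0 = perturbed. Intact
#' regions get 0% load; perturbed regions get the model's lesioned embedding
#' value (100% under ablation). The result is the characteristic-function
#' value v(configuration).
#'
#' @param model a [train_surrogate()] model.
#' @param config 0/1 vector of length `n_regions`, or a matrix with one
#'   configuration per row.
#' @param output_mode optional override of the model's output mode.
#' @return numeric vector of performance values (0/1 hard class or
#'   probabilities).
#' @export
evaluate_configuration <- function(model, config, output_mode = NULL) {
  stopifnot(inherits(model, "surrogate_model"))
  output_mode <- output_mode %||% model$output_mode
  if (is.null(dim(config))) config <- matrix(config, nrow = 1L)
  if (ncol(config) != length(model$region_id))
    stop("configuration length must equal the number of regions (",
         length(model$region_id), ")")
  if (!all(config %in% c(0, 1))) stop("configurations must be 0/1")
  feats <- (1 - config) * rep(model$lesioned_values, each = nrow(config))
  pr <- predict(model$fit, feats, type = "prob")
  if (output_mode == "class") as.numeric(pr >= 0.5) else pr
}

#' Leave-one-out evaluation of the surrogate
#'
#' Each patient is predicted by a forest trained on the remaining patients;
#' accuracy is the fraction of correct binary predictions. Also reports the
#' confusion counts and the F1 on the configured positive (deficit) class.
#' A fold whose training split is single-class still trains (all trees
#' predict the sole class); this is logged via the `single_class_folds`
#' field.
#'
#' @param dataset a [lesion_dataset()] with `n >= 3` patients.
#' @param spec a `predictor_spec`.
#' @param seed integer seed.
#' @param positive_class class for the F1 (default 0, the deficit class).
#' @return object of class `predictor_evaluation`: list with
#'   `loo_accuracy`, `f1`, `confusion` (tp/fp/tn/fn), `chance_accuracy`
#'   (`NA` until [chance_level()] is run), `predictions`,
#'   `single_class_folds`.
#' @export
loo_evaluation <- function(dataset, spec, seed = 1, positive_class = 0) {
  stopifnot(inherits(dataset, "lesion_dataset"),
            inherits(spec, "predictor_spec"))
  y <- dataset$performance
  n <- length(y)
  if (n < 3L) stop("leave-one-out needs at least 3 patients")
  ch <- spec$chosen
  pr <- rf_loo_predict_cpp(dataset$loads, y, as.integer(ch$n_trees),
                           depth_code(ch$max_depth),
                           mtry_of(ch$max_features, ncol(dataset$loads)),
                           isTRUE(ch$bootstrap), as.integer(ch$min_leaf),
                           as.integer(ch$min_split), as.integer(seed))
  pred <- as.integer(pr >= 0.5)
  cm <- confusion_of(y, pred, positive_class)
  single <- vapply(seq_len(n), function(i) length(unique(y[-i])) < 2L,
                   logical(1))
  structure(list(loo_accuracy = mean(pred == y),
                 f1 = unname(f1_score(cm["tp"], cm["fp"], cm["fn"])),
                 confusion = cm, chance_accuracy = NA_real_,
                 predictions = pred, positive_class = positive_class,
                 single_class_folds = sum(single), seed = seed),
            class = "predictor_evaluation")
}

#' @export
print.predictor_evaluation <- function(x, ...) {
  cat(sprintf(paste0("predictor_evaluation: LOO accuracy %.3f, F1(%s) %.3f",
                     "%s\n  confusion: TP %d  FP %d  TN %d  FN %d\n"),
              x$loo_accuracy, x$positive_class, x$f1,
              if (is.na(x$chance_accuracy)) ""
              else sprintf(", chance %.3f", x$chance_accuracy),
              x$confusion["tp"], x$confusion["fp"], x$confusion["tn"],
              x$confusion["fn"]))
  invisible(x)
}

#' Shuffled-label chance level of the surrogate
#'
#' Mean leave-one-out accuracy after permuting the binary scores across
#' patients, i.e. the performance of an arbitrary classifier on this lesion
#' distribution. For an imbalanced outcome it concentrates near the
#' majority-class proportion, which is the correct baseline against which to
#' judge the true-label accuracy.
#'
#' @param dataset a [lesion_dataset()].
#' @param spec a `predictor_spec`.
#' @param n_shuffles number of label permutations (default 20).
#' @param seed integer seed.
#' @return mean shuffled accuracy (scalar) with attribute `per_shuffle`.
#' @export
chance_level <- function(dataset, spec, n_shuffles = 20, seed = 1) {
  stopifnot(n_shuffles >= 1)
  y <- dataset$performance
  n <- length(y)
  seeds <- derive_seeds(seed, 2L * n_shuffles)
  acc <- vapply(seq_len(n_shuffles), function(s) {
    perm <- with_seed(seeds[s], sample.int(n))
    shuffled <- dataset
    shuffled$performance <- y[perm]
    shuffled$motor_score <- dataset$motor_score[perm]
    loo_evaluation(shuffled, spec, seed = seeds[n_shuffles + s],
                   positive_class = spec$positive_class %||% 0)$loo_accuracy
  }, numeric(1))
  structure(mean(acc), per_shuffle = acc)
}
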