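test_that("f1_score matches its definition and boundary semantics", {
  expect_equal(f1_score(10, 0, 0), 1)   # perfect precision and recall
  expect_equal(f1_score(0, 5, 5), 0)    # zero precision and recall
  expect_equal(f1_score(8, 2, 2), 0.8)  # P = R = 0.8
  expect_error(f1_score(-1, 0, 0), "non-negative")

  # algebraic identity f1 = tp / (tp + (fp + fn)/2) on random count triples
  counts <- with_test_seed(99, matrix(sample.int(50L, 300, TRUE) - 1L, ncol = 3))
  counts[, 1] <- counts[, 1] + 1L  # keep tp > 0 so both forms are defined
  expect_equal(f1_score(counts[, 1], counts[, 2], counts[, 3]),
               counts[, 1] / (counts[, 1] + (counts[, 2] + counts[, 3]) / 2))
})

test_that("hyperparameter search selects by cross-validated F1", {
  ds <- threshold_cohort(n = 60, seed = 4)

  # a grid of one is returned as-is
  g1 <- data.frame(n_trees = 40, max_depth = 6, max_features = NA_real_,
                   bootstrap = TRUE, min_leaf = 1, min_split = 2)
  spec1 <- optimize_hyperparameters(ds, g1, seed = 1)
  expect_equal(spec1$chosen, g1)

  # a separable rule reaches F1 = 1 in cross-validation
  expect_equal(max(spec1$cv_f1), 1)

  # XOR-style outcome: a depth-1 stump cannot express it, a deeper tree can
  n <- 120
  loads <- with_test_seed(7, {
    m <- matrix(runif(n * 3, 0, 100), n, 3)
    m[, 3] <- runif(n, 0, 2)
    m
  })
  score <- ifelse(xor(loads[, 1] > 50, loads[, 2] > 50), 4L, 10L)
  xor_ds <- lesion_dataset(loads, score, toy_region_set(2))
  g2 <- data.frame(n_trees = 60, max_depth = c(1, 4),
                   max_features = 1.0, bootstrap = TRUE,
                   min_leaf = 1, min_split = 2)
  spec2 <- optimize_hyperparameters(xor_ds, g2, seed = 2)
  expect_gt(spec2$cv_f1[2], spec2$cv_f1[1])
  expect_equal(spec2$chosen$max_depth, 4)

  expect_error(optimize_hyperparameters(
    lesion_dataset(loads, rep(10L, n), toy_region_set(2))),
    "both outcome classes")
  expect_error(optimize_hyperparameters(ds, g1[, 1:3]), "lacks columns")
})

test_that("the surrogate memorises separable data and is seed-deterministic", {
  ds <- threshold_cohort(n = 80, seed = 5)
  spec <- fixed_predictor_spec(n_trees = 60, max_depth = 8)
  model <- train_surrogate(ds, spec, seed = 3)
  pred <- predict(model$fit, ds$loads, type = "class")
  expect_gte(mean(pred == ds$performance), 0.95)

  model2 <- train_surrogate(ds, spec, seed = 3)
  probe <- matrix(runif(10 * 4, 0, 100), 10, 4)
  expect_identical(predict(model$fit, probe), predict(model2$fit, probe))

  expect_error(train_surrogate(
    lesion_dataset(ds$loads, rep(10L, 80), ds$region_set), spec),
    "both outcome classes")
})

test_that("binary configurations are embedded and evaluated as coalitions", {
  ds <- threshold_cohort(n = 80, seed = 6)
  spec <- fixed_predictor_spec(n_trees = 60, max_depth = 8)
  model <- train_surrogate(ds, spec, seed = 1)
  p <- n_regions(ds)
  expect_equal(evaluate_configuration(model, rep(1, p)), 1)  # all intact
  expect_equal(evaluate_configuration(model, rep(0, p)), 0)  # all ablated
  # lesioning only non-causal regions leaves performance intact
  cfg <- rep(1, p); cfg[2:3] <- 0
  expect_equal(evaluate_configuration(model, cfg), 1)
  expect_error(evaluate_configuration(model, rep(1, p - 1)), "length")
  expect_error(evaluate_configuration(model, rep(0.5, p)), "0/1")
  pr <- evaluate_configuration(model, rep(0, p), output_mode = "prob")
  expect_true(pr >= 0 && pr <= 1)

  # mean-load embedding presents lesioned regions at observed severities
  model_ml <- train_surrogate(ds, spec, seed = 1, embedding = "mean_load")
  expect_true(all(model_ml$lesioned_values <= 100))
  expect_equal(evaluate_configuration(model_ml, rep(1, p)), 1)
})

test_that("leave-one-out evaluation returns consistent accuracy and confusion", {
  ds <- threshold_cohort(n = 40, seed = 8)
  spec <- fixed_predictor_spec(n_trees = 60, max_depth = 8)
  ev <- loo_evaluation(ds, spec, seed = 2)
  expect_gte(ev$loo_accuracy, 0.9)  # deterministic single-region rule
  expect_equal(sum(ev$confusion), 40)
  expect_equal(ev$loo_accuracy,
               unname((ev$confusion["tp"] + ev$confusion["tn"]) / 40))

  # constant outcome: every fold single-class, accuracy 1, deficit-F1 0
  const <- lesion_dataset(ds$loads, rep(10L, 40), ds$region_set)
  ev_const <- loo_evaluation(const, spec, seed = 2)
  expect_equal(ev_const$loo_accuracy, 1)
  expect_equal(ev_const$f1, 0)
  expect_equal(ev_const$single_class_folds, 40)

  # duplicated patients: memorising the twin makes LOO perfect
  dup <- lesion_dataset(rbind(ds$loads, ds$loads),
                        rep(ds$motor_score, 2), ds$region_set,
                        patient_id = sprintf("d%02d", 1:80))
  expect_gte(loo_evaluation(dup, spec, seed = 2)$loo_accuracy, 0.99)

  expect_error(loo_evaluation(subset_patients(ds, 1:2), spec), "3 patients")
})

test_that("shuffled-label chance level sits at the majority-class proportion", {
  # balanced outcome -> chance near 0.5
  n <- 100
  loads <- with_test_seed(11, matrix(runif(n * 4, 0, 100), n, 4))
  score <- ifelse(loads[, 1] >= 50, 5L, 10L)  # ~50/50
  ds <- lesion_dataset(loads, score, toy_region_set(3))
  spec <- fixed_predictor_spec(n_trees = 30, max_depth = 6)
  ch <- chance_level(ds, spec, n_shuffles = 20, seed = 9)
  expect_lt(abs(as.numeric(ch) - max(table(score) / n)), 0.1)
  expect_length(attr(ch, "per_shuffle"), 20)

  # a single shuffle is allowed and returns a valid accuracy
  one <- chance_level(ds, spec, n_shuffles = 1, seed = 13)
  expect_true(one >= 0 && one <= 1)
})
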