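# games used repeatedly: the additive game v(S) = |S|/n and a 3-element
# "pair" game where only the coalition {1,2} creates value

additive_game <- function(n) {
  masks <- 0:(2^n - 1)
  size <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(n - 1))) > 0),
                 numeric(1))
  tabulated_game(size / n)
}

pair_game <- function() {
  v <- numeric(8)
  both <- c(3, 7) + 1  # masks containing elements 1 and 2
  v[both] <- 1
  tabulated_game(v)
}

test_that("exact Shapley enumeration satisfies the game axioms", {
  # symmetry + efficiency on the additive game
  g4 <- additive_game(4)
  expect_equal(unname(exact_shapley(g4)), rep(0.25, 4))

  # hand-enumerated 3-element game: elements 1,2 split the unit, 3 is dummy
  expect_equal(unname(exact_shapley(pair_game())), c(0.5, 0.5, 0))

  # dummy axiom on a game with a genuinely inert element
  set.seed(20)
  base <- runif(2^3)
  v <- numeric(2^4)
  for (m in 0:(2^4 - 1)) {
    inner <- bitwAnd(m, 7L)  # element 4 never matters
    v[m + 1] <- base[inner + 1]
  }
  gd <- tabulated_game(v)
  ex <- exact_shapley(gd)
  expect_equal(unname(ex[4]), 0)

  # efficiency to machine precision on a random game
  g <- tabulated_game(with_test_seed(21, runif(2^8)))
  ex8 <- exact_shapley(g)
  expect_equal(sum(ex8), g$values[2^8] - g$values[1], tolerance = 1e-12)

  expect_error(exact_shapley(structure(list(n = 25, ids = letters[1:25],
                                            v = identity),
                                       class = "msa_game")),
               "estimated_shapley")
})

test_that("permutation sampling estimates the Shapley value", {
  # zero-variance game: every permutation yields the same marginals
  g4 <- additive_game(4)
  expect_equal(as.numeric(estimated_shapley(g4, R = 3, seed = 1)),
               rep(0.25, 4))

  # R = 1 is the marginal vector of one permutation; it telescopes
  g <- tabulated_game(with_test_seed(22, runif(2^6)))
  one <- estimated_shapley(g, R = 1, seed = 5)
  expect_equal(sum(one), g$values[2^6] - g$values[1])

  # oracle agreement on a random 10-element game
  g10 <- tabulated_game(with_test_seed(23, runif(2^10)))
  ex <- exact_shapley(g10)
  es <- estimated_shapley(g10, R = 5000, seed = 6)
  expect_lt(max(abs(es - ex)), 0.02 * diff(range(g10$values)))

  # estimated efficiency also telescopes exactly for deterministic games
  expect_equal(sum(es), g10$values[2^10] - g10$values[1])

  # reproducibility under a fixed seed
  expect_identical(estimated_shapley(g10, R = 200, seed = 9),
                   estimated_shapley(g10, R = 200, seed = 9))
})

test_that("tabulated games accept bitstring-named values", {
  g <- tabulated_game(c("00" = 0, "10" = 0.2, "01" = 0.3, "11" = 1))
  # element 1 intact only = bitstring "10"
  expect_equal(g$v(rbind(c(1, 0))), 0.2)
  expect_equal(g$v(rbind(c(0, 1))), 0.3)
  expect_equal(unname(exact_shapley(g)), c(0.45, 0.55))
  expect_error(tabulated_game(c("00" = 0, "11" = 1)), "2\\^n")
})

test_that("surrogate games expose the trained predictor as v(S)", {
  ds <- threshold_cohort(n = 80, seed = 31)
  model <- train_surrogate(ds, fixed_predictor_spec(n_trees = 60,
                                                    max_depth = 8), seed = 2)
  game <- surrogate_game(model)
  p <- n_regions(ds)
  expect_equal(game$n, p)
  cfgs <- rbind(rep(1, p), rep(0, p), diag(p))
  expect_equal(game$v(cfgs), evaluate_configuration(model, cfgs))
  # exact Shapley through the surrogate: the causal region dominates
  ex <- exact_shapley(game)
  expect_equal(unname(which.max(ex)), 1L)
  expect_equal(sum(ex), game$v(rbind(rep(1, p))) - game$v(rbind(rep(0, p))))
})

test_that("bootstrap MSA aggregates replicates with percentile significance", {
  ds <- threshold_cohort(n = 80, seed = 32)
  spec <- fixed_predictor_spec(n_trees = 50, max_depth = 8)

  # B = 1: one estimated MSA on one resample, degenerate interval
  r1 <- bootstrap_msa(ds, spec, B = 1, R = 100, seed = 3)
  expect_equal(unname(r1$se), rep(0, 4))
  expect_equal(r1$ci_low, r1$ci_high)

  res <- bootstrap_msa(ds, spec, B = 40, R = 150, seed = 3)
  expect_equal(colnames(res$boot), ds$region_set$region_id)
  # the planted causal region is the top, significant contributor
  expect_equal(unname(which.max(res$contribution)), 1L)
  expect_true(res$significant[1])
  # significance flag is exactly the CI-excludes-zero rule
  expect_equal(unname(res$significant),
               unname(res$ci_low > 0 | res$ci_high < 0))
  # reproducibility
  res2 <- bootstrap_msa(ds, spec, B = 40, R = 150, seed = 3)
  expect_identical(res$contribution, res2$contribution)
  expect_identical(res$boot, res2$boot)

  # duplicating every patient leaves the mean contributions unchanged
  # within Monte-Carlo error
  dup <- lesion_dataset(rbind(ds$loads, ds$loads), rep(ds$motor_score, 2),
                        ds$region_set, patient_id = sprintf("d%02d", 1:160))
  res_dup <- bootstrap_msa(dup, spec, B = 40, R = 150, seed = 4)
  expect_lt(max(abs(res_dup$contribution - res$contribution)), 0.1)

  # z-rule option
  resz <- bootstrap_msa(ds, spec, B = 40, R = 150, seed = 3,
                        significance = "z")
  expect_true(resz$significant[1])

  expect_error(bootstrap_msa(
    lesion_dataset(ds$loads, rep(10L, 80), ds$region_set), spec),
    "both outcome classes")
})

test_that("contribution normalisation preserves signs and unit mass", {
  expect_equal(normalize_contributions(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_equal(normalize_contributions(c(1, -1)), c(0.5, -0.5))
  g4 <- additive_game(4)
  expect_equal(unname(normalize_contributions(exact_shapley(g4))),
               rep(0.25, 4))
  expect_error(normalize_contributions(c(0, 0)), "all-zero")
})
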