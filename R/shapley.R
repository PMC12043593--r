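#' Coalitional games over intact-region configurations
#'
#' A game assigns a performance value v(S) to every coalition S, where the
#' coalition is the set of INTACT elements: v of the empty coalition is the
#' all-lesioned performance and v of the grand coalition the all-intact one.
#' With this orientation a positive Shapley value means damaging the element
#' lowers performance.
#'
#' `tabulated_game()` wraps an explicit value table (for oracle testing and
#' small exact analyses); `surrogate_game()` wraps a trained
#' [train_surrogate()] model.
#'
#' @param values numeric vector of length `2^n`, indexed by the coalition
#'   bitmask (bit `i` set = element `i` intact, mask 0 = empty coalition),
#'   or a vector named by bitstrings such as `"0110"` (first character =
#'   element 1).
#' @param ids optional element identifiers.
#' @return object of class `msa_game`: list with `n`, `ids`, and `v` — a
#'   function mapping a 0/1 configuration matrix (one row per coalition) to
#'   values.
#' @export
tabulated_game <- function(values, ids = NULL) {
  if (!is.null(names(values)) && all(grepl("^[01]+$", names(values)))) {
    n <- nchar(names(values)[1])
    if (length(values) != 2^n || any(nchar(names(values)) != n))
      stop("need all 2^n bitstring-named values")
    mask <- vapply(strsplit(names(values), ""), function(b)
      sum(as.integer(b) * 2^(seq_along(b) - 1)), numeric(1))
    values <- values[order(mask)]
  } else {
    n <- as.integer(round(log2(length(values))))
    if (2^n != length(values)) stop("values must have length 2^n")
  }
  values <- as.numeric(values)
  ids <- ids %||% paste0("e", seq_len(n))
  v <- function(configs) {
    configs <- config_matrix(configs, n)
    values[as.vector(configs %*% 2^(seq_len(n) - 1)) + 1]
  }
  structure(list(n = n, ids = ids, v = v, values = values),
            class = "msa_game")
}

#' @param model a [train_surrogate()] model.
#' @param output_mode optional override of the model's output mode.
#' @rdname tabulated_game
#' @export
surrogate_game <- function(model, output_mode = NULL) {
  stopifnot(inherits(model, "surrogate_model"))
  structure(list(n = length(model$region_id), ids = model$region_id,
                 v = function(configs)
                   evaluate_configuration(model, configs, output_mode)),
            class = "msa_game")
}

config_matrix <- function(configs, n) {
  if (is.null(dim(configs))) configs <- matrix(configs, nrow = 1L)
  if (ncol(configs) != n)
    stop("configurations must have ", n, " columns")
  configs
}

#' Read a tabulated game from JSON
#'
#' The file is an object mapping coalition bitstrings to values, e.g.
#' `{"00": 0, "10": 0.2, "01": 0.3, "11": 1}`.
#'
#' @param path JSON file path.
#' @param ids optional element ids.
#' @return an `msa_game`.
#' @export
read_tabulated_game <- function(path, ids = NULL) {
  vals <- unlist(jsonlite::read_json(path))
  tabulated_game(vals, ids = ids)
}

#' Exact Shapley values by full enumeration
#'
#' gamma_i = sum over coalitions S not containing i of
#' `|S|! (n-|S|-1)! / n! * (v(S + i) - v(S))`. Exact but exponential: all
#' `2^n` coalition values are evaluated, so `n` is capped at 20; beyond
#' that use [estimated_shapley()].
#'
#' @param game an `msa_game`.
#' @return named numeric vector of contributions; sums to
#'   `v(full) - v(empty)` (efficiency) to machine precision.
#' @export
exact_shapley <- function(game) {
  stopifnot(inherits(game, "msa_game"))
  n <- game$n
  if (n > 20L)
    stop("exact enumeration is limited to 20 elements (2^n coalitions); ",
         "use estimated_shapley() for larger games")
  masks <- 0:(2^n - 1)
  pc <- integer(length(masks))
  for (b in seq_len(n) - 1L)
    pc <- pc + bitwAnd(bitwShiftR(masks, b), 1L)
  configs <- matrix(0L, length(masks), n)
  for (b in seq_len(n))
    configs[, b] <- bitwAnd(bitwShiftR(masks, b - 1L), 1L)
  v <- game$v(configs)
  # weight of a coalition of size s: s!(n-s-1)!/n! = 1 / (n * choose(n-1, s))
  w <- 1 / (n * choose(n - 1, 0:(n - 1)))
  out <- numeric(n)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(masks, bit) == 0L)
    out[i] <- sum(w[pc[without] + 1L] * (v[without + bit] - v[without]))
  }
  names(out) <- game$ids
  out
}

#' Estimated Shapley values by permutation sampling
#'
#' Draws `R` uniform random orderings of the elements; for each ordering,
#' every element's marginal contribution is v(predecessors + element) -
#' v(predecessors), and the estimate is the per-element mean over orderings.
#' This is the unbiased Monte-Carlo estimator of [exact_shapley()] with
#' error shrinking as `1/sqrt(R)`; it is what makes games over a hundred-odd
#' brain regions tractable.
#'
#' Within one run, repeated coalition evaluations are served from a cache of
#' unique configurations.
#'
#' @param game an `msa_game`.
#' @param R number of sampled permutations.
#' @param seed integer seed.
#' @param chunk permutations evaluated per batch (memory knob).
#' @return named numeric contributions with attributes `R` and `seed`.
#' @export
estimated_shapley <- function(game, R = 1000, seed = 1, chunk = 512L) {
  stopifnot(inherits(game, "msa_game"), R >= 1)
  n <- game$n
  contrib <- numeric(n)
  # row template: prefix coalition k+1 contains the first k drawn elements
  row_template <- unlist(lapply(seq_len(n), function(k) (k + 1L):(n + 1L)))
  times_template <- n:1
  done <- 0L
  draw <- 0L
  seeds <- derive_seeds(seed, ceiling(R / chunk))
  while (done < R) {
    m <- min(chunk, R - done)
    draw <- draw + 1L
    perms <- with_seed(seeds[draw],
                       t(vapply(seq_len(m), function(j) sample.int(n),
                                integer(n))))
    configs <- matrix(0L, m * (n + 1L), n)
    for (j in seq_len(m)) {
      off <- (j - 1L) * (n + 1L)
      configs[cbind(off + row_template, rep(perms[j, ], times_template))] <- 1L
    }
    key <- if (n <= 52L) as.vector(configs %*% (2^(seq_len(n) - 1)))
           else apply(configs, 1L, paste0, collapse = "")
    uniq <- !duplicated(key)
    vu <- game$v(configs[uniq, , drop = FALSE])
    v <- vu[match(key, key[uniq])]
    for (j in seq_len(m)) {
      off <- (j - 1L) * (n + 1L)
      dv <- v[(off + 2L):(off + n + 1L)] - v[(off + 1L):(off + n)]
      contrib[perms[j, ]] <- contrib[perms[j, ]] + dv
    }
    done <- done + m
  }
  structure(contrib / R, names = game$ids, R = R, seed = seed)
}

#' Normalise contributions to unit total absolute mass
#'
#' Each value is divided by the sum of absolute contributions; signs are
#' preserved. Reporting convenience only.
#'
#' @param contributions numeric vector with at least one nonzero entry.
#' @return normalised vector summing to 1 in absolute value.
#' @export
normalize_contributions <- function(contributions) {
  total <- sum(abs(contributions))
  if (total == 0) stop("cannot normalise an all-zero contribution vector")
  contributions / total
}
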