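#' Limb motor score from the two NIHSS limb items
#'
#' The stroke-scale motor items for the upper and lower limb are each graded
#' 0 (no drift) to 4 (no movement). The composite limb motor score is
#' `10 - (upper + lower)`: 10 means no limb impairment, 2 maximal deficit.
#'
#' @param upper_limb_item,lower_limb_item integers in `[0, 4]` (vectorised).
#' @return integer motor score(s) in `[2, 10]`.
#' @export
#' @examples
#' derive_motor_score(0, 0) # 10, intact
#' derive_motor_score(4, 4) # 2, major impairment
derive_motor_score <- function(upper_limb_item, lower_limb_item) {
  u <- check_item(upper_limb_item, "upper_limb_item")
  l <- check_item(lower_limb_item, "lower_limb_item")
  10L - (u + l)
}

check_item <- function(x, what) {
  if (any(is.na(x)) || any(x != as.integer(x)) || any(x < 0L) || any(x > 4L))
    stop(what, " must be integers in [0, 4]")
  as.integer(x)
}

#' Binary behavioural ability from the motor score
#'
#' Scores equal to the no-impairment ceiling (10) code as 1 ("normal"),
#' anything below as 0 ("pathological"). The output directly encodes
#' behavioural ability (1 = intact function), the orientation the Shapley
#' analysis requires of its performance measure.
#'
#' @param motor_score integer(s) in `[2, 10]`.
#' @return integer 0/1 vector.
#' @export
binarize_performance <- function(motor_score) {
  if (any(is.na(motor_score)) || any(motor_score != as.integer(motor_score)) ||
      any(motor_score < 2L) || any(motor_score > 10L))
    stop("motor_score must be integers in [2, 10]")
  as.integer(motor_score == 10L)
}
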