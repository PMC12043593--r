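#' Region catalogue with a rest-of-brain element
#'
#' An ordered set of atlas regions (ROIs), each with an integer atlas label
#' and a voxel count, plus exactly one designated "rest of brain" (RoB)
#' element. The RoB is a catch-all player absorbing tissue not modelled as an
#' individual region; during the iterative analysis, discarded regions are
#' pooled into it.
#'
#' @param region_id character vector of unique region identifiers.
#' @param voxel_count positive integer vector, voxels per region.
#' @param atlas_label integer atlas labels; unique among non-RoB regions.
#'   The RoB label may be `NA` (it has no single atlas label).
#' @param rob_id which `region_id` is the RoB element.
#' @return object of class `region_set`: a data frame with columns
#'   `region_id`, `atlas_label`, `voxel_count` and attribute `rob_id`.
#' @export
region_set <- function(region_id, voxel_count,
                       atlas_label = seq_along(region_id), rob_id) {
  region_id <- as.character(region_id)
  if (anyDuplicated(region_id))
    stop("region ids must be unique")
  if (length(rob_id) != 1L || !rob_id %in% region_id)
    stop("rob_id must name exactly one listed region")
  voxel_count <- as.numeric(voxel_count)
  if (length(voxel_count) != length(region_id) ||
      any(!is.finite(voxel_count)) || any(voxel_count <= 0))
    stop("voxel counts must be positive and one per region")
  atlas_label <- as.integer(atlas_label)
  non_rob <- region_id != rob_id
  if (anyDuplicated(atlas_label[non_rob & !is.na(atlas_label)]))
    stop("atlas labels must be unique among non-RoB regions")
  out <- data.frame(region_id = region_id, atlas_label = atlas_label,
                    voxel_count = voxel_count, stringsAsFactors = FALSE)
  attr(out, "rob_id") <- as.character(rob_id)
  class(out) <- c("region_set", "data.frame")
  out
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d regions (RoB: %s), %s voxels total\n",
              nrow(x), rob_id(x), format(sum(x$voxel_count), big.mark = ",")))
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more regions\n", nrow(x) - 10L))
  invisible(x)
}

#' RoB identifier of a region set
#' @param x a `region_set` (or an object carrying one, e.g. `lesion_dataset`).
#' @return character scalar.
#' @export
rob_id <- function(x) {
  if (inherits(x, "lesion_dataset")) x <- x$region_set
  attr(x, "rob_id")
}

#' Build a region set from an integer-labelled atlas volume
#'
#' Voxel counts are taken from the atlas; an extra RoB element covers all
#' non-background voxels not claimed by any listed label.
#'
#' @param atlas integer array; 0 is background.
#' @param labels integer labels of the regions to model individually.
#' @param region_id identifiers for `labels` (default `"roi_<label>"`).
#' @param rob_id identifier for the RoB element.
#' @return a [region_set()] of `length(labels) + 1` regions.
#' @export
region_set_from_atlas <- function(atlas, labels,
                                  region_id = paste0("roi_", labels),
                                  rob_id = "RoB") {
  labels <- as.integer(labels)
  counts <- vapply(labels, function(l) sum(atlas == l), numeric(1))
  if (any(counts == 0))
    warning("atlas labels absent from volume: ",
            paste(labels[counts == 0], collapse = ", "))
  rob_count <- sum(atlas != 0L & !(atlas %in% labels))
  if (rob_count == 0)
    stop("atlas has no unclaimed voxels for the RoB element")
  region_set(c(region_id, rob_id),
             # zero-support labels keep a unit count so the set stays valid
             voxel_count = c(pmax(counts, 1), rob_count),
             atlas_label = c(labels, NA_integer_),
             rob_id = rob_id)
}
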