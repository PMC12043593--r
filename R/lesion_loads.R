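#' Extract regional lesion loads from a mask and a labelled atlas
#'
#' Counts, for each region of a [region_set()], the voxels where the binary
#' lesion mask overlaps the region's atlas label, and expresses them as the
#' percentage of the region's voxels ("relative lesion size"). The RoB load
#' is computed over all non-background atlas voxels not claimed by any listed
#' region, so lesioned voxels are conserved: listed regions + RoB account for
#' every lesioned voxel inside the atlas.
#'
#' Both volumes must live on the same grid; registration/normalisation is an
#' upstream step and no resampling is attempted here.
#'
#' @param lesion_mask array of 0/1 lesion indicators.
#' @param atlas integer array of the same dimensions; 0 = background.
#' @param region_set a [region_set()]; non-RoB entries must carry
#'   `atlas_label`s.
#' @return list with `absolute` (lesioned voxel counts, named by region) and
#'   `relative` (percent loads in `[0, 100]`).
#' @export
extract_lesion_loads <- function(lesion_mask, atlas, region_set) {
  stopifnot(inherits(region_set, "region_set"))
  dm <- dim(lesion_mask) %||% length(lesion_mask)
  da <- dim(atlas) %||% length(atlas)
  if (!identical(as.integer(dm), as.integer(da)))
    stop("lesion mask and atlas are on different grids (",
         paste(dm, collapse = "x"), " vs ", paste(da, collapse = "x"), ")")
  mv <- unique(as.vector(lesion_mask))
  if (!all(mv %in% c(0, 1)))
    stop("lesion mask must be binary (0/1)")
  rob <- rob_id(region_set)
  ids <- region_set$region_id
  labels <- region_set$atlas_label
  lesioned <- lesion_mask == 1
  absolute <- numeric(length(ids))
  names(absolute) <- ids
  for (k in seq_along(ids)) {
    if (ids[k] == rob) next
    lab <- labels[k]
    if (!any(atlas == lab)) {
      warning("atlas label ", lab, " (", ids[k], ") absent from volume")
      absolute[k] <- 0
    } else {
      absolute[k] <- sum(lesioned & atlas == lab)
    }
  }
  claimed <- atlas %in% labels[ids != rob]
  absolute[rob] <- sum(lesioned & atlas != 0 & !claimed)
  relative <- 100 * absolute / region_set$voxel_count
  names(relative) <- ids
  list(absolute = absolute, relative = relative)
}

#' Lesion-load table for a cohort of masks
#'
#' @param masks list of binary arrays, one per patient.
#' @param atlas integer labelled array shared by all masks.
#' @param region_set a [region_set()].
#' @return numeric matrix `[n_patients x n_regions]` of percent loads.
#' @export
extract_lesion_load_table <- function(masks, atlas, region_set) {
  rows <- lapply(masks, function(m)
    extract_lesion_loads(m, atlas, region_set)$relative)
  out <- do.call(rbind, rows)
  rownames(out) <- names(masks)
  out
}
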