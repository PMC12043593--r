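#' Merge discarded regions into the rest-of-brain element
#'
#' Pools each discarded region's lesioned voxels into the RoB: the new RoB
#' load is `100 * (pooled lesioned voxels) / (pooled voxel count)`, i.e. the
#' voxel-count-weighted mean of the old RoB column and the discarded columns.
#' This pooling is associative and conserves each patient's total lesioned
#' voxel count exactly, which is what lets the iterative loop re-absorb
#' regions without losing lesion mass. Patient order, scores and the
#' remaining columns are untouched.
#'
#' @param dataset a [lesion_dataset()].
#' @param discard_ids region ids to fold into the RoB (must not include the
#'   RoB itself).
#' @return a `lesion_dataset` with the discarded columns removed and the RoB
#'   column and voxel count updated.
#' @export
merge_into_rob <- function(dataset, discard_ids) {
  stopifnot(inherits(dataset, "lesion_dataset"))
  rs <- dataset$region_set
  rob <- rob_id(rs)
  discard_ids <- as.character(discard_ids)
  if (rob %in% discard_ids)
    stop("the RoB element cannot be discarded")
  miss <- setdiff(discard_ids, rs$region_id)
  if (length(miss)) stop("unknown regions: ", paste(miss, collapse = ", "))
  if (!length(discard_ids)) return(dataset)

  vox <- structure(rs$voxel_count, names = rs$region_id)
  pool_ids <- c(rob, discard_ids)
  # lesioned voxels per patient in each pooled column
  lesioned <- sweep(dataset$loads[, pool_ids, drop = FALSE], 2L,
                    vox[pool_ids] / 100, `*`)
  new_rob_load <- rowSums(lesioned) / sum(vox[pool_ids]) * 100

  keep <- setdiff(rs$region_id, discard_ids)
  loads <- dataset$loads[, keep, drop = FALSE]
  loads[, rob] <- new_rob_load
  rows <- match(keep, rs$region_id)
  new_rs <- region_set(keep, voxel_count = ifelse(keep == rob,
                                                  sum(vox[pool_ids]),
                                                  vox[keep]),
                       atlas_label = rs$atlas_label[rows], rob_id = rob)
  lesion_dataset(loads, dataset$motor_score, new_rs,
                 patient_id = dataset$patient_id,
                 metadata = dataset$metadata)
}

#' Per-patient pooled lesioned-voxel count
#'
#' Diagnostic used to verify that merging regions into the RoB conserves
#' lesion mass across the iterative run.
#'
#' @param dataset a [lesion_dataset()].
#' @return numeric vector, lesioned voxels per patient.
#' @export
pooled_lesion_voxels <- function(dataset) {
  vox <- dataset$region_set$voxel_count
  as.numeric(dataset$loads %*% (vox / 100))
}
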