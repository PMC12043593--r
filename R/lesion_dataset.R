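#' Lesion-load cohort with binary behavioural outcome
#'
#' Container for the graded lesion data the analysis runs on: one row per
#' patient, one column per region (including the RoB), values the percentage
#' of the region's voxels covered by the patient's lesion, plus the integer
#' limb motor score and its binarised ability coding.
#'
#' @param loads numeric matrix `[n_patients x n_regions]` in `[0, 100]`;
#'   columns ordered as `region_set`.
#' @param motor_score integer vector in `[2, 10]`, one per patient.
#' @param region_set a [region_set()].
#' @param patient_id character vector (default `"p001"...`).
#' @param metadata optional data frame of per-patient covariates
#'   (e.g. logical columns `bilateral`, `recurrent`) used for subsetting.
#' @return object of class `lesion_dataset`: list with elements `patient_id`,
#'   `loads`, `motor_score`, `performance` (1 = intact), `region_set`,
#'   `metadata`.
#' @export
lesion_dataset <- function(loads, motor_score, region_set,
                           patient_id = NULL, metadata = NULL) {
  loads <- as.matrix(loads)
  storage.mode(loads) <- "double"
  n <- nrow(loads)
  if (!inherits(region_set, "region_set"))
    stop("region_set must be a region_set object")
  if (ncol(loads) != nrow(region_set))
    stop("loads must have one column per region (",
         nrow(region_set), " expected, got ", ncol(loads), ")")
  if (any(!is.finite(loads)) || any(loads < 0) || any(loads > 100))
    stop("lesion loads must lie in [0, 100]")
  if (length(motor_score) != n)
    stop("one motor score per patient required")
  performance <- binarize_performance(motor_score)
  if (is.null(patient_id))
    patient_id <- sprintf("p%03d", seq_len(n))
  patient_id <- as.character(patient_id)
  if (anyDuplicated(patient_id)) stop("patient ids must be unique")
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != n) stop("metadata must have one row per patient")
  }
  colnames(loads) <- region_set$region_id
  rownames(loads) <- patient_id
  structure(list(patient_id = patient_id, loads = loads,
                 motor_score = as.integer(motor_score),
                 performance = performance, region_set = region_set,
                 metadata = metadata),
            class = "lesion_dataset")
}

#' @export
print.lesion_dataset <- function(x, ...) {
  cat(sprintf(paste0("lesion_dataset: %d patients x %d regions (RoB: %s)\n",
                     "  outcome: %d normal (1) / %d pathological (0)\n",
                     "  mean lesion load %.2f%%, %.1f%% of cells nonzero\n"),
              length(x$patient_id), ncol(x$loads), rob_id(x),
              sum(x$performance == 1L), sum(x$performance == 0L),
              mean(x$loads), 100 * mean(x$loads > 0)))
  invisible(x)
}

#' Number of patients / regions
#' @param x a `lesion_dataset`.
#' @export
n_patients <- function(x) length(x$patient_id)

#' @rdname n_patients
#' @export
n_regions <- function(x) nrow(x$region_set)

#' Subset a cohort by patient
#'
#' Used for the leave-out sensitivity analyses (e.g. excluding bilateral or
#' recurrent strokes); no other computation changes.
#'
#' @param dataset a [lesion_dataset()].
#' @param keep logical or integer index over patients, or character
#'   patient ids.
#' @return a `lesion_dataset` restricted to the selected patients.
#' @export
subset_patients <- function(dataset, keep) {
  stopifnot(inherits(dataset, "lesion_dataset"))
  if (is.character(keep)) keep <- match(keep, dataset$patient_id)
  if (anyNA(keep)) stop("unknown patient id in subset")
  lesion_dataset(dataset$loads[keep, , drop = FALSE],
                 dataset$motor_score[keep], dataset$region_set,
                 patient_id = dataset$patient_id[keep],
                 metadata = if (!is.null(dataset$metadata))
                   dataset$metadata[keep, , drop = FALSE])
}

#' Apply the leave-out filters from a run configuration
#'
#' Drops patients whose metadata flags bilateral and/or recurrent strokes.
#'
#' @param dataset a [lesion_dataset()] with the corresponding metadata
#'   columns.
#' @param exclude_bilateral,exclude_recurrent logical flags.
#' @return the filtered `lesion_dataset`.
#' @export
filter_cohort <- function(dataset, exclude_bilateral = FALSE,
                          exclude_recurrent = FALSE) {
  keep <- rep(TRUE, n_patients(dataset))
  md <- dataset$metadata
  if (exclude_bilateral) {
    if (is.null(md$bilateral)) stop("metadata column 'bilateral' required")
    keep <- keep & !as.logical(md$bilateral)
  }
  if (exclude_recurrent) {
    if (is.null(md$recurrent)) stop("metadata column 'recurrent' required")
    keep <- keep & !as.logical(md$recurrent)
  }
  subset_patients(dataset, keep)
}
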