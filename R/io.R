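#' Read a lesion cohort from CSV files
#'
#' `loads_csv`: header of region ids, first column `patient_id`, one row per
#' patient, percent loads. `scores_csv`: either `(patient_id, upper_item,
#' lower_item)` — the motor score is derived as `10 - (upper + lower)` — or
#' `(patient_id, motor_score)` precomputed; extra columns (e.g. `bilateral`,
#' `recurrent`) are kept as patient metadata. `regions_json`, optional, maps
#' region id to `atlas_label` and `voxel_count`; without it, unit voxel
#' counts are assumed (sufficient for analyses that never merge on voxels).
#'
#' @param loads_csv,scores_csv,regions_json file paths.
#' @param rob_id region id of the RoB column (default: auto-detect a column
#'   named `RoB`, else the last column).
#' @return a [lesion_dataset()].
#' @export
read_lesion_dataset <- function(loads_csv, scores_csv, regions_json = NULL,
                                rob_id = NULL) {
  for (f in c(loads_csv, scores_csv, regions_json))
    if (!file.exists(f)) stop("no such file: ", f)
  loads <- read.csv(loads_csv, check.names = FALSE)
  if (names(loads)[1] != "patient_id")
    stop("first column of the loads table must be 'patient_id'")
  pid <- as.character(loads$patient_id)
  loads <- as.matrix(loads[, -1, drop = FALSE])
  scores <- read.csv(scores_csv)
  if (!"patient_id" %in% names(scores))
    stop("scores table must have a 'patient_id' column")
  m <- match(pid, as.character(scores$patient_id))
  if (anyNA(m)) stop("scores missing for patients: ",
                     paste(pid[is.na(m)], collapse = ", "))
  scores <- scores[m, , drop = FALSE]
  motor <- if ("motor_score" %in% names(scores)) {
    scores$motor_score
  } else if (all(c("upper_item", "lower_item") %in% names(scores))) {
    derive_motor_score(scores$upper_item, scores$lower_item)
  } else stop("scores table needs 'motor_score' or 'upper_item'+'lower_item'")
  meta_cols <- setdiff(names(scores),
                       c("patient_id", "motor_score", "upper_item",
                         "lower_item"))
  metadata <- if (length(meta_cols)) scores[meta_cols] else NULL
  ids <- colnames(loads)
  rob_id <- rob_id %||% if ("RoB" %in% ids) "RoB" else ids[length(ids)]
  if (!is.null(regions_json)) {
    reg <- jsonlite::read_json(regions_json, simplifyVector = TRUE)
    miss <- setdiff(ids, names(reg))
    if (length(miss)) stop("regions_json lacks entries for: ",
                           paste(miss, collapse = ", "))
    vox <- vapply(reg[ids], function(r) as.numeric(r$voxel_count),
                  numeric(1))
    lab <- vapply(reg[ids], function(r) {
      l <- r$atlas_label
      if (length(l) != 1L || is.na(l)) NA_integer_ else as.integer(l)
    }, integer(1))
  } else {
    vox <- rep(1, length(ids))
    lab <- seq_along(ids)
    lab[ids == rob_id] <- NA_integer_
  }
  rs <- region_set(ids, voxel_count = vox, atlas_label = lab,
                   rob_id = rob_id)
  lesion_dataset(loads, motor, rs, patient_id = pid, metadata = metadata)
}

#' Write a lesion cohort to CSV (+ region sidecar)
#'
#' @param dataset a [lesion_dataset()].
#' @param dir output directory; writes `loads.csv`, `scores.csv`,
#'   `regions.json`.
#' @return the directory, invisibly.
#' @export
write_lesion_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "lesion_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loads <- data.frame(patient_id = dataset$patient_id,
                      dataset$loads, check.names = FALSE)
  write.csv(loads, file.path(dir, "loads.csv"), row.names = FALSE)
  scores <- data.frame(patient_id = dataset$patient_id,
                       motor_score = dataset$motor_score)
  if (!is.null(dataset$metadata)) scores <- cbind(scores, dataset$metadata)
  write.csv(scores, file.path(dir, "scores.csv"), row.names = FALSE)
  rs <- dataset$region_set
  reg <- lapply(seq_len(nrow(rs)), function(i)
    list(atlas_label = rs$atlas_label[i],
         voxel_count = rs$voxel_count[i]))
  names(reg) <- rs$region_id
  jsonlite::write_json(reg, file.path(dir, "regions.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' Read a run configuration from JSON
#'
#' Recognised keys: `R`, `B`, `alpha`, `negligible_fraction`,
#' `max_iterations`, `seed`, `predictor` (`grid` as a list of columns,
#' `output_mode`), `embedding`, `significance`, `reoptimize`, and `subset`
#' (`exclude_bilateral`, `exclude_recurrent`), all optional.
#'
#' @param path JSON file.
#' @return a [run_config()] with attribute `subset`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- if (!is.null(j$predictor$grid))
    do.call(expand.grid, c(j$predictor$grid, KEEP.OUT.ATTRS = FALSE))
  else default_predictor_grid()
  cfg <- run_config(R = j$R %||% 1000, B = j$B %||% 1000,
                    alpha = j$alpha %||% 0.05,
                    negligible_fraction = j$negligible_fraction %||% 0.01,
                    max_iterations = j$max_iterations %||% 100,
                    seed = j$seed %||% 1, grid = grid,
                    output_mode = j$predictor$output_mode %||% "class",
                    embedding = j$embedding %||% "ablation",
                    significance = j$significance %||% "ci",
                    reoptimize = j$reoptimize %||% TRUE)
  attr(cfg, "subset") <- list(
    exclude_bilateral = isTRUE(j$subset$exclude_bilateral),
    exclude_recurrent = isTRUE(j$subset$exclude_recurrent))
  cfg
}

#' Write a run manifest for exact reruns
#'
#' Records the subcommand, options, seed, package and R versions, and MD5
#' hashes of the input files, so a run can be reproduced byte-for-byte.
#'
#' @param path output JSON path.
#' @param subcommand CLI subcommand (or calling context).
#' @param options named list of options.
#' @param inputs character vector of input file paths to hash.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, subcommand, options, inputs = character(0)) {
  inputs <- inputs[file.exists(inputs)]
  jsonlite::write_json(
    list(subcommand = subcommand, options = options,
         package_version = as.character(utils::packageVersion("lesionmsa")),
         r_version = R.version.string,
         input_md5 = as.list(tools::md5sum(inputs)),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
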