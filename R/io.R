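#' Write a cohort to disk
#'
#' One TSV per subject (T rows x N columns, header row of subregion
#' labels), a cohort manifest CSV and the parcellation CSV.
#'
#' @param cohort An `sd_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sd_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
  readr::write_csv(cohort$subjects, file.path(dir, "manifest.csv"))
  write_parcellation(cohort$parcellation, file.path(dir, "parcellation.csv"))
  purrr::iwalk(cohort$series, function(x, id) {
    readr::write_tsv(tibble::as_tibble(x, .name_repair = "minimal"),
                     file.path(dir, "timeseries", paste0(id, ".tsv")))
  })
  invisible(dir)
}

#' Read a cohort manifest
#'
#' @param path CSV with columns `subject_id`, `group`, `age`, `sex`,
#'   `education`, `bdi`.
#' @return A validated tibble.
#' @export
read_cohort_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("subject_id", "group", "age", "sex", "education", "bdi")
  missing <- setdiff(needed, names(m))
  if (length(missing) > 0) {
    stop(path, ": manifest is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(m$group), c("SD", "HC"))
  if (length(bad) > 0) {
    stop(path, ": unknown group label(s) ", paste(bad, collapse = ", "),
         "; allowed: SD, HC", call. = FALSE)
  }
  if (anyDuplicated(m$subject_id)) {
    stop(path, ": duplicated subject_id", call. = FALSE)
  }
  m
}

#' Read one subject's ROI time series
#'
#' @param path TSV, T rows x N columns, header row of subregion labels.
#' @return A numeric matrix.
#' @export
read_timeseries <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  mat <- as.matrix(x)
  if (!is.numeric(mat)) {
    stop(path, ": time series must be numeric", call. = FALSE)
  }
  if (anyNA(mat)) stop(path, ": time series contains missing values",
                       call. = FALSE)
  const <- apply(mat, 2, stats::sd) == 0
  if (any(const)) {
    warning(path, ": constant column(s) ",
            paste(colnames(mat)[const], collapse = ", "),
            "; build_network() will reject them", call. = FALSE)
  }
  mat
}

#' Read all time series named in a manifest
#'
#' @param dir Directory of per-subject TSVs named `<subject_id>.tsv`.
#' @param manifest A manifest tibble (see [read_cohort_manifest()]).
#' @return A named list of matrices, in manifest order.
#' @export
read_timeseries_dir <- function(dir, manifest) {
  paths <- file.path(dir, paste0(manifest$subject_id, ".tsv"))
  absent <- !file.exists(paths)
  if (any(absent)) {
    stop("missing time-series file(s): ",
         paste(basename(paths[absent]), collapse = ", "), call. = FALSE)
  }
  out <- purrr::map(paths, read_timeseries)
  names(out) <- manifest$subject_id
  out
}

#' Write / read a parcellation table
#'
#' @param parc A parcellation tibble.
#' @param path CSV path.
#' @return The parcellation tibble ([read_parcellation()]) or `path`,
#'   invisibly.
#' @export
write_parcellation <- function(parc, path) {
  validate_parcellation(parc)
  readr::write_csv(parc, path)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  parc <- readr::read_csv(path, show_col_types = FALSE)
  validate_parcellation(parc)
  parc
}

#' Write an edge-stat table to CSV
#'
#' @param stats Tibble from [edgewise_ttest()].
#' @param path CSV path.
#' @export
write_edge_stats <- function(stats, path) {
  readr::write_csv(stats, path)
  invisible(path)
}

#' Write a mask family
#'
#' The full mask is written both as an edge list and as a 0/1 matrix CSV;
#' fold masks as one edge-list CSV with a fold column.
#'
#' @param masks A `mask_family`.
#' @param dir Output directory.
#' @export
write_mask_family <- function(masks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(mask_edges(masks$full), file.path(dir, "full_mask_edges.csv"))
  readr::write_csv(
    tibble::as_tibble(masks$full + 0, .name_repair = "minimal"),
    file.path(dir, "full_mask_matrix.csv"))
  fold_edges <- purrr::imap_dfr(masks$folds, function(m, id) {
    dplyr::mutate(mask_edges(m), held_out = id, .before = 1)
  })
  readr::write_csv(fold_edges, file.path(dir, "fold_mask_edges.csv"))
  invisible(dir)
}

#' Write a fitted model report as JSON
#'
#' @param model An `sdc_model`.
#' @param path JSON path.
#' @export
write_model_report <- function(model, path) {
  jsonlite::write_json(
    list(model = model$model_name, family = model$family,
         confusion = as.list(model$confusion),
         metrics = as.list(model$metrics), auc = model$auc,
         roc = model$roc, folds = model$folds,
         predictions = model$predictions),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
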