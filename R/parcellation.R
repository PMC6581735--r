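#' Build a synthetic whole-brain parcellation table
#'
#' Constructs a parcellation mapping subregions to anatomical regions in the
#' layout of a bilateral human atlas: each merged region has a left and a
#' right hemispheric part, and one thalamic subregion is flagged as
#' containing the lateral habenula (LHb). The default emulates a
#' 246-subregion atlas: 23 bilateral regions with 10 subregions each plus a
#' thalamus with 16 subregions (8 per hemisphere). This is a synthetic label
#' table, not the atlas itself; it carries the structure the pipeline needs
#' (subregion-to-region mapping, hemisphere, LHb flag) with generic names.
#'
#' @param n_nodes Total number of subregions.
#' @param n_regions Number of merged (bilateral) regions.
#' @param thalamus_size Number of subregions in the final region
#'   ("Thalamus"), only honoured when the sizes work out; otherwise
#'   subregions are split as evenly as possible.
#' @return A tibble with columns `subregion_index`, `subregion_label`,
#'   `hemisphere` ("L"/"R"), `hemispheric_region`, `merged_region`, and
#'   `contains_lhb` (logical, exactly one `TRUE` — the right-hemisphere
#'   posterior parietal thalamic subregion, where LHb sits).
#' @examples
#' parc <- synthetic_parcellation(246, 24)
#' table(parc$merged_region)["Thalamus"]
#' @export
synthetic_parcellation <- function(n_nodes = 246, n_regions = 24,
                                   thalamus_size = 16) {
  stopifnot(n_nodes >= 2, n_regions >= 1, n_regions <= n_nodes)
  rest <- n_nodes - thalamus_size
  if (n_regions > 1 && thalamus_size >= 2 && rest >= n_regions - 1 &&
      rest %% (n_regions - 1) == 0) {
    sizes <- c(rep(rest %/% (n_regions - 1), n_regions - 1), thalamus_size)
  } else {
    base <- n_nodes %/% n_regions
    sizes <- rep(base, n_regions)
    extra <- n_nodes - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  }
  region_names <- c(sprintf("Region%02d", seq_len(n_regions - 1)), "Thalamus")
  if (n_regions == 1) region_names <- "Thalamus"

  thal_bases <- c("mPFtha", "mPMtha", "Stha", "rTtha",
                  "PPtha", "Otha", "cTtha", "lPFtha")
  rows <- purrr::map2(region_names, sizes, function(reg, sz) {
    n_l <- ceiling(sz / 2)
    hemi <- c(rep("L", n_l), rep("R", sz - n_l))
    if (reg == "Thalamus" && sz %% 2 == 0 && sz / 2 <= length(thal_bases)) {
      bases <- rep(thal_bases[seq_len(sz / 2)], 2)
    } else {
      bases <- paste0(reg, "_", c(seq_len(n_l), seq_len(sz - n_l)))
    }
    tibble::tibble(
      subregion_label = paste0(bases, "_", hemi),
      hemisphere = hemi,
      hemispheric_region = paste0(reg, "_", hemi),
      merged_region = reg
    )
  })
  parc <- dplyr::bind_rows(rows)
  parc$subregion_index <- seq_len(nrow(parc))
  parc$contains_lhb <- FALSE
  lhb <- which(parc$subregion_label == "PPtha_R")
  if (length(lhb) == 0) lhb <- max(which(parc$hemisphere == "R"))
  parc$contains_lhb[lhb[1]] <- TRUE
  parc <- dplyr::relocate(parc, "subregion_index")
  validate_parcellation(parc)
  parc
}

#' Validate a parcellation table
#'
#' Checks the schema and invariants a parcellation must satisfy: required
#' columns, unique subregion labels, contiguous 1-based indices, and each
#' subregion mapping to exactly one region.
#'
#' @param parc A parcellation tibble (see [synthetic_parcellation()]).
#' @return `parc`, invisibly, if valid; otherwise an error.
#' @export
validate_parcellation <- function(parc) {
  needed <- c("subregion_index", "subregion_label", "hemisphere",
              "hemispheric_region", "merged_region", "contains_lhb")
  missing <- setdiff(needed, names(parc))
  if (length(missing) > 0) {
    stop("parcellation is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(parc$subregion_label)) {
    stop("parcellation has duplicated subregion labels", call. = FALSE)
  }
  if (!identical(as.integer(parc$subregion_index), seq_len(nrow(parc)))) {
    stop("subregion_index must be 1..N in order", call. = FALSE)
  }
  if (!all(parc$hemisphere %in% c("L", "R"))) {
    stop("hemisphere must be 'L' or 'R'", call. = FALSE)
  }
  invisible(parc)
}

# node indices of one or more merged regions (error on unknown names)
region_nodes <- function(parc, regions) {
  unknown <- setdiff(regions, unique(parc$merged_region))
  if (length(unknown) > 0) {
    stop("unknown region(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  parc$subregion_index[parc$merged_region %in% regions]
}
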