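new_feature_specs <- function(name, family, scope, nodes) {
  tibble::tibble(name = name, family = family, scope = scope,
                 nodes = nodes)
}

#' Anatomical-region feature specifications
#'
#' One feature set per merged (bilateral) anatomical region: the
#' connections incident to that region's subregions. With the default
#' 48-hemispheric-region / 24-merged-region atlas layout this yields 24
#' specs, one per region-based classifier.
#'
#' @param parc A parcellation table.
#' @param scope `"incident"` (edges from the region to anywhere, default)
#'   or `"within"` (edges entirely inside the region).
#' @return A tibble of feature specs: `name`, `family`, `scope`, and
#'   `nodes` (list-column of subregion indices).
#' @export
anatomical_feature_specs <- function(parc, scope = c("incident", "within")) {
  scope <- match.arg(scope)
  validate_parcellation(parc)
  regions <- unique(parc$merged_region)
  new_feature_specs(
    name = regions, family = "anatomical", scope = scope,
    nodes = purrr::map(regions, ~ region_nodes(parc, .x))
  )
}

#' Sliding-window feature specifications
#'
#' Windows of `window_size` consecutive subregions in atlas order, slid
#' one row at a time over the adjacency matrix: `n_nodes - window_size + 1`
#' specs in total (231 for a 246-node atlas with windows of 16).
#'
#' @param n_nodes Number of subregions.
#' @param window_size Number of consecutive subregions per window.
#' @param scope `"within"` (edges joining two window members, default,
#'   matching the windows' role as self-contained subregion sets) or
#'   `"incident"`.
#' @return A tibble of feature specs (see [anatomical_feature_specs()]).
#' @export
window_feature_specs <- function(n_nodes, window_size,
                                 scope = c("within", "incident")) {
  scope <- match.arg(scope)
  stopifnot(n_nodes >= 1)
  if (window_size < 1 || window_size > n_nodes) {
    stop("window_size must be between 1 and n_nodes (", n_nodes, ")",
         call. = FALSE)
  }
  starts <- seq_len(n_nodes - window_size + 1)
  new_feature_specs(
    name = sprintf("window_%03d", starts), family = "window", scope = scope,
    nodes = purrr::map(starts, ~ .x:(.x + window_size - 1))
  )
}

#' Random-selection feature specifications
#'
#' Each spec draws `set_size` subregions uniformly without replacement;
#' `n_models` such draws, deterministic given the seed.
#'
#' @param n_nodes Number of subregions.
#' @param set_size Subregions per random set.
#' @param n_models Number of random specs to draw.
#' @param seed Integer seed.
#' @param scope `"within"` (connections joining two members of the random
#'   set, default) or `"incident"`.
#' @return A tibble of feature specs (see [anatomical_feature_specs()]).
#' @export
random_feature_specs <- function(n_nodes, set_size, n_models, seed = 1L,
                                 scope = c("within", "incident")) {
  scope <- match.arg(scope)
  stopifnot(set_size >= 1, set_size <= n_nodes, n_models >= 1)
  set.seed(seed)
  new_feature_specs(
    name = sprintf("random_%03d", seq_len(n_models)),
    family = "random", scope = scope,
    nodes = purrr::map(seq_len(n_models),
                       ~ sort(sample.int(n_nodes, set_size)))
  )
}

# resolve a one-row spec tibble or a bare list into (name, nodes, scope)
as_one_spec <- function(spec) {
  if (is.data.frame(spec)) {
    stopifnot(nrow(spec) == 1)
    spec <- list(name = spec$name, scope = spec$scope,
                 nodes = spec$nodes[[1]])
  }
  stopifnot(length(spec$nodes) >= 1, !anyDuplicated(spec$nodes))
  spec
}

#' Materialize a feature matrix for one spec
#'
#' Selects the masked edges touching the spec's node set — incident to it
#' (`scope = "incident"`) or entirely within it (`scope = "within"`) — and
#' returns the per-subject edge weights as a subjects x features matrix.
#' Columns follow the canonical edge order (lexicographic on (i, j) with
#' i < j) and are named "A--B" after the two subregions, so rebuilding
#' from the same spec and mask yields an identical matrix.
#'
#' @param spec A one-row feature-spec tibble (or list with `name`,
#'   `nodes`, `scope`).
#' @param mask A symmetric logical N x N matrix of selected edges.
#' @param networks Named list of adjacency matrices.
#' @return A numeric matrix, subjects in rows; zero columns (with a
#'   message) when no masked edge touches the node set.
#' @export
materialize_features <- function(spec, mask, networks) {
  spec <- as_one_spec(spec)
  n <- ncol(mask)
  stopifnot(max(abs(mask - t(mask))) == 0, all(spec$nodes >= 1),
            all(spec$nodes <= n))
  ed <- edge_index(n)
  in_set_i <- ed$i %in% spec$nodes
  in_set_j <- ed$j %in% spec$nodes
  touch <- if (identical(spec$scope, "within")) in_set_i & in_set_j
           else in_set_i | in_set_j
  sel <- touch & mask[cbind(ed$i, ed$j)]
  X <- edge_weight_matrix(networks)
  out <- X[, sel, drop = FALSE]
  lbl <- colnames(networks[[1]])
  if (is.null(lbl)) lbl <- as.character(seq_len(n))
  if (ncol(out) > 0) {
    colnames(out) <- paste0(lbl[ed$i[sel]], "--", lbl[ed$j[sel]])
  }
  if (ncol(out) == 0) {
    message("no significant connections for feature set '", spec$name, "'")
  }
  out
}
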