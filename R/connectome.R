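#' Build a weighted functional network from ROI time series
#'
#' Computes the Pearson correlation between every pair of subregion time
#' courses, applies the Fisher r-to-z transform, takes absolute values
#' (negative correlations are not interpreted as a different edge type),
#' zeroes the diagonal, and normalizes so edge weights fall in [0, 1].
#'
#' Perfect correlations (|r| = 1 off the diagonal) would give infinite z;
#' they are clipped at `atanh(1 - 1e-7)` with a warning. Normalization
#' `"max"` divides by the off-diagonal maximum of |z| (the default,
#' per-subject: the strongest edge gets weight 1); `"none"` returns |z|
#' unscaled, which [build_networks()] uses for cohort-wide normalization.
#'
#' @param ts A T x N numeric matrix (timepoints x subregions), columns
#'   named by subregion label.
#' @param normalize `"max"` or `"none"`.
#' @return An N x N symmetric numeric matrix with zero diagonal and, for
#'   `normalize = "max"`, entries in [0, 1].
#' @examples
#' ts <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("n", 1:4)))
#' W <- build_network(ts)
#' max(abs(W - t(W)))
#' @export
build_network <- function(ts, normalize = c("max", "none")) {
  normalize <- match.arg(normalize)
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 timepoints", call. = FALSE)
  if (anyNA(ts)) stop("time series contains missing values", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant time course for subregion(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(ts)
  diag(r) <- 0
  cap <- 1 - 1e-7
  if (any(abs(r) >= cap)) {
    warning("perfect off-diagonal correlation clipped at |r| = 1 - 1e-7",
            call. = FALSE)
    r <- pmin(pmax(r, -cap), cap)
  }
  z <- abs(atanh(r))
  diag(z) <- 0
  if (normalize == "max") {
    m <- max(z)
    if (m > 0) z <- z / m
  }
  dimnames(z) <- list(colnames(ts), colnames(ts))
  z
}

#' Build networks for a whole cohort
#'
#' Applies [build_network()] to every subject. With
#' `normalization = "subject"` each network is scaled by its own
#' off-diagonal maximum; with `"cohort"` all |z| matrices are divided by
#' the single largest |z| across the cohort, preserving between-subject
#' weight differences.
#'
#' @param x An `sd_cohort` (from [generate_cohort()]) or a named list of
#'   T x N time-series matrices.
#' @param normalization `"subject"` (default) or `"cohort"`.
#' @return A named list of N x N adjacency matrices.
#' @export
build_networks <- function(x, normalization = c("subject", "cohort")) {
  normalization <- match.arg(normalization)
  series <- if (inherits(x, "sd_cohort")) x$series else x
  stopifnot(is.list(series), length(series) >= 1)
  if (normalization == "subject") {
    purrr::map(series, build_network, normalize = "max")
  } else {
    zs <- purrr::map(series, build_network, normalize = "none")
    m <- max(purrr::map_dbl(zs, max))
    if (m > 0) zs <- purrr::map(zs, ~ .x / m)
    zs
  }
}

#' Weighted node degree
#'
#' The weighted degree of node i is the sum of its edge weights,
#' k_i = sum_j W_ij (self-connections carry weight zero).
#'
#' @param W A symmetric adjacency matrix.
#' @return A tibble with columns `node` and `degree`.
#' @examples
#' W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 0.5
#' node_degree(W)$degree
#' @export
node_degree <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W) || max(abs(W - t(W))) > 1e-10) {
    stop("adjacency matrix must be symmetric", call. = FALSE)
  }
  lbl <- colnames(W)
  if (is.null(lbl)) lbl <- as.character(seq_len(ncol(W)))
  tibble::tibble(node = lbl, degree = unname(rowSums(W) - diag(W)))
}

#' Weighted degrees for a cohort of networks
#'
#' @param networks Named list of adjacency matrices (one per subject).
#' @return A long tibble: `subject_id`, `node`, `degree`.
#' @export
cohort_degrees <- function(networks) {
  purrr::imap_dfr(networks, function(W, id) {
    d <- node_degree(W)
    tibble::tibble(subject_id = id, node = d$node, degree = d$degree)
  })
}
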