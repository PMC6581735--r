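# upper-triangle edge index in canonical order: lexicographic on (i, j), i < j
edge_index <- function(n) {
  i <- rep.int(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n), use.names = FALSE)
  tibble::tibble(i = i, j = j)
}

# subjects x edges matrix of upper-triangle weights, canonical edge order
edge_weight_matrix <- function(networks) {
  n <- ncol(networks[[1]])
  ed <- edge_index(n)
  lin <- (ed$j - 1L) * n + ed$i   # column-major linear index of (i, j)
  out <- vapply(networks, function(W) W[lin], numeric(nrow(ed)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(ed))
  out <- t(out)
  rownames(out) <- names(networks)
  attr(out, "edges") <- ed
  out
}

# vectorized two-sample t-test over columns of a subjects x edges matrix
two_sample_t_cols <- function(X, is_sd, var_equal = TRUE) {
  x1 <- X[is_sd, , drop = FALSE]
  x2 <- X[!is_sd, , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums((x1 - rep(m1, each = n1))^2) / (n1 - 1)
  v2 <- colSums((x2 - rep(m2, each = n2))^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- !is.finite(se) | se == 0
  if (any(degen)) {
    zero_diff <- degen & (m1 == m2)
    tstat[zero_diff] <- 0
    p[zero_diff] <- 1
    if (any(zero_diff)) {
      warning(sum(zero_diff),
              " edge(s) with zero variance in both groups; p set to 1",
              call. = FALSE)
    }
    inf_diff <- degen & (m1 != m2)
    tstat[inf_diff] <- sign(m1[inf_diff] - m2[inf_diff]) * Inf
    p[inf_diff] <- 0
  }
  list(t = tstat, p = p, mean_sd = m1, mean_hc = m2)
}

as_group_factor <- function(groups) {
  g <- as.character(groups)
  bad <- setdiff(unique(g), c("SD", "HC"))
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; allowed: SD, HC", call. = FALSE)
  }
  if (sum(g == "SD") < 2 || sum(g == "HC") < 2) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  g
}

#' Edge-wise two-sample tests between groups
#'
#' For every unordered subregion pair (i < j), compares the per-subject
#' edge weights W_ij between SD and HC with a two-sample t-test (pooled
#' variance by default, Welch optionally) and reports Benjamini-Hochberg
#' adjusted q-values alongside the raw two-sided p-values.
#'
#' @param networks Named list of symmetric adjacency matrices, identical
#'   node ordering across subjects.
#' @param groups Character vector of "SD"/"HC", one per subject, in the
#'   order of `networks`.
#' @param var_equal Pooled-variance Student test if `TRUE` (default),
#'   Welch if `FALSE`.
#' @return A tibble with one row per edge, N(N-1)/2 rows total:
#'   `node_i`, `node_j` (labels), `i`, `j` (1-based indices),
#'   `mean_sd`, `mean_hc`, `t_statistic`, `p_value`, `q_value`.
#' @export
edgewise_ttest <- function(networks, groups, var_equal = TRUE) {
  groups <- as_group_factor(groups)
  stopifnot(length(groups) == length(networks))
  X <- edge_weight_matrix(networks)
  ed <- attr(X, "edges")
  res <- two_sample_t_cols(X, groups == "SD", var_equal = var_equal)
  lbl <- colnames(networks[[1]])
  if (is.null(lbl)) lbl <- as.character(seq_len(ncol(networks[[1]])))
  tibble::tibble(
    node_i = lbl[ed$i], node_j = lbl[ed$j], i = ed$i, j = ed$j,
    mean_sd = unname(res$mean_sd), mean_hc = unname(res$mean_hc),
    t_statistic = unname(res$t), p_value = unname(res$p),
    q_value = bh_fdr(unname(res$p))
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Linear step-up FDR adjustment: the adjusted value of the k-th smallest
#' p is min over j >= k of m * p_(j) / j, capped at 1, returned in the
#' input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Numeric vector of adjusted q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Build the leakage-avoiding mask family
#'
#' Runs the edge-wise group test once on the full cohort (the full mask,
#' used for group-level profiling) and once per leave-one-out fold with
#' that subject excluded (the fold masks, used for feature selection
#' inside cross-validation so the held-out subject never influences which
#' edges are selected). An edge enters a mask iff its uncorrected p-value
#' (default) or BH q-value is below `alpha`.
#'
#' @inheritParams edgewise_ttest
#' @param alpha Significance level for mask inclusion.
#' @param criterion `"p"` (uncorrected, default) or `"q"` (BH-adjusted).
#' @return A `mask_family` object: list with `full` (N x N logical,
#'   symmetric, false diagonal), `folds` (named list of such matrices, one
#'   per subject, each computed without that subject), `alpha`,
#'   `criterion`, `subject_ids`, `node_labels`.
#' @export
build_mask_family <- function(networks, groups, alpha = 0.05,
                              criterion = c("p", "q"), var_equal = TRUE) {
  criterion <- match.arg(criterion)
  groups <- as_group_factor(groups)
  stopifnot(length(groups) == length(networks), length(networks) >= 3)
  X <- edge_weight_matrix(networks)
  ed <- attr(X, "edges")
  n <- ncol(networks[[1]])
  lbl <- colnames(networks[[1]])

  edge_stat <- function(keep) {
    g <- groups[keep]
    if (sum(g == "SD") < 2 || sum(g == "HC") < 2) {
      stop("holding out a subject leaves fewer than 2 subjects in a group",
           call. = FALSE)
    }
    res <- two_sample_t_cols(X[keep, , drop = FALSE], g == "SD",
                             var_equal = var_equal)
    if (criterion == "p") res$p else bh_fdr(res$p)
  }
  to_mask <- function(crit_vals) {
    m <- matrix(FALSE, n, n, dimnames = list(lbl, lbl))
    sel <- crit_vals < alpha
    m[cbind(ed$i[sel], ed$j[sel])] <- TRUE
    m[cbind(ed$j[sel], ed$i[sel])] <- TRUE
    m
  }
  all_idx <- seq_along(networks)
  full <- to_mask(suppressWarnings(edge_stat(all_idx)))
  folds <- purrr::map(all_idx,
                      ~ to_mask(suppressWarnings(edge_stat(all_idx[-.x]))))
  names(folds) <- names(networks)
  structure(list(full = full, folds = folds, alpha = alpha,
                 criterion = criterion, subject_ids = names(networks),
                 node_labels = lbl),
            class = "mask_family")
}

#' @export
print.mask_family <- function(x, ...) {
  cat(sprintf(
    "<mask_family> %d fold masks + full mask, alpha = %g on %s, %d edges in full mask\n",
    length(x$folds), x$alpha, x$criterion, sum(x$full) / 2))
  invisible(x)
}

#' Masked edges as a tibble
#'
#' @param mask A logical adjacency matrix (e.g. `mask_family$full`).
#' @return A tibble of selected edges: `i`, `j` (i < j), `node_i`, `node_j`.
#' @export
mask_edges <- function(mask) {
  n <- ncol(mask)
  ed <- edge_index(n)
  sel <- mask[cbind(ed$i, ed$j)]
  lbl <- colnames(mask)
  if (is.null(lbl)) lbl <- as.character(seq_len(n))
  tibble::tibble(i = ed$i[sel], j = ed$j[sel],
                 node_i = lbl[ed$i[sel]], node_j = lbl[ed$j[sel]])
}
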