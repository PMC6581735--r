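# masked edges joined with their p-values from an edge-stat table
masked_edge_stats <- function(stats, mask) {
  sel <- mask[cbind(stats$i, stats$j)]
  stats[sel, c("i", "j", "node_i", "node_j", "p_value")]
}

#' Significant-connection profile per region
#'
#' Counts, for each region, the masked edges incident to its subregions
#' (an edge internal to the region is counted once) and the mean p-value
#' of those edges. `level = "hemispheric"` splits each merged region's
#' count between its left and right parts: an edge is attributed to the
#' hemisphere of its endpoint inside the region, and an edge with both
#' endpoints inside to the hemisphere of the lower-indexed one, so the
#' two hemispheric counts always sum to the merged count.
#'
#' @param stats An edge-stat tibble from [edgewise_ttest()].
#' @param mask A symmetric logical matrix of selected edges (normally the
#'   full-cohort mask).
#' @param parc The parcellation table.
#' @param level `"merged"` (default) or `"hemispheric"`.
#' @return A tibble: `region`, `n_connections`, `mean_p` (`NA` when a
#'   region has no masked connection).
#' @export
region_connection_profile <- function(stats, mask, parc,
                                      level = c("merged", "hemispheric")) {
  level <- match.arg(level)
  validate_parcellation(parc)
  me <- masked_edge_stats(stats, mask)
  regions <- if (level == "merged") unique(parc$merged_region)
             else unique(parc$hemispheric_region)
  col <- if (level == "merged") "merged_region" else "hemispheric_region"
  reg_of <- parc[[col]][order(parc$subregion_index)]
  merged_of <- parc$merged_region[order(parc$subregion_index)]
  purrr::map_dfr(regions, function(reg) {
    if (level == "merged") {
      sel <- reg_of[me$i] == reg | reg_of[me$j] == reg
    } else {
      mreg <- unique(merged_of[reg_of == reg])
      in_m_i <- merged_of[me$i] == mreg
      in_m_j <- merged_of[me$j] == mreg
      # attribute to the lower-indexed endpoint when both are inside
      focal_end <- ifelse(in_m_i, me$i, me$j)
      sel <- (in_m_i | in_m_j) & reg_of[focal_end] == reg
    }
    tibble::tibble(
      region = reg,
      n_connections = sum(sel),
      mean_p = if (any(sel)) mean(me$p_value[sel]) else NA_real_)
  })
}

#' Partner-region distribution of one region's significant connections
#'
#' For a focal region, attributes each of its masked incident edges to the
#' (merged) region of the other endpoint; edges joining two of the focal
#' region's own subregions are attributed to the focal region itself, so
#' the partner counts sum exactly to the focal region's connection count.
#'
#' @inheritParams region_connection_profile
#' @param focal A merged-region name.
#' @return A tibble: `partner_region`, `n_connections`, `mean_p`, sorted
#'   by descending count.
#' @export
focal_partner_profile <- function(stats, mask, parc, focal) {
  validate_parcellation(parc)
  nodes <- region_nodes(parc, focal)
  me <- masked_edge_stats(stats, mask)
  reg_of <- parc$merged_region[order(parc$subregion_index)]
  me <- me[me$i %in% nodes | me$j %in% nodes, ]
  partner <- ifelse(reg_of[me$i] == focal & reg_of[me$j] == focal,
                    focal,
                    ifelse(reg_of[me$i] == focal, reg_of[me$j],
                           reg_of[me$i]))
  dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(
        tibble::tibble(partner_region = partner, p_value = me$p_value),
        .data$partner_region),
      n_connections = dplyr::n(), mean_p = mean(.data$p_value),
      .groups = "drop"),
    dplyr::desc(.data$n_connections))
}

#' Per-subregion profile within a focal region
#'
#' Counts the masked edges incident to each subregion of the focal region
#' (an edge between two focal subregions counts for both of them) and
#' their mean p-value.
#'
#' @inheritParams focal_partner_profile
#' @return A tibble: `subregion`, `hemisphere`, `contains_lhb`,
#'   `n_connections`, `mean_p`.
#' @export
subregion_profile <- function(stats, mask, parc, focal) {
  validate_parcellation(parc)
  nodes <- region_nodes(parc, focal)
  me <- masked_edge_stats(stats, mask)
  purrr::map_dfr(nodes, function(nd) {
    sel <- me$i == nd | me$j == nd
    row <- parc[parc$subregion_index == nd, ]
    tibble::tibble(
      subregion = row$subregion_label,
      hemisphere = row$hemisphere,
      contains_lhb = row$contains_lhb,
      n_connections = sum(sel),
      mean_p = if (any(sel)) mean(me$p_value[sel]) else NA_real_)
  })
}

#' Does model accuracy track connection count or p-value?
#'
#' Pearson correlations (with two-sided tests) of per-region model
#' accuracy against (a) the region's number of significant connections
#' and (b) their mean p-value — the confounder check that the well-
#' performing regions are not simply the ones with many or strongly
#' significant connections.
#'
#' @param model_summary A tibble from [evaluate_models()] over the
#'   anatomical family (`model` = region name, `accuracy`).
#' @param profile A tibble from [region_connection_profile()].
#' @return A tibble with one row per predictor (`n_connections`,
#'   `mean_p`): `term`, `r`, `p_value`, `n`.
#' @export
accuracy_confounder_check <- function(model_summary, profile) {
  joined <- dplyr::inner_join(model_summary, profile,
                              by = c(model = "region"))
  if (nrow(joined) < 3) stop("need at least 3 models", call. = FALSE)
  one <- function(term) {
    x <- joined[[term]]; y <- joined$accuracy
    keep <- stats::complete.cases(x, y)
    if (stats::sd(y[keep]) == 0 || stats::sd(x[keep]) == 0) {
      warning("constant vector; correlation undefined for ", term,
              call. = FALSE)
      return(tibble::tibble(term = term, r = NA_real_, p_value = NA_real_,
                            n = sum(keep)))
    }
    ct <- stats::cor.test(x[keep], y[keep])
    tibble::tibble(term = term, r = unname(ct$estimate),
                   p_value = ct$p.value, n = sum(keep))
  }
  dplyr::bind_rows(one("n_connections"), one("mean_p"))
}

#' Accuracy after randomly thinning a model's connections
#'
#' Repeats the LOOCV evaluation of one feature set with only `target_n`
#' randomly sampled masked connections available (the sample is drawn
#' from the full-mask feature edges and intersected with every fold
#' mask). Used to test whether a high-performing region keeps its
#' accuracy when its connection count is reduced to another region's.
#'
#' @inheritParams loocv_evaluate
#' @param target_n Number of connections to keep per repeat.
#' @param n_repeats Number of random subsamples.
#' @param seed Integer seed; the whole experiment is deterministic
#'   given it.
#' @return A one-row tibble: `target_n`, `n_repeats`, `mean_accuracy`,
#'   with the per-repeat accuracies in the `per_repeat` attribute.
#' @export
subsample_connections_experiment <- function(networks, groups, spec, masks,
                                             cfg = svm_config(), target_n,
                                             n_repeats = 100, seed = 1L) {
  spec1 <- as_one_spec(spec)
  n_nodes <- ncol(masks$full)
  ed <- edge_index(n_nodes)
  in_i <- ed$i %in% spec1$nodes
  in_j <- ed$j %in% spec1$nodes
  touch <- if (identical(spec1$scope, "within")) in_i & in_j else in_i | in_j
  avail <- which(touch & masks$full[cbind(ed$i, ed$j)])
  if (length(avail) == 0) stop("no masked connections to subsample",
                               call. = FALSE)
  if (target_n > length(avail)) {
    message("target_n (", target_n, ") exceeds the ", length(avail),
            " available connections; using all")
    target_n <- length(avail)
  }
  set.seed(seed)
  accs <- purrr::map_dbl(seq_len(n_repeats), function(r) {
    keep_edges <- sample(avail, target_n)
    keep <- matrix(FALSE, n_nodes, n_nodes,
                   dimnames = dimnames(masks$full))
    keep[cbind(ed$i[keep_edges], ed$j[keep_edges])] <- TRUE
    keep[cbind(ed$j[keep_edges], ed$i[keep_edges])] <- TRUE
    sub_masks <- masks
    sub_masks$full <- masks$full & keep
    sub_masks$folds <- purrr::map(masks$folds, ~ .x & keep)
    fit <- loocv_evaluate(networks, groups, spec, sub_masks, cfg)
    fit$metrics$accuracy
  })
  out <- tibble::tibble(target_n = target_n, n_repeats = n_repeats,
                        mean_accuracy = mean(accs))
  attr(out, "per_repeat") <- accs
  out
}

#' Group comparison of weighted node degree per subregion
#'
#' Two-sample t-test (pooled by default) of the weighted degree of each
#' subregion of a focal region between SD and HC, with the direction of
#' any significant difference.
#'
#' @param degrees Long tibble from [cohort_degrees()] (`subject_id`,
#'   `node`, `degree`).
#' @param groups Named "SD"/"HC" vector (names = subject ids), or an
#'   unnamed vector in the order the subjects appear in `degrees`.
#' @param parc The parcellation table.
#' @param focal A merged-region name.
#' @param alpha Significance level for calling a direction (default 0.01).
#' @param var_equal Pooled t if `TRUE`, Welch otherwise.
#' @return A tibble per focal subregion: `subregion`, `hemisphere`,
#'   `contains_lhb`, `mean_degree_sd`, `mean_degree_hc`, `t_statistic`,
#'   `p_value`, `direction` ("SD<HC", "SD>HC" or "ns").
#' @export
compare_subregion_degrees <- function(degrees, groups, parc, focal,
                                      alpha = 0.01, var_equal = TRUE) {
  validate_parcellation(parc)
  ids <- unique(degrees$subject_id)
  if (is.null(names(groups))) {
    stopifnot(length(groups) == length(ids))
    names(groups) <- ids
  }
  groups <- as_group_factor(groups[ids])
  rows <- parc[parc$merged_region == focal, ]
  if (nrow(rows) == 0) stop("unknown region: ", focal, call. = FALSE)
  purrr::map_dfr(seq_len(nrow(rows)), function(k) {
    lbl <- rows$subregion_label[k]
    d <- degrees[degrees$node == lbl, ]
    d <- d[match(ids, d$subject_id), ]
    x <- d$degree[groups == "SD"]
    y <- d$degree[groups == "HC"]
    res <- two_sample_t_cols(matrix(c(x, y), ncol = 1),
                             c(rep(TRUE, length(x)), rep(FALSE, length(y))),
                             var_equal = var_equal)
    dir <- if (res$p < alpha) {
      if (mean(x) < mean(y)) "SD<HC" else "SD>HC"
    } else "ns"
    tibble::tibble(
      subregion = lbl, hemisphere = rows$hemisphere[k],
      contains_lhb = rows$contains_lhb[k],
      mean_degree_sd = mean(x), mean_degree_hc = mean(y),
      t_statistic = unname(res$t), p_value = unname(res$p),
      direction = dir)
  })
}
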