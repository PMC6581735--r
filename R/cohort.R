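#' Specify a synthetic cohort
#'
#' Bundles the design parameters of a simulated two-group resting-state
#' study: group sizes, network size, scan length, where group-differential
#' connectivity is planted, and how strong it is. The defaults emulate the
#' study design the pipeline targets: 34 subclinically depressed (SD)
#' subjects and 40 healthy controls (HC), 246 subregions, 180 retained
#' timepoints per subject.
#'
#' @param n_sd,n_hc Number of SD / HC subjects (each at least 2).
#' @param n_nodes Number of subregions (network nodes).
#' @param n_timepoints Retained timepoints per subject (at least 10).
#' @param planted_regions Character vector of merged-region names whose
#'   incident edges carry a group effect; empty for a null cohort.
#' @param effect_size Target group difference in population correlation
#'   (delta r) on planted edges, in (-1, 1). Positive values weaken SD
#'   connectivity relative to HC (SD lower, HC higher).
#' @param background_noise_sd Marginal SD of the simulated signal.
#' @param hetero_sd SD of the per-subject random perturbation added to each
#'   edge's population correlation, so edge weights vary across subjects
#'   within group (a two-sample test needs within-group variance). The
#'   default 0.15 matches the between-subject spread of edge-wise
#'   resting-state correlations typically reported for test-retest and
#'   cohort data (SD of r around 0.1-0.2).
#' @param base_within,base_between Baseline population correlation within /
#'   between merged regions (the shared block structure).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_sd = 34, n_hc = 40, n_nodes = 246,
                        n_timepoints = 180,
                        planted_regions = character(), effect_size = 0,
                        background_noise_sd = 1, hetero_sd = 0.15,
                        base_within = 0.3, base_between = 0.1,
                        seed = 1L) {
  stopifnot(n_sd >= 2, n_hc >= 2, n_nodes >= 2, n_timepoints >= 10,
            abs(effect_size) < 1, background_noise_sd > 0, hetero_sd >= 0)
  structure(
    list(n_sd = as.integer(n_sd), n_hc = as.integer(n_hc),
         n_nodes = as.integer(n_nodes),
         n_timepoints = as.integer(n_timepoints),
         planted_regions = planted_regions, effect_size = effect_size,
         background_noise_sd = background_noise_sd, hetero_sd = hetero_sd,
         base_within = base_within, base_between = base_between,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# clip negative eigenvalues to a small positive floor and renormalize the
# diagonal to 1, so the matrix is a valid correlation matrix
repair_psd <- function(mat, floor = 1e-8) {
  ev <- eigen(mat, symmetric = TRUE)
  if (min(ev$values) >= floor) return(mat)
  vals <- pmax(ev$values, floor)
  out <- ev$vectors %*% (vals * t(ev$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

# group-level population correlation matrix with planted edge shifts
build_population_cor <- function(spec, parc, group) {
  n <- spec$n_nodes
  base <- matrix(spec$base_between, n, n)
  for (reg in unique(parc$merged_region)) {
    idx <- region_nodes(parc, reg)
    base[idx, idx] <- spec$base_within
  }
  if (length(spec$planted_regions) > 0 && spec$effect_size != 0) {
    nodes <- region_nodes(parc, spec$planted_regions)
    shift <- spec$effect_size / 2 * if (group == "SD") -1 else 1
    base[nodes, ] <- base[nodes, ] + shift
    base[, nodes] <- t(base[nodes, , drop = FALSE])
  }
  base <- pmin(pmax(base, -0.99), 0.99)
  diag(base) <- 1
  target <- base
  base <- repair_psd(base)
  dev <- abs(base - target)
  diag(dev) <- 0
  if (max(dev) > 0.05) {
    bad <- which(dev == max(dev), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "planted correlation shift is infeasible: edge (%d, %d) deviates by %.3f after nearest-PSD repair",
      bad[1], bad[2], max(dev)), call. = FALSE)
  }
  base
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject ROI time series from a multivariate normal whose
#' population correlation matrix is a shared block-structured base; edges
#' incident to `planted_regions` are shifted by half the effect size in
#' each direction (SD down, HC up). Each subject receives a small random
#' perturbation of every edge correlation (`hetero_sd`) before a
#' nearest-positive-semidefinite repair, so that edge weights vary across
#' subjects within a group. Demographics (age, sex, education, BDI-II) are
#' sampled group-matched in expectation, with SD subjects constrained to
#' BDI-II > 13.
#'
#' @param spec A [cohort_spec()].
#' @param parcellation A parcellation table; defaults to a
#'   [synthetic_parcellation()] sized to the spec.
#' @return An `sd_cohort` list with elements `subjects` (tibble:
#'   `subject_id`, `group`, `age`, `sex`, `education`, `bdi`), `series`
#'   (named list of T x N matrices, columns labelled by subregion),
#'   `parcellation`, and `spec`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_sd = 3, n_hc = 3, n_nodes = 12,
#'                                    n_timepoints = 40, seed = 1),
#'                        synthetic_parcellation(12, 3))
#' dim(coh$series[[1]])
#' @export
generate_cohort <- function(spec, parcellation = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(parcellation)) {
    parcellation <- synthetic_parcellation(
      spec$n_nodes, n_regions = max(1L, min(24L, spec$n_nodes %/% 4L)))
  }
  validate_parcellation(parcellation)
  if (nrow(parcellation) != spec$n_nodes) {
    stop("parcellation has ", nrow(parcellation), " subregions but spec asks ",
         spec$n_nodes, call. = FALSE)
  }
  set.seed(spec$seed)
  n <- spec$n_sd + spec$n_hc
  groups <- c(rep("SD", spec$n_sd), rep("HC", spec$n_hc))
  ids <- sprintf("sub-%03d", seq_len(n))

  subjects <- tibble::tibble(
    subject_id = ids,
    group = groups,
    age = pmin(pmax(round(stats::rnorm(n, 19.8, 1.3)), 19), 25),
    sex = ifelse(stats::runif(n) < 0.43, "M", "F"),
    education = round(stats::rnorm(n, 13.1, 0.6), 1),
    bdi = ifelse(groups == "SD",
                 pmax(14, round(stats::rnorm(n, 22.6, 6.9))),
                 pmin(13, pmax(0, round(stats::rnorm(n, 6, 4)))))
  )

  pop <- list(SD = build_population_cor(spec, parcellation, "SD"),
              HC = build_population_cor(spec, parcellation, "HC"))
  labels <- parcellation$subregion_label
  series <- purrr::map(seq_len(n), function(s) {
    cm <- pop[[groups[s]]]
    if (spec$hetero_sd > 0) {
      eps <- matrix(stats::rnorm(spec$n_nodes^2, 0, spec$hetero_sd),
                    spec$n_nodes)
      eps <- (eps + t(eps)) / 2
      diag(eps) <- 0
      cm <- pmin(pmax(cm + eps, -0.99), 0.99)
      diag(cm) <- 1
      cm <- repair_psd(cm)
    }
    x <- MASS::mvrnorm(spec$n_timepoints, mu = rep(0, spec$n_nodes),
                       Sigma = cm * spec$background_noise_sd^2)
    colnames(x) <- labels
    x
  })
  names(series) <- ids
  structure(list(subjects = subjects, series = series,
                 parcellation = parcellation, spec = spec),
            class = "sd_cohort")
}

#' @export
print.sd_cohort <- function(x, ...) {
  cat(sprintf(
    "<sd_cohort> %d subjects (%d SD, %d HC), %d subregions, %d timepoints\n",
    nrow(x$subjects), sum(x$subjects$group == "SD"),
    sum(x$subjects$group == "HC"), x$spec$n_nodes, x$spec$n_timepoints))
  invisible(x)
}

#' Compare demographics between groups
#'
#' Two-sample pooled t-tests for age and education and an (uncorrected)
#' chi-square test for sex, SD vs HC, computed from the subject records.
#'
#' @param subjects A subject tibble with columns `group` (SD/HC), `age`,
#'   `sex`, `education`.
#' @return A tibble with one row per variable: `variable`, `test`,
#'   `mean_sd`, `mean_hc` (group means; for sex, the proportion of males),
#'   `statistic`, `p_value`.
#' @export
compare_demographics <- function(subjects) {
  stopifnot(all(c("group", "age", "sex", "education") %in% names(subjects)))
  if (length(unique(subjects$group)) < 2) {
    stop("both groups must be present to compare demographics",
         call. = FALSE)
  }
  sd_rows <- subjects[subjects$group == "SD", ]
  hc_rows <- subjects[subjects$group == "HC", ]
  num_test <- function(v) {
    x <- sd_rows[[v]]; y <- hc_rows[[v]]
    if (stats::sd(c(x, y)) == 0) {
      return(tibble::tibble(variable = v, test = "pooled t",
                            mean_sd = mean(x), mean_hc = mean(y),
                            statistic = 0, p_value = 1))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    tibble::tibble(variable = v, test = "pooled t",
                   mean_sd = mean(x), mean_hc = mean(y),
                   statistic = unname(tt$statistic),
                   p_value = tt$p.value)
  }
  tab <- table(factor(subjects$group, c("SD", "HC")),
               factor(subjects$sex, c("M", "F")))
  sex_row <- if (any(colSums(tab) == 0)) {
    tibble::tibble(variable = "sex", test = "chi-square",
                   mean_sd = mean(sd_rows$sex == "M"),
                   mean_hc = mean(hc_rows$sex == "M"),
                   statistic = 0, p_value = 1)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble::tibble(variable = "sex", test = "chi-square",
                   mean_sd = mean(sd_rows$sex == "M"),
                   mean_hc = mean(hc_rows$sex == "M"),
                   statistic = unname(ct$statistic), p_value = ct$p.value)
  }
  dplyr::bind_rows(num_test("age"), num_test("education"), sex_row)
}
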