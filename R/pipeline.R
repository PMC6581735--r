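#' Pipeline configuration
#'
#' All knobs of the end-to-end analysis in one validated list. Either
#' point `manifest`, `timeseries_dir` and `parcellation` at files written
#' in the package's formats, or leave them `NULL` and pass a generated
#' cohort directly to [run_pipeline()].
#'
#' @param manifest,timeseries_dir,parcellation Input paths (optional when
#'   a cohort object is supplied).
#' @param out_dir Output directory for all artifacts.
#' @param alpha_mask Edge-significance level for masks.
#' @param mask_criterion `"p"` (uncorrected) or `"q"` (BH-adjusted).
#' @param normalization `"subject"` or `"cohort"` network scaling.
#' @param scope Feature scope: `"family"` (default) keeps each family's
#'   own default — connections incident to the region for anatomical
#'   models, connections within the node set for window and random
#'   models; `"incident"` or `"within"` force one scope everywhere.
#' @param window_size Sliding-window width in subregions.
#' @param n_random_models,random_set_size Random-selection family size.
#' @param n_window_models Cap on the number of window models evaluated
#'   (`Inf` for all); windows are expensive and the family is large.
#' @param svm An [svm_config()].
#' @param degree_alpha Significance level for the node-degree comparison.
#' @param focal_region Region profiled in depth (partner and subregion
#'   profiles, degree comparison); default the region of the best
#'   anatomical model.
#' @param seed Integer master seed for the randomized stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(manifest = NULL, timeseries_dir = NULL,
                            parcellation = NULL, out_dir = tempfile("sdc_"),
                            alpha_mask = 0.05,
                            mask_criterion = c("p", "q"),
                            normalization = c("subject", "cohort"),
                            scope = c("family", "incident", "within"),
                            window_size = 16, n_random_models = 100,
                            random_set_size = 16,
                            n_window_models = Inf,
                            svm = svm_config(), degree_alpha = 0.01,
                            focal_region = NULL, seed = 1L) {
  cfg <- list(manifest = manifest, timeseries_dir = timeseries_dir,
              parcellation = parcellation, out_dir = out_dir,
              alpha_mask = alpha_mask,
              mask_criterion = match.arg(mask_criterion),
              normalization = match.arg(normalization),
              scope = match.arg(scope),
              window_size = window_size,
              n_random_models = n_random_models,
              random_set_size = random_set_size,
              n_window_models = n_window_models,
              svm = svm, degree_alpha = degree_alpha,
              focal_region = focal_region, seed = as.integer(seed))
  for (p in c("manifest", "timeseries_dir", "parcellation")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("config path does not exist: ", p, " = ", cfg[[p]],
           call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments; `svm` may be a nested mapping of [svm_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$svm)) raw$svm <- do.call(svm_config, raw$svm)
  do.call(pipeline_config, raw)
}

stage_msg <- function(t0, ...) {
  message(sprintf("[%6.1fs] ", as.numeric(Sys.time()) - t0), ...)
}

#' Run the full analysis pipeline
#'
#' Load (or accept) the cohort, build the weighted networks, construct the
#' leakage-avoiding mask family, evaluate the anatomical, sliding-window
#' and random-selection SVM families under LOOCV, run the confounder
#' checks, and profile the focal region (partner regions, subregions,
#' node degree). All artifacts are written under `config$out_dir` with
#' the config (seed included) echoed alongside; deterministic stages are
#' bit-identical on rerun with the same config.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional `sd_cohort` generated in-session (used instead
#'   of the config's input paths).
#' @return Invisibly, a list with the loaded inputs and every result
#'   table: `networks`, `edge_stats`, `masks`, `model_summary`,
#'   `confounders`, `region_profile`, `partner_profile`,
#'   `subregion_profile`, `degree_comparison`, `demographics`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- as.numeric(Sys.time())
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (is.null(cohort)) {
    if (is.null(config$manifest) || is.null(config$timeseries_dir) ||
        is.null(config$parcellation)) {
      stop("either supply a cohort or set manifest, timeseries_dir and ",
           "parcellation paths in the config", call. = FALSE)
    }
    stage_msg(t0, "loading cohort from ", config$manifest)
    subjects <- read_cohort_manifest(config$manifest)
    series <- read_timeseries_dir(config$timeseries_dir, subjects)
    parc <- read_parcellation(config$parcellation)
  } else {
    subjects <- cohort$subjects
    series <- cohort$series
    parc <- cohort$parcellation
  }
  n_nodes <- nrow(parc)
  if (config$window_size > n_nodes) {
    stop("window_size (", config$window_size, ") exceeds the number of ",
         "subregions (", n_nodes, ")", call. = FALSE)
  }
  groups <- subjects$group

  stage_msg(t0, "building ", length(series), " networks (",
            config$normalization, " normalization)")
  networks <- build_networks(series, normalization = config$normalization)

  stage_msg(t0, "edge-wise tests and mask family (alpha = ",
            config$alpha_mask, " on ", config$mask_criterion, ")")
  stats <- edgewise_ttest(networks, groups)
  masks <- build_mask_family(networks, groups, alpha = config$alpha_mask,
                             criterion = config$mask_criterion)

  sc <- function(default) {
    if (config$scope == "family") default else config$scope
  }
  anat <- anatomical_feature_specs(parc, scope = sc("incident"))
  wins <- window_feature_specs(n_nodes, config$window_size,
                               scope = sc("within"))
  if (is.finite(config$n_window_models) &&
      nrow(wins) > config$n_window_models) {
    set.seed(config$seed)
    wins <- wins[sort(sample.int(nrow(wins), config$n_window_models)), ]
  }
  rand <- random_feature_specs(n_nodes, config$random_set_size,
                               config$n_random_models,
                               seed = config$seed, scope = sc("within"))

  stage_msg(t0, "evaluating ", nrow(anat), " anatomical + ", nrow(wins),
            " window + ", nrow(rand), " random models under LOOCV")
  model_summary <- dplyr::bind_rows(
    evaluate_models(networks, groups, anat, masks, config$svm),
    evaluate_models(networks, groups, wins, masks, config$svm),
    evaluate_models(networks, groups, rand, masks, config$svm))

  profile <- region_connection_profile(stats, masks$full, parc)
  confounders <- accuracy_confounder_check(
    model_summary[model_summary$family == "anatomical", ], profile)

  anat_rows <- model_summary[model_summary$family == "anatomical", ]
  focal <- config$focal_region
  if (is.null(focal)) focal <- anat_rows$model[which.max(anat_rows$accuracy)]
  stage_msg(t0, "profiling focal region: ", focal)
  partners <- focal_partner_profile(stats, masks$full, parc, focal)
  subprof <- subregion_profile(stats, masks$full, parc, focal)
  degs <- cohort_degrees(networks)
  degcmp <- compare_subregion_degrees(
    degs, stats::setNames(groups, subjects$subject_id), parc, focal,
    alpha = config$degree_alpha)
  demog <- compare_demographics(subjects)

  stage_msg(t0, "writing artifacts to ", out)
  readr::write_csv(subjects, file.path(out, "manifest.csv"))
  write_edge_stats(stats, file.path(out, "edge_stats.csv"))
  write_mask_family(masks, file.path(out, "masks"))
  readr::write_csv(model_summary, file.path(out, "model_summary.csv"))
  readr::write_csv(profile, file.path(out, "region_profile.csv"))
  readr::write_csv(confounders, file.path(out, "confounder_checks.csv"))
  readr::write_csv(partners, file.path(out, "focal_partner_profile.csv"))
  readr::write_csv(subprof, file.path(out, "focal_subregion_profile.csv"))
  readr::write_csv(degcmp, file.path(out, "degree_comparison.csv"))
  readr::write_csv(demog, file.path(out, "demographics.csv"))
  echo <- config
  echo$svm <- unclass(echo$svm)
  echo <- unclass(echo)
  echo$config_hash <- rlang::hash(echo)
  echo$run_time <- format(Sys.time())
  yaml::write_yaml(echo, file.path(out, "config.yaml"))

  stage_msg(t0, "done")
  invisible(list(subjects = subjects, parcellation = parc,
                 networks = networks, edge_stats = stats, masks = masks,
                 model_summary = model_summary, confounders = confounders,
                 region_profile = profile, partner_profile = partners,
                 subregion_profile = subprof, degree_comparison = degcmp,
                 demographics = demog, focal_region = focal))
}
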