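# a small cohort with enough masked edges for profiling tests
profiled_fixture <- function() {
  parc <- toy_parc(10, 2)
  coh <- generate_cohort(
    cohort_spec(n_sd = 8, n_hc = 8, n_nodes = 10, n_timepoints = 50,
                planted_regions = "Thalamus", effect_size = 0.5, seed = 13),
    parc)
  nets <- build_networks(coh)
  g <- coh$subjects$group
  stats <- edgewise_ttest(nets, g)
  masks <- build_mask_family(nets, g, alpha = 0.2)
  list(parc = parc, nets = nets, groups = g, stats = stats, masks = masks)
}

test_that("region profiles match brute-force pair enumeration", {
  fx <- profiled_fixture()
  prof <- region_connection_profile(fx$stats, fx$masks$full, fx$parc)
  me <- mask_edges(fx$masks$full)
  reg_of <- fx$parc$merged_region
  for (k in seq_len(nrow(prof))) {
    nodes <- region_nodes_for_test(fx$parc, prof$region[k])
    sel <- me$i %in% nodes | me$j %in% nodes
    expect_equal(prof$n_connections[k], sum(sel))
    if (any(sel)) {
      masked_stats <- fx$stats[fx$masks$full[cbind(fx$stats$i, fx$stats$j)], ]
      inc <- masked_stats$i %in% nodes | masked_stats$j %in% nodes
      expect_equal(prof$mean_p[k], mean(masked_stats$p_value[inc]),
                   tolerance = 1e-12)
    }
  }
  # conservation: summing counts over regions counts inter-region edges
  # twice and intra-region edges once
  n_inter <- sum(reg_of[me$i] != reg_of[me$j])
  n_intra <- sum(reg_of[me$i] == reg_of[me$j])
  expect_equal(sum(prof$n_connections), 2 * n_inter + n_intra)
})

test_that("hemispheric counts sum to the merged-region count", {
  fx <- profiled_fixture()
  merged <- region_connection_profile(fx$stats, fx$masks$full, fx$parc)
  hemi <- region_connection_profile(fx$stats, fx$masks$full, fx$parc,
                                    level = "hemispheric")
  for (k in seq_len(nrow(merged))) {
    parts <- hemi[startsWith(hemi$region,
                             paste0(merged$region[k], "_")), ]
    expect_equal(sum(parts$n_connections), merged$n_connections[k])
  }
})

test_that("partner attribution is exhaustive and self-edges stay focal", {
  fx <- profiled_fixture()
  focal <- "Thalamus"
  partners <- focal_partner_profile(fx$stats, fx$masks$full, fx$parc, focal)
  merged <- region_connection_profile(fx$stats, fx$masks$full, fx$parc)
  expect_equal(sum(partners$n_connections),
               merged$n_connections[merged$region == focal])
  # brute force the intra-focal count
  nodes <- region_nodes_for_test(fx$parc, focal)
  me <- mask_edges(fx$masks$full)
  intra <- sum(me$i %in% nodes & me$j %in% nodes)
  if (intra > 0) {
    expect_equal(
      partners$n_connections[partners$partner_region == focal], intra)
  }
  expect_error(focal_partner_profile(fx$stats, fx$masks$full, fx$parc,
                                     "Nowhere"), "unknown region")
})

test_that("subregion profiles count incident masked edges per subregion", {
  fx <- profiled_fixture()
  sp <- subregion_profile(fx$stats, fx$masks$full, fx$parc, "Thalamus")
  me <- mask_edges(fx$masks$full)
  for (k in seq_len(nrow(sp))) {
    nd <- fx$parc$subregion_index[fx$parc$subregion_label == sp$subregion[k]]
    expect_equal(sp$n_connections[k], sum(me$i == nd | me$j == nd))
  }
  expect_equal(sum(sp$contains_lhb), 1)

  # empty mask: zero counts, missing mean p
  empty <- fx$masks$full & FALSE
  sp0 <- subregion_profile(fx$stats, empty, fx$parc, "Thalamus")
  expect_true(all(sp0$n_connections == 0))
  expect_true(all(is.na(sp0$mean_p)))
})

test_that("confounder correlations match closed forms", {
  ms <- tibble::tibble(model = c("A", "B", "C"),
                       accuracy = c(0.2, 0.4, 0.6))
  prof <- tibble::tibble(region = c("A", "B", "C"),
                         n_connections = c(10, 20, 30),
                         mean_p = c(0.03, 0.02, 0.01))
  out <- accuracy_confounder_check(ms, prof)
  expect_equal(out$r[out$term == "n_connections"], 1, tolerance = 1e-12)
  expect_lt(out$p_value[out$term == "n_connections"], 1e-6)
  expect_equal(out$r[out$term == "mean_p"], -1, tolerance = 1e-12)

  flat <- ms
  flat$accuracy <- rep(0.5, 3)
  expect_warning(expect_warning(
    out2 <- accuracy_confounder_check(flat, prof), "constant"), "constant")
  expect_true(all(is.na(out2$r)))
  expect_error(accuracy_confounder_check(ms[1:2, ], prof[1:2, ]),
               "at least 3")
})

test_that("connection subsampling is seeded and degrades with target 1", {
  fx <- profiled_fixture()
  spec <- anatomical_feature_specs(fx$parc)[2, ]  # Thalamus (planted)
  cfg <- tiny_svm_config()
  full_fit <- loocv_evaluate(fx$nets, fx$groups, spec, fx$masks, cfg)

  n_avail <- nrow(mask_edges(fx$masks$full))
  nodes <- region_nodes_for_test(fx$parc, "Thalamus")
  me <- mask_edges(fx$masks$full)
  n_spec <- sum(me$i %in% nodes | me$j %in% nodes)

  # identity case: keeping every connection reproduces the full model
  same <- subsample_connections_experiment(
    fx$nets, fx$groups, spec, fx$masks, cfg,
    target_n = n_spec, n_repeats = 1, seed = 5)
  expect_equal(same$mean_accuracy, full_fit$metrics$accuracy)

  # bit-identical rerun under a fixed seed
  a <- subsample_connections_experiment(
    fx$nets, fx$groups, spec, fx$masks, cfg,
    target_n = max(1, n_spec %/% 2), n_repeats = 2, seed = 9)
  b <- subsample_connections_experiment(
    fx$nets, fx$groups, spec, fx$masks, cfg,
    target_n = max(1, n_spec %/% 2), n_repeats = 2, seed = 9)
  expect_identical(attr(a, "per_repeat"), attr(b, "per_repeat"))

  # a single connection rarely matches the full model on a planted cohort
  one <- subsample_connections_experiment(
    fx$nets, fx$groups, spec, fx$masks, cfg,
    target_n = 1, n_repeats = 10, seed = 2)
  expect_gte(mean(attr(one, "per_repeat") < full_fit$metrics$accuracy), 0.9)
})

test_that("degree comparison flags planted SD deficits with pooled t", {
  # hand-built degrees: SD (1,1,1) vs HC (2,2.1,1.9) on one subregion
  parc <- toy_parc(4, 2)
  lbl <- parc$subregion_label
  degrees <- tibble::tibble(
    subject_id = rep(sprintf("s%d", 1:6), each = 4),
    node = rep(lbl, 6),
    degree = 5)
  focal_lbl <- parc$subregion_label[parc$merged_region == "Thalamus"][1]
  degrees$degree[degrees$node == focal_lbl] <-
    c(1, 1, 1, 2, 2.1, 1.9)
  g <- stats::setNames(rep(c("SD", "HC"), each = 3), sprintf("s%d", 1:6))
  out <- suppressWarnings(
    compare_subregion_degrees(degrees, g, parc, "Thalamus", alpha = 0.01))
  row <- out[out$subregion == focal_lbl, ]
  sp2 <- (2 * 0 + 2 * stats::var(c(2, 2.1, 1.9))) / 4
  t_hand <- (1 - 2) / sqrt(sp2 * (2 / 3))
  expect_equal(row$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(row$p_value, 2 * stats::pt(-abs(t_hand), 4),
               tolerance = 1e-12)
  expect_equal(row$direction, "SD<HC")
  # untouched subregions are flat: not significant
  others <- out[out$subregion != focal_lbl, ]
  expect_true(all(others$direction == "ns"))

  # identical groups: everything ns
  g2 <- stats::setNames(rep(c("SD", "HC"), 3), sprintf("s%d", 1:6))
  degrees2 <- degrees
  degrees2$degree <- rep(stats::rnorm(4, 5), 6)
  out2 <- suppressWarnings(
    compare_subregion_degrees(degrees2, g2, parc, "Thalamus"))
  expect_true(all(out2$direction == "ns"))
})
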