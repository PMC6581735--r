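test_that("confusion-matrix metrics follow their defining formulas", {
  m <- confusion_metrics(c(tn = 37, fp = 3, fn = 3, tp = 31))
  expect_equal(m$sensitivity, 31 / 34)
  expect_equal(m$specificity, 37 / 40)
  expect_equal(m$accuracy, 68 / 74)

  m2 <- confusion_metrics(c(tn = 38, fp = 2, fn = 5, tp = 29))
  expect_equal(m2$specificity, 0.95)

  m3 <- confusion_metrics(c(tn = 10, fp = 0, fn = 0, tp = 7))
  expect_equal(unlist(m3), c(accuracy = 1, sensitivity = 1,
                             specificity = 1))
  expect_error(confusion_metrics(c(tn = 5, fp = 2, fn = 0, tp = 0)),
               "empty class")
})

test_that("AUC equals the pairwise-comparison oracle and pROC", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1), positive = 1)$auc, 1)
  expect_equal(roc_auc(rep(0.3, 6), rep(c("SD", "HC"), 3))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1),
                       positive = 1)$auc, 0.75)
  expect_error(roc_auc(1:3, rep("SD", 3)), "both classes")

  set.seed(17)
  for (rep in 1:20) {
    n <- sample(4:30, 1)
    labels <- sample(rep(c("SD", "HC"), length.out = n))
    if (length(unique(labels)) < 2) next
    scores <- round(stats::rnorm(n), sample(0:2, 1))  # force some ties
    out <- roc_auc(scores, labels)
    expect_equal(out$auc, pairwise_auc(scores, labels), tolerance = 1e-12)
    expect_equal(out$auc,
                 as.numeric(suppressMessages(pROC::auc(
                   pROC::roc(labels, scores, levels = c("HC", "SD"),
                             direction = "<")))),
                 tolerance = 1e-12)
    # staircase from (0,0) to (1,1), monotone in both coordinates
    expect_equal(out$roc$fpr[1], 0)
    expect_equal(out$roc$tpr[1], 0)
    expect_equal(utils::tail(out$roc$fpr, 1), 1)
    expect_equal(utils::tail(out$roc$tpr, 1), 1)
    expect_true(all(diff(out$roc$fpr) >= 0))
    expect_true(all(diff(out$roc$tpr) >= 0))
    # trapezoid area under the swept curve equals the rank AUC
    trap <- sum(diff(out$roc$fpr) *
                  (utils::head(out$roc$tpr, -1) +
                     utils::tail(out$roc$tpr, -1)) / 2)
    expect_equal(trap, out$auc, tolerance = 1e-12)
  }
})

test_that("LOOCV separates a hand-built margin perfectly", {
  sep <- separated_networks(w_sd = c(0.95, 0.9, 0.85),
                            w_hc = c(0.15, 0.1, 0.05))
  masks <- build_mask_family(sep$networks, sep$groups, alpha = 0.05)
  spec <- tibble::tibble(name = "toy", family = "anatomical",
                         scope = "incident", nodes = list(1:2))
  fit <- loocv_evaluate(sep$networks, sep$groups, spec, masks,
                        tiny_svm_config())
  expect_equal(fit$confusion, c(tn = 3L, fp = 0L, fn = 0L, tp = 3L))
  expect_equal(fit$metrics$accuracy, 1)
  expect_equal(fit$auc, 1)
  # reported metrics always equal the confusion-matrix formulas
  expect_equal(fit$metrics, confusion_metrics(fit$confusion))
  # deterministic rerun
  fit2 <- loocv_evaluate(sep$networks, sep$groups, spec, masks,
                         tiny_svm_config())
  expect_equal(generics::glance(fit), generics::glance(fit2))
  expect_equal(generics::tidy(fit), generics::tidy(fit2))
})

test_that("empty-feature folds fall back to the training majority class", {
  sep <- separated_networks(w_sd = c(0.9, 0.85, 0.8),
                            w_hc = c(0.2, 0.15, 0.1, 0.25))
  masks <- build_mask_family(sep$networks, sep$groups, alpha = 0.05)
  masks$full[] <- FALSE
  masks$folds <- lapply(masks$folds, function(m) m & FALSE)
  spec <- tibble::tibble(name = "toy", family = "anatomical",
                         scope = "incident", nodes = list(1:2))
  fit <- loocv_evaluate(sep$networks, sep$groups, spec, masks,
                        tiny_svm_config())
  td <- generics::tidy(fit)
  expect_true(all(td$empty_fold))
  expect_true(all(td$n_features == 0))
  # majority of the training set: HC for held-out SD subjects (3 vs 3),
  # and HC for held-out HC subjects (3 SD vs 3 HC ties resolved by order)
  expect_true(all(td$decision_value == 0))
})

test_that("the held-out subject cannot influence its fold's mask or tuning", {
  parc <- toy_parc(10, 2)
  coh <- generate_cohort(
    cohort_spec(n_sd = 6, n_hc = 6, n_nodes = 10, n_timepoints = 50,
                planted_regions = "Thalamus", effect_size = 0.5, seed = 11),
    parc)
  nets <- build_networks(coh)
  g <- coh$subjects$group
  masks <- build_mask_family(nets, g, alpha = 0.1)
  spec <- anatomical_feature_specs(parc)[2, ]
  cfg <- tiny_svm_config()
  fit <- loocv_evaluate(nets, g, spec, masks, cfg)

  s <- 4
  corrupted <- nets
  corrupted[[s]] <- rand_adj(10, seed = 999)
  masks_c <- build_mask_family(corrupted, g, alpha = 0.1)
  expect_identical(masks_c$folds[[s]], masks$folds[[s]])

  fit_c <- loocv_evaluate(corrupted, g, spec, masks_c, cfg)
  td <- generics::tidy(fit)[s, ]
  td_c <- generics::tidy(fit_c)[s, ]
  expect_equal(td_c$C, td$C)
  expect_equal(td_c$gamma, td$gamma)
  expect_equal(td_c$n_features, td$n_features)
})

test_that("degenerate cohorts are refused before any fold runs", {
  sep <- separated_networks(w_sd = c(0.9), w_hc = c(0.2, 0.1, 0.3))
  spec <- tibble::tibble(name = "toy", family = "anatomical",
                         scope = "incident", nodes = list(1:2))
  masks <- list(full = complete_mask(3),
                folds = rep(list(complete_mask(3)), 4),
                alpha = 1, criterion = "p")
  names(masks$folds) <- names(sep$networks)
  expect_error(
    loocv_evaluate(sep$networks, sep$groups, spec, masks,
                   tiny_svm_config()),
    "at least 2 subjects per group")
})
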