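#' RBF-SVM configuration
#'
#' Grids for the penalty C and kernel width gamma of the radial-basis
#' kernel K(x, x') = exp(-gamma * ||x - x'||^2), searched exhaustively by
#' inner cross-validation. Defaults follow the libsvm grid-search
#' recommendation: C = 2^-5, 2^-3, ..., 2^15 and
#' gamma = 2^-15, 2^-13, ..., 2^3.
#'
#' @param C_grid,gamma_grid Positive numeric grids.
#' @param inner_folds Folds for the inner (grid-search) cross-validation,
#'   stratified by class.
#' @param seed Integer seed controlling inner-fold assignment.
#' @param scale_features Standardize each feature by training-fold mean/SD
#'   before fitting (edge weights are already in [0, 1], so default off).
#' @param grid_mode `"nested"` re-runs the grid search inside every
#'   leave-one-out fold on the training subjects only (default);
#'   `"global"` tunes once on the full cohort and reuses the pair.
#' @return An `svm_config` list.
#' @export
svm_config <- function(C_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2),
                       inner_folds = 5, seed = 1L,
                       scale_features = FALSE,
                       grid_mode = c("nested", "global")) {
  grid_mode <- match.arg(grid_mode)
  stopifnot(length(C_grid) > 0, all(C_grid > 0),
            length(gamma_grid) > 0, all(gamma_grid > 0),
            inner_folds >= 2)
  structure(list(C_grid = sort(C_grid), gamma_grid = sort(gamma_grid),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed),
                 scale_features = isTRUE(scale_features),
                 grid_mode = grid_mode),
            class = "svm_config")
}

# stratified k-fold assignment, deterministic given seed
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_svm <- function(x, y, C, gamma) {
  e1071::svm(x, factor(y, levels = c("HC", "SD")), kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE)
}

# predict classes and SD-oriented decision values
predict_svm <- function(model, x) {
  pr <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  flip <- !startsWith(colnames(dv)[1], "SD")
  list(class = as.character(pr),
       dval = as.numeric(dv) * if (flip) -1 else 1)
}

majority_class <- function(y) names(which.max(table(y)))

# exhaustive (C, gamma) grid search by stratified inner CV accuracy;
# ties broken toward the smallest C, then the smallest gamma
grid_search_cv <- function(x, y, cfg, seed) {
  k <- min(cfg$inner_folds, min(table(y)) * 2L, length(y) - 1L)
  k <- max(k, 2L)
  fold <- stratified_folds(y, k, seed)
  best <- list(acc = -Inf, C = NA_real_, gamma = NA_real_)
  for (C in cfg$C_grid) {
    for (gamma in cfg$gamma_grid) {
      correct <- 0L
      for (f in seq_len(k)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2) {
          pred <- rep(majority_class(y[tr]), sum(!tr))
        } else {
          m <- fit_svm(x[tr, , drop = FALSE], y[tr], C, gamma)
          pred <- predict_svm(m, x[!tr, , drop = FALSE])$class
        }
        correct <- correct + sum(pred == y[!tr])
      }
      acc <- correct / length(y)
      if (acc > best$acc + 1e-12) best <- list(acc = acc, C = C, gamma = gamma)
    }
  }
  best
}

#' Evaluate one feature set under leave-one-out cross-validation
#'
#' For every subject s: features are materialized from that fold's mask
#' (computed without s, never the full-cohort mask); (C, gamma) is chosen
#' by stratified inner cross-validation on the training subjects only; the
#' tuned model is refit on all training subjects and predicts s. Decision
#' values are pooled over folds into a single ROC curve; hard predictions
#' accumulate the confusion matrix. Folds whose mask leaves no feature
#' predict the training-set majority class with decision value 0.
#'
#' @param networks Named list of adjacency matrices.
#' @param groups "SD"/"HC" per subject, in `networks` order.
#' @param spec A one-row feature-spec tibble (see
#'   [anatomical_feature_specs()] and friends).
#' @param masks A [build_mask_family()] object aligned with the subjects.
#' @param cfg An [svm_config()].
#' @return An `sdc_model` object; see [glance.sdc_model()] /
#'   [tidy.sdc_model()] for tabular views.
#' @export
loocv_evaluate <- function(networks, groups, spec, masks, cfg = svm_config()) {
  groups <- as_group_factor(groups)
  n <- length(networks)
  stopifnot(n >= 3, length(groups) == n, length(masks$folds) == n)
  spec1 <- as_one_spec(spec)
  ids <- names(networks)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  global_pair <- NULL
  if (cfg$grid_mode == "global") {
    Xg <- materialize_features(spec1, masks$full, networks)
    global_pair <- if (ncol(Xg) > 0) {
      grid_search_cv(Xg, groups, cfg, seed = cfg$seed)
    }
  }

  pred <- character(n); dval <- numeric(n)
  chosen <- vector("list", n)
  for (s in seq_len(n)) {
    ytr <- groups[-s]
    if (length(unique(ytr)) < 2) {
      stop("training subjects in fold ", s, " are single-class",
           call. = FALSE)
    }
    Xall <- suppressMessages(
      materialize_features(spec1, masks$folds[[s]], networks))
    if (ncol(Xall) == 0) {
      pred[s] <- majority_class(ytr)
      dval[s] <- 0
      chosen[[s]] <- tibble::tibble(subject_id = ids[s], C = NA_real_,
                                    gamma = NA_real_, n_features = 0L,
                                    empty_fold = TRUE)
      next
    }
    Xtr <- Xall[-s, , drop = FALSE]
    Xte <- Xall[s, , drop = FALSE]
    if (cfg$scale_features) {
      mu <- colMeans(Xtr)
      sg <- apply(Xtr, 2, stats::sd)
      sg[sg == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
    }
    pair <- if (!is.null(global_pair)) global_pair else {
      grid_search_cv(Xtr, ytr, cfg, seed = cfg$seed + s)
    }
    m <- fit_svm(Xtr, ytr, pair$C, pair$gamma)
    pr <- predict_svm(m, Xte)
    pred[s] <- pr$class
    dval[s] <- pr$dval
    chosen[[s]] <- tibble::tibble(subject_id = ids[s], C = pair$C,
                                  gamma = pair$gamma,
                                  n_features = ncol(Xall),
                                  empty_fold = FALSE)
  }
  cm <- c(tn = sum(pred == "HC" & groups == "HC"),
          fp = sum(pred == "SD" & groups == "HC"),
          fn = sum(pred == "HC" & groups == "SD"),
          tp = sum(pred == "SD" & groups == "SD"))
  roc <- roc_auc(dval, groups, positive = "SD")
  structure(list(
    model_name = spec1$name,
    family = if (is.data.frame(spec)) spec$family else NA_character_,
    confusion = cm,
    metrics = confusion_metrics(cm),
    roc = roc$roc, auc = roc$auc,
    folds = dplyr::bind_rows(chosen),
    predictions = tibble::tibble(subject_id = ids, group = groups,
                                 predicted = pred, decision_value = dval)
  ), class = "sdc_model")
}

#' @export
print.sdc_model <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<sdc_model> %s: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
    x$model_name, m$accuracy, m$sensitivity, m$specificity, x$auc))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' SD is the positive class: sensitivity = tp / (tp + fn) among SD,
#' specificity = tn / (tn + fp) among HC,
#' accuracy = (tp + tn) / (tp + tn + fp + fn).
#'
#' @param cm Named numeric vector or one-row data frame with `tn`, `fp`,
#'   `fn`, `tp`.
#' @return A one-row tibble: `accuracy`, `sensitivity`, `specificity`.
#' @examples
#' confusion_metrics(c(tn = 37, fp = 3, fn = 3, tp = 31))
#' @export
confusion_metrics <- function(cm) {
  cm <- as.list(cm)
  stopifnot(all(c("tn", "fp", "fn", "tp") %in% names(cm)))
  tn <- cm$tn; fp <- cm$fp; fn <- cm$fn; tp <- cm$tp
  stopifnot(tn >= 0, fp >= 0, fn >= 0, tp >= 0)
  if (tp + fn == 0 || tn + fp == 0) {
    stop("confusion matrix has an empty class", call. = FALSE)
  }
  tibble::tibble(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp)
  )
}

#' ROC curve and AUC from decision values
#'
#' Standard threshold sweep over the scores (a case is called positive
#' when its score is >= the threshold), giving a staircase from (0, 0) to
#' (1, 1). The AUC is the rank-based Mann-Whitney statistic normalized by
#' n_pos * n_neg, with tied scores receiving half credit — identical to
#' the trapezoidal area under the swept curve.
#'
#' @param scores Numeric decision values, larger meaning more
#'   positive-like.
#' @param labels Class labels.
#' @param positive The positive-class label (default "SD").
#' @return List with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), positive = 1)$auc
#' @export
roc_auc <- function(scores, labels, positive = "SD") {
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- purrr::map_dfr(thr, function(th) {
    tibble::tibble(threshold = th,
                   fpr = sum(!pos & scores >= th) / n_neg,
                   tpr = sum(pos & scores >= th) / n_pos)
  })
  roc <- dplyr::bind_rows(
    tibble::tibble(threshold = Inf, fpr = 0, tpr = 0), pts)
  if (utils::tail(roc$fpr, 1) < 1 || utils::tail(roc$tpr, 1) < 1) {
    roc <- dplyr::bind_rows(roc,
      tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  list(roc = roc, auc = auc)
}

#' Evaluate a whole family of feature specs
#'
#' Runs [loocv_evaluate()] on every row of a feature-spec tibble and
#' binds the one-row summaries.
#'
#' @inheritParams loocv_evaluate
#' @param specs A feature-spec tibble (one model per row).
#' @param .progress Emit a message per model.
#' @return A tibble with one row per model (the [glance.sdc_model()]
#'   columns).
#' @export
evaluate_models <- function(networks, groups, specs, masks,
                            cfg = svm_config(), .progress = FALSE) {
  purrr::map_dfr(seq_len(nrow(specs)), function(k) {
    if (.progress) message("model ", specs$name[k])
    generics::glance(
      loocv_evaluate(networks, groups, specs[k, ], masks, cfg))
  })
}
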