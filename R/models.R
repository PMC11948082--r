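# Response-prediction models: gradient-boosted tree classifiers on selected
# radiomics features (single-timepoint sets) and fused radiomics + clinical
# models, with frozen preprocessing statistics so that applying a fitted
# bundle never refits anything.

#' Gradient-boosted learner configuration
#'
#' @param max_depth Tree depth.
#' @param eta Learning rate.
#' @param nrounds Number of trees.
#' @param subsample Row subsampling fraction.
#' @return List of class `hab_learner`.
#' @export
learner_config <- function(max_depth = 3, eta = 0.1, nrounds = 200, subsample = 0.8) {
  structure(
    list(
      max_depth = max_depth, eta = eta, nrounds = nrounds,
      subsample = subsample
    ),
    class = "hab_learner"
  )
}

fit_xgb <- function(x, y, learner, seed) {
  params <- list(
    objective = "binary:logistic", max_depth = learner$max_depth,
    eta = learner$eta, subsample = learner$subsample,
    nthread = 1, seed = seed %||% 0, verbosity = 0
  )
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = learner$nrounds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' AUC computed as the tie-corrected rank statistic: the probability that a
#' random positive outscores a random negative (ties counted half).
#'
#' @param scores Numeric predictions.
#' @param labels Binary outcome.
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

youden_threshold <- function(scores, y) {
  cand <- sort(unique(scores))
  cuts <- c(-Inf, (cand[-1] + cand[-length(cand)]) / 2, Inf)
  j <- vapply(cuts, function(t) {
    pred <- scores > t
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    sens + spec - 1
  }, numeric(1))
  cuts[which.max(j)]
}

new_model_bundle <- function(model_id, booster, feature_list, learner,
                             threshold, cv_auc, seed, clinical_levels = NULL) {
  structure(
    list(
      model_id = model_id, booster = booster, feature_list = feature_list,
      learner = learner, decision_threshold = threshold, cv_auc = cv_auc,
      seed = seed, clinical_levels = clinical_levels
    ),
    class = "hab_model"
  )
}

#' @export
print.hab_model <- function(x, ...) {
  cat(sprintf(
    "<hab_model %s: %d features, CV AUC %.3f, threshold %.3f>\n",
    x$model_id, length(x$feature_list),
    x$cv_auc %||% NA_real_, x$decision_threshold
  ))
  invisible(x)
}

model_matrix_from <- function(table, feature_list) {
  missing <- setdiff(feature_list, names(table))
  if (length(missing)) {
    stop(
      "features missing from table: ", paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  as.matrix(dplyr::select(table, dplyr::all_of(feature_list)))
}

#' Train a single-timepoint radiomics model
#'
#' Fits a gradient-boosted tree classifier on one selected feature set
#' (one timepoint, whole-tumor or habitat features), records the stratified
#' ten-fold cross-validated AUC, and freezes the decision threshold at
#' Youden's J on the training predictions.
#'
#' @param table Feature tibble (`patient_id` + selected features).
#' @param labels Binary outcome (factor or 0/1).
#' @param model_id Identifier, e.g. `"preSHR"`.
#' @param learner A [learner_config()].
#' @param n_folds CV folds for the recorded AUC (0 skips CV).
#' @param seed Integer seed.
#' @return A `hab_model` bundle.
#' @export
train_single_timepoint <- function(table, labels, model_id = "model",
                                   learner = learner_config(), n_folds = 10,
                                   seed = NULL) {
  if (length(unique(labels)) < 2) stop("labels contain a single class", call. = FALSE)
  y <- as_binary_labels(labels)
  if (min(table(y)) < 10) {
    warning("fewer than 10 patients in a class; CV estimates will be unstable", call. = FALSE)
  }
  feats <- feature_cols(table)
  x <- model_matrix_from(table, feats)
  with_local_seed(seed, {
    cv_auc <- NA_real_
    cv_pred <- NULL
    if (n_folds > 1) {
      foldid <- stratified_folds(y, n_folds)
      preds <- numeric(length(y))
      for (f in seq_len(n_folds)) {
        tr <- foldid != f
        if (length(unique(y[tr])) < 2) next
        fit_f <- fit_xgb(x[tr, , drop = FALSE], y[tr], learner, seed = (seed %||% 0) + f)
        preds[!tr] <- stats::predict(fit_f, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
      }
      cv_auc <- auc_mw(preds, y)
      cv_pred <- preds
    }
    booster <- fit_xgb(x, y, learner, seed = seed %||% 0)
    train_pred <- stats::predict(booster, xgboost::xgb.DMatrix(x))
    out <- new_model_bundle(
      model_id, booster, feats, learner,
      threshold = youden_threshold(train_pred, y),
      cv_auc = cv_auc, seed = seed
    )
    out$cv_pred <- cv_pred
    out
  })
}

#' One-hot encode the clinical covariates
#'
#' @param clinical Tibble with `patient_id`, `cT_stage`, `ER`, `HER2`.
#' @return Tibble of dummy indicators keyed by `patient_id`.
#' @export
clinical_dummies <- function(clinical) {
  required <- c("patient_id", "cT_stage", "ER", "HER2")
  missing_cols <- setdiff(required, names(clinical))
  if (length(missing_cols)) {
    stop("clinical table lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- clinical$patient_id[
    is.na(clinical$cT_stage) | is.na(clinical$ER) | is.na(clinical$HER2)
  ]
  if (length(bad)) {
    stop("missing clinical values for patient(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    patient_id = clinical$patient_id,
    clin_cT1 = as.numeric(clinical$cT_stage == "cT1"),
    clin_cT2 = as.numeric(clinical$cT_stage == "cT2"),
    clin_cT3 = as.numeric(clinical$cT_stage == "cT3"),
    clin_cT4 = as.numeric(clinical$cT_stage == "cT4"),
    clin_ER_neg = as.numeric(clinical$ER == "neg"),
    clin_HER2_pos = as.numeric(clinical$HER2 == "pos")
  )
}

#' Train a fused clinical + longitudinal radiomics model
#'
#' Concatenates the selected pre- and mid-treatment feature sets (habitat or
#' whole-tumor) with one-hot clinical covariates (cT stage, ER, HER2) into a
#' single boosted-tree learner.
#'
#' @param pre_table,mid_table Selected feature tibbles per timepoint.
#' @param clinical Clinical covariate tibble (see [clinical_dummies()]).
#' @param labels Binary outcome aligned with the tables.
#' @inheritParams train_single_timepoint
#' @return A `hab_model` bundle.
#' @export
train_fusion <- function(pre_table, mid_table, clinical, labels,
                         model_id = "ClinSHR", learner = learner_config(),
                         n_folds = 10, seed = NULL) {
  stopifnot(identical(pre_table$patient_id, mid_table$patient_id))
  cd <- clinical_dummies(clinical)
  joined <- dplyr::inner_join(pre_table, mid_table,
    by = "patient_id",
    suffix = c("", "_middup")
  )
  joined <- dplyr::inner_join(joined, cd, by = "patient_id")
  if (nrow(joined) != nrow(pre_table)) {
    stop("clinical table does not cover all patients", call. = FALSE)
  }
  train_single_timepoint(joined, labels,
    model_id = model_id, learner = learner,
    n_folds = n_folds, seed = seed
  )
}

#' Predict response probabilities from a fitted bundle
#'
#' @param object A `hab_model`.
#' @param table Feature tibble containing the bundle's feature list.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.hab_model <- function(object, table, ...) {
  x <- model_matrix_from(table, object$feature_list)
  stats::predict(object$booster, xgboost::xgb.DMatrix(x))
}

#' Evaluate a fitted model bundle
#'
#' Discrimination (AUC by the Mann-Whitney formulation, 95% DeLong CI),
#' sensitivity/specificity/accuracy at the bundle's frozen threshold, and
#' the confusion matrix. Nothing is refitted.
#'
#' @param bundle A `hab_model`.
#' @param table Feature tibble.
#' @param labels Binary outcome.
#' @return A list of class `hab_eval`.
#' @export
evaluate <- function(bundle, table, labels) {
  scores <- predict(bundle, table)
  eval_scores(scores, labels,
    threshold = bundle$decision_threshold,
    model_id = bundle$model_id
  )
}

#' @rdname evaluate
#' @param scores Predicted probabilities (for evaluating raw score sets).
#' @param threshold Decision threshold.
#' @param model_id Identifier carried into the report.
#' @export
eval_scores <- function(scores, labels, threshold = 0.5, model_id = "scores") {
  if (length(unique(labels)) < 2) {
    return(structure(
      list(
        model_id = model_id, auc = NA_real_, auc_ci = c(NA, NA),
        note = "single-class evaluation set; AUC undefined"
      ),
      class = "hab_eval"
    ))
  }
  y <- as_binary_labels(labels)
  auc <- auc_mw(scores, y)
  ci <- tryCatch(
    suppressWarnings({
      r <- pROC::roc(y, scores, quiet = TRUE, direction = "<")
      as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]
    }),
    error = function(e) c(NA_real_, NA_real_)
  )
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  structure(
    list(
      model_id = model_id, auc = auc, auc_ci = ci,
      sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
      accuracy = (tp + tn) / length(y),
      confusion = matrix(c(tn, fp, fn, tp), 2, 2,
        dimnames = list(predicted = c("neg", "pos"), actual = c("neg", "pos"))
      ),
      threshold = threshold, n = length(y),
      scores = scores, labels = y
    ),
    class = "hab_eval"
  )
}

#' @export
print.hab_eval <- function(x, ...) {
  if (is.na(x$auc)) {
    cat(sprintf("<hab_eval %s: %s>\n", x$model_id, x$note))
    return(invisible(x))
  }
  cat(sprintf(
    "<hab_eval %s: AUC %.3f (95%% CI %.3f-%.3f), sens %.1f%%, spec %.1f%%, n = %d>\n",
    x$model_id, x$auc, x$auc_ci[1], x$auc_ci[2],
    100 * x$sensitivity, 100 * x$specificity, x$n
  ))
  invisible(x)
}

#' Calibration curve with logistic recalibration
#'
#' Quantile-binned reliability points (mean predicted probability vs
#' observed event rate) plus the intercept and slope of a logistic
#' recalibration of the outcome on the logit of the predictions.
#'
#' @param predictions Probabilities in \[0, 1\].
#' @param labels Binary outcome.
#' @param n_bins Number of quantile bins.
#' @return A tibble of class `hab_calibration` with attributes `intercept`
#'   and `slope`.
#' @export
calibration_curve <- function(predictions, labels, n_bins = 10) {
  y <- as_binary_labels(labels)
  if (any(predictions < 0 | predictions > 1)) {
    stop("predictions must lie in [0, 1]", call. = FALSE)
  }
  if (n_bins > length(y) / 2) stop("too many bins for the sample size", call. = FALSE)
  qs <- unique(stats::quantile(predictions, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(qs) < 2) {
    rep(1L, length(predictions))
  } else {
    cut(predictions, breaks = qs, include.lowest = TRUE, labels = FALSE)
  }
  pts <- tibble::tibble(predicted = predictions, observed = y, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean_predicted = mean(.data$predicted),
      observed_rate = mean(.data$observed),
      n = dplyr::n(), .groups = "drop"
    )
  lp <- stats::qlogis(pmin(pmax(predictions, 1e-10), 1 - 1e-10))
  co <- if (stats::sd(lp) > 0) {
    stats::coef(suppressWarnings(stats::glm(y ~ lp, family = stats::binomial())))
  } else {
    c(NA_real_, NA_real_)
  }
  structure(pts,
    intercept = unname(co[1]), slope = unname(co[2]),
    class = c("hab_calibration", class(pts))
  )
}

#' Decision-curve analysis
#'
#' Net benefit `NB(t) = TP/n - (FP/n) t/(1-t)` of the model across threshold
#' probabilities, with treat-all and treat-none references.
#'
#' @param predictions Probabilities.
#' @param labels Binary outcome.
#' @param thresholds Threshold probability grid in (0, 1).
#' @return A tibble of class `hab_decision_curve`: threshold, net_benefit
#'   for model / treat_all / treat_none.
#' @export
decision_curve <- function(predictions, labels, thresholds = seq(0.05, 0.95, 0.01)) {
  y <- as_binary_labels(labels)
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  }
  n <- length(y)
  prev <- mean(y)
  rows <- lapply(thresholds, function(t) {
    pred <- predictions >= t
    tp <- sum(pred & y == 1)
    fp <- sum(pred & y == 0)
    tibble::tibble(
      threshold = t,
      model = tp / n - (fp / n) * t / (1 - t),
      treat_all = prev - (1 - prev) * t / (1 - t),
      treat_none = 0
    )
  })
  structure(dplyr::bind_rows(rows),
    class = c("hab_decision_curve", class(rows[[1]]))
  )
}

#' Per-subgroup evaluation without refitting
#'
#' @param bundle A `hab_model`.
#' @param table Feature tibble.
#' @param labels Binary outcome.
#' @param grouping Character/factor vector (e.g. molecular subtype) aligned
#'   with the rows.
#' @param min_n Minimum subgroup size with both classes; smaller subgroups
#'   are flagged, not evaluated.
#' @return Tibble with one row per subgroup: n, evaluated, auc, ci bounds.
#' @export
subgroup_eval <- function(bundle, table, labels, grouping, min_n = 10) {
  stopifnot(length(grouping) == nrow(table))
  y <- as_binary_labels(labels)
  groups <- sort(unique(as.character(grouping)))
  rows <- lapply(groups, function(g) {
    sel <- grouping == g
    ok <- sum(sel) >= min_n && length(unique(y[sel])) == 2
    if (!ok) {
      return(tibble::tibble(
        subgroup = g, n = sum(sel), evaluated = FALSE,
        auc = NA_real_, auc_lo = NA_real_, auc_hi = NA_real_,
        sensitivity = NA_real_, specificity = NA_real_
      ))
    }
    ev <- evaluate(bundle, table[sel, , drop = FALSE], y[sel])
    tibble::tibble(
      subgroup = g, n = sum(sel), evaluated = TRUE,
      auc = ev$auc, auc_lo = ev$auc_ci[1], auc_hi = ev$auc_ci[2],
      sensitivity = ev$sensitivity, specificity = ev$specificity
    )
  })
  dplyr::bind_rows(rows)
}

# ---- broom-style methods --------------------------------------------------

#' Tidy a fitted model bundle
#'
#' @param x A `hab_model`.
#' @param ... Unused.
#' @return Tibble of feature importances (gain) for the bundle's features.
#' @export
tidy.hab_model <- function(x, ...) {
  imp <- tryCatch(
    xgboost::xgb.importance(model = x$booster),
    error = function(e) NULL
  )
  if (is.null(imp)) {
    return(tibble::tibble(feature = x$feature_list, gain = NA_real_))
  }
  tibble::tibble(feature = imp$Feature, gain = imp$Gain)
}

#' @rdname tidy.hab_model
#' @export
glance.hab_model <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id, n_features = length(x$feature_list),
    cv_auc = x$cv_auc %||% NA_real_, threshold = x$decision_threshold,
    nrounds = x$learner$nrounds, max_depth = x$learner$max_depth
  )
}

#' @rdname tidy.hab_model
#' @export
tidy.hab_eval <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id, metric = c("auc", "sensitivity", "specificity", "accuracy"),
    value = c(x$auc, x$sensitivity %||% NA, x$specificity %||% NA, x$accuracy %||% NA)
  )
}

#' @rdname tidy.hab_model
#' @export
glance.hab_eval <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id, auc = x$auc,
    auc_lo = x$auc_ci[1], auc_hi = x$auc_ci[2],
    sensitivity = x$sensitivity %||% NA_real_,
    specificity = x$specificity %||% NA_real_,
    accuracy = x$accuracy %||% NA_real_, n = x$n %||% NA_integer_
  )
}

#' Train a stacked clinical + longitudinal fusion model
#'
#' Score-stacking alternative to feature concatenation: a logistic
#' meta-learner combines the out-of-fold cross-validated scores of the two
#' fitted single-timepoint bundles with the one-hot clinical covariates.
#' Using out-of-fold scores keeps the meta-fit honest; at application time
#' the base bundles produce scores on the new data and the frozen
#' meta-coefficients combine them.
#'
#' @param pre_model,mid_model Fitted `hab_model` bundles for the pre- and
#'   mid-treatment feature sets, trained with `n_folds > 1` on the same
#'   patients (their `cv_pred` supplies the stacking design).
#' @param clinical Clinical covariate tibble for the training patients.
#' @param labels Binary outcome aligned with the training rows.
#' @param model_id Identifier.
#' @return A list of class `hab_stacked_model`.
#' @export
train_fusion_stacked <- function(pre_model, mid_model, clinical, labels,
                                 model_id = "ClinSHR") {
  if (is.null(pre_model$cv_pred) || is.null(mid_model$cv_pred)) {
    stop("base bundles need out-of-fold CV predictions (train with n_folds > 1)",
      call. = FALSE
    )
  }
  y <- as_binary_labels(labels)
  cd <- clinical_dummies(clinical)
  df <- data.frame(
    pre_score = stats::qlogis(pmin(pmax(pre_model$cv_pred, 1e-6), 1 - 1e-6)),
    mid_score = stats::qlogis(pmin(pmax(mid_model$cv_pred, 1e-6), 1 - 1e-6)),
    cd[, setdiff(names(cd), "patient_id")]
  )
  meta <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  train_scores <- stats::predict(meta, newdata = df, type = "response")
  structure(
    list(
      model_id = model_id, pre_model = pre_model, mid_model = mid_model,
      meta = meta,
      decision_threshold = youden_threshold(train_scores, y)
    ),
    class = "hab_stacked_model"
  )
}

#' @rdname train_fusion_stacked
#' @param object A `hab_stacked_model`.
#' @param pre_table,mid_table Feature tibbles for new patients.
#' @param ... Unused.
#' @export
predict.hab_stacked_model <- function(object, pre_table, mid_table, clinical, ...) {
  cd <- clinical_dummies(clinical)
  df <- data.frame(
    pre_score = stats::qlogis(pmin(pmax(
      predict(object$pre_model, pre_table), 1e-6
    ), 1 - 1e-6)),
    mid_score = stats::qlogis(pmin(pmax(
      predict(object$mid_model, mid_table), 1e-6
    ), 1 - 1e-6)),
    cd[, setdiff(names(cd), "patient_id")]
  )
  as.numeric(stats::predict(object$meta, newdata = df, type = "response"))
}

#' @export
print.hab_stacked_model <- function(x, ...) {
  cat(sprintf(
    "<hab_stacked_model %s: logistic stack of %s + %s + clinical, threshold %.3f>\n",
    x$model_id, x$pre_model$model_id, x$mid_model$model_id, x$decision_threshold
  ))
  invisible(x)
}
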