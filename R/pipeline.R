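# End-to-end workflow: cohort images -> habitat maps -> feature table ->
# per-set selection cascade -> single-timepoint and fused models -> held-out
# evaluation. This is the harness used by the package's own recovery
# experiments and the worked examples.

#' Split a patient feature table into the four model feature sets
#'
#' Uses the provenance-tagged names to form the pre/mid whole-tumor (TR) and
#' habitat (SHR) sets.
#'
#' @param features Feature tibble from [feature_table()].
#' @return Named list of four tibbles: `preTR`, `preSHR`, `midTR`, `midSHR`.
#' @export
split_feature_sets <- function(features) {
  nm <- setdiff(names(features), "patient_id")
  mf <- feature_manifest(nm)
  sets <- list(
    preTR = mf$feature[mf$timepoint == "pre" & mf$region == "TR"],
    preSHR = mf$feature[mf$timepoint == "pre" & mf$region != "TR"],
    midTR = mf$feature[mf$timepoint == "mid" & mf$region == "TR"],
    midSHR = mf$feature[mf$timepoint == "mid" & mf$region != "TR"]
  )
  lapply(sets, function(cols) {
    dplyr::select(features, dplyr::all_of(c("patient_id", cols)))
  })
}

drop_na_columns <- function(table) {
  keep <- vapply(table, function(col) !anyNA(col), logical(1))
  table[, keep, drop = FALSE]
}

#' Fit and evaluate the response-prediction model family
#'
#' Given a feature table, outcome labels and clinical covariates, performs a
#' stratified train/test split, runs the selection cascade independently on
#' each of the four feature sets (pre/mid x TR/SHR) on training data only,
#' fits the four single-timepoint boosted models plus the two fused
#' clinical + longitudinal models (Clin-SHR, Clin-TR), and evaluates
#' everything on the held-out patients.
#'
#' @param features Feature tibble from [feature_table()].
#' @param labels Binary outcome aligned with `features` rows.
#' @param clinical Clinical covariate tibble (`patient_id`, `cT_stage`,
#'   `ER`, `HER2`).
#' @param train_fraction Fraction of patients in the training split.
#' @param alpha,rho_threshold,n_folds Cascade parameters.
#' @param learner A [learner_config()].
#' @param fusion `"stack"` (default): logistic score-stacking of the two
#'   single-timepoint models with the clinical dummies;
#'   `"concatenate"`: one boosted learner on the joined feature sets.
#' @param max_features Cap on features entering the LASSO per set (top
#'   Mann-Whitney ranks), keeping the cascade tractable on wide panels.
#' @param seed Integer seed (split, cascade folds, learner).
#' @return List of class `hab_model_family`: `models`, `evaluations`
#'   (tibble of held-out AUCs), `selection` (per-set cascades), `split`.
#' @export
fit_response_models <- function(features, labels, clinical,
                                train_fraction = 0.5, alpha = 0.05,
                                rho_threshold = 0.9, n_folds = 10,
                                learner = learner_config(),
                                fusion = c("stack", "concatenate"),
                                max_features = 60, seed = NULL) {
  fusion <- match.arg(fusion)
  stopifnot(nrow(features) == length(labels))
  y <- as_binary_labels(labels)
  with_local_seed(seed, {
    split_seed <- sample.int(1e6, 1)
    idx_train <- logical(nrow(features))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      n_tr <- max(2, round(train_fraction * length(idx)))
      idx_train[sample(idx, n_tr)] <- TRUE
    }
    sets <- split_feature_sets(drop_na_columns(features))
    cascades <- list()
    selected_tabs_train <- list()
    selected_tabs_test <- list()
    for (s in names(sets)) {
      tab <- sets[[s]]
      tr_tab <- tab[idx_train, , drop = FALSE]
      # pre-rank cap keeps the LASSO stage tractable on wide panels
      fc <- feature_cols(tr_tab)
      if (length(fc) > max_features) {
        u <- vapply(fc, function(f) centred_u(tr_tab[[f]], y[idx_train]), numeric(1))
        keep <- names(sort(u, decreasing = TRUE))[seq_len(max_features)]
        tr_tab <- dplyr::select(tr_tab, dplyr::all_of(c("patient_id", keep)))
      }
      casc <- select_cascade(tr_tab, y[idx_train],
        rho_threshold = rho_threshold,
        alpha = alpha, n_folds = n_folds, seed = sample.int(1e6, 1)
      )
      cascades[[s]] <- casc
      sel <- casc$selected
      if (!length(sel)) {
        # fall back to the single best-ranked feature so the model exists
        u <- vapply(feature_cols(tr_tab), function(f) {
          centred_u(tr_tab[[f]], y[idx_train])
        }, numeric(1))
        sel <- names(which.max(u))
      }
      selected_tabs_train[[s]] <- dplyr::select(
        tab[idx_train, ], dplyr::all_of(c("patient_id", sel))
      )
      selected_tabs_test[[s]] <- dplyr::select(
        tab[!idx_train, ], dplyr::all_of(c("patient_id", sel))
      )
    }
    models <- list()
    evals <- list()
    for (s in names(sets)) {
      m <- train_single_timepoint(selected_tabs_train[[s]], y[idx_train],
        model_id = s, learner = learner, n_folds = n_folds,
        seed = sample.int(1e6, 1)
      )
      models[[s]] <- m
      evals[[s]] <- evaluate(m, selected_tabs_test[[s]], y[!idx_train])
    }
    for (fus in c("SHR", "TR")) {
      id <- paste0("Clin", fus)
      pre_t <- selected_tabs_train[[paste0("pre", fus)]]
      mid_t <- selected_tabs_train[[paste0("mid", fus)]]
      if (fusion == "stack") {
        m <- train_fusion_stacked(
          models[[paste0("pre", fus)]], models[[paste0("mid", fus)]],
          clinical[idx_train, ], y[idx_train], model_id = id
        )
        scores <- predict(m,
          pre_table = selected_tabs_test[[paste0("pre", fus)]],
          mid_table = selected_tabs_test[[paste0("mid", fus)]],
          clinical = clinical[!idx_train, ]
        )
      } else {
        m <- train_fusion(pre_t, mid_t, clinical[idx_train, ], y[idx_train],
          model_id = id, learner = learner, n_folds = n_folds,
          seed = sample.int(1e6, 1)
        )
        test_joined <- dplyr::inner_join(
          selected_tabs_test[[paste0("pre", fus)]],
          selected_tabs_test[[paste0("mid", fus)]],
          by = "patient_id", suffix = c("", "_middup")
        ) |>
          dplyr::inner_join(clinical_dummies(clinical[!idx_train, ]), by = "patient_id")
        scores <- predict(m, test_joined)
      }
      models[[id]] <- m
      evals[[id]] <- eval_scores(
        scores, y[!idx_train],
        threshold = m$decision_threshold, model_id = id
      )
    }
    evaluations <- dplyr::bind_rows(lapply(evals, glance))
    structure(
      list(
        models = models, evaluations = evaluations, selection = cascades,
        split = idx_train, evals = evals
      ),
      class = "hab_model_family"
    )
  })
}

#' @export
print.hab_model_family <- function(x, ...) {
  cat("Response-model family (held-out evaluation)\n")
  print(x$evaluations[, c("model_id", "auc", "auc_lo", "auc_hi", "sensitivity", "specificity")])
  invisible(x)
}

#' Build the four feature sets and models straight from a synthetic cohort
#'
#' Convenience wrapper: habitat delineation + feature extraction
#' ([feature_table()]) followed by [fit_response_models()].
#'
#' @param cohort_data List from [generate_cohort()] (with images).
#' @param config A [feature_panel()]; the default here is the compact
#'   original-channel first-order + shape panel used for simulation studies.
#' @param k Habitat count.
#' @param n_supervoxels Supervoxel target for delineation.
#' @param ... Passed to [fit_response_models()].
#' @param seed Integer seed.
#' @return A `hab_model_family`.
#' @export
cohort_response_models <- function(cohort_data,
                                   config = feature_panel(
                                     families = c("shape", "firstorder"),
                                     transforms = "original"
                                   ),
                                   k = 3, n_supervoxels = 60, ..., seed = NULL) {
  feats <- feature_table(cohort_data$imaging,
    k = k, config = config,
    n_supervoxels = n_supervoxels, seed = seed %||% 1
  )
  stopifnot(identical(feats$patient_id, cohort_data$cohort$patient_id))
  fit_response_models(feats, cohort_data$cohort$outcome, cohort_data$cohort,
    seed = seed, ...
  )
}
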