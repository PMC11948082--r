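test_that("AUC equals brute-force pairwise concordance", {
  set.seed(1)
  for (rep in 1:50) {
    n <- sample(8:30, 1)
    y <- sample(0:1, n, TRUE)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    s <- sample(round(runif(n), 2)) # include ties
    expect_equal(auc_mw(s, y), auc_bruteforce(s, y), tolerance = 1e-12)
  }
})

test_that("hand-built score sets give the enumerated AUCs", {
  # two positives {0.9, 0.8}, two negatives {0.4, 0.1}: all 4 pairs concordant
  expect_equal(auc_mw(c(0.9, 0.8, 0.4, 0.1), c(1, 1, 0, 0)), 1.0)
  # one inversion: 3 of 4 pairs concordant
  expect_equal(auc_mw(c(0.9, 0.3, 0.4, 0.1), c(1, 1, 0, 0)), 0.75)
})

test_that("a perfect score set evaluates to perfect operating characteristics", {
  y <- rep(c(0, 1), each = 20)
  ev <- eval_scores(as.numeric(y), y, threshold = 0.5)
  expect_equal(ev$auc, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_identical(sum(ev$confusion), 40L)
  expect_identical(ev$confusion["pos", "pos"], 20L)
})

test_that("single-class evaluation reports AUC as undefined", {
  ev <- eval_scores(runif(10), rep(1, 10))
  expect_true(is.na(ev$auc))
  expect_match(ev$note, "undefined")
})

test_that("boosted models are deterministic and null-calibrated", {
  set.seed(2)
  n <- 120
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  tab <- tibble::as_tibble(as.data.frame(x))
  y <- sample(0:1, n, TRUE)
  m1 <- train_single_timepoint(tab, y, seed = 5, n_folds = 5)
  m2 <- train_single_timepoint(tab, y, seed = 5, n_folds = 5)
  expect_identical(predict(m1, tab), predict(m2, tab))
  # independent labels: CV AUC near chance
  expect_gt(m1$cv_auc, 0.35)
  expect_lt(m1$cv_auc, 0.65)
  expect_error(train_single_timepoint(tab, rep(1, n)), "single class")
})

test_that("fusion requires complete clinical data and uses it", {
  set.seed(3)
  n <- 240
  clin <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:n),
    cT_stage = sample(c("cT1", "cT2", "cT3", "cT4"), n, TRUE),
    ER = sample(c("pos", "neg"), n, TRUE),
    HER2 = sample(c("pos", "neg"), n, TRUE)
  )
  # outcome driven by clinical only; radiomics is noise
  y <- rbinom(n, 1, plogis(-0.5 + 2 * (clin$HER2 == "pos") + 1.5 * (clin$ER == "neg")))
  noise <- function() {
    tibble::tibble(
      patient_id = clin$patient_id,
      a = rnorm(n), b = rnorm(n)
    )
  }
  fus <- train_fusion(noise(), noise(), clin, y, n_folds = 5, seed = 9)
  rad <- train_single_timepoint(noise(), y, n_folds = 5, seed = 9)
  expect_gt(fus$cv_auc, rad$cv_auc)
  clin_bad <- clin
  clin_bad$ER[c(3, 7)] <- NA
  expect_error(train_fusion(noise(), noise(), clin_bad, y), "P003")
})

test_that("calibration curve recovers slope near one for calibrated predictions", {
  set.seed(4)
  n <- 2000
  p <- runif(n, 0.05, 0.95)
  y <- rbinom(n, 1, p)
  cal <- calibration_curve(p, y, n_bins = 10)
  expect_gt(attr(cal, "slope"), 0.9)
  expect_lt(attr(cal, "slope"), 1.1)
  # overconfident predictions (logit doubled) give slope < 1
  p_over <- plogis(2 * qlogis(p))
  cal_over <- calibration_curve(p_over, y, n_bins = 10)
  expect_lt(attr(cal_over, "slope"), 1)
  # constant prediction on balanced labels: a single bin at (0.5, 0.5)
  cal_const <- calibration_curve(rep(0.5, 40), rep(0:1, 20), n_bins = 5)
  expect_identical(nrow(tibble::as_tibble(cal_const)), 1L)
  expect_equal(cal_const$mean_predicted, 0.5)
  expect_equal(cal_const$observed_rate, 0.5)
  expect_error(calibration_curve(p[1:10], y[1:10], n_bins = 8), "bins")
})

test_that("decision curve satisfies its algebraic identities", {
  set.seed(5)
  y <- rep(c(0, 1), each = 30)
  prev <- mean(y)
  # perfect classifier: NB equals prevalence below every positive score
  s_perfect <- ifelse(y == 1, 0.9, 0.1)
  dc <- decision_curve(s_perfect, y, thresholds = seq(0.15, 0.85, 0.05))
  expect_true(all(abs(dc$model[dc$threshold < 0.9] - prev) < 1e-12))
  # treat-all crosses zero exactly at t = prevalence
  dc2 <- decision_curve(runif(60), y, thresholds = prev)
  expect_equal(dc2$treat_all, 0, tolerance = 1e-12)
  expect_identical(unique(dc$treat_none), 0)
  # random scores: model never beats max(treat-all, 0) by more than MC noise
  s_rand <- runif(60)
  dc3 <- decision_curve(s_rand, y)
  expect_true(all(dc3$model <= pmax(dc3$treat_all, 0) + 0.12))
})

test_that("subgroup evaluation matches the global report and flags empties", {
  set.seed(6)
  n <- 100
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  tab <- tibble::as_tibble(as.data.frame(x))
  y <- rbinom(n, 1, plogis(x[, 1]))
  m <- train_single_timepoint(tab, y, n_folds = 0, seed = 1)
  whole <- subgroup_eval(m, tab, y, rep("all", n))
  ev <- evaluate(m, tab, y)
  expect_equal(whole$auc, ev$auc)
  mixed <- subgroup_eval(m, tab, y, c(rep("big", n - 4), rep("tiny", 4)))
  expect_false(mixed$evaluated[mixed$subgroup == "tiny"])
  expect_true(is.na(mixed$auc[mixed$subgroup == "tiny"]))
})

test_that("applying a bundle to its training table reproduces training predictions", {
  set.seed(7)
  n <- 60
  tab <- tibble::as_tibble(as.data.frame(
    matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  ))
  y <- rbinom(n, 1, 0.4)
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  m <- train_single_timepoint(tab, y, n_folds = 0, seed = 3)
  p1 <- predict(m, tab)
  p2 <- predict(m, tab)
  expect_identical(p1, p2)
  expect_error(predict(m, tab[, 1:3]), "missing")
})

test_that("DeLong intervals cover the empirical AUC point estimate", {
  set.seed(8)
  n <- 200
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(x))
  ev <- eval_scores(x, y)
  expect_true(ev$auc_ci[1] <= ev$auc && ev$auc <= ev$auc_ci[2])
  expect_gt(ev$auc_ci[2] - ev$auc_ci[1], 0)
})
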