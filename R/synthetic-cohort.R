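# Synthetic cohorts: clinical covariates plus per-patient phantom pairs with
# outcome generated from a logistic model whose imaging signal lives in the
# subregional composition, not the whole-tumor mean.

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) <= 0) x <- alpha
  x / sum(x)
}

#' Generate a synthetic patient cohort with paired phantoms
#'
#' Draws clinical covariates (cT stage, ER, HER2, derived molecular subtype),
#' per-patient planted habitat compositions at the two timepoints, and a
#' binary response outcome from a logistic model. The imaging signal enters
#' through (a) the planted mid-treatment class-1 (high-enhancement) volume
#' fraction, with lower residual class-1 fraction favouring response, and
#' (b) a per-patient class-contrast term; the whole-tumor mean intensity is
#' matched across outcomes by construction (per-patient class means are
#' shifted so the composition-weighted mean is constant), so whole-tumor
#' first-order averages carry no outcome signal.
#'
#' @param n_patients Number of patients (at least 20).
#' @param effect Standardized effect size of the subregional terms on the
#'   outcome log-odds; 0 plants no imaging signal.
#' @param clinical_log_odds Length-3 log-odds for the cT1, HER2-positive and
#'   ER-negative indicators.
#' @param pcr_base_rate Target marginal response prevalence in (0, 1).
#' @param images Generate phantom image pairs (set `FALSE` for covariate-only
#'   cohorts, e.g. prevalence checks at large n).
#' @param size Phantom grid size passed to [generate_phantom_pair()].
#' @param class_sds,noise_sd Phantom noise settings.
#' @param seed Integer seed.
#' @return A list with `cohort` (a tibble: patient_id, cT_stage, ER, HER2,
#'   subtype, outcome, planted fractions) and `imaging` (per-patient phantom
#'   pairs, `NULL` when `images = FALSE`).
#' @examples
#' coh <- generate_cohort(n_patients = 40, images = FALSE, seed = 1)
#' dplyr::count(coh$cohort, outcome)
#' @export
generate_cohort <- function(n_patients,
                            effect = 2.4,
                            clinical_log_odds = c(cT1 = 0.8, HER2pos = 0.7, ERneg = 0.5),
                            pcr_base_rate = 0.4,
                            images = TRUE,
                            size = c(32, 32, 32),
                            class_sds = c(15, 15, 15),
                            noise_sd = 5,
                            seed = NULL) {
  if (n_patients < 20) stop("n_patients must be at least 20", call. = FALSE)
  if (effect < 0) stop("effect must be non-negative", call. = FALSE)
  if (pcr_base_rate <= 0 || pcr_base_rate >= 1) {
    stop("pcr_base_rate must be in (0, 1)", call. = FALSE)
  }
  with_local_seed(seed, {
    n <- n_patients
    # clinical covariates, marginals loosely matching a locally advanced
    # breast-cancer population
    cT <- sample(c("cT1", "cT2", "cT3", "cT4"), n, TRUE, prob = c(0.07, 0.72, 0.16, 0.05))
    ER <- sample(c("pos", "neg"), n, TRUE, prob = c(0.65, 0.35))
    HER2 <- sample(c("pos", "neg"), n, TRUE, prob = c(0.4, 0.6))
    subtype <- ifelse(HER2 == "pos", "HER2+",
      ifelse(ER == "neg", "TN", "HR+/HER2-")
    )
    # planted compositions: the pre profile is patient-specific (Dirichlet
    # around a typical baseline); the mid profile is the SAME tumor after a
    # treatment shift that depletes the high-enhancement class, plus
    # response noise -- so the two timepoints are longitudinally coupled
    conc_pre <- 12
    conc_mid <- 25
    treat_shift <- c(0.55, 1.00, 1.45)
    frac_pre <- t(sapply(seq_len(n), function(i) rdirichlet1(conc_pre * c(0.40, 0.35, 0.25))))
    frac_mid <- t(sapply(seq_len(n), function(i) {
      m <- frac_pre[i, ] * treat_shift
      rdirichlet1(conc_mid * m / sum(m))
    }))
    contrast <- stats::rlnorm(n, 0, 0.15) # per-patient class-mean gap scale
    z <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
    # contrast enters at low weight: histogram standardization upstream
    # removes most across-patient contrast information, so the learnable
    # signal is concentrated in the composition term
    img_term <- effect * (-z(frac_mid[, 1]) + 0.25 * z(contrast))
    clin_term <- clinical_log_odds[1] * (cT == "cT1") +
      clinical_log_odds[2] * (HER2 == "pos") +
      clinical_log_odds[3] * (ER == "neg")
    lp0 <- img_term + clin_term
    alpha <- stats::uniroot(
      function(a) mean(stats::plogis(a + lp0)) - pcr_base_rate,
      interval = c(-20, 20)
    )$root
    p <- stats::plogis(alpha + lp0)
    outcome <- NULL
    for (attempt in 1:10) {
      draw <- stats::rbinom(n, 1, p)
      if (length(unique(draw)) == 2) {
        outcome <- draw
        break
      }
      warning("degenerate single-outcome draw; re-drawing", call. = FALSE)
    }
    if (is.null(outcome)) stop("could not draw both outcome classes in 10 attempts", call. = FALSE)

    base_means <- c(300, 200, 100)
    target_mean <- sum(c(0.35, 0.35, 0.30) * base_means)
    imaging <- NULL
    if (images) {
      imaging <- vector("list", n)
      for (i in seq_len(n)) {
        mu <- mean(base_means) + contrast[i] * (base_means - mean(base_means))
        # match the composition-weighted (whole-tumor) mean at each timepoint
        mu_pre <- mu + (target_mean - sum(frac_pre[i, ] * mu))
        mu_mid <- mu + (target_mean - sum(frac_mid[i, ] * mu))
        ph_seed <- sample.int(.Machine$integer.max, 1)
        pre <- generate_phantom_pair(
          size = size, fractions_pre = frac_pre[i, ], fractions_mid = frac_mid[i, ],
          class_means = mu_pre, class_sds = class_sds, noise_sd = noise_sd,
          seed = ph_seed
        )
        # regenerate the mid image with its own mean matching; geometry is
        # re-drawn from the same seed so pre/mid stay a coherent pair
        mid <- generate_phantom_pair(
          size = size, fractions_pre = frac_pre[i, ], fractions_mid = frac_mid[i, ],
          class_means = mu_mid, class_sds = class_sds, noise_sd = noise_sd,
          seed = ph_seed
        )
        imaging[[i]] <- list(
          pre = pre$pre,
          mid = mid$mid,
          truth = utils::modifyList(pre$truth, list(
            latent_class_map_mid = mid$truth$latent_class_map_mid,
            realized_fractions_mid = mid$truth$realized_fractions_mid
          ))
        )
      }
      names(imaging) <- sprintf("P%03d", seq_len(n))
    }
    cohort <- tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      cT_stage = cT, ER = ER, HER2 = HER2, subtype = subtype,
      outcome = factor(ifelse(outcome == 1, "pCR", "non-pCR"), levels = c("non-pCR", "pCR")),
      f1_pre = frac_pre[, 1], f2_pre = frac_pre[, 2], f3_pre = frac_pre[, 3],
      f1_mid = frac_mid[, 1], f2_mid = frac_mid[, 2], f3_mid = frac_mid[, 3],
      contrast = contrast
    )
    list(cohort = cohort, imaging = imaging)
  })
}
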