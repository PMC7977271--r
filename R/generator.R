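#' Default condition definitions for the synthetic population
#'
#' Five headline chronic-condition groups of an older primary-care panel
#' (diabetes, neoplasm, heart disease, psychiatric, lung) at their target
#' marginal prevalences, plus rarer severe variants (complicated diabetes,
#' metastatic cancer, heart failure) that exercise the dominance rules of
#' the packaged toy model. `risk_loading` is the slope of condition
#' presence on latent log-severity; codes are a toy vocabulary, not a
#' licensed code system.
#'
#' @return Tibble with columns `condition`, `prevalence`, `risk_loading`,
#'   `codes` (list-column).
#' @export
default_condition_defs <- function() {
  tibble::tibble(
    condition = c("diabetes", "diabetes_complicated", "neoplasm",
                  "metastatic_cancer", "heart_disease", "heart_failure",
                  "psychiatric", "lung"),
    prevalence = c(0.11, 0.030, 0.11, 0.015, 0.10, 0.040, 0.08, 0.05),
    risk_loading = c(1.0, 1.6, 0.8, 2.0, 1.3, 1.6, 0.7, 1.0),
    codes = list(c("DM1", "DM2"), "DMC", c("NEO", "LYMPH"), "METS",
                 c("CAD", "MI"), "CHF", c("DEP", "SCZ", "BIP"),
                 c("COPD", "ASTH")))
}

#' Configuration for the synthetic patient-population generator
#'
#' The defaults are calibrated so a 40,000-patient draw reproduces the
#' margins of a stratified adult primary-care panel: about 57% female, mean
#' age near 61, the five condition prevalences of
#' [default_condition_defs()], a toy-HCC score distribution with median
#' near 0.60 and IQR near (0.28, 0.80), follow-year outcome rates near 30%
#' (ED >= 1), 12% (ED >= 2), 14% (hospitalization >= 1) and 9%
#' (expenditures >= $30,000), with the top decile of patients carrying
#' roughly two thirds of total spend.
#'
#' @param n_patients Number of patients (> 0).
#' @param seed Integer seed; every random draw flows from it.
#' @param female_fraction Proportion female.
#' @param age_mean,age_sd Normal age parameters in years (ages are
#'   truncated to \[18, 102)).
#' @param condition_defs Condition table as in [default_condition_defs()].
#' @param latent_risk List with `meanlog`, `sdlog` of the positive latent
#'   severity lambda (log-normal).
#' @param outcome_model Per-outcome link parameters. `ed` and `hosp` are
#'   lists with `base` (annual event rate at median severity), `elasticity`
#'   (rate multiplier per unit latent log-severity) and `dispersion`
#'   (gamma-frailty overdispersion; 0 is Poisson). `expend` has `meanlog`
#'   (log base-cost at median severity), `elasticity`, `sdlog_person`
#'   (person effect shared across years), `sdlog_year` (year-to-year
#'   noise), and per-event add-ons `ed_cost`, `hosp_cost` in USD.
#' @param practice_mode How the simulated practice assigns tiers:
#'   `"intuition"`, `"algorithm"` or `"adjudication"`.
#' @param intuition_noise SD of the noise added to latent log-severity
#'   when tiering by clinical intuition (information loss; 0 = omniscient).
#' @param adjudication_prob Probability a reviewer replaces the algorithmic
#'   tier with the latent-severity tier.
#' @param tier_proportions Four tier-size proportions (low, moderate,
#'   high, very high) summing to 1.
#' @param payer_probs Probabilities for payer classes medicare, dual,
#'   other (the first two are the subset with reliable outcome feeds).
#' @param seen_prior_prob Probability the patient was seen before the
#'   risk-stratification date.
#' @param attrition_prob Probability the record indicates death or leaving
#'   the practice during observation.
#' @param rs_date Risk-stratification date (day 0), identical for the
#'   panel.
#' @param hcc_model Model used by the `"algorithm"`/`"adjudication"` tier
#'   modes; defaults to [toy_hcc_model()].
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 40000,
                             seed = 20210318,
                             female_fraction = 0.57,
                             age_mean = 60.3,
                             age_sd = 17.5,
                             condition_defs = default_condition_defs(),
                             latent_risk = list(meanlog = 0, sdlog = 0.9),
                             outcome_model = list(
                               ed = list(base = 0.38, elasticity = 1.0,
                                         dispersion = 1.0),
                               hosp = list(base = 0.108, elasticity = 1.3,
                                           dispersion = 1.0),
                               expend = list(meanlog = 7.3, elasticity = 1.8,
                                             sdlog_person = 0.85,
                                             sdlog_year = 0.60,
                                             ed_cost = 900, hosp_cost = 13000)),
                             practice_mode = c("adjudication", "intuition",
                                               "algorithm"),
                             intuition_noise = 2.0,
                             adjudication_prob = 0.7,
                             tier_proportions = c(low = 0.40, moderate = 0.30,
                                                  high = 0.20, very_high = 0.10),
                             payer_probs = c(medicare = 0.088, dual = 0.012,
                                             other = 0.90),
                             seen_prior_prob = 0.97,
                             attrition_prob = 0.03,
                             rs_date = as.Date("2015-01-01"),
                             hcc_model = toy_hcc_model()) {
  practice_mode <- match.arg(practice_mode)
  if (!is.numeric(n_patients) || length(n_patients) != 1 ||
      n_patients < 1 || n_patients != round(n_patients)) {
    abort("`n_patients` must be a positive whole number.")
  }
  assert_proportion(female_fraction, "female_fraction")
  assert_proportion(seen_prior_prob, "seen_prior_prob")
  assert_proportion(attrition_prob, "attrition_prob")
  assert_proportion(adjudication_prob, "adjudication_prob")
  if (intuition_noise < 0) abort("`intuition_noise` must be nonnegative.")
  tp <- as.numeric(tier_proportions)
  if (length(tp) != 4 || any(tp < 0) || abs(sum(tp) - 1) > 1e-9) {
    abort("`tier_proportions` must be four proportions summing to 1.")
  }
  cd <- tibble::as_tibble(condition_defs)
  if (any(cd$prevalence <= 0 | cd$prevalence >= 1)) {
    abort("Condition prevalences must lie strictly inside (0, 1).")
  }
  if (any(cd$risk_loading < 0)) abort("Risk loadings must be nonnegative.")
  if (latent_risk$sdlog < 0) abort("`latent_risk$sdlog` must be nonnegative.")
  pp <- as.numeric(payer_probs)
  if (length(pp) != 3 || any(pp < 0) || abs(sum(pp) - 1) > 1e-9) {
    abort("`payer_probs` must be three probabilities summing to 1.")
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         female_fraction = female_fraction, age_mean = age_mean,
         age_sd = age_sd, condition_defs = cd, latent_risk = latent_risk,
         outcome_model = outcome_model, practice_mode = practice_mode,
         intuition_noise = intuition_noise,
         adjudication_prob = adjudication_prob,
         tier_proportions = setNames(tp, tier_levels),
         payer_probs = setNames(pp, c("medicare", "dual", "other")),
         seen_prior_prob = seen_prior_prob, attrition_prob = attrition_prob,
         rs_date = as.Date(rs_date), hcc_model = hcc_model),
    class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  n = %d, seed = %d, mode = %s\n", x$n_patients, x$seed, x$practice_mode))
  cat(sprintf("  %d condition definitions; tier targets %s\n",
              nrow(x$condition_defs),
              paste(sprintf("%.2f", x$tier_proportions), collapse = "/")))
  invisible(x)
}

# intercept such that mean(plogis(a + slope * z)) hits the target prevalence
solve_prevalence_intercept <- function(z, slope, target) {
  uniroot(function(a) mean(plogis(a + slope * z)) - target,
          lower = -30, upper = 30, tol = 1e-10)$root
}

# size-matched quantile tiers via the same tie-preserving cut-point rule
# the evaluation pipeline uses; exact within integer rounding on
# continuous scores, "as close as ties allow" on discrete ones
quantile_tier <- function(x, proportions) {
  assign_tiers(x, fit_cutpoints(x, proportions))
}

#' Generate a synthetic risk-stratified patient population
#'
#' Draws a panel whose structure mirrors what the downstream analysis
#' assumes: a positive latent severity lambda (log-normal) drives condition
#' presence (logistic in log lambda, with intercepts solved so marginal
#' prevalences match the configuration on the realized draw), overdispersed
#' ED and hospitalization counts (gamma-frailty Poisson, i.e. negative
#' binomial, with the same person-level rate generating the prior and
#' follow year so utilization is correlated across years), and heavy-tailed
#' expenditures (log-normal base cost plus per-event costs). Practice tiers
#' are then assigned by [simulate_practice_tiers()] under the configured
#' mode.
#'
#' @param config A [generator_config()].
#' @return Tibble with one row per patient: identifiers, demographics,
#'   `diagnosis_codes` (list-column), `latent_risk`, `practice_tier`,
#'   payer class, retention flags and prior/follow-year utilization.
#'   Identical configuration and seed give identical output.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_patients
  set.seed(config$seed)

  sex <- ifelse(runif(n) < config$female_fraction, "F", "M")
  lo <- pnorm(18, config$age_mean, config$age_sd)
  hi <- pnorm(102, config$age_mean, config$age_sd)
  age <- qnorm(runif(n, lo, hi), config$age_mean, config$age_sd)

  z <- rnorm(n, config$latent_risk$meanlog, config$latent_risk$sdlog)
  zc <- z - config$latent_risk$meanlog
  lambda <- exp(z)

  # conditions: logistic in log lambda, intercept solved per condition
  cd <- config$condition_defs
  idx_list <- list(); code_list <- list()
  for (i in seq_len(nrow(cd))) {
    a <- solve_prevalence_intercept(zc, cd$risk_loading[i], cd$prevalence[i])
    present <- which(runif(n) < plogis(a + cd$risk_loading[i] * zc))
    codes <- cd$codes[[i]]
    primary <- codes[sample.int(length(codes), length(present), replace = TRUE)]
    idx_list[[length(idx_list) + 1L]] <- present
    code_list[[length(code_list) + 1L]] <- primary
    if (length(codes) > 1) {
      for (extra in codes) {
        hit <- present[runif(length(present)) < 0.3 & primary != extra]
        if (length(hit) > 0) {
          idx_list[[length(idx_list) + 1L]] <- hit
          code_list[[length(code_list) + 1L]] <- rep(extra, length(hit))
        }
      }
    }
  }
  all_idx <- unlist(idx_list)
  all_codes <- unlist(code_list)
  diagnosis_codes <- split(all_codes, factor(all_idx, levels = seq_len(n)))
  diagnosis_codes <- lapply(diagnosis_codes, function(s) unique(unname(s)))

  draw_counts <- function(par) {
    mu <- par$base * exp(par$elasticity * zc)
    rate <- if (par$dispersion > 0) {
      mu * rgamma(n, shape = 1 / par$dispersion, rate = 1 / par$dispersion)
    } else mu
    list(prior = rpois(n, rate), follow = rpois(n, rate))
  }
  ed <- draw_counts(config$outcome_model$ed)
  hosp <- draw_counts(config$outcome_model$hosp)

  ex <- config$outcome_model$expend
  base_cost <- exp(ex$meanlog + ex$elasticity * zc + rnorm(n, 0, ex$sdlog_person))
  prior_expend <- base_cost * exp(rnorm(n, 0, ex$sdlog_year)) +
    ex$ed_cost * ed$prior + ex$hosp_cost * hosp$prior
  follow_expend <- base_cost * exp(rnorm(n, 0, ex$sdlog_year)) +
    ex$ed_cost * ed$follow + ex$hosp_cost * hosp$follow

  payer_class <- sample(c("medicare", "dual", "other"), n, replace = TRUE,
                        prob = config$payer_probs)
  seen_prior <- runif(n) < config$seen_prior_prob
  deceased_or_left <- runif(n) < config$attrition_prob

  patients <- tibble::tibble(
    patient_id = sprintf("P%07d", seq_len(n)),
    age = age, sex = sex,
    diagnosis_codes = unname(diagnosis_codes),
    latent_risk = lambda,
    practice_tier = factor(NA_character_, levels = tier_levels, ordered = TRUE),
    rs_date = config$rs_date,
    payer_class = payer_class,
    seen_prior = seen_prior,
    deceased_or_left = deceased_or_left,
    prior_ed = ed$prior, follow_ed = ed$follow,
    prior_hosp = hosp$prior, follow_hosp = hosp$follow,
    prior_expend = round(prior_expend, 2),
    follow_expend = round(follow_expend, 2))
  simulate_practice_tiers(patients, config)
}

#' Simulate how a practice assigns risk tiers
#'
#' Three stylized workflows fill `practice_tier`:
#' * `intuition` — the tier is the size-matched quantile tier of latent
#'   log-severity plus normal noise with SD `intuition_noise`, modelling a
#'   clinician who sees true risk imperfectly.
#' * `algorithm` — the tier is the quantile tier of the HCC-style score
#'   computed from the observed diagnosis codes only.
#' * `adjudication` — starts from the algorithmic tier; with probability
#'   `adjudication_prob` a reviewer corrects it to the latent-severity
#'   quantile tier.
#'
#' Tiers are size-matched to `tier_proportions` with the tie-preserving
#' cut-point rule of [fit_cutpoints()]: exact within integer rounding when
#' scores are continuous (intuition, latent), as close as ties allow for
#' the discrete algorithmic score. Randomness is seeded deterministically
#' from `config$seed`, so the same configuration reproduces the same
#' tiers.
#'
#' @param patients Population table with a `latent_risk` column.
#' @param config A [generator_config()].
#' @return `patients` with `practice_tier` filled (ordered factor).
#' @export
simulate_practice_tiers <- function(patients, config) {
  stopifnot(inherits(config, "generator_config"))
  patients <- tibble::as_tibble(patients)
  if (!"latent_risk" %in% names(patients) || anyNA(patients$latent_risk)) {
    abort("`patients` must carry a complete `latent_risk` column.")
  }
  set.seed(derive_seed(config$seed, 11))
  n <- nrow(patients)
  props <- config$tier_proportions
  tier <- switch(
    config$practice_mode,
    intuition = {
      noisy <- log(patients$latent_risk) + rnorm(n, 0, config$intuition_noise)
      quantile_tier(noisy, props)
    },
    algorithm = {
      s <- score_patients(patients, config$hcc_model)$hcc_score
      quantile_tier(s, props)
    },
    adjudication = {
      s <- score_patients(patients, config$hcc_model)$hcc_score
      alg <- quantile_tier(s, props)
      latent <- quantile_tier(log(patients$latent_risk), props)
      fix <- runif(n) < config$adjudication_prob
      out <- as.character(alg)
      out[fix] <- as.character(latent)[fix]
      factor(out, levels = tier_levels, ordered = TRUE)
    },
    abort(sprintf("Unknown practice mode '%s'.", config$practice_mode)))
  patients$practice_tier <- tier
  patients
}
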