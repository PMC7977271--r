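#' Apply the cohort retention filters
#'
#' Patients are retained when they were seen prior to risk stratification,
#' carry a valid practice tier, and their record does not indicate death or
#' leaving the practice during observation — applied in that order so the
#' exclusion counts attribute each loss to the first failing rule. The
#' outcome-analysis subset additionally requires a payer class with
#' reliable outcome feeds (medicare or dual).
#'
#' @param patients Data frame with columns `seen_prior`, `practice_tier`,
#'   `deceased_or_left` (and `payer_class` when `require_outcomes`).
#' @param require_outcomes Also restrict to payer classes with reliable
#'   outcomes?
#' @return List with `cohort` (filtered tibble) and `report` (one-row
#'   tibble of running ns and per-filter exclusion counts).
#' @export
apply_cohort_filters <- function(patients, require_outcomes = FALSE) {
  patients <- tibble::as_tibble(patients)
  need <- c("seen_prior", "practice_tier", "deceased_or_left")
  if (require_outcomes) need <- c(need, "payer_class")
  miss <- setdiff(need, names(patients))
  if (length(miss) > 0) {
    abort(sprintf("`patients` lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  n_input <- nrow(patients)
  step1 <- patients[!is.na(patients$seen_prior) & patients$seen_prior, ]
  step2 <- step1[!is.na(step1$practice_tier) &
                   as.character(step1$practice_tier) %in% tier_levels, ]
  step3 <- step2[!is.na(step2$deceased_or_left) & !step2$deceased_or_left, ]
  cohort <- step3
  n_with_outcomes <- NA_integer_
  excl_payer <- NA_integer_
  if (require_outcomes) {
    cohort <- step3[step3$payer_class %in% c("medicare", "dual"), ]
    n_with_outcomes <- nrow(cohort)
    excl_payer <- nrow(step3) - nrow(cohort)
  }
  report <- tibble::tibble(
    n_input = n_input,
    n_after_seen_prior = nrow(step1),
    n_after_valid_score = nrow(step2),
    n_after_not_deceased_or_left = nrow(step3),
    n_with_outcomes = n_with_outcomes,
    excluded_not_seen_prior = n_input - nrow(step1),
    excluded_invalid_score = nrow(step1) - nrow(step2),
    excluded_deceased_or_left = nrow(step2) - nrow(step3),
    excluded_unreliable_outcomes = excl_payer)
  list(cohort = cohort, report = report)
}

#' Study configuration for the end-to-end evaluation
#'
#' A study is a set of simulated practices (one [generator_config()] each,
#' named by practice) analysed jointly: filter, score, tier both ways,
#' agreement, dichotomized outcomes and stratified performance.
#'
#' @param practices Named list of [generator_config()]s. Defaults to a
#'   six-practice panel mirroring a typical mix: one practice tiering by
#'   clinical intuition, one by algorithm alone, four by adjudication.
#' @param thresholds [outcome_thresholds()] for dichotomizing outcomes.
#' @param outcome_window `"follow"` (predictive evaluation, default) or
#'   `"prior"` (the calibration year).
#' @param high_risk_rule `"very_high"` (default: only the single top tier
#'   counts as high risk) or `"high_or_above"`.
#' @param model HCC-style model used to score patients.
#' @param seed Study-level seed; per-practice seeds derive from it.
#' @param out_dir Optional directory; when given, all result tables, the
#'   run manifest and intermediate CSVs are written there.
#' @return A list of class `study_config`.
#' @export
study_config <- function(practices = default_practices(),
                         thresholds = outcome_thresholds(),
                         outcome_window = c("follow", "prior"),
                         high_risk_rule = c("very_high", "high_or_above"),
                         model = toy_hcc_model(),
                         seed = 1L,
                         out_dir = NULL) {
  outcome_window <- match.arg(outcome_window)
  high_risk_rule <- match.arg(high_risk_rule)
  if (length(practices) == 0 ||
      !all(vapply(practices, inherits, TRUE, "generator_config"))) {
    abort("`practices` must be a non-empty list of generator_config objects.")
  }
  if (is.null(names(practices)) || any(names(practices) == "")) {
    names(practices) <- sprintf("practice_%d", seq_along(practices))
  }
  structure(list(practices = practices, thresholds = thresholds,
                 outcome_window = outcome_window,
                 high_risk_rule = high_risk_rule, model = model,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "study_config")
}

#' Default six-practice study panel
#'
#' One intuition practice, one algorithm-only practice and four
#' adjudication practices, sized so the whole study stays quick to run;
#' scale `n_per_practice` up for tighter Monte-Carlo error.
#'
#' @param n_per_practice Patients per practice.
#' @param seed Base seed; each practice gets a distinct derived seed.
#' @return Named list of [generator_config()]s.
#' @export
default_practices <- function(n_per_practice = 3000, seed = 1L) {
  modes <- c(intuition = "intuition", algorithm = "algorithm",
             adjudication_1 = "adjudication", adjudication_2 = "adjudication",
             adjudication_3 = "adjudication", adjudication_4 = "adjudication")
  out <- lapply(seq_along(modes), function(i) {
    generator_config(n_patients = n_per_practice,
                     seed = derive_seed(seed, i),
                     practice_mode = modes[[i]])
  })
  names(out) <- names(modes)
  out
}

#' Run the full risk-stratification evaluation study
#'
#' Simulates each practice, applies the cohort filters, computes HCC-style
#' scores, fits size-matched tier cut-points per practice, compares the
#' practice and algorithmic high-risk flags (concordance, kappa, 4x4
#' cross-tab, on the full cohort and on the reliable-outcome cohort),
#' dichotomizes the chosen window's outcomes and produces stratified
#' diagnostic-performance summaries with paired tests. When
#' `config$out_dir` is set, writes every table as CSV plus a JSON manifest
#' (seed, thresholds, package version) so each reported number is
#' recomputable from the emitted files.
#'
#' @param config A [study_config()].
#' @return A list of class `study_report`: `cohort_report`, `agreement`,
#'   `tier_crosstab`, `metrics` (stratified summary by practice mode),
#'   `by_practice`, `across`, `cutpoints`, and the analysis cohort.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))

  pops <- purrr::imap(config$practices, function(pc, nm) {
    dplyr::mutate(generate_population(pc),
                  practice = nm, approach = pc$practice_mode,
                  patient_id = paste0(nm, "_", patient_id))
  })
  all_patients <- dplyr::bind_rows(pops)

  filtered <- apply_cohort_filters(all_patients)
  cohort <- filtered$cohort

  scored <- score_patients(cohort, config$model)
  cohort$hcc_score <- scored$hcc_score

  # size-matched cut-points fitted per practice on its own scored panel
  cutpoints <- list()
  cohort$hcc_tier <- factor(NA_character_, levels = tier_levels, ordered = TRUE)
  for (nm in unique(cohort$practice)) {
    sel <- cohort$practice == nm
    cp <- fit_cutpoints(cohort$hcc_score[sel],
                        config$practices[[nm]]$tier_proportions)
    cohort$hcc_tier[sel] <- assign_tiers(cohort$hcc_score[sel], cp)
    cutpoints[[nm]] <- cp
  }

  flag_of <- function(tiers) {
    if (config$high_risk_rule == "very_high") high_risk_flag(tiers)
    else as.character(tiers) %in% c("high", "very_high")
  }
  cohort$practice_high <- flag_of(cohort$practice_tier)
  cohort$hcc_high <- flag_of(cohort$hcc_tier)

  outcome_filtered <- apply_cohort_filters(cohort, require_outcomes = TRUE)
  outcome_cohort <- dichotomize(outcome_filtered$cohort, config$thresholds,
                                window = config$outcome_window)

  agreement <- dplyr::bind_rows(
    agreement_summary(cohort$practice_high, cohort$hcc_high,
                      "practice vs HCC, full cohort"),
    agreement_summary(outcome_cohort$practice_high, outcome_cohort$hcc_high,
                      "practice vs HCC, outcome cohort"))
  crosstab <- tier_crosstab(cohort$practice_tier, cohort$hcc_tier)

  metrics <- stratified_summary(outcome_cohort, stratum_col = "approach")
  by_practice <- stratified_summary(outcome_cohort, stratum_col = "practice")
  across <- across_strata(by_practice)

  report <- structure(
    list(cohort_report = filtered$report,
         outcome_cohort_report = outcome_filtered$report,
         agreement = agreement, tier_crosstab = crosstab,
         metrics = metrics, by_practice = by_practice, across = across,
         cutpoints = cutpoints, outcome_cohort = outcome_cohort,
         config = config),
    class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  cohort: %d scored, %d in outcome analysis\n",
              x$cohort_report$n_after_not_deceased_or_left,
              x$outcome_cohort_report$n_with_outcomes))
  ag <- x$agreement[1, ]
  cat(sprintf("  full-cohort agreement %.0f%%, kappa %.2f (%s), both/either %.1f%%\n",
              100 * ag$pct_agreement, ag$kappa, ag$band, 100 * ag$both_over_either))
  cat(sprintf("  stratified metrics: %d rows over %d strata\n",
              nrow(x$metrics), length(unique(x$metrics$stratum))))
  invisible(x)
}

write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$cohort_report, file.path(out_dir, "cohort_report.csv"))
  readr::write_csv(report$outcome_cohort_report,
                   file.path(out_dir, "outcome_cohort_report.csv"))
  readr::write_csv(report$agreement, file.path(out_dir, "agreement.csv"))
  readr::write_csv(report$tier_crosstab, file.path(out_dir, "tier_crosstab.csv"))
  readr::write_csv(report$metrics, file.path(out_dir, "metrics_by_approach.csv"))
  readr::write_csv(report$by_practice, file.path(out_dir, "metrics_by_practice.csv"))
  readr::write_csv(report$across, file.path(out_dir, "metrics_across_practices.csv"))
  cohort_out <- dplyr::select(report$outcome_cohort, -"diagnosis_codes")
  readr::write_csv(cohort_out, file.path(out_dir, "outcome_cohort.csv"))
  manifest <- list(
    seed = report$config$seed,
    package_version = as.character(utils::packageVersion("riskstrat")),
    r_version = R.version.string,
    outcome_window = report$config$outcome_window,
    high_risk_rule = report$config$high_risk_rule,
    thresholds = unclass(report$config$thresholds),
    practices = lapply(report$config$practices, function(p) {
      list(n = p$n_patients, seed = p$seed, mode = p$practice_mode)
    }),
    cutpoints = lapply(report$cutpoints, function(cp) {
      list(c1 = cp$c1, c2 = cp$c2, c3 = cp$c3)
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
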