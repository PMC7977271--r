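#' Write a population to plain-text files
#'
#' Writes `patients.csv` (one row per patient, ISO-8601 dates, the
#' diagnosis list-column dropped) and `diagnoses.csv` in long format
#' (`patient_id`, `code`).
#'
#' @param patients Population tibble from [generate_population()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(patients, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  diagnoses <- tibble::tibble(
    patient_id = rep(patients$patient_id, lengths(patients$diagnosis_codes)),
    code = unlist(patients$diagnosis_codes, use.names = FALSE) %||% character())
  flat <- dplyr::select(tibble::as_tibble(patients), -"diagnosis_codes")
  readr::write_csv(flat, file.path(dir, "patients.csv"))
  readr::write_csv(diagnoses, file.path(dir, "diagnoses.csv"))
  invisible(dir)
}

#' Read a population written by [write_population()]
#'
#' @param dir Directory holding `patients.csv` and `diagnoses.csv`.
#' @return Population tibble with the `diagnosis_codes` list-column
#'   rebuilt and `practice_tier` restored as an ordered factor.
#' @export
read_population <- function(dir) {
  patients <- readr::read_csv(file.path(dir, "patients.csv"),
                              col_types = readr::cols())
  diagnoses <- readr::read_csv(file.path(dir, "diagnoses.csv"),
                               col_types = readr::cols(.default = "c"))
  sets <- split(diagnoses$code, factor(diagnoses$patient_id,
                                       levels = patients$patient_id))
  patients$diagnosis_codes <- lapply(unname(sets), as.character)
  patients$practice_tier <- factor(patients$practice_tier,
                                   levels = tier_levels, ordered = TRUE)
  dplyr::relocate(patients, "diagnosis_codes", .after = "sex")
}

#' Serialize a generator configuration to YAML
#'
#' Everything except the model object is written; on read the model is
#' reloaded from `hcc_model_dir` when given, else the packaged toy model.
#'
#' @param config A [generator_config()].
#' @param path Output file.
#' @param hcc_model_dir Optional directory holding `map.csv`,
#'   `hierarchy.csv`, `coef.csv` to record as the model source.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(config, path, hcc_model_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  x <- unclass(config)
  x$hcc_model <- NULL
  x$hcc_model_dir <- hcc_model_dir
  x$rs_date <- format(x$rs_date)
  x$condition_defs <- lapply(seq_len(nrow(config$condition_defs)), function(i) {
    list(condition = config$condition_defs$condition[i],
         prevalence = config$condition_defs$prevalence[i],
         risk_loading = config$condition_defs$risk_loading[i],
         codes = as.list(config$condition_defs$codes[[i]]))
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a generator configuration from YAML
#'
#' @param path File written by [write_generator_config()].
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  cd <- tibble::tibble(
    condition = vapply(x$condition_defs, `[[`, "", "condition"),
    prevalence = vapply(x$condition_defs, `[[`, 0, "prevalence"),
    risk_loading = vapply(x$condition_defs, `[[`, 0, "risk_loading"),
    codes = lapply(x$condition_defs, function(d) unlist(d$codes)))
  model <- if (!is.null(x$hcc_model_dir)) {
    load_hcc_model(file.path(x$hcc_model_dir, "map.csv"),
                   file.path(x$hcc_model_dir, "hierarchy.csv"),
                   file.path(x$hcc_model_dir, "coef.csv"))
  } else toy_hcc_model()
  generator_config(
    n_patients = x$n_patients, seed = x$seed,
    female_fraction = x$female_fraction, age_mean = x$age_mean,
    age_sd = x$age_sd, condition_defs = cd, latent_risk = x$latent_risk,
    outcome_model = x$outcome_model, practice_mode = x$practice_mode,
    intuition_noise = x$intuition_noise,
    adjudication_prob = x$adjudication_prob,
    tier_proportions = unlist(x$tier_proportions),
    payer_probs = unlist(x$payer_probs),
    seen_prior_prob = x$seen_prior_prob, attrition_prob = x$attrition_prob,
    rs_date = as.Date(x$rs_date), hcc_model = model)
}
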