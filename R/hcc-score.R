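#' Map diagnosis codes to condition categories
#'
#' Codes absent from the model's map are skipped (real EHR feeds are dirty);
#' the number skipped is attached as the `"n_unmapped"` attribute so callers
#' can log it.
#'
#' @param codes Character vector of diagnosis codes (duplicates allowed;
#'   set semantics apply).
#' @param model An [hcc_model()].
#' @return Character vector of distinct condition categories, with attribute
#'   `n_unmapped` giving the count of distinct codes that had no mapping.
#' @export
#' @examples
#' m <- toy_hcc_model()
#' map_codes_to_ccs(c("DM2", "DM2", "NOT_A_CODE"), m)
map_codes_to_ccs <- function(codes, model) {
  stopifnot(inherits(model, "hcc_model"))
  codes <- unique(as.character(codes))
  idx <- match(codes, model$code_to_cc$code)
  ccs <- unique(model$code_to_cc$cc[idx[!is.na(idx)]])
  structure(ccs, n_unmapped = sum(is.na(idx)))
}

#' Apply hierarchy (dominance) rules to a category set
#'
#' For every rule `(dominant, suppressed)` whose dominant category is
#' present, the suppressed category is removed; rules are re-applied until a
#' fixpoint is reached, so chains of rules resolve correctly.
#'
#' @param ccs Character vector of condition categories.
#' @param model An [hcc_model()].
#' @return Subset of `ccs` surviving suppression.
#' @export
apply_hierarchies <- function(ccs, model) {
  stopifnot(inherits(model, "hcc_model"))
  ccs <- unique(as.character(ccs))
  h <- model$hierarchies
  repeat {
    drop <- unique(h$suppressed_cc[h$dominant_cc %in% ccs])
    drop <- intersect(drop, ccs)
    if (length(drop) == 0) break
    ccs <- setdiff(ccs, drop)
  }
  ccs
}

demographic_weight <- function(age, sex, model) {
  dw <- model$demographic_weights
  i <- which(dw$sex == sex & age >= dw$age_lo & age < dw$age_hi)
  if (length(i) != 1) abort(sprintf("No demographic cell for sex=%s, age=%.1f.", sex, age))
  dw$weight[i]
}

#' Score a single patient
#'
#' The score is the age-sex demographic weight plus the sum of category
#' weights over the categories surviving hierarchy suppression. It is not
#' clamped to any observed range.
#'
#' @param age Age in years (>= 0).
#' @param sex `"F"` or `"M"`.
#' @param codes Character vector of diagnosis codes.
#' @param model An [hcc_model()].
#' @return A list with elements `score` (nonnegative number),
#'   `surviving_ccs` (character vector) and `n_unmapped`.
#' @export
#' @examples
#' m <- toy_hcc_model()
#' hcc_score(70, "F", c("DM2", "DMC"), m)$score
hcc_score <- function(age, sex, codes, model) {
  stopifnot(length(age) == 1, length(sex) == 1, age >= 0, sex %in% c("F", "M"))
  ccs <- map_codes_to_ccs(codes, model)
  surviving <- apply_hierarchies(ccs, model)
  w <- model$cc_weights$weight[match(surviving, model$cc_weights$cc)]
  list(score = demographic_weight(age, sex, model) + sum(w),
       surviving_ccs = surviving,
       n_unmapped = attr(ccs, "n_unmapped"))
}

#' Score a patient table
#'
#' Vectorized scoring of a whole panel. Diagnoses are taken either from a
#' long `diagnoses` table (`patient_id`, `code`) or, when that is `NULL`,
#' from a `diagnosis_codes` list-column on `patients` (the layout the
#' synthetic generator produces).
#'
#' @param patients Data frame with columns `patient_id`, `age`, `sex` (and
#'   optionally `diagnosis_codes`).
#' @param model An [hcc_model()]; defaults to the packaged toy model.
#' @param diagnoses Optional long data frame with columns `patient_id`,
#'   `code`.
#' @return A tibble with one row per patient: `patient_id`, `hcc_score`,
#'   `surviving_ccs` (list-column), joined in the input order. Skipped
#'   (unmapped) code counts are reported once via a message.
#' @export
score_patients <- function(patients, model = toy_hcc_model(), diagnoses = NULL) {
  patients <- tibble::as_tibble(patients)
  need <- c("patient_id", "age", "sex")
  miss <- setdiff(need, names(patients))
  if (length(miss) > 0) abort(sprintf("`patients` lacks column(s): %s",
                                      paste(miss, collapse = ", ")))
  if (is.null(diagnoses)) {
    if (!"diagnosis_codes" %in% names(patients)) {
      abort("Provide `diagnoses` or a `diagnosis_codes` list-column.")
    }
    code_sets <- patients$diagnosis_codes
  } else {
    diagnoses <- tibble::as_tibble(diagnoses)
    sets <- split(as.character(diagnoses$code),
                  factor(diagnoses$patient_id, levels = patients$patient_id))
    code_sets <- unname(sets)
  }

  # demographic component, vectorized over age bands
  if (!all(patients$sex %in% c("F", "M"))) abort("`sex` must be 'F' or 'M'.")
  if (any(patients$age < 0)) abort("`age` must be nonnegative.")
  dw <- model$demographic_weights
  demo <- numeric(nrow(patients))
  for (s in c("F", "M")) {
    b <- dw[dw$sex == s, ]
    b <- b[order(b$age_lo), ]
    sel <- patients$sex == s
    demo[sel] <- b$weight[findInterval(patients$age[sel], b$age_lo)]
  }

  # resolve each distinct code set once: panels have few distinct combinations
  keys <- vapply(code_sets, function(s) paste(sort(unique(as.character(s))), collapse = "\r"),
                 character(1))
  uk <- unique(keys)
  resolved <- lapply(uk, function(k) {
    codes <- if (nzchar(k)) strsplit(k, "\r", fixed = TRUE)[[1]] else character()
    ccs <- map_codes_to_ccs(codes, model)
    surv <- apply_hierarchies(ccs, model)
    list(weight = sum(model$cc_weights$weight[match(surv, model$cc_weights$cc)]),
         surv = surv, n_unmapped = attr(ccs, "n_unmapped"))
  })
  hit <- resolved[match(keys, uk)]
  n_unmapped <- sum(vapply(hit, `[[`, 0, "n_unmapped"))
  if (n_unmapped > 0) {
    inform(sprintf("score_patients: skipped %d unmapped diagnosis code(s).", n_unmapped))
  }
  tibble::tibble(
    patient_id = patients$patient_id,
    hcc_score = demo + vapply(hit, `[[`, 0, "weight"),
    surviving_ccs = lapply(hit, `[[`, "surv"))
}
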