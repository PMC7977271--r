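#' Construct a hierarchical-condition-category risk model
#'
#' An HCC-style model maps diagnosis codes to condition categories, applies
#' hierarchy rules in which a dominant (more severe) category suppresses a
#' set of milder related categories, and sums nonnegative weights for the
#' surviving categories on top of an age-sex demographic weight.
#'
#' @param code_to_cc Data frame with columns `code`, `cc`: each diagnosis
#'   code maps to at most one condition category.
#' @param hierarchies Data frame with columns `dominant_cc`, `suppressed_cc`
#'   (one pair per row). May have zero rows. The implied graph must be
#'   acyclic.
#' @param cc_weights Data frame with columns `cc`, `weight` (weights >= 0).
#'   Every category referenced by `code_to_cc` or `hierarchies` must appear
#'   here.
#' @param demographic_weights Data frame with columns `sex` ("F"/"M"),
#'   `age_lo`, `age_hi`, `weight`. For each sex the half-open age bands
#'   `[age_lo, age_hi)` must be disjoint and cover `[0, Inf)`.
#' @return An object of class `hcc_model`.
#' @seealso [load_hcc_model()], [toy_hcc_model()], [score_patients()]
#' @export
hcc_model <- function(code_to_cc, hierarchies, cc_weights, demographic_weights) {
  code_to_cc <- tibble::as_tibble(code_to_cc)[, c("code", "cc")]
  hierarchies <- tibble::as_tibble(hierarchies)
  if (nrow(hierarchies) == 0) {
    hierarchies <- tibble::tibble(dominant_cc = character(), suppressed_cc = character())
  }
  hierarchies <- hierarchies[, c("dominant_cc", "suppressed_cc")]
  cc_weights <- tibble::as_tibble(cc_weights)[, c("cc", "weight")]
  demographic_weights <- tibble::as_tibble(demographic_weights)[
    , c("sex", "age_lo", "age_hi", "weight")]

  if (anyDuplicated(code_to_cc$code)) {
    dup <- unique(code_to_cc$code[duplicated(code_to_cc$code)])
    abort(sprintf("Diagnosis code(s) mapped more than once: %s",
                  paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(cc_weights$cc)) abort("Duplicate category rows in `cc_weights`.")
  if (any(cc_weights$weight < 0) || any(demographic_weights$weight < 0)) {
    abort("All model weights must be nonnegative.")
  }

  known <- cc_weights$cc
  refs <- unique(c(code_to_cc$cc, hierarchies$dominant_cc, hierarchies$suppressed_cc))
  missing_cc <- setdiff(refs, known)
  if (length(missing_cc) > 0) {
    abort(sprintf("Category(ies) without a coefficient: %s",
                  paste(missing_cc, collapse = ", ")))
  }
  check_hierarchy_acyclic(hierarchies)
  check_age_bands(demographic_weights)

  structure(
    list(code_to_cc = code_to_cc, hierarchies = hierarchies,
         cc_weights = cc_weights, demographic_weights = demographic_weights),
    class = "hcc_model")
}

# depth-first cycle detection on the dominance graph
check_hierarchy_acyclic <- function(hierarchies) {
  edges <- split(hierarchies$suppressed_cc, hierarchies$dominant_cc)
  state <- new.env(parent = emptyenv())
  visit <- function(node) {
    s <- state[[node]] %||% "unseen"
    if (s == "active") abort("Hierarchy rules contain a cycle.")
    if (s == "done") return(invisible())
    state[[node]] <- "active"
    for (child in edges[[node]] %||% character()) visit(child)
    state[[node]] <- "done"
  }
  for (node in names(edges)) visit(node)
  invisible(hierarchies)
}

check_age_bands <- function(dw) {
  if (!all(dw$sex %in% c("F", "M"))) abort("`sex` must be 'F' or 'M'.")
  for (s in c("F", "M")) {
    b <- dw[dw$sex == s, ]
    if (nrow(b) == 0) abort(sprintf("No age bands for sex '%s'.", s))
    b <- b[order(b$age_lo), ]
    if (any(b$age_hi <= b$age_lo)) abort("Age bands must satisfy lo < hi.")
    if (b$age_lo[1] != 0 || !is.infinite(b$age_hi[nrow(b)]) ||
        (nrow(b) > 1 && any(b$age_lo[-1] != b$age_hi[-nrow(b)]))) {
      abort(sprintf(
        "Age bands for sex '%s' must be disjoint half-open intervals covering [0, Inf).", s))
    }
  }
  invisible(dw)
}

#' Load an HCC-style model from its three CSV files
#'
#' @param map_file CSV with columns `code`, `cc`.
#' @param hierarchy_file CSV with columns `dominant_cc`, `suppressed_cc`.
#' @param coef_file CSV with columns `kind` (`cc` or `demo`), `key1`, `key2`,
#'   `weight`. For `cc` rows `key1` is the category and `key2` is empty; for
#'   `demo` rows `key1` is the sex and `key2` the age band written `"lo-hi"`
#'   (the last band uses `Inf`, e.g. `"85-Inf"`).
#' @return An [hcc_model()].
#' @export
load_hcc_model <- function(map_file, hierarchy_file, coef_file) {
  map <- readr::read_csv(map_file, col_types = readr::cols(.default = "c"))
  hier <- readr::read_csv(hierarchy_file, col_types = readr::cols(.default = "c"))
  coef <- readr::read_csv(coef_file, col_types = readr::cols(
    kind = "c", key1 = "c", key2 = "c", weight = "d"))
  if (!all(coef$kind %in% c("cc", "demo"))) {
    abort("`kind` column of the coefficient file must be 'cc' or 'demo'.")
  }
  cc_rows <- coef[coef$kind == "cc", ]
  demo_rows <- coef[coef$kind == "demo", ]
  bands <- strsplit(demo_rows$key2, "-", fixed = TRUE)
  if (any(lengths(bands) != 2)) abort("Demo age bands must be written 'lo-hi'.")
  demographic_weights <- tibble::tibble(
    sex = demo_rows$key1,
    age_lo = as.numeric(vapply(bands, `[`, "", 1L)),
    age_hi = as.numeric(vapply(bands, `[`, "", 2L)),
    weight = demo_rows$weight)
  hcc_model(
    code_to_cc = map,
    hierarchies = hier,
    cc_weights = tibble::tibble(cc = cc_rows$key1, weight = cc_rows$weight),
    demographic_weights = demographic_weights)
}

#' The packaged toy HCC model
#'
#' A small, licensing-free model in the same file format as user-supplied
#' models: 8 condition categories over a toy diagnosis vocabulary, three
#' dominance rules (complicated diabetes over diabetes, metastatic cancer
#' over neoplasm, heart failure over coronary disease), and age-sex
#' demographic weights. Its weights are calibrated so that, on the default
#' synthetic population, the score distribution has a median near 0.60 with
#' an interquartile range near (0.28, 0.80).
#'
#' @return An [hcc_model()].
#' @export
toy_hcc_model <- function() {
  dir <- system.file("extdata", "toy_hcc", package = "riskstrat", mustWork = TRUE)
  load_hcc_model(file.path(dir, "map.csv"),
                 file.path(dir, "hierarchy.csv"),
                 file.path(dir, "coef.csv"))
}

#' @export
print.hcc_model <- function(x, ...) {
  cat("<hcc_model>\n")
  cat(sprintf("  %d diagnosis codes -> %d condition categories\n",
              nrow(x$code_to_cc), nrow(x$cc_weights)))
  cat(sprintf("  %d hierarchy rule(s); %d demographic cells\n",
              nrow(x$hierarchies), nrow(x$demographic_weights)))
  invisible(x)
}
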