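# Small hand-built model used across tests: two diabetes categories under a
# dominance rule, one independent category, and two age bands per sex.
tiny_model <- function(hierarchies = data.frame(dominant_cc = "CC_DIAB_COMP",
                                                suppressed_cc = "CC_DIAB")) {
  hcc_model(
    code_to_cc = data.frame(code = c("DM2", "DM1", "DMC", "CHF"),
                            cc = c("CC_DIAB", "CC_DIAB", "CC_DIAB_COMP", "CC_CHF")),
    hierarchies = hierarchies,
    cc_weights = data.frame(cc = c("CC_DIAB", "CC_DIAB_COMP", "CC_CHF"),
                            weight = c(0.30, 0.50, 0.40)),
    demographic_weights = data.frame(
      sex = rep(c("F", "M"), each = 2),
      age_lo = c(0, 65, 0, 65), age_hi = c(65, Inf, 65, Inf),
      weight = c(0.20, 0.40, 0.18, 0.38)))
}

# write a three-file model directory for loader tests
write_model_dir <- function(dir, map, hier, coef) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(map, file.path(dir, "map.csv"), row.names = FALSE)
  utils::write.csv(hier, file.path(dir, "hierarchy.csv"), row.names = FALSE)
  utils::write.csv(coef, file.path(dir, "coef.csv"), row.names = FALSE)
  dir
}

# independent fixpoint oracle for hierarchy suppression: every rule whose
# dominant category is present at the start of a round marks its suppressed
# category; marked categories drop together, then the round repeats
oracle_suppress <- function(ccs, rules) {
  repeat {
    marked <- character()
    for (i in seq_len(nrow(rules))) {
      if (rules$dominant_cc[i] %in% ccs && rules$suppressed_cc[i] %in% ccs) {
        marked <- c(marked, rules$suppressed_cc[i])
      }
    }
    if (length(marked) == 0) return(sort(ccs))
    ccs <- ccs[!ccs %in% marked]
  }
}

# direct-formula kappa from raw logical vectors (independent of the
# concordance_table route)
oracle_kappa <- function(a, b) {
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  (po - pe) / (1 - pe)
}

# small fast generator config for pipeline-level tests
quick_config <- function(n = 1500, seed = 42, ...) {
  generator_config(n_patients = n, seed = seed, ...)
}
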