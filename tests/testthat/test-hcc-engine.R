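test_that("a well-formed three-file model round-trips through the loader", {
  dir <- write_model_dir(
    withr::local_tempdir(),
    map = data.frame(code = c("DM2", "DMC"), cc = c("CC_DIAB", "CC_DIAB_COMP")),
    hier = data.frame(dominant_cc = "CC_DIAB_COMP", suppressed_cc = "CC_DIAB"),
    coef = data.frame(
      kind = c("cc", "cc", "demo", "demo", "demo", "demo"),
      key1 = c("CC_DIAB", "CC_DIAB_COMP", "F", "F", "M", "M"),
      key2 = c("", "", "0-65", "65-Inf", "0-65", "65-Inf"),
      weight = c(0.3, 0.5, 0.2, 0.4, 0.18, 0.38)))
  m <- load_hcc_model(file.path(dir, "map.csv"), file.path(dir, "hierarchy.csv"),
                      file.path(dir, "coef.csv"))
  expect_s3_class(m, "hcc_model")
  expect_equal(nrow(m$cc_weights), 2)
  expect_equal(nrow(m$demographic_weights), 4)
  expect_true(is.infinite(m$demographic_weights$age_hi[2]))
})

test_that("model validation rejects broken inputs", {
  base_map <- data.frame(code = "DM2", cc = "CC_DIAB")
  base_cw <- data.frame(cc = "CC_DIAB", weight = 0.3)
  base_dw <- data.frame(sex = c("F", "M"), age_lo = 0, age_hi = Inf, weight = 0.2)

  # hierarchy referencing a category with no coefficient
  expect_error(
    hcc_model(base_map,
              data.frame(dominant_cc = "CC_GHOST", suppressed_cc = "CC_DIAB"),
              base_cw, base_dw),
    "without a coefficient")
  # one code mapped to two categories
  expect_error(
    hcc_model(data.frame(code = c("DM2", "DM2"), cc = c("CC_DIAB", "CC_OTHER")),
              data.frame(dominant_cc = character(), suppressed_cc = character()),
              data.frame(cc = c("CC_DIAB", "CC_OTHER"), weight = c(0.3, 0.2)),
              base_dw),
    "mapped more than once")
  # cyclic dominance
  expect_error(
    hcc_model(base_map,
              data.frame(dominant_cc = c("CC_DIAB", "CC_B"),
                         suppressed_cc = c("CC_B", "CC_DIAB")),
              data.frame(cc = c("CC_DIAB", "CC_B"), weight = c(0.3, 0.2)),
              base_dw),
    "cycle")
  # age bands with a gap
  expect_error(
    hcc_model(base_map,
              data.frame(dominant_cc = character(), suppressed_cc = character()),
              base_cw,
              data.frame(sex = c("F", "F", "M"), age_lo = c(0, 70, 0),
                         age_hi = c(65, Inf, Inf), weight = 0.2)),
    "covering")
  # negative weight
  expect_error(
    hcc_model(base_map,
              data.frame(dominant_cc = character(), suppressed_cc = character()),
              data.frame(cc = "CC_DIAB", weight = -0.1), base_dw),
    "nonnegative")
})

test_that("code mapping has set semantics and skips unmapped codes", {
  m <- tiny_model()
  expect_identical(as.character(map_codes_to_ccs(character(), m)), character(0))
  one <- map_codes_to_ccs(c("DM2", "DM2"), m)
  expect_identical(as.character(one), "CC_DIAB")
  mixed <- map_codes_to_ccs(c("DM2", "UNKNOWN_CODE"), m)
  expect_identical(as.character(mixed), "CC_DIAB")
  expect_equal(attr(mixed, "n_unmapped"), 1)
})

test_that("hierarchy suppression reaches a fixpoint through rule chains", {
  m <- tiny_model()
  expect_identical(apply_hierarchies(character(), m), character(0))
  expect_identical(apply_hierarchies(c("CC_DIAB_COMP", "CC_DIAB"), m), "CC_DIAB_COMP")
  # chain A > B, B > C collapses {A, B, C} to {A}
  chain <- hcc_model(
    code_to_cc = data.frame(code = c("a", "b", "c"), cc = c("A", "B", "C")),
    hierarchies = data.frame(dominant_cc = c("A", "B"), suppressed_cc = c("B", "C")),
    cc_weights = data.frame(cc = c("A", "B", "C"), weight = c(1, 1, 1)),
    demographic_weights = data.frame(sex = c("F", "M"), age_lo = 0,
                                     age_hi = Inf, weight = 0))
  expect_identical(apply_hierarchies(c("A", "B", "C"), chain), "A")
  expect_setequal(apply_hierarchies(c("B", "C"), chain), "B")
})

test_that("hierarchy suppression agrees with the brute-force oracle on all subsets", {
  cats <- c("A", "B", "C", "D", "E", "F")
  rules <- data.frame(dominant_cc = c("A", "B", "D", "E"),
                      suppressed_cc = c("B", "C", "C", "F"))
  m <- hcc_model(
    code_to_cc = data.frame(code = tolower(cats), cc = cats),
    hierarchies = rules,
    cc_weights = data.frame(cc = cats, weight = 0.1),
    demographic_weights = data.frame(sex = c("F", "M"), age_lo = 0,
                                     age_hi = Inf, weight = 0))
  for (mask in 0:(2^6 - 1)) {
    subset <- cats[bitwAnd(mask, 2^(0:5)) > 0]
    expect_identical(sort(apply_hierarchies(subset, m)),
                     oracle_suppress(subset, rules))
  }
})

test_that("single-patient scores follow the demographic + surviving-category sum", {
  m <- tiny_model()
  # demographic-only patient
  expect_equal(hcc_score(70, "F", character(), m)$score, 0.40)
  # dominance removes the milder diabetes weight: 0.40 + 0.50
  both <- hcc_score(70, "F", c("DM2", "DMC"), m)
  expect_equal(both$score, 0.90)
  expect_identical(both$surviving_ccs, "CC_DIAB_COMP")
  # without the rule both categories contribute: 0.40 + 0.30 + 0.50
  no_rule <- tiny_model(hierarchies = data.frame(dominant_cc = character(),
                                                 suppressed_cc = character()))
  expect_equal(hcc_score(70, "F", c("DM2", "DMC"), no_rule)$score, 1.20)
})

test_that("scores are monotone in codes and hierarchies only reduce them", {
  m <- tiny_model()
  no_rule <- tiny_model(hierarchies = data.frame(dominant_cc = character(),
                                                 suppressed_cc = character()))
  codes_pool <- c("DM2", "DM1", "DMC", "CHF", "JUNK1", "JUNK2")
  set.seed(11)
  for (i in 1:50) {
    codes <- sample(codes_pool, sample(0:5, 1))
    extra <- sample(setdiff(codes_pool, codes), 1)
    age <- runif(1, 20, 95); sex <- sample(c("F", "M"), 1)
    s0 <- hcc_score(age, sex, codes, m)$score
    s1 <- hcc_score(age, sex, c(codes, extra), m)$score
    w_extra <- {
      cc <- as.character(map_codes_to_ccs(extra, m))
      if (length(cc) == 0) 0 else m$cc_weights$weight[match(cc, m$cc_weights$cc)]
    }
    expect_gte(s1 + 1e-12, s0)                # adding a code never lowers a score
    expect_lte(s1, s0 + w_extra + 1e-12)      # and adds at most its own weight
    expect_lte(s0, hcc_score(age, sex, codes, no_rule)$score + 1e-12)
  }
})

test_that("panel scoring matches the single-patient path and input order", {
  m <- tiny_model()
  patients <- tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    age = c(70, 40, 80), sex = c("F", "M", "M"),
    diagnosis_codes = list(c("DM2", "DMC"), character(), c("CHF", "NOPE")))
  out <- suppressMessages(score_patients(patients, m))
  expect_identical(out$patient_id, patients$patient_id)
  expect_equal(out$hcc_score,
               c(hcc_score(70, "F", c("DM2", "DMC"), m)$score,
                 hcc_score(40, "M", character(), m)$score,
                 hcc_score(80, "M", c("CHF", "NOPE"), m)$score))
  # long-format diagnoses give the same answer
  diag_long <- tibble::tibble(patient_id = c("p1", "p1", "p3", "p3"),
                              code = c("DM2", "DMC", "CHF", "NOPE"))
  out2 <- suppressMessages(
    score_patients(patients[, 1:3], m, diagnoses = diag_long))
  expect_equal(out2$hcc_score, out$hcc_score)
})
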