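test_that("confusion counts follow the flag/outcome cross-tabulation", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  t1 <- confusion(y, y)
  expect_equal(c(t1$fp, t1$fn), c(0, 0))
  t2 <- confusion(!y, y)
  expect_equal(c(t2$tp, t2$tn), c(0, 0))
  t3 <- confusion(rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 90, 70, 810)),
                  rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 90, 70, 810)))
  expect_equal(c(t3$tp, t3$fp, t3$fn, t3$tn), c(30, 90, 70, 810))
  expect_error(confusion(c(TRUE, FALSE), TRUE), "equal length")
})

test_that("diagnostic metrics follow their printed formulas", {
  m <- diagnostic_metrics(confusion_table(tp = 30, fp = 90, fn = 70, tn = 810))
  expect_equal(m$sensitivity, 0.30)
  expect_equal(m$ppv, 0.25)
  expect_equal(m$accuracy, 0.84)
  expect_equal(m$specificity, 810 / 900)
  expect_equal(m$npv, 810 / 880)
  all_right <- diagnostic_metrics(confusion_table(10, 0, 0, 20))
  expect_true(all(unlist(all_right) == 1))
  # zero denominators surface as NA, never as zero
  deg <- diagnostic_metrics(confusion_table(0, 0, 5, 95))
  expect_true(is.na(deg$ppv))
  expect_equal(deg$specificity, 1)
  expect_equal(deg$npv, 0.95)
})

test_that("metrics match closed forms on random confusion tables", {
  set.seed(17)
  for (i in 1:500) {
    cts <- rmultinom(1, sample(20:500, 1), runif(4, 0.05, 1))[, 1]
    t <- confusion_table(cts[1], cts[2], cts[3], cts[4])
    m <- diagnostic_metrics(t)
    ratio <- function(a, b) if (b == 0) NA_real_ else a / b
    expect_equal(m$sensitivity, ratio(cts[1], cts[1] + cts[3]))
    expect_equal(m$specificity, ratio(cts[4], cts[4] + cts[2]))
    expect_equal(m$ppv, ratio(cts[1], cts[1] + cts[2]))
    expect_equal(m$npv, ratio(cts[4], cts[4] + cts[3]))
    expect_equal(m$accuracy, sum(cts[c(1, 4)]) / sum(cts))
  }
})

test_that("the c-statistic is the tie-adjusted rank probability", {
  expect_equal(c_statistic(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(c_statistic(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  # enumerate the four positive-negative pairs by hand: two ties, one win, one loss
  expect_equal(c_statistic(c(1, 1, 2, 2), c(FALSE, TRUE, FALSE, TRUE)), 0.5)
  expect_warning(res <- c_statistic(1:4, rep(TRUE, 4)), "Both outcome classes")
  expect_true(is.na(res))
})

test_that("the c-statistic is invariant under strictly monotone transforms", {
  set.seed(23)
  score <- rlnorm(300)
  y <- runif(300) < plogis(log(score))
  base <- c_statistic(score, y)
  expect_equal(c_statistic(log(score), y), base)
  expect_equal(c_statistic(rank(score), y), base)
  expect_equal(c_statistic(score^3, y), base)
})

test_that("paired sensitivity comparison uses the discordant-pair exact test", {
  # identical flags: no discordance, p = 1
  y <- rep(TRUE, 50)
  f <- rep(c(TRUE, FALSE), 25)
  same <- compare_sensitivity_paired(f, f, y)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
  # 100 positives: a flags 40, b flags 30, both 25 -> discordant 15 vs 5
  outcome <- rep(TRUE, 100)
  a <- rep(c(TRUE, TRUE, FALSE, FALSE), c(25, 15, 5, 55))
  b <- rep(c(TRUE, FALSE, TRUE, FALSE), c(25, 15, 5, 55))
  cmp <- compare_sensitivity_paired(a, b, outcome)
  expect_equal(cmp$delta, 0.10)
  expect_equal(cmp$p_value, 0.0413894653, tolerance = 1e-8)
  expect_match(cmp$method, "exact")
  # outcome-negative rows must not influence the test
  cmp2 <- compare_sensitivity_paired(c(a, TRUE, FALSE), c(b, FALSE, TRUE),
                                     c(outcome, FALSE, FALSE))
  expect_equal(cmp2$p_value, cmp$p_value)
  expect_warning(res <- compare_sensitivity_paired(a, b, rep(FALSE, 100)),
                 "No outcome-positive")
  expect_true(is.na(res$p_value))
})

test_that("the exact paired test reproduces exact McNemar for all small discordant splits", {
  for (m in 1:20) {
    for (b_cnt in 0:m) {
      a_cnt <- m - b_cnt
      # positives only: 3 flagged by both, 2 by neither, plus the discordant split
      fa <- rep(c(TRUE, TRUE, FALSE, FALSE), c(3, a_cnt, b_cnt, 2))
      fb <- rep(c(TRUE, FALSE, TRUE, FALSE), c(3, a_cnt, b_cnt, 2))
      y <- rep(TRUE, length(fa))
      p <- compare_sensitivity_paired(fa, fb, y)$p_value
      expect_equal(p, stats::binom.test(a_cnt, m, 0.5)$p.value, tolerance = 1e-12)
    }
  }
})

test_that("paired PPV comparison estimates the relative PPV with overlap-aware variance", {
  y <- rep(TRUE, 10)
  f <- rep(c(TRUE, FALSE), 5)
  same <- compare_ppv_paired(f, f, y)
  expect_equal(same$ratio, 1)
  expect_equal(same$p_value, 1)
  # a: 50 calls, 20 true (PPV .40); b: 40 calls, 10 true (PPV .25)
  cells <- tibble::tribble(
    ~a, ~b, ~d, ~n,
    TRUE,  TRUE,  TRUE,   7,
    TRUE,  TRUE,  FALSE, 18,
    TRUE,  FALSE, TRUE,  13,
    TRUE,  FALSE, FALSE, 12,
    FALSE, TRUE,  TRUE,   3,
    FALSE, TRUE,  FALSE, 12,
    FALSE, FALSE, TRUE,  20,
    FALSE, FALSE, FALSE, 415)
  fa <- rep(cells$a, cells$n); fb <- rep(cells$b, cells$n); y2 <- rep(cells$d, cells$n)
  cmp <- compare_ppv_paired(fa, fb, y2)
  expect_equal(cmp$estimate_a, 0.40)
  expect_equal(cmp$estimate_b, 0.25)
  expect_equal(cmp$ratio, 1.6)
  # paired nonparametric bootstrap oracle on the same subjects, at a cohort
  # size where both flags have enough true calls for the asymptotics
  fa <- rep(fa, 3); fb <- rep(fb, 3); y2 <- rep(y2, 3)
  cmp <- compare_ppv_paired(fa, fb, y2)
  set.seed(1234)
  n <- length(fa)
  boot <- replicate(4000, {
    i <- sample.int(n, n, replace = TRUE)
    na <- sum(fa[i]); nb <- sum(fb[i])
    nad <- sum(fa[i] & y2[i]); nbd <- sum(fb[i] & y2[i])
    if (na == 0 || nb == 0 || nad == 0 || nbd == 0) NA_real_
    else log((nad / na) / (nbd / nb))
  })
  p_boot <- 2 * pnorm(-abs(log(cmp$ratio)) / stats::sd(boot, na.rm = TRUE))
  expect_lt(abs(cmp$p_value - p_boot), 0.02)
  expect_warning(zero <- compare_ppv_paired(rep(FALSE, 10), f, y), "zero positive")
  expect_true(is.na(zero$p_value))
})

test_that("stratified summaries carry metrics, deltas and paired p-values per stratum", {
  set.seed(31)
  n <- 600
  lat <- rnorm(n)
  d <- tibble::tibble(
    stratum = rep(c("adjudication", "intuition"), each = n / 2),
    practice_high = runif(n) < plogis(lat + ifelse(stratum == "adjudication", 1, -1.5)),
    hcc_high = runif(n) < plogis(lat),
    high_ed = runif(n) < plogis(lat - 1),
    high_hosp = runif(n) < plogis(lat - 1.2),
    high_expend = runif(n) < plogis(lat - 1.5))
  s <- stratified_summary(d, stratum_col = "stratum")
  expect_equal(nrow(s), 2 * 3 * 5)  # strata x outcomes x metrics
  expect_equal(s$delta, s$practice - s$hcc)
  expect_true(all(!is.na(s$p_value[s$metric %in% c("sensitivity", "ppv")])))
  expect_true(all(is.na(s$p_value[s$metric == "accuracy"])))
  # identical flags give all-zero deltas
  d2 <- d; d2$practice_high <- d2$hcc_high
  s2 <- stratified_summary(d2, stratum_col = "stratum")
  expect_true(all(s2$delta == 0))
  expect_true(all(s2$p_value[!is.na(s2$p_value)] == 1))
  # across-strata averages match direct means
  acr <- across_strata(s)
  row <- acr[acr$outcome == "ed" & acr$metric == "sensitivity", ]
  expect_equal(row$practice_mean,
               mean(s$practice[s$outcome == "ed" & s$metric == "sensitivity"]))
  expect_equal(row$practice_min,
               min(s$practice[s$outcome == "ed" & s$metric == "sensitivity"]))
})

test_that("empty strata are flagged, not dropped", {
  d <- tibble::tibble(
    stratum = character(0), practice_high = logical(0), hcc_high = logical(0),
    high_ed = logical(0), high_hosp = logical(0), high_expend = logical(0))
  d1 <- tibble::tibble(
    stratum = "solo", practice_high = TRUE, hcc_high = TRUE,
    high_ed = TRUE, high_hosp = FALSE, high_expend = FALSE)
  s <- stratified_summary(dplyr::bind_rows(d1, d), stratum_col = "stratum")
  expect_equal(unique(s$stratum), "solo")
  expect_true(all(!s$empty))
})

test_that("mean delta difference averages over outcomes and is antisymmetric", {
  summary <- tibble::tibble(
    stratum = rep(c("adjudication", "intuition"), each = 3),
    outcome = rep(c("ed", "hosp", "expend"), 2),
    metric = "sensitivity",
    delta = c(0.03, -0.09, -0.09, -0.18, -0.17, -0.27))
  d <- mean_delta_difference(summary, "sensitivity", "adjudication", "intuition")
  expect_equal(d, mean(c(0.03, -0.09, -0.09)) - mean(c(-0.18, -0.17, -0.27)))
  expect_equal(mean_delta_difference(summary, "sensitivity", "intuition",
                                     "adjudication"), -d)
  expect_equal(mean_delta_difference(summary, "sensitivity", "adjudication",
                                     "adjudication"), 0)
  expect_error(mean_delta_difference(summary, "ppv", "adjudication", "intuition"),
               "lacks complete")
})
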