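# Median/IQR summaries, percentage variation, normality-gated paired tests,
# follow-up regression, and the report builder.

test_that("median and IQR follow the linear-interpolation convention", {
  expect_equal(median_iqr(c(1, 2, 3)), c(median = 2, iqr = 1))
  expect_equal(median_iqr(c(1, 2, 3, 4)),
               c(median = 2.5, iqr = 3.25 - 1.75))
  expect_equal(unname(median_iqr(rep(7, 10))["iqr"]), 0)
  expect_error(median_iqr(numeric(0)), "no values")
})

test_that("percentage variation is signed with the stated baseline", {
  expect_equal(pct_variation(291.14, 280.95), 3.5, tolerance = 0.005)
  expect_equal(pct_variation(0.027, 0.05), -85.19, tolerance = 0.005)
  expect_equal(pct_variation(5, 5), 0)
  expect_error(pct_variation(0, 1), "zero baseline")
  # antisymmetry up to the baseline change:
  # pct(a, b) = -pct(b, a) * (b / a)
  set.seed(12)
  a <- runif(20, 1, 10); b <- runif(20, 1, 10)
  expect_equal(pct_variation(a, b), -pct_variation(b, a) * (b / a),
               tolerance = 1e-12)
})

test_that("paired comparison picks the t-branch for a Gaussian shift", {
  set.seed(101)
  n <- 50
  b <- rnorm(n, 10, 1)
  a <- b + 2 + rnorm(n, 0, 0.3)
  cmp <- paired_compare(a, b)
  expect_equal(cmp$test_used, "paired_t")
  expect_lt(cmp$p_value, 0.05)
  expect_true(cmp$significant)
  expect_equal(cmp$n, n)
  expect_equal(cmp$pct_variation,
               pct_variation(median(a), median(b)), tolerance = 1e-12)
})

test_that("heavy-tailed differences route to the Wilcoxon branch", {
  set.seed(55)
  n <- 30
  b <- rnorm(n, 10, 0.1)
  contam <- ifelse(runif(n) < 0.2, 8, 0.05) * sample(c(-1, 1), n, TRUE)
  a <- b + contam
  cmp <- paired_compare(a, b)
  expect_equal(cmp$test_used, "wilcoxon")
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
})

test_that("degenerate paired inputs are handled", {
  x <- c(1, 2, 3, 4, 5)
  expect_warning(res <- paired_compare(x, x), "zero")
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  expect_error(paired_compare(1:2, 2:3), "at least 3")
  # constant non-zero shift: difference certain
  res2 <- paired_compare(x + 1, x)
  expect_true(res2$significant)
})

test_that("paired comparison is invariant to patient ordering and common shifts", {
  set.seed(77)
  a <- rlnorm(20, 2, 0.3); b <- a * exp(rnorm(20, 0.1, 0.2))
  base <- paired_compare(a, b)
  perm <- sample(20)
  expect_equal(paired_compare(a[perm], b[perm])$p_value, base$p_value)
  # additive shift and positive scaling of both samples preserve the
  # wilcoxon p when that branch is taken, and the t p exactly
  shifted <- paired_compare(a + 5, b + 5)
  expect_equal(shifted$p_value, base$p_value, tolerance = 1e-9)
  scaled <- paired_compare(a * 3, b * 3)
  expect_equal(scaled$p_value, base$p_value, tolerance = 1e-9)
})

test_that("follow-up regression returns slope, R2 and p", {
  x <- c(3, 6, 9, 12, 15)
  fit <- suppressWarnings(fu_regression(x, 2 * x))  # perfect fit
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  set.seed(9)
  fit2 <- fu_regression(rnorm(9, 8, 3), rnorm(9))
  expect_true(fit2$p_value > 0 && fit2$p_value <= 1)
  expect_error(fu_regression(rep(8, 5), rnorm(5)), "constant")
  # null simulation: mean R^2 ~ 1/(n-1)
  set.seed(10)
  r2 <- replicate(400, fu_regression(rnorm(9), rnorm(9))$r_squared)
  expect_lt(abs(mean(r2) - 1 / 8), 0.03)
})

test_that("results report reproduces cell summaries and comparisons", {
  cells <- reference_cohort_summary()
  tab <- sample_cohort(cohort_spec(cells, n_patients = 9, seed = 5))
  rep <- build_results_report(tab)
  # calibrated cohort: summary medians equal the cells exactly
  s <- rep$summary
  row <- s[s$metric == "length" & s$timepoint == "PRE" &
             s$segment == "SFA" & s$configuration == "straight", ]
  expect_equal(row$median, 291.14, tolerance = 1e-9)
  expect_equal(row$iqr, 47.81, tolerance = 1e-9)
  # decomposition grid present for PA
  expect_true(all(c("t_front", "t_lat") %in% rep$decomposition$metric))
  # straight-vs-bent and pre-vs-post comparisons both present
  expect_true(any(grepl("straight vs", rep$comparisons$comparison)))
  expect_true(any(grepl("PRE vs", rep$comparisons$comparison)))
  # percentage variations recomputable from the summary medians
  cmp <- rep$comparisons
  r <- cmp[cmp$metric == "length" & cmp$segment == "SFA" &
             cmp$comparison == "PRE.straight vs PRE.bent", ]
  expect_equal(r$pct_variation, pct_variation(r$median_a, r$median_b))
  expect_output(print(rep), "Paired comparisons")
})

test_that("missing cells are reported, not dropped", {
  cells <- reference_cohort_summary()
  tab <- sample_cohort(cohort_spec(cells, n_patients = 6, seed = 5))
  tab$length[tab$configuration == "bent" & tab$segment == "PA"] <- NA
  rep <- build_results_report(tab)
  expect_true(any(grepl("length PA", rep$missing_cells)))
})

test_that("single-patient-scale cohorts skip tests with a notice", {
  cells <- reference_cohort_summary()
  tab <- sample_cohort(cohort_spec(cells, n_patients = 3, seed = 2))
  tab <- tab[tab$patient_id == 1, ]
  rep <- build_results_report(tab)
  expect_true(all(is.na(rep$comparisons$p_value)))
  expect_true(length(rep$notes) > 0)
  expect_equal(rep$n_patients, 1)
})
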