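#' Median and interquartile range
#'
#' Quantiles use the linear-interpolation convention (R type 7, the common
#' spreadsheet/statistics default); at small n the IQR depends on this
#' choice, so it is fixed here.
#'
#' @param values numeric vector (length >= 1, NAs dropped).
#' @return named numeric vector `c(median = , iqr = )`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], iqr = q[3] - q[1])
}

#' Percentage variation between two medians
#'
#' Signed percentage change relative to the baseline:
#' `(a - b) / a * 100`, with `a` the baseline (straight-knee, or
#' pre-operative) median and `b` the comparison median. Positive values mean
#' the quantity decreased from baseline ("shortened by x%"), negative values
#' that it increased ("increase of |x|%"); the reporting layer renders the
#' magnitude together with the direction word.
#'
#' @param median_a baseline median (non-zero).
#' @param median_b comparison median.
#' @return signed percentage.
#' @export
pct_variation <- function(median_a, median_b) {
  if (any(median_a == 0)) stop("zero baseline median")
  (median_a - median_b) / median_a * 100
}

#' Normality-gated paired comparison
#'
#' The paired differences `a - b` are tested for normality with a
#' Kolmogorov-Smirnov-type test; if normality is not rejected at 0.05 the
#' paired t-test is used, otherwise the two-sided Wilcoxon signed-rank test.
#' The default normality variant is the Lilliefors-corrected KS test
#' (mean and SD estimated from the data); `normality = "ks"` uses the plain
#' KS test on standardized differences instead. Wilcoxon handling: zero
#' differences are dropped before ranking, ties get midranks, the p-value is
#' exact for n <= 25 without ties and a normal approximation with continuity
#' correction otherwise.
#'
#' @param values_a,values_b paired measurements (same patients, same order).
#' @param alpha significance level for the final comparison (default 0.05).
#' @param labels optional `c(name_a, name_b)` labels.
#' @param normality `"lilliefors"` (default) or `"ks"`.
#' @return list of class `comparison_result`: `median_a`, `iqr_a`,
#'   `median_b`, `iqr_b`, `pct_variation` (baseline `a`), `test_used`
#'   (`"paired_t"` or `"wilcoxon"`), `p_value`, `significant`,
#'   `normality_p`, `n`.
#' @export
paired_compare <- function(values_a, values_b, alpha = 0.05,
                           labels = c("a", "b"),
                           normality = c("lilliefors", "ks")) {
  normality <- match.arg(normality)
  ok <- !is.na(values_a) & !is.na(values_b)
  a <- values_a[ok]; b <- values_b[ok]
  n <- length(a)
  if (n != length(b)) stop("paired samples must have equal length")
  if (n < 3) stop("need at least 3 pairs")
  d <- a - b
  ma <- median_iqr(a); mb <- median_iqr(b)
  if (all(d == 0)) {
    warning("all paired differences are zero; returning p = 1")
    res <- list(test_used = "wilcoxon", p_value = 1, normality_p = NA_real_)
  } else if (stats::sd(d) == 0) {
    # constant non-zero shift: normality test degenerate, t-test exact
    res <- list(test_used = "paired_t",
                p_value = 0, normality_p = NA_real_)
  } else {
    norm_p <- if (normality == "lilliefors") {
      nortest::lillie.test(d)$p.value
    } else {
      suppressWarnings(ks.test((d - mean(d)) / stats::sd(d), "pnorm")$p.value)
    }
    if (norm_p >= 0.05) {
      res <- list(test_used = "paired_t",
                  p_value = t.test(a, b, paired = TRUE)$p.value,
                  normality_p = norm_p)
    } else {
      n_nonzero <- sum(d != 0)
      exact <- n_nonzero <= 25 && !any(duplicated(abs(d[d != 0])))
      p <- suppressWarnings(
        wilcox.test(a, b, paired = TRUE, exact = exact, correct = TRUE)$p.value)
      res <- list(test_used = "wilcoxon", p_value = p, normality_p = norm_p)
    }
  }
  structure(c(list(median_a = unname(ma["median"]), iqr_a = unname(ma["iqr"]),
                   median_b = unname(mb["median"]), iqr_b = unname(mb["iqr"]),
                   pct_variation = pct_variation(unname(ma["median"]),
                                                 unname(mb["median"])),
                   labels = labels, n = n,
                   significant = res$p_value < alpha),
              res),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %.4g (IQR %.4g)  vs  %s: %.4g (IQR %.4g)\n",
              x$labels[1], x$median_a, x$iqr_a,
              x$labels[2], x$median_b, x$iqr_b))
  dir <- if (x$pct_variation >= 0) "decrease" else "increase"
  cat(sprintf("  %s of %.4g%%; %s p = %.4g%s\n",
              dir, abs(x$pct_variation), x$test_used, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Follow-up time regression check
#'
#' Ordinary least-squares regression of a measured variation on follow-up
#' time, used to verify that the observed geometric variations are not
#' driven by how long after treatment the follow-up scan was taken.
#'
#' @param fu_months follow-up times (months), non-constant, length >= 3.
#' @param variations per-patient variations of a parameter.
#' @return list with `slope`, `intercept`, `r_squared` and the two-sided
#'   slope `p_value`.
#' @export
fu_regression <- function(fu_months, variations) {
  if (length(fu_months) != length(variations)) stop("lengths differ")
  if (length(fu_months) < 3) stop("need at least 3 observations")
  if (stats::sd(fu_months) == 0) stop("constant follow-up time")
  fit <- lm(variations ~ fu_months)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]))
}

# ---- cohort-level reporting -------------------------------------------------

summary_grid <- function(records, metric_col) {
  keys <- unique(records[, c("timepoint", "configuration", "segment")])
  keys <- keys[order(keys$timepoint, keys$segment, keys$configuration), ]
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- records$timepoint == keys$timepoint[i] &
      records$configuration == keys$configuration[i] &
      records$segment == keys$segment[i]
    v <- records[[metric_col]][sel]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NULL)
    mi <- median_iqr(v)
    data.frame(keys[i, ], metric = metric_col, median = mi["median"],
               iqr = mi["iqr"], n = length(v), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Build the cohort results report
#'
#' Summarizes a cohort of morphometry records into (i) a median (IQR) grid
#' per (metric, timepoint, configuration, segment), (ii) the analogous grid
#' for the decomposed tortuosities T_Front/T_Lat, and (iii) the list of
#' paired comparisons: straight vs bent within each timepoint (baseline
#' straight) and PRE vs FU1 within each configuration (baseline PRE), each
#' with its percentage variation and normality-gated paired test. With fewer
#' than 3 patients the summaries are still produced but the tests are
#' skipped with a notice.
#'
#' @param records data.frame as produced by [sample_cohort()] or
#'   [run_measure()]: columns `patient_id`, `timepoint`, `configuration`,
#'   `segment`, `length`, `tortuosity`, `mean_diameter`, optionally
#'   `t_front`, `t_lat`.
#' @param alpha significance level.
#' @param normality normality-test variant, see [paired_compare()].
#' @return list of class `results_report` with `summary` (grid),
#'   `decomposition` (T_Front/T_Lat grid), `comparisons` (data.frame),
#'   `missing_cells` and `notes`.
#' @export
build_results_report <- function(records, alpha = 0.05,
                                 normality = c("lilliefors", "ks")) {
  normality <- match.arg(normality)
  if (nrow(records) == 0) stop("empty records table")
  metrics <- c("length", "tortuosity", "mean_diameter")
  grids <- do.call(rbind, lapply(metrics, function(m) summary_grid(records, m)))
  dec <- do.call(rbind, lapply(c("t_front", "t_lat"), function(m)
    if (m %in% names(records)) summary_grid(records, m)))
  notes <- character(0)
  n_pat <- length(unique(records$patient_id))

  # expected cells: both configurations per (timepoint, segment)
  keys <- unique(records[, c("timepoint", "segment")])
  missing_cells <- character(0)
  comparisons <- list()
  add_cmp <- function(metric, tp, seg, cfg_a, cfg_b, kind) {
    sel <- function(cfg, tpp) {
      r <- records[records$segment == seg & records$configuration == cfg &
                     records$timepoint == tpp, ]
      r <- r[order(r$patient_id), ]
      r
    }
    if (kind == "straight_vs_bent") {
      ra <- sel(cfg_a, tp); rb <- sel(cfg_b, tp)
      lab <- c(paste0(tp, ".straight"), paste0(tp, ".bent"))
    } else {
      ra <- sel(cfg_a, "PRE"); rb <- sel(cfg_a, "FU1")
      lab <- c(paste0(cfg_a, ".PRE"), paste0(cfg_a, ".FU1"))
    }
    common <- intersect(ra$patient_id, rb$patient_id)
    va <- ra[[metric]][match(common, ra$patient_id)]
    vb <- rb[[metric]][match(common, rb$patient_id)]
    ok <- !is.na(va) & !is.na(vb)
    va <- va[ok]; vb <- vb[ok]
    if (length(va) == 0) {
      missing_cells <<- c(missing_cells,
                          paste(metric, seg, paste(lab, collapse = " vs ")))
      return(NULL)
    }
    if (length(va) < 3) {
      notes <<- c(notes, sprintf(
        "%s %s %s: only %d pair(s); medians reported, test skipped",
        metric, seg, paste(lab, collapse = " vs "), length(va)))
      return(data.frame(metric = metric, segment = seg,
                        comparison = paste(lab, collapse = " vs "),
                        median_a = median_iqr(va)["median"],
                        median_b = median_iqr(vb)["median"],
                        pct_variation = pct_variation(median_iqr(va)["median"],
                                                      median_iqr(vb)["median"]),
                        test_used = NA, p_value = NA, significant = NA,
                        n = length(va), row.names = NULL))
    }
    cmp <- paired_compare(va, vb, alpha = alpha, labels = lab,
                          normality = normality)
    data.frame(metric = metric, segment = seg,
               comparison = paste(lab, collapse = " vs "),
               median_a = cmp$median_a, median_b = cmp$median_b,
               pct_variation = cmp$pct_variation, test_used = cmp$test_used,
               p_value = cmp$p_value, significant = cmp$significant,
               n = cmp$n, row.names = NULL)
  }
  all_metrics <- c(metrics, intersect(c("t_front", "t_lat"), names(records)))
  # a metric that is entirely absent for a segment (e.g. decomposition
  # columns for the SFA) is not applicable there, as opposed to missing
  applicable <- function(m, seg) any(!is.na(records[[m]][records$segment == seg]))
  for (m in all_metrics) {
    for (tp in unique(records$timepoint))
      for (seg in unique(records$segment))
        if (applicable(m, seg))
          comparisons[[length(comparisons) + 1L]] <-
            add_cmp(m, tp, seg, "straight", "bent", "straight_vs_bent")
    if (all(c("PRE", "FU1") %in% records$timepoint))
      for (cfg in unique(records$configuration))
        for (seg in unique(records$segment))
          if (applicable(m, seg))
            comparisons[[length(comparisons) + 1L]] <-
              add_cmp(m, NA, seg, cfg, cfg, "pre_vs_post")
  }
  comparisons <- do.call(rbind, comparisons)
  structure(list(summary = grids, decomposition = dec,
                 comparisons = comparisons,
                 missing_cells = missing_cells, notes = notes,
                 n_patients = n_pat),
            class = "results_report")
}

#' @export
print.results_report <- function(x, ...) {
  cat(sprintf("Cohort results report (%d patients)\n", x$n_patients))
  cat("\nSummary (median (IQR)):\n")
  s <- x$summary
  s$cell <- sprintf("%.4g (%.4g)", s$median, s$iqr)
  print(s[, c("metric", "timepoint", "segment", "configuration", "cell")],
        row.names = FALSE)
  if (!is.null(x$decomposition)) {
    cat("\nTortuosity decomposition (median (IQR)):\n")
    d <- x$decomposition
    d$cell <- sprintf("%.4g (%.4g)", d$median, d$iqr)
    print(d[, c("metric", "timepoint", "segment", "configuration", "cell")],
          row.names = FALSE)
  }
  if (!is.null(x$comparisons)) {
    cat("\nPaired comparisons:\n")
    cc <- x$comparisons
    cc$pct <- sprintf("%+.2f%%", -cc$pct_variation)
    cc$p <- ifelse(is.na(cc$p_value), "-",
                   ifelse(cc$p_value < 0.001, "<0.001",
                          sprintf("%.3f", cc$p_value)))
    print(cc[, c("metric", "segment", "comparison", "pct", "test_used", "p")],
          row.names = FALSE)
  }
  if (length(x$missing_cells))
    cat("\nMissing cells:", paste(x$missing_cells, collapse = "; "), "\n")
  if (length(x$notes)) cat("\nNotes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Percentage variations from a table of summary medians
#'
#' Convenience for the fixture path: given per-cell medians (no raw
#' patients), compute the straight-vs-bent percentage variation of every
#' (metric, timepoint, segment) with the straight-knee median as baseline.
#'
#' @param cells data.frame as [reference_cohort_summary()].
#' @return data.frame with `metric`, `timepoint`, `segment`,
#'   `median_straight`, `median_bent`, `pct_variation` (signed, baseline
#'   straight).
#' @export
summary_pct_variations <- function(cells = reference_cohort_summary()) {
  keys <- unique(cells[, c("metric", "timepoint", "segment")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- cells[cells$metric == keys$metric[i] &
                 cells$timepoint == keys$timepoint[i] &
                 cells$segment == keys$segment[i], ]
    ms <- sub$median[sub$configuration == "straight"]
    mb <- sub$median[sub$configuration == "bent"]
    if (length(ms) != 1 || length(mb) != 1) return(NULL)
    data.frame(keys[i, ], median_straight = ms, median_bent = mb,
               pct_variation = pct_variation(ms, mb), row.names = NULL)
  })
  do.call(rbind, out)
}
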