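# Diagnostic-accuracy metrics with Wald confidence intervals, the 2x2
# testing toolkit (Pearson / Yates / Fisher / exact-or-asymptotic McNemar)
# and the expected-frequency-driven test-selection rule.

#' Contingency table of a screen against pathology
#'
#' @param tp,fn,fp,tn non-negative integer counts (true positive, false
#'   negative, false positive, true negative).
#' @return list of class `"contingency_table"`.
#' @export
contingency_table <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("empty table")
  structure(as.list(counts), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  FP %d  TN %d  (n = %d)\n",
              x$tp, x$fn, x$fp, x$tn, x$tp + x$fn + x$fp + x$tn))
  invisible(x)
}

#' Tabulate a classified cohort against pathology
#'
#' Builds the TP/FN/FP/TN table for one system's screen labels on one
#' density stratum. Positive pathology is `"malignant"`.
#'
#' @param cohort classified cohort data frame (see [classify_cohort]) with
#'   `<system>_screen` and `pathology` columns.
#' @param system `"pnigars"` or `"lungrads"`.
#' @param stratum `"SN"`, `"PSN"`, `"GGN"` or `"all"`.
#' @return a [contingency_table].
#' @export
confusion <- function(cohort, system = c("pnigars", "lungrads"),
                      stratum = c("all", "SN", "PSN", "GGN")) {
  system <- match.arg(system)
  stratum <- match.arg(stratum)
  col <- if (system == "pnigars") "pni_screen" else "lungrads_screen"
  if (!col %in% names(cohort))
    stop("cohort has no ", col, " column; run classify_cohort() first")
  keep <- if (stratum == "all") rep(TRUE, nrow(cohort)) else cohort$density_type == stratum
  if (!any(keep)) stop("empty stratum: ", stratum)
  scr <- cohort[[col]][keep]
  mal <- cohort$pathology[keep] == "malignant"
  contingency_table(
    tp = sum(mal & scr == "positive"),
    fn = sum(mal & scr == "negative"),
    fp = sum(!mal & scr == "positive"),
    tn = sum(!mal & scr == "negative")
  )
}

#' Wald confidence interval for a proportion
#'
#' `p +/- z * sqrt(p (1 - p) / n)`, clipped to `[0, 1]`. Degenerate at
#' p = 0 or 1 (zero width), as is characteristic of the Wald interval.
#'
#' @param p observed proportion.
#' @param n denominator count (> 0).
#' @param level confidence level.
#' @return numeric vector `c(lo, hi)`.
#' @export
wald_ci <- function(p, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

.diag_prop <- function(num, den, level) {
  p <- num / den
  ci <- wald_ci(p, den, level)
  structure(list(estimate = p, ci_low = ci[1], ci_high = ci[2], n = den),
            class = "diag_prop")
}

#' @export
print.diag_prop <- function(x, ...) {
  cat(sprintf("%s%% (95%% CI %s-%s), n = %d\n", format_percent(x$estimate),
              format_percent(x$ci_low), format_percent(x$ci_high), x$n))
  invisible(x)
}

#' Sensitivity, specificity and agreement rate
#'
#' Point estimates with Wald confidence intervals. Sensitivity is
#' TP/(TP+FN), specificity TN/(FP+TN), agreement rate (TP+TN)/n - the
#' proportion of nodules whose screen result matches pathology.
#'
#' @param ct a [contingency_table].
#' @param level confidence level.
#' @return list with `estimate`, `ci_low`, `ci_high`, `n`.
#' @export
sensitivity <- function(ct, level = 0.95) {
  if (ct$tp + ct$fn == 0) stop("no malignant cases")
  .diag_prop(ct$tp, ct$tp + ct$fn, level)
}

#' @rdname sensitivity
#' @export
specificity <- function(ct, level = 0.95) {
  if (ct$fp + ct$tn == 0) stop("no benign cases")
  .diag_prop(ct$tn, ct$fp + ct$tn, level)
}

#' @rdname sensitivity
#' @export
agreement_rate <- function(ct, level = 0.95) {
  .diag_prop(ct$tp + ct$tn, ct$tp + ct$fn + ct$fp + ct$tn, level)
}

#' Round half away from zero
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values (ties go away from zero, unlike [round()]).
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Render a proportion as a one-decimal percentage
#'
#' Two-stage rendering: the proportion is first carried to four decimals,
#' then expressed as a percentage rounded to one decimal, half away from
#' zero (so 0.81047 renders as 81.1, via 0.8105). This is the display
#' convention used throughout the package's reports.
#'
#' @param p proportion in `[0, 1]`.
#' @return numeric percentage with one decimal.
#' @export
format_percent <- function(p) {
  round_half_up(round_half_up(p, 4) * 100, 1)
}

# ---- 2x2 hypothesis tests -------------------------------------------------

.as_fourfold <- function(t) {
  m <- matrix(as.numeric(t), nrow = 2, byrow = TRUE)
  if (any(m < 0)) stop("negative cell count")
  if (sum(m) == 0) stop("empty table")
  m
}

.test_result <- function(method, statistic, p_value) {
  structure(list(method = method, statistic = statistic, p_value = p_value),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  st <- if (is.na(x$statistic)) "" else sprintf("statistic = %.4g, ", x$statistic)
  cat(sprintf("%s: %sp = %.4g\n", x$method, st, x$p_value))
  invisible(x)
}

#' Pearson chi-square test on a fourfold table
#'
#' @param t 2x2 counts as `c(a, b, c, d)` (row-major) or a 2x2 matrix.
#' @return list with `method`, `statistic`, `p_value` (df = 1, two-sided).
#' @export
pearson_chi2 <- function(t) {
  m <- .as_fourfold(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) stop("zero margin")
  # small-expected-count warnings are the province of select_test()
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  .test_result("pearson", unname(res$statistic), res$p.value)
}

#' Yates continuity-corrected chi-square test
#'
#' Each term uses `(|obs - exp| - 0.5)^2 / exp`, with the correction capped
#' so a deviation under 0.5 contributes zero.
#'
#' @inheritParams pearson_chi2
#' @export
yates_chi2 <- function(t) {
  m <- .as_fourfold(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) stop("zero margin")
  res <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  .test_result("yates", unname(res$statistic), res$p.value)
}

#' Fisher's exact probability test
#'
#' Two-sided p-value by the probability method: the sum of hypergeometric
#' probabilities, over tables with the observed margins, of all tables no
#' more probable than the observed one.
#'
#' @inheritParams pearson_chi2
#' @export
fisher_exact <- function(t) {
  m <- .as_fourfold(t)
  res <- stats::fisher.test(m)
  .test_result("fisher", NA_real_, res$p.value)
}

#' McNemar test on discordant pairs
#'
#' For paired screens, `b` and `c` are the two discordant counts. With
#' `b + c >= 25` the asymptotic chi-square statistic `(b - c)^2 / (b + c)`
#' (df = 1, no continuity correction) is used; with fewer discordant pairs
#' the exact two-sided binomial test on `min(b, c)` of `b + c` trials at
#' probability one half. `b = c = 0` gives p = 1.
#'
#' @param b,c discordant counts.
#' @return list with `method`, `statistic`, `p_value`.
#' @export
mcnemar_test <- function(b, c) {
  n <- b + c
  if (n == 0) return(.test_result("mcnemar", 0, 1))
  if (n >= 25) {
    stat <- (b - c)^2 / n
    .test_result("mcnemar", stat, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  } else {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    .test_result("mcnemar_exact", NA_real_, p)
  }
}

#' Choose the test for a fourfold table
#'
#' Rule driven by sample size and the minimum expected (theoretical)
#' frequency T = row margin x column margin / n: Fisher's exact method when
#' n < 40 or T < 1; Yates' correction when n >= 40 and 1 < T < 5; the plain
#' Pearson chi-square otherwise.
#'
#' @inheritParams pearson_chi2
#' @return `"fisher"`, `"yates"` or `"pearson"`.
#' @export
select_test <- function(t) {
  m <- .as_fourfold(t)
  n <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / n
  min_e <- min(expected)
  if (n < 40 || min_e < 1) "fisher"
  else if (min_e > 1 && min_e < 5) "yates"
  else "pearson"
}

#' Run the selected test
#'
#' Applies [select_test()] and dispatches to the corresponding test.
#'
#' @inheritParams pearson_chi2
#' @export
auto_test <- function(t) {
  switch(select_test(t),
         fisher = fisher_exact(t),
         yates = yates_chi2(t),
         pearson = pearson_chi2(t))
}

# ---- system comparison ----------------------------------------------------

#' Compare the two systems on a classified cohort
#'
#' Per stratum (SN, PSN, GGN and the pooled total) and per system, builds
#' the confusion table and the sensitivity / specificity / agreement-rate
#' summaries, then compares the systems: paired McNemar tests on
#' sensitivity (among malignant nodules) and specificity (among benign),
#' and a test on the agreement rates chosen by the expected-frequency rule.
#'
#' @param cohort classified cohort (see [classify_cohort]) carrying both
#'   systems' screen columns.
#' @param level confidence level for the intervals.
#' @return list of class `"system_comparison"`: `summary`, a data frame
#'   with one row per stratum x system (counts, estimates and one-decimal
#'   percentages), and `tests`, a data frame of the between-system tests.
#' @export
compare_systems <- function(cohort, level = 0.95) {
  need <- c("pni_screen", "lungrads_screen", "pathology", "density_type")
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  strata <- c("SN", "PSN", "GGN", "all")
  systems <- c(lungrads = "Lung-RADS", pnigars = "PNI-GARS")
  rows <- list()
  tests <- list()
  for (st in strata) {
    present <- if (st == "all") nrow(cohort) > 0 else any(cohort$density_type == st)
    if (!present) next
    for (sys in names(systems)) {
      ct <- confusion(cohort, system = sys, stratum = st)
      se <- if (ct$tp + ct$fn > 0) sensitivity(ct, level) else NULL
      sp <- if (ct$fp + ct$tn > 0) specificity(ct, level) else NULL
      ar <- agreement_rate(ct, level)
      fmt <- function(x, f) if (is.null(x)) NA_real_ else f(x)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, system = systems[[sys]],
        tp = ct$tp, fn = ct$fn, fp = ct$fp, tn = ct$tn,
        se = fmt(se, function(x) x$estimate),
        se_pct = fmt(se, function(x) format_percent(x$estimate)),
        se_lo_pct = fmt(se, function(x) format_percent(x$ci_low)),
        se_hi_pct = fmt(se, function(x) format_percent(x$ci_high)),
        sp = fmt(sp, function(x) x$estimate),
        sp_pct = fmt(sp, function(x) format_percent(x$estimate)),
        sp_lo_pct = fmt(sp, function(x) format_percent(x$ci_low)),
        sp_hi_pct = fmt(sp, function(x) format_percent(x$ci_high)),
        ar = ar$estimate,
        ar_pct = format_percent(ar$estimate),
        ar_lo_pct = format_percent(ar$ci_low),
        ar_hi_pct = format_percent(ar$ci_high),
        row.names = NULL
      )
    }
    keep <- if (st == "all") rep(TRUE, nrow(cohort)) else cohort$density_type == st
    sub <- cohort[keep, ]
    mal <- sub$pathology == "malignant"
    # paired sensitivity: discordant malignant nodules
    b_se <- sum(mal & sub$pni_screen == "positive" & sub$lungrads_screen == "negative")
    c_se <- sum(mal & sub$pni_screen == "negative" & sub$lungrads_screen == "positive")
    t_se <- mcnemar_test(b_se, c_se)
    # paired specificity: discordant benign nodules (correct = negative)
    b_sp <- sum(!mal & sub$pni_screen == "negative" & sub$lungrads_screen == "positive")
    c_sp <- sum(!mal & sub$pni_screen == "positive" & sub$lungrads_screen == "negative")
    t_sp <- mcnemar_test(b_sp, c_sp)
    # agreement rate: system x correct/incorrect, test chosen by the T rule
    pni_ok <- sum((sub$pni_screen == "positive") == mal)
    lung_ok <- sum((sub$lungrads_screen == "positive") == mal)
    ar_tab <- c(pni_ok, nrow(sub) - pni_ok, lung_ok, nrow(sub) - lung_ok)
    t_ar <- if (any(colSums(.as_fourfold(ar_tab)) == 0)) {
      fisher_exact(ar_tab)
    } else {
      auto_test(ar_tab)
    }
    tests[[length(tests) + 1L]] <- data.frame(
      stratum = st,
      indicator = c("Se", "Sp", "AR"),
      method = c(t_se$method, t_sp$method, t_ar$method),
      statistic = c(t_se$statistic, t_sp$statistic, t_ar$statistic),
      p_value = c(t_se$p_value, t_sp$p_value, t_ar$p_value),
      row.names = NULL
    )
  }
  structure(list(summary = do.call(rbind, rows), tests = do.call(rbind, tests)),
            class = "system_comparison")
}

#' @export
print.system_comparison <- function(x, ...) {
  s <- x$summary
  cat("Diagnostic accuracy by stratum and system\n")
  out <- data.frame(
    stratum = s$stratum, system = s$system,
    TP = s$tp, FN = s$fn, FP = s$fp, TN = s$tn,
    `Se%` = s$se_pct, `Sp%` = s$sp_pct, `AR%` = s$ar_pct,
    check.names = FALSE
  )
  print(out, row.names = FALSE)
  cat("\nBetween-system tests\n")
  print(x$tests, row.names = FALSE, digits = 4)
  invisible(x)
}
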