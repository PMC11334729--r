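# Group statistics: demographics tests, covariate-adjusted group comparisons,
# and metric ~ MoCA regressions.

METRIC_COLUMNS <- c("network_size", "degree", "connectivity_density",
                    "clustering_coefficient", "path_length",
                    "gamma", "lambda", "sigma")

#' Join covariates and metrics into a cohort table
#'
#' @param covariates data.frame with subject_id, diagnosis, age, sex,
#'   education, TIV, MMSE, MoCA, CDR.
#' @param metrics data.frame from [cohort_global_metrics()] (or NULL to use
#'   covariates alone).
#' @return A data.frame of class \code{cohort_table}.
#' @export
cohort_table <- function(covariates, metrics = NULL) {
  if (anyDuplicated(covariates$subject_id))
    stopf("duplicated subject_id in covariates")
  if (!all(covariates$diagnosis %in% c("CN", "MCI", "AD")))
    stopf("diagnosis must be one of CN, MCI, AD")
  out <- covariates
  if (!is.null(metrics)) {
    if (anyDuplicated(metrics$subject_id))
      stopf("duplicated subject_id in metrics")
    out <- merge(covariates, metrics, by = "subject_id", sort = FALSE)
  }
  out$diagnosis <- factor(as.character(out$diagnosis),
                          levels = c("CN", "MCI", "AD"))
  class(out) <- c("cohort_table", "data.frame")
  out
}

nuisance_design <- function(cohort, covariates = c("age", "sex", "education", "TIV")) {
  X <- list()
  for (v in covariates) {
    col <- cohort[[v]]
    if (v == "sex") col <- as.numeric(col == "M")
    X[[v]] <- col
  }
  as.data.frame(X)
}

#' Demographics and clinical-score tests
#'
#' Chi-squared test on the sex-by-group table; one-way ANOVA for age,
#' education, MMSE and MoCA; Kruskal-Wallis for CDR. Per-group mean, sd and
#' range are echoed alongside each test.
#'
#' @param cohort a [cohort_table()] (metrics not required).
#' @return A data.frame of class \code{demographics_table}: one row per
#'   variable with per-group summaries, the test used, its statistic and p.
#' @export
demographics_table <- function(cohort) {
  groups <- levels(droplevels(cohort$diagnosis))
  if (length(groups) < 2) stopf("need at least 2 diagnostic groups")
  cont_vars <- intersect(c("age", "education", "MMSE", "MoCA"), names(cohort))
  for (v in cont_vars) {
    ns <- tapply(!is.na(cohort[[v]]), cohort$diagnosis, sum)
    small <- names(ns)[!is.na(ns) & ns < 2]
    if (length(small))
      stopf("group %s has fewer than 2 observations of %s",
            paste(small, collapse = ","), v)
  }
  summarize <- function(v) {
    vapply(groups, function(g) {
      x <- cohort[[v]][cohort$diagnosis == g]
      x <- x[!is.na(x)]
      sprintf("%.2f ± %.2f [%.1f-%.1f]", mean(x), stats::sd(x),
              min(x), max(x))
    }, character(1))
  }
  rows <- list()
  sex_tab <- table(cohort$diagnosis, cohort$sex)
  chi <- suppressWarnings(stats::chisq.test(sex_tab))
  rows[["sex"]] <- data.frame(
    variable = "sex", test = "chi-squared",
    statistic = unname(chi$statistic), p_value = chi$p.value,
    t(vapply(groups, function(g)
      sprintf("%d M / %d F", sum(cohort$diagnosis == g & cohort$sex == "M"),
              sum(cohort$diagnosis == g & cohort$sex == "F")), character(1))),
    stringsAsFactors = FALSE, check.names = FALSE)
  for (v in cont_vars) {
    fit <- stats::aov(cohort[[v]] ~ cohort$diagnosis)
    an <- summary(fit)[[1]]
    rows[[v]] <- data.frame(
      variable = v, test = "one-way ANOVA",
      statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
      t(summarize(v)), stringsAsFactors = FALSE, check.names = FALSE)
  }
  if ("CDR" %in% names(cohort)) {
    kw <- stats::kruskal.test(cohort$CDR, cohort$diagnosis)
    rows[["CDR"]] <- data.frame(
      variable = "CDR", test = "Kruskal-Wallis",
      statistic = unname(kw$statistic), p_value = kw$p.value,
      t(summarize("CDR")), stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("demographics_table", "data.frame")
  out
}

#' Covariate-adjusted group-difference model for one metric
#'
#' Least-squares fit of \code{metric ~ diagnosis + age + sex + education +
#' TIV} with CN as the reference level; the group effect is the F-test of the
#' two diagnosis indicator terms jointly (nested-model comparison).
#'
#' @param cohort a [cohort_table()] with metric columns.
#' @param metric metric column name.
#' @return List of class \code{metric_group_model}: coefficient table, overall
#'   group F statistic, degrees of freedom, p-value, and n_used.
#' @export
metric_group_model <- function(cohort, metric) {
  if (!metric %in% names(cohort)) stopf("no metric column '%s'", metric)
  d <- data.frame(y = cohort[[metric]], diagnosis = cohort$diagnosis,
                  nuisance_design(cohort))
  d <- d[stats::complete.cases(d), ]
  full <- stats::lm(y ~ diagnosis + age + sex + education + TIV, data = d)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stopf("rank-deficient design; collinear terms: %s",
          paste(bad, collapse = ", "))
  }
  reduced <- stats::lm(y ~ age + sex + education + TIV, data = d)
  cmp <- stats::anova(reduced, full)
  cf <- summary(full)$coefficients
  structure(list(
    metric = metric,
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              std_error = cf[, 2], statistic = cf[, 3],
                              p_raw = cf[, 4], row.names = NULL,
                              stringsAsFactors = FALSE),
    f_statistic = cmp$F[2], df = c(cmp$Df[2], cmp$Res.Df[2]),
    p_value = cmp$`Pr(>F)`[2], n_used = nrow(d)
  ), class = "metric_group_model")
}

#' @export
print.metric_group_model <- function(x, ...) {
  cat(sprintf("Group model for %s: F(%d, %d) = %.3f, p = %.4g (n = %d)\n",
              x$metric, x$df[1], x$df[2], x$f_statistic, x$p_value, x$n_used))
  invisible(x)
}

#' Pairwise group comparisons for one metric
#'
#' Welch two-sample t-tests for CN vs MCI, CN vs AD, and MCI vs AD. With
#' \code{adjust = TRUE} (default) the tests are run on residuals of
#' \code{metric ~ age + sex + education + TIV} fitted on the whole sample.
#' The three p-values are BH-corrected as one family.
#'
#' @param cohort a [cohort_table()].
#' @param metric metric column name.
#' @param adjust regress out nuisance covariates first (default TRUE).
#' @return data.frame with one row per contrast: estimate (mean difference),
#'   t statistic, df, p_raw, p_fdr, group sizes.
#' @export
pairwise_group_tests <- function(cohort, metric, adjust = TRUE) {
  if (!metric %in% names(cohort)) stopf("no metric column '%s'", metric)
  groups <- c("CN", "MCI", "AD")
  if (!all(groups %in% cohort$diagnosis))
    stopf("all three groups (CN, MCI, AD) must be present")
  d <- data.frame(y = cohort[[metric]], diagnosis = cohort$diagnosis,
                  nuisance_design(cohort))
  d <- d[stats::complete.cases(d), ]
  y <- if (adjust) {
    stats::resid(stats::lm(y ~ age + sex + education + TIV, data = d))
  } else d$y
  pairs <- list(c("CN", "MCI"), c("CN", "AD"), c("MCI", "AD"))
  rows <- lapply(pairs, function(pr) {
    a <- y[d$diagnosis == pr[1]]
    b <- y[d$diagnosis == pr[2]]
    tt <- stats::t.test(a, b)
    data.frame(metric = metric, contrast = paste(pr, collapse = " vs "),
               estimate = mean(a) - mean(b),
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, n1 = length(a), n2 = length(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_raw)
  out$adjusted <- adjust
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-preserving.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1))
    stopf("p-values must be finite and lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Regression of a network metric on MoCA
#'
#' Fits \code{metric ~ MoCA + age + sex + education + TIV} within the whole
#' sample or one diagnostic group, with listwise deletion of missing MoCA.
#' Reports the MoCA slope, its p-value and n_used, plus the companion
#' (unadjusted) Pearson correlation between the metric and MoCA.
#'
#' @param cohort a [cohort_table()].
#' @param metric metric column name.
#' @param subset "all" or one of "CN", "MCI", "AD".
#' @return One-row data.frame: subset, metric, beta, std_error, statistic,
#'   p_value, pearson_r, n_used.
#' @export
moca_metric_regression <- function(cohort, metric, subset = "all") {
  if (!metric %in% names(cohort)) stopf("no metric column '%s'", metric)
  d <- if (identical(subset, "all")) cohort else
    cohort[cohort$diagnosis == subset, , drop = FALSE]
  d <- data.frame(y = d[[metric]], MoCA = d$MoCA, nuisance_design(d))
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < ncol(d) + 2)
    stopf("insufficient data in subset '%s': %d complete rows", subset, nrow(d))
  fit <- stats::lm(y ~ MoCA + age + sex + education + TIV, data = d)
  cf <- summary(fit)$coefficients["MoCA", ]
  data.frame(subset = subset, metric = metric,
             beta = unname(cf[1]), std_error = unname(cf[2]),
             statistic = unname(cf[3]), p_value = unname(cf[4]),
             pearson_r = stats::cor(d$y, d$MoCA), n_used = nrow(d),
             stringsAsFactors = FALSE)
}

#' Run the full statistical battery
#'
#' Demographics tests, per-metric covariate-adjusted group models with
#' FDR-corrected pairwise contrasts, and metric ~ MoCA regressions overall and
#' per group, for every metric column present.
#'
#' @param cohort a [cohort_table()] with metric columns.
#' @param metrics metric columns to analyze (defaults to all present).
#' @param adjust passed to [pairwise_group_tests()].
#' @return List of class \code{gm_stats}: demographics, group_models (named
#'   list), pairwise (data.frame), moca (data.frame).
#' @export
group_statistics <- function(cohort, metrics = intersect(METRIC_COLUMNS, names(cohort)),
                             adjust = TRUE) {
  demo <- demographics_table(cohort)
  models <- lapply(metrics, function(m) metric_group_model(cohort, m))
  names(models) <- metrics
  pw <- do.call(rbind, lapply(metrics, function(m)
    pairwise_group_tests(cohort, m, adjust = adjust)))
  subsets <- c("all", intersect(c("CN", "MCI", "AD"), unique(as.character(cohort$diagnosis))))
  moca <- do.call(rbind, lapply(metrics, function(m)
    do.call(rbind, lapply(subsets, function(s)
      tryCatch(moca_metric_regression(cohort, m, subset = s),
               error = function(e) NULL)))))
  structure(list(demographics = demo, group_models = models,
                 pairwise = pw, moca = moca),
            class = "gm_stats")
}

#' @export
print.gm_stats <- function(x, ...) {
  cat("== Demographics ==\n")
  print(as.data.frame(x$demographics), digits = 3)
  cat("\n== Covariate-adjusted group effects ==\n")
  for (m in x$group_models) print(m)
  cat("\n== Pairwise contrasts (FDR-corrected) ==\n")
  print(x$pairwise[, c("metric", "contrast", "estimate", "p_raw", "p_fdr")],
        digits = 3)
  cat("\n== Metric ~ MoCA regressions ==\n")
  print(x$moca[, c("subset", "metric", "beta", "p_value", "pearson_r", "n_used")],
        digits = 3)
  invisible(x)
}
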