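# Group statistics: BH-FDR, demographics tests, covariate-adjusted models,
# pairwise contrasts, MoCA regressions.

# build a covariate table directly (no imaging) with optional planted effects
make_table <- function(n_per_group = 50, seed = 1,
                       metric_fun = function(d, age, edu, tiv, n) rnorm(n)) {
  set.seed(seed)
  groups <- rep(c("CN", "MCI", "AD"), each = n_per_group)
  n <- length(groups)
  age <- rnorm(n, 74, 7)
  edu <- rnorm(n, 16, 2.5)
  tiv <- rnorm(n, 1450, 120)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  moca <- pmin(30, pmax(0, rnorm(n, c(CN = 24, MCI = 22, AD = 18)[groups], 3)))
  out <- data.frame(subject_id = sprintf("s%03d", 1:n), diagnosis = groups,
                    age = age, sex = sex, education = edu, TIV = tiv,
                    MMSE = rnorm(n, 27, 2), MoCA = moca,
                    CDR = ifelse(groups == "CN", 0, 0.5),
                    stringsAsFactors = FALSE)
  out$metric <- metric_fun(groups, age, edu, tiv, n)
  cohort_table(out)
}

test_that("bh_fdr reproduces hand-computed step-up adjustments", {
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.2, 0.5)), c(0.4, 0.5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_true(all(bh_fdr(c(0.01, 0.02, 0.03, 0.04)) <= 0.05))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("bh_fdr matches the brute-force step-up oracle on random vectors", {
  for (s in 1:100) {
    set.seed(s)
    p <- runif(sample(1:100, 1))^sample(1:3, 1)
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("demographics table runs the right test per variable", {
  tab <- make_table(seed = 3)
  demo <- demographics_table(tab)
  expect_setequal(demo$variable, c("sex", "age", "education", "MMSE", "MoCA", "CDR"))
  expect_equal(demo$test[demo$variable == "sex"], "chi-squared")
  expect_equal(demo$test[demo$variable == "CDR"], "Kruskal-Wallis")
  expect_true(all(demo$test[demo$variable %in% c("age", "MoCA")] == "one-way ANOVA"))
  # MoCA differs by construction; age does not
  expect_lt(demo$p_value[demo$variable == "MoCA"], 0.001)
})

test_that("an age/sex-matched sex table is not significant", {
  # group sex counts as reported for an age/gender-matched cohort
  counts <- list(CN = c(M = 90, F = 95), MCI = c(M = 85, F = 65),
                 AD = c(M = 88, F = 65))
  rows <- do.call(rbind, lapply(names(counts), function(g)
    data.frame(diagnosis = g,
               sex = rep(c("M", "F"), counts[[g]]))))
  n <- nrow(rows)
  set.seed(1)
  tab <- cohort_table(data.frame(subject_id = sprintf("s%03d", 1:n),
                                 rows, age = rnorm(n, 74, 7),
                                 education = rnorm(n, 16, 2), TIV = rnorm(n, 1450, 100),
                                 MMSE = rnorm(n, 27, 2), MoCA = rnorm(n, 22, 4),
                                 CDR = 0.5))
  demo <- demographics_table(tab)
  expect_gt(demo$p_value[demo$variable == "sex"], 0.05)
})

test_that("identical groups give a zero F statistic", {
  base <- make_table(n_per_group = 10, seed = 5)
  rows <- base[base$diagnosis == "CN", ]
  copied <- do.call(rbind, lapply(c("CN", "MCI", "AD"), function(g) {
    r <- rows
    r$diagnosis <- g
    r$subject_id <- paste0(r$subject_id, g)
    r
  }))
  demo <- demographics_table(cohort_table(copied))
  expect_equal(demo$statistic[demo$variable == "age"], 0, tolerance = 1e-10)
  expect_equal(demo$p_value[demo$variable == "age"], 1, tolerance = 1e-10)
})

test_that("demographics errors name a group that is too small", {
  tab <- make_table(n_per_group = 5, seed = 2)
  tab$MoCA[tab$diagnosis == "AD"][2:5] <- NA
  expect_error(demographics_table(tab), "AD")
})

test_that("ANOVA keeps its nominal type-I error under the null", {
  hits <- 0
  for (s in 1:200) {
    tab <- make_table(n_per_group = 20, seed = 1000 + s)
    demo <- demographics_table(tab)
    if (demo$p_value[demo$variable == "MMSE"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.02)
  expect_lte(hits / 200, 0.09)
})

test_that("group model recovers planted coefficients exactly on noise-free data", {
  tab <- make_table(seed = 11, metric_fun = function(d, age, edu, tiv, n) {
    0.5 + 0.02 * age - 0.01 * edu + 0.001 * tiv +
      c(CN = 0, MCI = -0.3, AD = -0.8)[d]
  })
  # summary.lm warns on an essentially perfect fit; that is the point here
  fit <- suppressWarnings(metric_group_model(tab, "metric"))
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "age"], 0.02, tolerance = 1e-10)
  expect_equal(cf$estimate[cf$term == "diagnosisMCI"], -0.3, tolerance = 1e-10)
  expect_equal(cf$estimate[cf$term == "diagnosisAD"], -0.8, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-12)
})

test_that("group model rejects a rank-deficient design", {
  tab <- make_table(seed = 12)
  tab$TIV <- 2 * tab$age + 3
  expect_error(metric_group_model(tab, "metric"), "collinear")
})

test_that("group-effect F test holds its size under covariate confounding", {
  hits <- 0
  for (s in 1:200) {
    tab <- make_table(n_per_group = 20, seed = 3000 + s,
                      metric_fun = function(d, age, edu, tiv, n)
                        0.05 * age + rnorm(n))
    if (metric_group_model(tab, "metric")$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.02)
  expect_lte(hits / 200, 0.09)
})

test_that("group-effect F test detects a two-residual-sd AD deficit", {
  hits <- 0
  for (s in 1:100) {
    tab <- make_table(n_per_group = 50, seed = 5000 + s,
                      metric_fun = function(d, age, edu, tiv, n)
                        rnorm(n) - 2 * (d == "AD"))
    if (metric_group_model(tab, "metric")$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.95)
})

test_that("pairwise tests cover three contrasts with a BH family per metric", {
  tab <- make_table(seed = 21, metric_fun = function(d, age, edu, tiv, n)
    rnorm(n) + 2 * (d == "CN"))
  pw <- pairwise_group_tests(tab, "metric")
  expect_setequal(pw$contrast, c("CN vs MCI", "CN vs AD", "MCI vs AD"))
  expect_equal(pw$p_fdr, bh_fdr(pw$p_raw))
  expect_lt(pw$p_fdr[pw$contrast == "CN vs AD"], 0.001)
  pw_raw <- pairwise_group_tests(tab, "metric", adjust = FALSE)
  expect_false(any(pw_raw$adjusted))
  expect_error(pairwise_group_tests(tab[tab$diagnosis != "AD", ], "metric"),
               "three groups")
})

test_that("pairwise tests are null-calibrated on identical distributions", {
  hits <- 0
  for (s in 1:200) {
    tab <- make_table(n_per_group = 20, seed = 7000 + s)
    pw <- pairwise_group_tests(tab, "metric")
    if (pw$p_raw[pw$contrast == "CN vs AD"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.02)
  expect_lte(hits / 200, 0.09)
})

test_that("MoCA regression recovers a noise-free planted model exactly", {
  tab <- make_table(seed = 31, metric_fun = function(d, age, edu, tiv, n) n)
  tab$metric <- 3 + 0.25 * tab$MoCA + 0.01 * tab$age - 0.002 * tab$TIV
  # summary.lm warns on an essentially perfect fit; that is the point here
  res <- suppressWarnings(moca_metric_regression(tab, "metric"))
  expect_equal(res$beta, 0.25, tolerance = 1e-10)
  expect_equal(res$n_used, nrow(tab))
})

test_that("MoCA regression accounts for missing scores listwise", {
  tab <- make_table(n_per_group = 30, seed = 32)
  tab$MoCA[c(3, 10, 44)] <- NA
  res <- moca_metric_regression(tab, "metric")
  expect_equal(res$n_used, 87)
  res_cn <- moca_metric_regression(tab, "metric", subset = "CN")
  expect_equal(res_cn$n_used, sum(tab$diagnosis == "CN" & !is.na(tab$MoCA)))
  tiny <- tab[c(1, 2, 31, 61), ]
  expect_error(moca_metric_regression(cohort_table(tiny), "metric"),
               "insufficient")
})

test_that("MoCA slope is estimated within 2 SE at the nominal rate", {
  covered <- 0
  for (s in 1:200) {
    tab <- make_table(n_per_group = 50, seed = 9000 + s)
    b <- 0.1
    tab$metric <- 1 + b * tab$MoCA + rnorm(nrow(tab), 0, 1)
    res <- moca_metric_regression(tab, "metric")
    if (abs(res$beta - b) <= 2 * res$std_error) covered <- covered + 1
  }
  expect_gte(covered / 200, 0.93)
})

test_that("MoCA regression is null-calibrated under a zero slope", {
  hits <- 0
  for (s in 1:200) {
    tab <- make_table(n_per_group = 50, seed = 11000 + s)
    if (moca_metric_regression(tab, "metric")$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.02)
  expect_lte(hits / 200, 0.09)
})

test_that("cohort_table validates joins and group labels", {
  cov <- make_table(n_per_group = 3, seed = 41)
  expect_error(cohort_table(rbind(cov, cov[1, ])), "duplicated")
  bad <- cov
  bad$diagnosis <- as.character(bad$diagnosis)
  bad$diagnosis[1] <- "XX"
  expect_error(cohort_table(bad), "CN, MCI, AD")
  metrics <- data.frame(subject_id = cov$subject_id, sigma = rnorm(nrow(cov)))
  joined <- cohort_table(cov[, names(cov) != "metric"], metrics)
  expect_true("sigma" %in% names(joined))
  expect_equal(nrow(joined), nrow(cov))
})

test_that("group_statistics assembles the full battery", {
  tab <- make_table(n_per_group = 30, seed = 51)
  tab$sigma <- rnorm(nrow(tab)) + 0.5 * (tab$diagnosis == "CN")
  res <- group_statistics(tab, metrics = "sigma")
  expect_s3_class(res, "gm_stats")
  expect_named(res$group_models, "sigma")
  expect_equal(nrow(res$pairwise), 3)
  expect_setequal(unique(res$moca$subset), c("all", "CN", "MCI", "AD"))
})
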