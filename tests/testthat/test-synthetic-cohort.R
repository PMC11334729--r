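# Synthetic-cohort generator: covariate calibration, template contracts,
# image-model contracts, determinism.

test_that("per-group covariate means are calibrated within sampling error", {
  # CN age: mean 74.8, sd 7.17, n = 185; the sample mean should fall within
  # 3 standard errors in essentially every replicate
  bound <- 3 * 7.17 / sqrt(185)
  fails <- 0
  for (s in 1:20) {
    spec <- cohort_spec(seed = s)
    cov <- sample_covariates(spec)
    m <- mean(cov$age[cov$diagnosis == "CN"])
    if (abs(m - 74.8) > bound) fails <- fails + 1
  }
  expect_lte(fails, 1)
})

test_that("degenerate zero-sd spec reproduces group means exactly", {
  demo <- default_demographics()
  for (col in grep("_sd$", names(demo))) demo[[col]] <- 0
  spec <- cohort_spec(group_sizes = c(CN = 4, MCI = 4, AD = 4),
                      demographics = demo, atrophy_sd = 0,
                      moca_missing = c(CN = 0, MCI = 0, AD = 0), seed = 3)
  cov <- sample_covariates(spec)
  for (g in c("CN", "MCI", "AD")) {
    rows <- cov[cov$diagnosis == g, ]
    d <- demo[demo$group == g, ]
    expect_equal(rows$age, rep(d$age_mean, 4))
    expect_equal(rows$education, rep(d$education_mean, 4))
    expect_equal(rows$MMSE, rep(d$mmse_mean, 4))
    expect_equal(rows$MoCA, rep(d$moca_mean, 4))
  }
})

test_that("covariate sampling is deterministic under a fixed seed", {
  spec <- small_spec(seed = 11)
  expect_identical(sample_covariates(spec), sample_covariates(spec))
})

test_that("CN subjects always have CDR 0 and scores respect scale bounds", {
  spec <- cohort_spec(group_sizes = c(CN = 40, MCI = 40, AD = 40), seed = 5)
  cov <- sample_covariates(spec)
  expect_true(all(cov$CDR[cov$diagnosis == "CN"] == 0))
  expect_true(all(cov$CDR %in% c(0, 0.5, 1, 2)))
  expect_true(all(cov$MMSE >= 0 & cov$MMSE <= 30))
  expect_true(all(cov$MoCA >= 0 & cov$MoCA <= 30, na.rm = TRUE))
})

test_that("template satisfies its range, structure and determinism contracts", {
  spec <- small_spec(shape = c(30, 30, 30))
  tpl <- build_template(spec)
  expect_true(all(tpl$values >= 0 & tpl$values <= 1))
  M <- gmnet:::cube_value_matrix(tpl$values, 3L)
  expect_gt(sum(apply(M, 2, max) == 0), 0)          # at least one empty cube
  expect_gt(sum(colMeans(M) > 0.3), 0)              # at least one GM-rich cube
  expect_identical(tpl$values, build_template(spec)$values)
  expect_true(is.array(attr(tpl, "atrophy_mask")))
  expect_gt(sum(attr(tpl, "atrophy_mask")), 0)
})

test_that("degenerate parameters make the image exactly template x (1 + shared signal)", {
  spec <- small_spec(n = 1, seed = 21,
                     decoherence_level = c(CN = 0, MCI = 0, AD = 0),
                     noise_sd = 0, atrophy_sd = 0,
                     atrophy_level = c(CN = 0, MCI = 0, AD = 0),
                     brain_size_sd = 0)
  tpl <- build_template(spec)
  sf <- make_shared_fields(spec, seed = 33)
  subj <- data.frame(subject_id = "a", diagnosis = "CN", true_atrophy = 0)
  img <- simulate_subject_image(tpl, subj, spec, sf, seed = 99)
  # reconstruct the shared signal from the cohort fields
  K <- ncol(sf$patterns)
  Wc <- vapply(seq_len(K), function(k)
    colMeans(gmnet:::cube_value_matrix(sf$loadings[[k]], 3L)),
    numeric(prod(spec$image_shape %/% 3L)))
  S <- gmnet:::expand_cube_signal(sf$patterns %*% t(Wc) / sqrt(K),
                                  spec$image_shape)
  expected <- pmax(tpl$values * (1 + spec$signal_amplitude * S), 0)
  expect_equal(img$values, expected, tolerance = 1e-12)
  # and no subject-specific randomness: another subject/seed gives the same image
  img2 <- simulate_subject_image(tpl, subj, spec, sf, seed = 1234)
  expect_identical(img$values, img2$values)
})

test_that("atrophy acts multiplicatively inside the recorded mask", {
  spec <- small_spec(n = 1, seed = 2, noise_sd = 0, brain_size_sd = 0,
                     decoherence_level = c(CN = 0, MCI = 0, AD = 0),
                     signal_amplitude = 0)
  tpl <- build_template(spec)
  sf <- make_shared_fields(spec, seed = 3)
  subj <- data.frame(subject_id = "a", diagnosis = "AD", true_atrophy = 0.5)
  img <- simulate_subject_image(tpl, subj, spec, sf, seed = 4)
  mask <- attr(tpl, "atrophy_mask")
  expect_equal(img$values[mask], 0.5 * tpl$values[mask], tolerance = 1e-12)
  expect_equal(img$values[!mask], tpl$values[!mask], tolerance = 1e-12)
})

test_that("mean inter-cube similarity declines with decoherence", {
  # averaged over >= 10 seeds, mean |r| strictly decreases across the
  # default group levels and collapses at extreme decoherence
  levels <- c(0.05, 0.12, 0.2, 0.9)
  mean_absr <- function(d, fs, ss) {
    spec <- small_spec(n = 1, seed = fs,
                       decoherence_level = c(CN = d, MCI = d, AD = d),
                       brain_size_sd = 0)
    tpl <- build_template(spec)
    sf <- make_shared_fields(spec, seed = fs)
    subj <- data.frame(subject_id = "s", diagnosis = "AD", true_atrophy = 0)
    img <- simulate_subject_image(tpl, subj, spec, sf, seed = ss)
    sim <- build_similarity_matrix(img, partition_cubes(img))
    mean(abs(sim[upper.tri(sim)]))
  }
  curves <- sapply(1:10, function(s)
    vapply(levels, mean_absr, numeric(1), fs = 13 * s, ss = 7 * s + 1))
  expect_true(all(diff(rowMeans(curves)) < 0))
})

test_that("a decoherence-0 subject has higher mean |r| than a decoherence-0.9 subject", {
  wins <- 0
  for (s in 1:20) {
    spec0 <- small_spec(n = 1, seed = s, brain_size_sd = 0,
                        decoherence_level = c(CN = 0, MCI = 0, AD = 0))
    spec9 <- small_spec(n = 1, seed = s, brain_size_sd = 0,
                        decoherence_level = c(CN = 0.9, MCI = 0.9, AD = 0.9))
    tpl <- build_template(spec0)
    sf <- make_shared_fields(spec0, seed = s)
    subj <- data.frame(subject_id = "s", diagnosis = "CN", true_atrophy = 0)
    mr <- function(spec) {
      img <- simulate_subject_image(tpl, subj, spec, sf, seed = 1000 + s)
      sim <- build_similarity_matrix(img, partition_cubes(img))
      mean(abs(sim[upper.tri(sim)]))
    }
    if (mr(spec0) > mr(spec9)) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("simulate_cohort returns matched images and covariates with TIV filled in", {
  spec <- small_spec(n = 2, seed = 6)
  coh <- simulate_cohort(spec)
  expect_length(coh$images, 6)
  expect_equal(nrow(coh$covariates), 6)
  expect_true(all(is.finite(coh$covariates$TIV) & coh$covariates$TIV > 0))
  expect_identical(names(coh$images), coh$covariates$subject_id)
  # determinism end to end
  coh2 <- simulate_cohort(spec)
  expect_identical(coh$covariates, coh2$covariates)
  expect_identical(coh$images[[6]]$values, coh2$images[[6]]$values)
})

test_that("zero MoCA coupling leaves MoCA uncorrelated with atrophy severity", {
  for (s in 1:5) {
    spec <- cohort_spec(group_sizes = c(CN = 200, MCI = 200, AD = 200),
                        moca_coupling = 0,
                        moca_missing = c(CN = 0, MCI = 0, AD = 0), seed = s)
    cov <- sample_covariates(spec)
    for (g in c("CN", "MCI", "AD")) {
      rows <- cov[cov$diagnosis == g, ]
      expect_lt(abs(cor(rows$MoCA, rows$true_atrophy)), 3 / sqrt(nrow(rows)))
    }
  }
})

test_that("full-size covariate draws reproduce the MoCA group means", {
  # average over seeds: a single MoCA draw has se ~0.45 in the MCI group
  # (sd 4.6, ~100 observed), so per-seed means can graze the 1-point bound
  moca <- rowMeans(sapply(1:5, function(s) {
    cov <- sample_covariates(cohort_spec(seed = s))   # 185/150/153 subjects
    tapply(cov$MoCA, cov$diagnosis, mean, na.rm = TRUE)
  }))
  expect_lt(abs(moca["CN"] - 24.3), 1)
  expect_lt(abs(moca["MCI"] - 21.83), 1)
  expect_lt(abs(moca["AD"] - 17.89), 1)
})
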