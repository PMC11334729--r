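#' Sample subject covariates for a synthetic cohort
#'
#' Draws one covariate record per subject: age, education, MMSE and MoCA from
#' per-group normal distributions (clamped to their scale bounds), sex from the
#' group male fraction, CDR from the per-group categorical distribution (CN is
#' always 0), and a latent atrophy severity \code{true_atrophy} from
#' \code{Normal(atrophy_level\[group\], atrophy_sd)} truncated to \[0, 0.9\].
#' MoCA is coupled to atrophy: the within-group-centred severity enters the
#' MoCA mean with slope \code{moca_coupling}, so metric~MoCA regressions have a
#' planted effect once network metrics inherit the atrophy/decoherence
#' gradient. A per-group fraction of MoCA scores is set missing. TIV is filled
#' in later from each generated image (see [simulate_cohort()]).
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed (defaults to \code{spec$seed}).
#' @return A data.frame with one row per subject: subject_id, diagnosis, age,
#'   sex, education, TIV (NA here), MMSE, MoCA, CDR, true_atrophy.
#' @export
sample_covariates <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "cohort_spec")) stopf("spec must be a cohort_spec")
  with_seed(seed, {
    rows <- lapply(seq_along(spec$groups), function(gi) {
      g <- spec$groups[gi]
      n <- spec$group_sizes[gi]
      dm <- spec$demographics[gi, ]
      age <- stats::rnorm(n, dm$age_mean, dm$age_sd)
      edu <- clamp(stats::rnorm(n, dm$education_mean, dm$education_sd), 0, 20)
      mmse <- clamp(stats::rnorm(n, dm$mmse_mean, dm$mmse_sd), 0, 30)
      sex <- ifelse(stats::runif(n) < dm$male_frac, "M", "F")
      cdr_d <- spec$cdr[[g]]
      cdr <- if (length(cdr_d$values) == 1L) rep(cdr_d$values, n) else
        sample(cdr_d$values, n, replace = TRUE, prob = cdr_d$probs)
      atr <- clamp(stats::rnorm(n, spec$atrophy_level[g], spec$atrophy_sd), 0, 0.9)
      moca <- clamp(dm$moca_mean +
                      spec$moca_coupling * (atr - spec$atrophy_level[g]) +
                      stats::rnorm(n, 0, dm$moca_sd), 0, 30)
      moca[stats::runif(n) < spec$moca_missing[g]] <- NA_real_
      data.frame(
        subject_id = sprintf("sub-%s%03d", g, seq_len(n)),
        diagnosis = g, age = age, sex = sex, education = edu,
        TIV = NA_real_, MMSE = mmse, MoCA = moca, CDR = cdr,
        true_atrophy = atr, stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out$diagnosis <- factor(out$diagnosis, levels = spec$groups)
    rownames(out) <- NULL
    out
  })
}

#' Simulate one subject's GM image
#'
#' Applies the generative model
#' \code{template * (1 - true_atrophy * atrophy_mask) * (1 + signal) + noise},
#' clipped at zero. The structured signal weights the cohort-shared
#' pattern-carrier fields by a mixture of the cohort-shared loading fields
#' (weight \code{1 - decoherence}) and subject-independent smooth loading
#' noise at cube scale (weight \code{decoherence}), scaled by
#' \code{signal_amplitude}; see [cohort_spec()] for the model. TIV (ml) is
#' computed from the generated image as the volume of voxels with GM > 0.05
#' and returned as attribute \code{tiv_ml}.
#'
#' @param template template [gm_image()] from [build_template()].
#' @param subject one row of the covariate table (needs \code{diagnosis},
#'   \code{true_atrophy}, \code{subject_id}).
#' @param spec the [cohort_spec()].
#' @param shared_fields cohort-shared fields from [make_shared_fields()]:
#'   list with \code{patterns} and \code{loadings}, each K arrays of the
#'   template's shape.
#' @param seed integer seed for this subject.
#' @return A [gm_image()] with attribute \code{tiv_ml}.
#' @export
simulate_subject_image <- function(template, subject, spec, shared_fields, seed) {
  shape <- spec$image_shape
  if (!identical(dim(template$values), as.integer(shape)))
    stopf("template shape does not match spec image_shape")
  for (f in shared_fields$loadings) {
    if (!identical(dim(f), as.integer(shape)))
      stopf("shared field shape does not match spec image_shape")
  }
  g <- as.character(subject$diagnosis)
  d <- spec$decoherence_level[[g]]
  atr <- subject$true_atrophy
  mask <- attr(template, "atrophy_mask")
  Pmat <- shared_fields$patterns
  K <- ncol(Pmat)

  with_seed(seed, {
    # per-cube loading matrix from the shared loading fields
    Wc <- vapply(seq_len(K), function(k)
      colMeans(cube_value_matrix(shared_fields$loadings[[k]], 3L)),
      numeric(prod(shape %/% 3L)))
    # Decoherence d blends the structured, cohort-shared covariance (weight
    # 1 - d) with (a) a common-mode pattern whose weight d(1-d)^2 models
    # dedifferentiation -- correlations become less selective, randomizing
    # edge placement -- and (b) subject-independent per-cube pattern noise
    # (weight ~0.71 d) that attenuates all correlations. Net effect across
    # the working range: mean inter-cube similarity falls monotonically,
    # clustering and the small-world coefficients degrade toward randomness,
    # and connectivity density changes only mildly -- the disease phenotype.
    n_cubes <- nrow(Wc)
    Sw <- Pmat %*% t(Wc) / sqrt(K)
    if (d > 0) {
      dediff_w <- 2.2 * d * (1 - d)^2
      indep_w <- sqrt(1 - 0.7^2) * d
      Q <- matrix(stats::rnorm(27 * n_cubes), 27, n_cubes)
      Sw <- (1 - d) * Sw +
        dediff_w * matrix(shared_fields$common, 27, n_cubes) +
        indep_w * Q
      # decoherence redistributes covariance; total signal variance is held
      # fixed so global image statistics (e.g. TIV) carry no group signature
      Sw <- Sw / sqrt((1 - d)^2 + dediff_w^2 + indep_w^2)
    }
    signal <- spec$signal_amplitude * expand_cube_signal(Sw, shape)
    vals <- template$values * (1 - atr * mask) * (1 + signal)
    # subject brain size: a smaller support radius trims outer cubes, giving
    # TIV and network-size variability independent of diagnosis
    if (spec$brain_size_sd > 0) {
      b <- min(1, stats::rnorm(1, 1, spec$brain_size_sd))
      cube_rho <- attr(template, "cube_rho")
      if (!is.null(cube_rho) && b < 1) {
        drop <- expand_cube_signal(
          matrix(rep(as.numeric(cube_rho > b), each = 27), nrow = 27),
          shape) > 0
        vals[drop] <- 0
      }
    }
    if (spec$noise_sd > 0) {
      vals <- vals + array(stats::rnorm(prod(shape), 0, spec$noise_sd), shape)
    }
    vals <- pmax(vals, 0)
    img <- gm_image(vals, voxel_size_mm = spec$voxel_size_mm,
                    subject_id = subject$subject_id)
    attr(img, "tiv_ml") <- sum(vals > 0.05) * spec$voxel_size_mm^3 / 1000
    img
  })
}

#' Cohort-shared fields
#'
#' The cohort's covariance substrate: a 27 x K matrix of unit-variance
#' micro-patterns (one 3x3x3-voxel pattern per column, realized identically at
#' every cube position, so two cubes anywhere in the volume whose loading
#' vectors align carry literally similar voxel patterns — the substrate of
#' long-range structural covariance) and K smooth loading fields (smoothed at
#' three times \code{smoothing_fwhm_mm}, creating modular, spatially coherent
#' covariance).
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return List with elements \code{patterns} (27 x K matrix),
#'   \code{loadings} (list of K arrays) and \code{common} (the common-mode
#'   27-pattern).
#' @export
make_shared_fields <- function(spec, seed) {
  sigma_w <- fwhm_to_sigma(3 * spec$smoothing_fwhm_mm, spec$voxel_size_mm)
  shape <- spec$image_shape
  with_seed(seed, {
    patterns <- vapply(seq_len(spec$n_shared_fields), function(k) {
      p <- stats::rnorm(27)
      (p - mean(p)) / stats::sd(p)
    }, numeric(27))
    loadings <- lapply(seq_len(spec$n_shared_fields), function(k)
      smooth_field(shape, sigma_w))
    common <- stats::rnorm(27)
    common <- (common - mean(common)) / stats::sd(common)
    list(patterns = patterns, loadings = loadings, common = common)
  })
}

# Expand a 27 x n_cubes cube-signal matrix back to a full voxel array
# (trailing voxels that fill no cube get 0).
expand_cube_signal <- function(S, shape) {
  npa <- shape %/% 3L
  dim(S) <- c(3L, 3L, 3L, npa)
  S <- aperm(S, c(1, 4, 2, 5, 3, 6))
  dim(S) <- 3L * npa
  out <- array(0, shape)
  out[seq_len(3 * npa[1]), seq_len(3 * npa[2]), seq_len(3 * npa[3])] <- S
  out
}

#' Simulate a full synthetic cohort
#'
#' Samples covariates, builds the template and the cohort-shared fields, and
#' generates one GM image per subject; TIV is computed from each image and
#' written back into the covariate table. Fully reproducible under
#' \code{spec$seed}.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class \code{gm_cohort}: list with \code{images} (list
#'   of [gm_image()]), \code{covariates} (data.frame), \code{template}, and
#'   \code{spec}.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stopf("spec must be a cohort_spec")
  n <- sum(spec$group_sizes)
  seeds <- derive_seeds(spec$seed, n + 2L)
  covariates <- sample_covariates(spec, seed = seeds[1])
  template <- build_template(spec)
  shared <- make_shared_fields(spec, seed = seeds[2])
  images <- vector("list", n)
  for (i in seq_len(n)) {
    img <- simulate_subject_image(template, covariates[i, ], spec, shared,
                                  seed = seeds[i + 2L])
    covariates$TIV[i] <- attr(img, "tiv_ml")
    images[[i]] <- img
  }
  names(images) <- covariates$subject_id
  structure(list(images = images, covariates = covariates,
                 template = template, spec = spec),
            class = "gm_cohort")
}

#' @export
print.gm_cohort <- function(x, ...) {
  tab <- table(x$covariates$diagnosis)
  cat(sprintf("Synthetic GM cohort: %d subjects (%s), images %s at %g mm\n",
              nrow(x$covariates),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
              paste(x$spec$image_shape, collapse = "x"),
              x$spec$voxel_size_mm))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Images as NIfTI-1 (.nii.gz) and covariates as a UTF-8 CSV with the header
#' \code{subject_id,diagnosis,age,sex,education,TIV,MMSE,MoCA,CDR}.
#'
#' @param cohort a \code{gm_cohort}.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (img in cohort$images) {
    write_gm_image(img, file.path(dir, paste0(img$subject_id, ".nii.gz")))
  }
  cols <- c("subject_id", "diagnosis", "age", "sex", "education",
            "TIV", "MMSE", "MoCA", "CDR")
  utils::write.csv(cohort$covariates[, cols],
                   file.path(dir, "covariates.csv"), row.names = FALSE)
  invisible(dir)
}
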