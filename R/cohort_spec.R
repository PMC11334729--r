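#' Default per-group demographic parameters
#'
#' Group-level means and standard deviations for age, education, MMSE and MoCA,
#' together with the male fraction, for the three diagnostic groups (CN:
#' cognitively normal, MCI: mild cognitive impairment, AD: Alzheimer's
#' disease). Values are calibrated to a typical Alzheimer's-continuum
#' cross-sectional cohort in which the groups are matched on age and sex but
#' differ in education and cognition.
#'
#' @return A data.frame with one row per diagnostic group.
#' @export
default_demographics <- function() {
  data.frame(
    group          = c("CN", "MCI", "AD"),
    age_mean       = c(74.8, 73.45, 75.47),
    age_sd         = c(7.17, 8.7, 7.74),
    education_mean = c(16.83, 15.8, 15.59),
    education_sd   = c(2.36, 3, 2.64),
    mmse_mean      = c(29.06, 26.83, 22.89),
    mmse_sd        = c(1.13, 2.54, 2.96),
    moca_mean      = c(24.3, 21.83, 17.89),
    moca_sd        = c(1.95, 4.6, 5.4),
    male_frac      = c(90 / 185, 85 / 150, 88 / 153),
    stringsAsFactors = FALSE
  )
}

# CDR is an ordinal dementia-severity scale; per-group category distributions.
# CN is 0 by definition of the cohort; MCI is dominated by 0.5; AD spans 0.5-2.
cdr_distributions <- function() {
  list(
    CN  = list(values = 0,               probs = 1),
    MCI = list(values = c(0.5, 1),       probs = c(0.94, 0.06)),
    AD  = list(values = c(0.5, 1, 2),    probs = c(0.55, 0.36, 0.09))
  )
}

#' Specify a synthetic cohort
#'
#' Collects every parameter of the synthetic-cohort generator: group sizes and
#' demographic distributions, the voxel grid, and the image-model parameters
#' (atrophy, spatial decoherence, field smoothness, noise). The generated GM
#' images follow
#' \deqn{I = T (1 - a A)(1 + s ((1-d) F_{shared} + d F_{indep})) + \epsilon,}
#' where \eqn{T} is a fixed anatomical template, \eqn{A} its recorded atrophy
#' mask, \eqn{a} the subject's atrophy severity, and \eqn{d} the group
#' decoherence level. The structured signal is built from \eqn{K} cohort-shared
#' 3x3x3-voxel micro-patterns \eqn{p_k} realized identically at every cube,
#' weighted by cohort-shared smooth loading fields \eqn{W_k} (long spatial
#' range, creating modular inter-regional covariance):
#' \deqn{S \propto (1-d)\, K^{-1/2} \textstyle\sum_k W_k p_k
#'       \; + \; 2.2\, d (1-d)^2 \, p_0 \; + \; 0.71\, d \, Q,}
#' where \eqn{p_0} is a cohort-shared common-mode pattern (dedifferentiation:
#' with disease, correlations become less selective, so edge placement
#' randomizes) and \eqn{Q} is subject-independent per-cube pattern noise that
#' attenuates all correlations. Across the working range of \eqn{d}, mean
#' inter-cube similarity falls monotonically and clustering and the
#' small-world coefficients degrade toward randomness while connectivity
#' density changes only mildly — the empirical disease phenotype.
#'
#' @param group_sizes named integer vector, subjects per group (CN, MCI, AD).
#' @param demographics data.frame as returned by [default_demographics()].
#' @param image_shape integer(3), voxel grid dimensions (each >= 9).
#' @param voxel_size_mm scalar voxel edge length in mm (default 2, so a
#'   3x3x3-voxel cube spans 6 mm).
#' @param atrophy_level named numeric, per-group mean multiplicative GM
#'   reduction inside the atrophy mask, in \[0, 1); nondecreasing CN <= MCI <= AD.
#' @param atrophy_sd within-group sd of subject atrophy severity.
#' @param decoherence_level named numeric in \[0, 1\], per-group weight of
#'   subject-independent (short-range) signal; nondecreasing CN <= MCI <= AD.
#' @param moca_coupling slope linking subject atrophy severity (centred within
#'   group) to MoCA score, in MoCA points per unit atrophy (negative: more
#'   atrophy, lower score).
#' @param noise_sd additive voxel noise sd (GM units).
#' @param brain_size_sd sd of the per-subject brain-size factor that scales
#'   the GM support radius (drives realistic TIV and network-size variability,
#'   independent of diagnosis).
#' @param signal_amplitude sd of the multiplicative structured signal.
#' @param smoothing_fwhm_mm FWHM (mm) of the pattern-carrier fields
#'   (default 8 mm, typical VBM smoothing practice).
#' @param n_shared_fields number of pattern-carrier/loading field pairs K.
#' @param moca_missing named numeric in \[0, 1\], per-group probability that
#'   MoCA is missing (emulating incomplete neuropsychological batteries).
#' @param seed integer RNG seed for the whole cohort.
#' @return An object of class \code{cohort_spec}.
#' @seealso [simulate_cohort()], [build_template()]
#' @export
cohort_spec <- function(group_sizes = c(CN = 185L, MCI = 150L, AD = 153L),
                        demographics = default_demographics(),
                        image_shape = c(30L, 30L, 30L),
                        voxel_size_mm = 2,
                        atrophy_level = c(CN = 0.02, MCI = 0.12, AD = 0.25),
                        atrophy_sd = 0.05,
                        decoherence_level = c(CN = 0.05, MCI = 0.12, AD = 0.2),
                        moca_coupling = -12,
                        noise_sd = 0.01,
                        brain_size_sd = 0.02,
                        signal_amplitude = 0.4,
                        smoothing_fwhm_mm = 8,
                        n_shared_fields = 6L,
                        moca_missing = c(CN = 13 / 185, MCI = 50 / 150, AD = 61 / 153),
                        seed = 1L) {
  groups <- c("CN", "MCI", "AD")
  named3 <- function(x, what) {
    x <- unlist(x)   # accept YAML/JSON-style named lists
    if (is.null(names(x))) names(x) <- groups
    if (!all(groups %in% names(x)))
      stopf("'%s' must be named with CN, MCI, AD", what)
    x[groups]
  }
  group_sizes <- named3(group_sizes, "group_sizes")
  if (!all(vapply(group_sizes, is_count, logical(1))))
    stopf("all group sizes must be integers >= 1")
  if (length(image_shape) != 3L || any(image_shape < 9))
    stopf("image_shape must have 3 dimensions, each >= 9 voxels")
  if (voxel_size_mm <= 0) stopf("voxel_size_mm must be positive")
  atrophy_level <- named3(atrophy_level, "atrophy_level")
  decoherence_level <- named3(decoherence_level, "decoherence_level")
  moca_missing <- named3(moca_missing, "moca_missing")
  if (any(atrophy_level < 0) || any(atrophy_level >= 1))
    stopf("atrophy_level must lie in [0, 1)")
  if (any(decoherence_level < 0) || any(decoherence_level > 1))
    stopf("decoherence_level must lie in [0, 1]")
  if (is.unsorted(atrophy_level) || is.unsorted(decoherence_level))
    stopf("atrophy_level and decoherence_level must be nondecreasing CN <= MCI <= AD")
  if (any(moca_missing < 0) || any(moca_missing > 1))
    stopf("moca_missing must lie in [0, 1]")
  sds <- unlist(demographics[, grep("_sd$", names(demographics))])
  if (any(sds < 0) || atrophy_sd < 0 || noise_sd < 0 || brain_size_sd < 0)
    stopf("standard deviations must be nonnegative")
  if (!setequal(demographics$group, groups))
    stopf("demographics must contain rows for CN, MCI, AD")
  if (n_shared_fields < 2) stopf("n_shared_fields must be >= 2")

  structure(list(
    group_sizes = as.integer(group_sizes),
    groups = groups,
    demographics = demographics[match(groups, demographics$group), ],
    cdr = cdr_distributions(),
    image_shape = as.integer(image_shape),
    voxel_size_mm = voxel_size_mm,
    atrophy_level = atrophy_level,
    atrophy_sd = atrophy_sd,
    decoherence_level = decoherence_level,
    moca_coupling = moca_coupling,
    noise_sd = noise_sd,
    brain_size_sd = brain_size_sd,
    signal_amplitude = signal_amplitude,
    smoothing_fwhm_mm = smoothing_fwhm_mm,
    n_shared_fields = as.integer(n_shared_fields),
    moca_missing = moca_missing,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic GM cohort specification\n")
  cat(sprintf("  groups: CN=%d MCI=%d AD=%d subjects\n",
              x$group_sizes[1], x$group_sizes[2], x$group_sizes[3]))
  cat(sprintf("  image: %s voxels at %g mm\n",
              paste(x$image_shape, collapse = "x"), x$voxel_size_mm))
  cat(sprintf("  atrophy: %s  decoherence: %s\n",
              paste(signif(x$atrophy_level, 3), collapse = "/"),
              paste(signif(x$decoherence_level, 3), collapse = "/")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
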