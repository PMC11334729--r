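# Anatomical template and smooth random fields for the synthetic cohort.

fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm) {
  (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))
}

# Separable 3D Gaussian smoothing by banded convolution along each axis.
# Boundary rows are renormalized (truncated kernel), so a constant array is
# preserved exactly.
gaussian_smooth_3d <- function(x, sigma_vox) {
  if (sigma_vox <= 0) return(x)
  d <- dim(x)
  kernel_matrix <- function(n) {
    r <- max(1L, ceiling(3 * sigma_vox))
    k <- stats::dnorm(-r:r, sd = sigma_vox)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok]
      K[i, ] <- K[i, ] / sum(K[i, ])
    }
    K
  }
  # axis 1
  x <- array(kernel_matrix(d[1]) %*% matrix(x, d[1], d[2] * d[3]), d)
  # axis 2
  x <- aperm(x, c(2, 1, 3))
  x <- array(kernel_matrix(d[2]) %*% matrix(x, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
  x <- aperm(x, c(2, 1, 3))
  # axis 3
  x <- aperm(x, c(3, 1, 2))
  x <- array(kernel_matrix(d[3]) %*% matrix(x, d[3], d[1] * d[2]), c(d[3], d[1], d[2]))
  aperm(x, c(2, 3, 1))
}

# A unit-variance, zero-mean smooth Gaussian random field (draws from the
# current RNG stream).
smooth_field <- function(shape, sigma_vox) {
  f <- gaussian_smooth_3d(array(stats::rnorm(prod(shape)), shape), sigma_vox)
  (f - mean(f)) / stats::sd(f)
}

# Normalized coordinates: 0 at the image centre, 1 at 45% of each dimension.
normalized_coords <- function(shape) {
  lapply(seq_len(3L), function(a) {
    (seq_len(shape[a]) - (shape[a] + 1) / 2) / (0.45 * shape[a])
  })
}

#' Build the deterministic anatomical template
#'
#' A deterministic 3D GM field in \[0, 1\] shared by all subjects of a cohort:
#' an ellipsoidal GM volume with gently varying deep-GM density and zero
#' background (so corner cubes are empty and network size varies with the GM
#' support). The template is piecewise-constant at cube (3x3x3-voxel)
#' granularity with cube-aligned support, so every retained node has a
#' homogeneous tissue density: inter-cube correlations are then carried
#' entirely by the generative covariance model rather than by shared template
#' gradients, and signal-to-noise is uniform across nodes. The template
#' carries an \code{atrophy_mask} attribute marking the bilateral
#' inferior-lateral (temporal/parietal-like) vulnerable regions where
#' disease-related atrophy is applied — the ground-truth footprint for
#' voxel-wise mapping.
#'
#' @param spec a [cohort_spec()].
#' @return A [gm_image()] with attribute \code{atrophy_mask} (logical array).
#' @export
build_template <- function(spec) {
  shape <- spec$image_shape
  npa <- shape %/% 3L
  # normalized cube-center coordinates (0 at image centre, 1 at 45% extent)
  centers <- lapply(1:3, function(a) {
    v <- (seq_len(npa[a]) - 0.5) * 3
    (v - (shape[a] + 1) / 2) / (0.45 * shape[a])
  })
  cc <- expand.grid(x = centers[[1]], y = centers[[2]], z = centers[[3]])
  rho <- sqrt(cc$x^2 + cc$y^2 + cc$z^2)
  blob <- function(cx, cy, cz, amp, width) {
    amp * exp(-((cc$x - cx)^2 + (cc$y - cy)^2 + (cc$z - cz)^2) / width^2)
  }
  level <- 0.6 + blob(0.35, 0.2, -0.05, 0.15, 0.4) +
    blob(-0.35, 0.2, -0.05, 0.15, 0.4) +
    blob(0, -0.4, 0.15, 0.12, 0.35)
  cube_gm <- ifelse(rho <= 1, clamp(level, 0, 1), 0)

  # bilateral inferior-lateral vulnerable cubes
  cube_mask <- rho >= 0.5 & rho <= 1 & cc$z < -0.15 & abs(cc$x) > 0.25

  values <- expand_cube_signal(matrix(rep(cube_gm, each = 27), nrow = 27),
                               shape)
  mask_arr <- expand_cube_signal(matrix(rep(as.numeric(cube_mask & cube_gm > 0),
                                            each = 27), nrow = 27), shape) > 0
  img <- gm_image(values, voxel_size_mm = spec$voxel_size_mm,
                  subject_id = "template")
  attr(img, "atrophy_mask") <- mask_arr
  attr(img, "cube_rho") <- rho
  img
}
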