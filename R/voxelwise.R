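# Voxel-wise association mapping between the small-world coefficient and GM
# volume, with covariate control and permutation-based cluster correction.

image_stack <- function(images) {
  dims <- unique(lapply(images, function(im) dim(im$values)))
  if (length(dims) != 1L) stopf("images are not on one grid")
  Y <- vapply(images, function(im) as.vector(im$values),
              numeric(prod(dims[[1]])))
  list(Y = t(Y), dim = dims[[1]],
       voxel_size_mm = images[[1]]$voxel_size_mm)
}

#' Voxel-wise partial correlation map
#'
#' At each voxel with nonzero GM variance, the partial correlation across
#' subjects between voxel GM value and the small-world coefficient (sigma),
#' after regressing both on an intercept plus the nuisance covariates
#' (age, sex, TIV by default). Zero-variance voxels get r = 0 and are masked.
#'
#' @param images list of [gm_image()] on one grid (one per subject).
#' @param sigma per-subject small-world coefficient (numeric).
#' @param covariates data.frame of nuisance covariates (columns age, sex,
#'   TIV; sex may be "M"/"F").
#' @return An object of class \code{stat_map}: \code{r_map} (3D array),
#'   \code{z_map} (NULL until [r_to_z()]), \code{mask}, subject count and the
#'   residual data needed for permutation testing.
#' @export
voxelwise_partial_correlation <- function(images, sigma, covariates) {
  st <- image_stack(images)
  n <- nrow(st$Y)
  if (length(sigma) != n) stopf("sigma length must equal number of images")
  if (nrow(covariates) != n) stopf("covariates rows must equal number of images")
  if (n < ncol(covariates) + 4)
    stopf("need at least covariates + 4 subjects")
  X <- as.matrix(nuisance_design(covariates, covariates = names(covariates)))
  qrX <- qr(cbind(1, X))
  s_res <- qr.resid(qrX, sigma)
  Y_res <- qr.resid(qrX, st$Y)
  ynorm <- sqrt(colSums(Y_res^2))
  snorm <- sqrt(sum(s_res^2))
  mask <- ynorm > 1e-10 & snorm > 1e-10
  r <- numeric(ncol(Y_res))
  r[mask] <- as.vector(crossprod(Y_res[, mask, drop = FALSE], s_res)) /
    (ynorm[mask] * snorm)
  r <- clamp(r, -1, 1)
  structure(list(
    r_map = array(r, st$dim),
    z_map = NULL,
    mask = array(mask, st$dim),
    n_subjects = n,
    n_covariates = ncol(X),
    voxel_size_mm = st$voxel_size_mm,
    dim = st$dim,
    Y_res = Y_res, s_res = s_res, ynorm = ynorm
  ), class = "stat_map")
}

#' Fisher r-to-z transform for a partial-correlation map
#'
#' \eqn{z = \mathrm{atanh}(r) \sqrt{n - c - 3}} where \eqn{c} is the number of
#' nuisance covariates, stored alongside the r map.
#'
#' @param map a [voxelwise_partial_correlation()] result.
#' @return The map with \code{z_map} filled in.
#' @export
r_to_z <- function(map) {
  dof <- map$n_subjects - map$n_covariates - 3
  if (dof <= 0) stopf("insufficient subjects for the r-to-z transform")
  r <- clamp(map$r_map, -1 + 1e-12, 1 - 1e-12)
  map$z_map <- atanh(r) * sqrt(dof)
  map$z_map[!map$mask] <- 0
  map
}

# Connected components of a voxel index set under 6-connectivity
# (face-adjacent). Returns a list of integer vectors of linear voxel indices.
components_6conn <- function(idx, dim) {
  if (length(idx) == 0L) return(list())
  coords <- arrayInd(idx, dim)
  strides <- c(1L, dim[1], dim[1] * dim[2])
  edges <- NULL
  for (a in 1:3) {
    ok <- coords[, a] < dim[a]
    if (!any(ok)) next
    nb <- idx[ok] + strides[a]
    m <- match(nb, idx)
    hit <- !is.na(m)
    if (any(hit)) {
      edges <- rbind(edges, cbind(which(ok)[hit], m[hit]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  split(idx, comp$membership)
}

#' Cluster-level thresholding with a permutation null
#'
#' Thresholds the z map at \code{|z| > voxel_z} (two-tailed), labels
#' 6-connectivity clusters, and assigns each a cluster-level p-value from a
#' permutation null: the sigma residuals are permuted across subjects
#' \code{n_perm} times, the map recomputed, and the maximum suprathreshold
#' cluster size recorded per permutation. Clusters with permutation
#' p < \code{cluster_p} survive. With \code{n_perm = 0}, an extent-only mode
#' keeps clusters of at least \code{min_extent} voxels.
#'
#' @param map a [r_to_z()]-transformed \code{stat_map}.
#' @param voxel_z voxel-level |z| threshold (default 3.29, i.e. two-tailed
#'   p < 0.001).
#' @param cluster_p cluster-level significance (default 0.05).
#' @param n_perm number of permutations (default 1000; a warning below 100).
#' @param seed RNG seed for the permutations.
#' @param min_extent minimum cluster size (voxels) in extent-only mode.
#' @return A data.frame of class \code{cluster_table}, one row per surviving
#'   cluster: cluster_id, size_voxels, peak voxel coordinates (0-based) and mm
#'   coordinates, peak_z, p_cluster; sorted by decreasing size. Cluster voxel
#'   indices are attached as attribute \code{members}.
#' @export
cluster_threshold <- function(map, voxel_z = 3.29, cluster_p = 0.05,
                              n_perm = 1000L, seed = 1L, min_extent = 100L) {
  if (is.null(map$z_map)) stopf("run r_to_z() before cluster thresholding")
  if (n_perm > 0 && n_perm < 100)
    warning("fewer than 100 permutations gives a coarse cluster null")
  dof <- sqrt(map$n_subjects - map$n_covariates - 3)
  idx <- which(abs(map$z_map) > voxel_z)
  comps <- components_6conn(idx, map$dim)
  sizes <- lengths(comps)

  if (n_perm > 0 && length(comps) > 0) {
    # permutation null of the maximum cluster size
    snorm <- sqrt(sum(map$s_res^2))
    r_thresh <- tanh(voxel_z / dof)
    max_sizes <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        sp <- map$s_res[sample.int(length(map$s_res))]
        r <- numeric(length(map$ynorm))
        ok <- map$mask
        r[ok] <- as.vector(crossprod(map$Y_res[, ok, drop = FALSE], sp)) /
          (map$ynorm[ok] * snorm)
        idx_b <- which(abs(r) > r_thresh)
        cb <- components_6conn(idx_b, map$dim)
        if (length(cb) == 0L) 0L else max(lengths(cb))
      }, integer(1))
    })
    p_cluster <- vapply(sizes, function(s)
      (1 + sum(max_sizes >= s)) / (n_perm + 1), numeric(1))
    keep <- p_cluster < cluster_p
  } else {
    p_cluster <- rep(NA_real_, length(comps))
    keep <- sizes >= min_extent
  }

  comps <- comps[keep]
  sizes <- sizes[keep]
  p_cluster <- p_cluster[keep]
  rows <- lapply(seq_along(comps), function(i) {
    vox <- comps[[i]]
    z <- map$z_map[vox]
    pk <- vox[which.max(abs(z))]
    co <- arrayInd(pk, map$dim) - 1L
    data.frame(cluster_id = i, size_voxels = sizes[i],
               peak_x_vox = co[1], peak_y_vox = co[2], peak_z_vox = co[3],
               peak_x_mm = co[1] * map$voxel_size_mm,
               peak_y_mm = co[2] * map$voxel_size_mm,
               peak_z_mm = co[3] * map$voxel_size_mm,
               peak_z_value = z[which.max(abs(z))],
               p_cluster = p_cluster[i], stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(0), size_voxels = integer(0),
               peak_x_vox = integer(0), peak_y_vox = integer(0),
               peak_z_vox = integer(0), peak_x_mm = numeric(0),
               peak_y_mm = numeric(0), peak_z_mm = numeric(0),
               peak_z_value = numeric(0), p_cluster = numeric(0))
  ord <- order(-out$size_voxels)
  out <- out[ord, , drop = FALSE]
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "members") <- comps[ord]
  attr(out, "voxel_z") <- voxel_z
  attr(out, "connectivity") <- "6 (face-adjacent)"
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Render the cluster table
#'
#' Clusters sorted by decreasing size with peak coordinates in mm and peak z
#' (no anatomical labels; coordinates are in the synthetic image space).
#'
#' @param clusters a [cluster_threshold()] result.
#' @return The same data.frame, printed with a header.
#' @export
cluster_report <- function(clusters) {
  cat(sprintf("Clusters at |z| > %.2f (%s connectivity)\n",
              attr(clusters, "voxel_z"), attr(clusters, "connectivity")))
  if (nrow(clusters) == 0L) {
    cat("  (no surviving clusters)\n")
  } else {
    print(as.data.frame(clusters)[, c("cluster_id", "size_voxels",
                                      "peak_x_mm", "peak_y_mm", "peak_z_mm",
                                      "peak_z_value", "p_cluster")],
          digits = 3, row.names = FALSE)
  }
  invisible(clusters)
}

#' Write statistical maps as NIfTI-1 volumes
#'
#' @param map a \code{stat_map}.
#' @param prefix output path prefix; writes \code{<prefix>_r.nii.gz} and, if
#'   present, \code{<prefix>_z.nii.gz}.
#' @return Written paths, invisibly.
#' @export
write_stat_map <- function(map, prefix) {
  paths <- character(0)
  # r and z maps can be negative, so write arrays directly (not via gm_image)
  write_raw <- function(arr, path) {
    nii <- RNifti::asNifti(arr)
    RNifti::pixdim(nii) <- rep(map$voxel_size_mm, 3)
    RNifti::writeNifti(nii, path, datatype = "float")
    path
  }
  paths <- c(paths, write_raw(map$r_map, paste0(prefix, "_r.nii.gz")))
  if (!is.null(map$z_map))
    paths <- c(paths, write_raw(map$z_map, paste0(prefix, "_z.nii.gz")))
  invisible(paths)
}
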