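#' Partition a GM image into cube nodes
#'
#' Divides the voxel grid into non-overlapping, axis-aligned
#' \code{cube_edge}^3-voxel cubes starting at the image origin; trailing voxels
#' that do not fill a cube are discarded. A cube is retained as a network node
#' iff at least one of its voxels has GM value > \code{gm_eps}, so background
#' cubes are excluded and network size varies by subject.
#'
#' @param image a [gm_image()].
#' @param cube_edge voxels per cube edge (default 3, i.e. 6 mm at 2 mm voxels).
#' @param gm_eps GM presence threshold for node retention (default 0.05).
#' @return An object of class \code{cube_grid}: list with \code{origins}
#'   (n x 3 matrix of 0-based voxel origins of all candidate cubes),
#'   \code{retained} (logical), \code{cube_edge}, \code{n_per_axis}.
#' @export
partition_cubes <- function(image, cube_edge = 3L, gm_eps = 0.05) {
  d <- dim(image$values)
  if (any(d < cube_edge)) stopf("image is smaller than one cube per axis")
  npa <- d %/% cube_edge
  M <- cube_value_matrix(image$values, cube_edge)
  idx <- as.matrix(expand.grid(i = seq_len(npa[1]), j = seq_len(npa[2]),
                               k = seq_len(npa[3])))
  origins <- (idx - 1L) * cube_edge
  colnames(origins) <- c("x", "y", "z")
  retained <- matrixStats_colMax(M) > gm_eps
  structure(list(origins = origins, retained = retained,
                 cube_edge = as.integer(cube_edge), n_per_axis = npa,
                 gm_eps = gm_eps),
            class = "cube_grid")
}

# columnwise max without extra deps
matrixStats_colMax <- function(M) apply(M, 2L, max)

# Rearrange a 3D array into a (cube_edge^3) x n_cubes matrix; cube order is
# column-major over cube indices, matching expand.grid in partition_cubes.
cube_value_matrix <- function(values, cube_edge = 3L) {
  d <- dim(values)
  npa <- d %/% cube_edge
  v <- values[seq_len(npa[1] * cube_edge),
              seq_len(npa[2] * cube_edge),
              seq_len(npa[3] * cube_edge), drop = FALSE]
  dim(v) <- c(cube_edge, npa[1], cube_edge, npa[2], cube_edge, npa[3])
  v <- aperm(v, c(1, 3, 5, 2, 4, 6))
  dim(v) <- c(cube_edge^3, prod(npa))
  v
}

#' Extract retained cube values
#'
#' @param image a [gm_image()].
#' @param grid a [partition_cubes()] result.
#' @return A (cube_edge^3) x n_retained matrix, one column per network node.
#' @export
cube_values <- function(image, grid) {
  M <- cube_value_matrix(image$values, grid$cube_edge)
  M[, grid$retained, drop = FALSE]
}

#' Pearson correlation between two cubes
#'
#' Standard Pearson correlation over the aligned (corresponding-position)
#' voxel values of two cubes. Returns \code{NA} when either vector has zero
#' variance (the undefined-correlation marker).
#'
#' @param values_i,values_j numeric vectors of equal length (27 for the
#'   default 3-voxel cube edge).
#' @return Correlation coefficient, or \code{NA} if undefined.
#' @export
cube_pair_correlation <- function(values_i, values_j) {
  if (length(values_i) != length(values_j))
    stopf("cube value vectors differ in length")
  if (!all(is.finite(values_i)) || !all(is.finite(values_j)))
    stopf("cube values must be finite")
  if (stats::sd(values_i) == 0 || stats::sd(values_j) == 0) return(NA_real_)
  stats::cor(values_i, values_j)
}

# The 48 rotation/reflection symmetries of the cube, as index permutations of
# a cube_edge^3 vector (generated by composing axis permutations and flips).
cube_symmetry_permutations <- function(cube_edge = 3L) {
  n <- cube_edge
  base <- array(seq_len(n^3), c(n, n, n))
  perms <- list()
  seen <- character(0)
  axes <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
               c(3, 1, 2), c(3, 2, 1))
  flips <- expand.grid(f1 = c(FALSE, TRUE), f2 = c(FALSE, TRUE),
                       f3 = c(FALSE, TRUE))
  for (a in axes) {
    for (r in seq_len(nrow(flips))) {
      arr <- aperm(base, a)
      if (flips$f1[r]) arr <- arr[n:1, , , drop = FALSE]
      if (flips$f2[r]) arr <- arr[, n:1, , drop = FALSE]
      if (flips$f3[r]) arr <- arr[, , n:1, drop = FALSE]
      key <- paste(arr, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        perms[[length(perms) + 1L]] <- as.vector(arr)
      }
    }
  }
  perms
}

#' Build the inter-cube similarity matrix
#'
#' Pearson correlations between all pairs of retained cubes (27 aligned voxel
#' values per cube by default). Undefined correlations (zero-variance cubes)
#' are recorded as 0; their count is attached as attributes. With
#' \code{max_rotation = TRUE} the similarity of a pair is the maximum
#' correlation over the 48 rotation/reflection symmetries of the cube (the
#' orientation-invariant variant of the construction method).
#'
#' @param image a [gm_image()].
#' @param grid a [partition_cubes()] result built from the same image.
#' @param max_rotation maximize correlation over cube symmetries (default
#'   FALSE: plain aligned-voxel correlation).
#' @return A symmetric n x n matrix of class \code{similarity_matrix} with
#'   attributes \code{n_obs} (voxels per cube), \code{n_zero_variance}
#'   (zero-variance nodes) and \code{n_undefined_pairs}.
#' @export
build_similarity_matrix <- function(image, grid, max_rotation = FALSE) {
  M <- cube_values(image, grid)
  n <- ncol(M)
  if (n == 0L) stopf("empty network: no retained cubes")
  sds <- apply(M, 2L, stats::sd)
  zero_var <- sds == 0
  if (max_rotation) {
    perms <- cube_symmetry_permutations(grid$cube_edge)
    R <- matrix(-Inf, n, n)
    for (p in perms) {
      R <- suppressWarnings(pmax(R, stats::cor(M, M[p, , drop = FALSE])))
    }
    # symmetrize: max over orientations of either member of a pair
    R <- pmax(R, t(R))
  } else {
    R <- suppressWarnings(stats::cor(M))
  }
  R[is.na(R)] <- 0
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  n_undef <- sum(zero_var) * (n - 1) - choose(sum(zero_var), 2)
  structure(R, class = c("similarity_matrix", "matrix"),
            n_obs = nrow(M), n_zero_variance = sum(zero_var),
            n_undefined_pairs = n_undef)
}

#' Binarize a similarity matrix by FDR control
#'
#' Converts each unique pair's correlation to a t statistic
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with \eqn{n - 2} degrees of freedom
#' (\eqn{n} = voxels per cube, 27 by default), computes the one-sided p-value
#' for positive association, applies Benjamini-Hochberg control at level
#' \code{q} across all unique pairs of this network, and sets an edge for
#' pairs that are BH-significant and have \eqn{r > 0}. Negative correlations
#' never form edges.
#'
#' @param sim a [build_similarity_matrix()] result.
#' @param q FDR level (default 0.05).
#' @return A symmetric binary matrix of class \code{adjacency_matrix} with a
#'   zero diagonal and attributes \code{n_edges} and \code{q}.
#' @export
threshold_fdr <- function(sim, q = 0.05) {
  if (length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1)
    stopf("q must lie strictly between 0 and 1")
  n_obs <- attr(sim, "n_obs")
  if (is.null(n_obs) || n_obs < 3) stopf("similarity matrix needs n_obs >= 3")
  n <- nrow(sim)
  ut <- upper.tri(sim)
  r <- sim[ut]
  r_c <- clamp(r, -1 + 1e-15, 1 - 1e-15)
  tstat <- r_c * sqrt((n_obs - 2) / (1 - r_c^2))
  tstat[r >= 1] <- Inf
  tstat[r <= -1] <- -Inf
  p <- stats::pt(tstat, df = n_obs - 2, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = "BH")
  edge <- p_adj <= q & r > 0
  A <- matrix(0L, n, n)
  A[ut][edge] <- 1L
  A <- A + t(A)
  structure(A, class = c("adjacency_matrix", "matrix"),
            n_edges = sum(edge), q = q, mode = "fdr")
}

#' Binarize a similarity matrix at a fixed connectivity density
#'
#' Alternative thresholding mode for sensitivity analyses: keeps the top
#' \code{density} fraction of positive correlations as edges.
#'
#' @param sim a [build_similarity_matrix()] result.
#' @param density target fraction of all possible edges, in (0, 1).
#' @return An \code{adjacency_matrix} as in [threshold_fdr()].
#' @export
threshold_density <- function(sim, density = 0.05) {
  if (density <= 0 || density >= 1) stopf("density must lie in (0, 1)")
  n <- nrow(sim)
  ut <- upper.tri(sim)
  r <- sim[ut]
  k <- floor(density * length(r))
  edge <- logical(length(r))
  if (k > 0) {
    ord <- order(r, decreasing = TRUE)[seq_len(k)]
    edge[ord] <- r[ord] > 0
  }
  A <- matrix(0L, n, n)
  A[ut][edge] <- 1L
  A <- A + t(A)
  structure(A, class = c("adjacency_matrix", "matrix"),
            n_edges = sum(edge), density_target = density, mode = "density")
}

#' Fit a single-subject gray-matter network
#'
#' The main per-subject constructor: partitions the GM image into cube nodes,
#' correlates all retained cube pairs, and binarizes by FDR (default) or at a
#' fixed density. The result is an unweighted, undirected graph.
#'
#' @param image a [gm_image()].
#' @param q FDR level for binarization (default 0.05).
#' @param cube_edge voxels per cube edge (default 3).
#' @param gm_eps GM presence threshold for node retention (default 0.05).
#' @param mode \code{"fdr"} (default) or \code{"density"}.
#' @param density target density when \code{mode = "density"}.
#' @param max_rotation use the orientation-maximized cube correlation.
#' @param keep_similarity retain the similarity matrix in the result.
#' @return An object of class \code{gm_network}: adjacency, cube grid, node
#'   count, edge count, connectivity density (percent), and construction
#'   parameters.
#' @export
gm_network <- function(image, q = 0.05, cube_edge = 3L, gm_eps = 0.05,
                       mode = c("fdr", "density"), density = 0.05,
                       max_rotation = FALSE, keep_similarity = FALSE) {
  mode <- match.arg(mode)
  grid <- partition_cubes(image, cube_edge = cube_edge, gm_eps = gm_eps)
  if (!any(grid$retained)) stopf("empty network: image has no GM above gm_eps")
  sim <- build_similarity_matrix(image, grid, max_rotation = max_rotation)
  adj <- if (mode == "fdr") threshold_fdr(sim, q = q) else
    threshold_density(sim, density = density)
  n <- nrow(adj)
  E <- attr(adj, "n_edges")
  structure(list(
    adjacency = adj,
    grid = grid,
    similarity = if (keep_similarity) sim else NULL,
    subject_id = image$subject_id,
    voxel_size_mm = image$voxel_size_mm,
    n_nodes = n,
    n_edges = E,
    density_percent = if (n >= 2) 100 * E / (n * (n - 1) / 2) else NA_real_,
    q = q, gm_eps = gm_eps, cube_edge = as.integer(cube_edge),
    mode = mode, max_rotation = max_rotation,
    n_zero_variance = attr(sim, "n_zero_variance")
  ), class = "gm_network")
}

#' @export
print.gm_network <- function(x, ...) {
  cat(sprintf("Single-subject GM network '%s'\n", x$subject_id))
  cat(sprintf("  nodes: %d (%d-voxel cubes, gm_eps %g)\n",
              x$n_nodes, x$cube_edge^3, x$gm_eps))
  cat(sprintf("  edges: %d (density %.2f%%), %s binarization%s\n",
              x$n_edges, x$density_percent,
              if (x$mode == "fdr") sprintf("FDR q=%g", x$q) else "fixed-density",
              if (x$max_rotation) ", rotation-maximized" else ""))
  invisible(x)
}

#' @export
summary.gm_network <- function(object, n_random = 20L, seed = 1L, ...) {
  m <- compute_global_metrics(object, n_random = n_random, seed = seed)
  print(object)
  print(m)
  invisible(m)
}

#' @export
plot.gm_network <- function(x, ...) {
  k <- colSums(x$adjacency)
  graphics::hist(k, breaks = "FD", main = sprintf("Degree distribution (%s)",
                                                  x$subject_id),
                 xlab = "node degree", col = "grey80", border = "white", ...)
  invisible(x)
}
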