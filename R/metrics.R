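# Global graph metrics and small-world normalization.

as_adjacency <- function(x) {
  if (inherits(x, "gm_network")) return(x$adjacency)
  if (is.matrix(x)) {
    if (!isTRUE(all.equal(unname(x), unname(t(x)))))
      stopf("adjacency matrix must be symmetric")
    if (any(x != 0 & x != 1)) stopf("adjacency entries must be 0/1")
    if (any(diag(x) != 0)) stopf("adjacency diagonal must be zero")
    return(x)
  }
  stopf("expected a gm_network or an adjacency matrix")
}

as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' Mean degree
#'
#' Average number of connections per node, \eqn{2E/N}; 0 for an edgeless graph.
#'
#' @param adj an adjacency matrix or [gm_network()].
#' @return Scalar mean degree.
#' @export
mean_degree <- function(adj) {
  A <- as_adjacency(adj)
  if (nrow(A) == 0L) return(0)
  mean(colSums(A))
}

#' Connectivity density (percent)
#'
#' Percentage of existing connections among all possible node pairs,
#' \eqn{100 E / (N(N-1)/2)}.
#'
#' @inheritParams mean_degree
#' @return Scalar percent in \[0, 100\].
#' @export
connectivity_density <- function(adj) {
  A <- as_adjacency(adj)
  n <- nrow(A)
  if (n < 2) stopf("connectivity density undefined for fewer than 2 nodes")
  100 * sum(A) / (n * (n - 1))
}

#' Average clustering coefficient
#'
#' Mean over all nodes of \eqn{C_i = 2 t_i / (k_i (k_i - 1))} where \eqn{t_i}
#' is the number of edges among node i's neighbors; nodes with degree < 2
#' contribute \eqn{C_i = 0}.
#'
#' @inheritParams mean_degree
#' @return Scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(adj) {
  A <- as_adjacency(adj)
  if (nrow(A) == 0L) return(0)
  clustering_igraph(as_igraph(A))
}

clustering_igraph <- function(g) {
  val <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  if (is.nan(val)) 0 else val
}

path_length_igraph <- function(g) {
  if (igraph::ecount(g) == 0L)
    stopf("path length undefined: graph has no edges")
  comp <- igraph::components(g)
  biggest <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == biggest))
  L <- igraph::mean_distance(sub, directed = FALSE, unconnected = FALSE)
  structure(L, component_fraction = max(comp$csize) / igraph::vcount(g))
}

#' Characteristic path length
#'
#' Average shortest-path length (in edges) over all pairs of nodes within the
#' largest connected component. The fraction of nodes belonging to that
#' component is attached as attribute \code{component_fraction}.
#'
#' @inheritParams mean_degree
#' @return Scalar path length with attribute \code{component_fraction}.
#' @export
characteristic_path_length <- function(adj) {
  A <- as_adjacency(adj)
  path_length_igraph(as_igraph(A))
}

#' Degree-preserving randomization
#'
#' Maslov-Sneppen double-edge-swap rewiring: attempts
#' \code{n_swaps_per_edge * E} swaps, rejecting any that would create
#' self-loops or multi-edges. The degree sequence is preserved exactly.
#'
#' @inheritParams mean_degree
#' @param n_swaps_per_edge swap attempts per edge (default 10).
#' @param seed integer RNG seed.
#' @return A rewired adjacency matrix of class \code{adjacency_matrix}.
#' @export
randomize_degree_preserving <- function(adj, n_swaps_per_edge = 10L, seed = 1L) {
  A <- as_adjacency(adj)
  E <- sum(A) / 2
  if (E < 2) {
    warning("graph has no swappable edge pair; returning input unchanged")
    return(A)
  }
  g <- as_igraph(A)
  rg <- with_seed(seed, {
    igraph::rewire(g, with = igraph::keeping_degseq(
      loops = FALSE, niter = ceiling(n_swaps_per_edge * E)))
  })
  B <- as.matrix(igraph::as_adjacency_matrix(rg, type = "both", sparse = TRUE))
  storage.mode(B) <- "integer"
  structure(B, class = c("adjacency_matrix", "matrix"), n_edges = E)
}

#' Small-world metrics
#'
#' Normalized clustering coefficient (gamma), normalized path length (lambda)
#' and the small-world coefficient (sigma = gamma / lambda), computed against
#' \code{n_random} degree-preserving random reference graphs: gamma = C /
#' mean(C_rand), lambda = L / mean(L_rand). A replicate whose path length is
#' undefined is skipped and counted.
#'
#' @inheritParams mean_degree
#' @param n_random number of random reference graphs (default 20).
#' @param seed master seed; replicate seeds are derived from it.
#' @return List with gamma, lambda, sigma, the per-replicate C_rand / L_rand
#'   values, and \code{n_used}.
#' @export
small_world_metrics <- function(adj, n_random = 20L, seed = 1L) {
  A <- as_adjacency(adj)
  g <- as_igraph(A)
  C <- clustering_igraph(g)
  L <- as.numeric(path_length_igraph(g))
  seeds <- derive_seeds(seed, n_random)
  E <- igraph::ecount(g)
  C_rand <- numeric(0)
  L_rand <- numeric(0)
  skipped <- 0L
  for (i in seq_len(n_random)) {
    rg <- if (E < 2) g else with_seed(seeds[i], {
      igraph::rewire(g, with = igraph::keeping_degseq(loops = FALSE,
                                                      niter = 10L * E))
    })
    Lr <- tryCatch(as.numeric(path_length_igraph(rg)),
                   error = function(e) NA_real_)
    if (!is.finite(Lr)) {
      skipped <- skipped + 1L
      next
    }
    C_rand <- c(C_rand, clustering_igraph(rg))
    L_rand <- c(L_rand, Lr)
  }
  if (length(L_rand) == 0L)
    stopf("all %d random replicates had undefined path length", n_random)
  gamma <- C / mean(C_rand)
  lambda <- L / mean(L_rand)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       C = C, L = L, C_rand = C_rand, L_rand = L_rand,
       n_used = length(L_rand), n_skipped = skipped)
}

#' Compute all global network metrics for one subject
#'
#' Composes network size, mean degree, connectivity density, clustering
#' coefficient, characteristic path length, and the small-world metrics
#' gamma, lambda and sigma (sigma stored as gamma/lambda exactly).
#'
#' @inheritParams small_world_metrics
#' @return An object of class \code{global_metrics} (also a one-row list
#'   convertible with [as.data.frame()]).
#' @export
compute_global_metrics <- function(adj, n_random = 20L, seed = 1L) {
  A <- as_adjacency(adj)
  sid <- if (inherits(adj, "gm_network")) adj$subject_id else NA_character_
  L <- characteristic_path_length(A)
  sw <- small_world_metrics(A, n_random = n_random, seed = seed)
  structure(list(
    subject_id = sid,
    network_size = nrow(A),
    degree = mean_degree(A),
    connectivity_density = connectivity_density(A),
    clustering_coefficient = clustering_coefficient(A),
    path_length = as.numeric(L),
    gamma = sw$gamma,
    lambda = sw$lambda,
    sigma = sw$sigma,
    component_fraction = attr(L, "component_fraction"),
    n_random = as.integer(n_random),
    n_random_used = sw$n_used,
    random_seed = as.integer(seed)
  ), class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat("Global network metrics\n")
  cat(sprintf("  size %d, degree %.2f, density %.2f%%\n",
              x$network_size, x$degree, x$connectivity_density))
  cat(sprintf("  C %.4f, L %.4f (component %.1f%%)\n",
              x$clustering_coefficient, x$path_length,
              100 * x$component_fraction))
  cat(sprintf("  gamma %.4f, lambda %.4f, sigma %.4f (%d random refs)\n",
              x$gamma, x$lambda, x$sigma, x$n_random_used))
  invisible(x)
}

#' @export
as.data.frame.global_metrics <- function(x, ...) {
  data.frame(subject_id = x$subject_id, network_size = x$network_size,
             degree = x$degree, connectivity_density = x$connectivity_density,
             clustering_coefficient = x$clustering_coefficient,
             path_length = x$path_length, gamma = x$gamma, lambda = x$lambda,
             sigma = x$sigma, component_fraction = x$component_fraction,
             n_random = x$n_random, random_seed = x$random_seed,
             stringsAsFactors = FALSE)
}

#' Per-subject metrics for a whole cohort
#'
#' Builds each subject's network and computes its global metrics; per-subject
#' randomization seeds are derived from \code{seed}.
#'
#' @param cohort a \code{gm_cohort} (or list of [gm_image()]).
#' @param q,cube_edge,gm_eps passed to [gm_network()].
#' @param n_random random reference graphs per subject.
#' @param seed master seed.
#' @return A data.frame, one row per subject, covariates not included.
#' @export
cohort_global_metrics <- function(cohort, q = 0.05, cube_edge = 3L,
                                  gm_eps = 0.05, n_random = 20L, seed = 1L) {
  images <- if (inherits(cohort, "gm_cohort")) cohort$images else cohort
  seeds <- derive_seeds(seed, length(images))
  rows <- lapply(seq_along(images), function(i) {
    net <- gm_network(images[[i]], q = q, cube_edge = cube_edge,
                      gm_eps = gm_eps)
    as.data.frame(compute_global_metrics(net, n_random = n_random,
                                         seed = seeds[i]))
  })
  do.call(rbind, rows)
}
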