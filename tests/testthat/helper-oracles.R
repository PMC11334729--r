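# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (triangle enumeration, Floyd-Warshall, hand-rolled
# step-up) so they share no code path with the implementation.

# clustering coefficient by explicit triangle enumeration over neighbor pairs
oracle_clustering <- function(A) {
  n <- nrow(A)
  if (n == 0) return(0)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (A[nb[a], nb[b]] == 1) t_i <- t_i + 1
      }
    }
    ci[i] <- 2 * t_i / (k * (k - 1))
  }
  mean(ci)
}

# all-pairs shortest paths by Floyd-Warshall; mean over pairs within the
# largest connected component
oracle_path_length <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  # connected components from reachability
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[is.finite(D[i, ])] <- cid
    }
  }
  sizes <- table(comp)
  big <- as.integer(names(sizes)[which.max(sizes)])
  idx <- which(comp == big)
  if (length(idx) < 2) stop("largest component has no pairs")
  sub <- D[idx, idx]
  mean(sub[upper.tri(sub)])
}

# Benjamini-Hochberg step-up adjusted p-values, from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# seeded Erdos-Renyi adjacency matrix
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  ut <- upper.tri(A)
  A[ut] <- as.integer(runif(sum(ut)) < p)
  A + t(A)
}

# ring lattice: n nodes, each connected to k nearest neighbors (k even)
ring_lattice <- function(n, k) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (s in seq_len(k / 2)) {
      j <- ((i - 1 + s) %% n) + 1
      A[i, j] <- A[j, i] <- 1L
    }
  }
  A
}

complete_graph <- function(n) {
  A <- matrix(1L, n, n)
  diag(A) <- 0L
  A
}

# small default cohort spec used across tests (fast but structurally faithful)
small_spec <- function(n = 2, shape = c(24, 24, 24), seed = 1, ...) {
  cohort_spec(group_sizes = c(CN = n, MCI = n, AD = n),
              image_shape = shape, seed = seed, ...)
}

# a deterministic GM image with nonzero variance in every cube
uniform_image <- function(shape = c(30, 30, 30), value = 0.5, jitter_seed = 1) {
  set.seed(jitter_seed)
  vals <- array(value + 0.1 * runif(prod(shape)), shape)
  gm_image(vals, voxel_size_mm = 2, subject_id = "uniform")
}
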