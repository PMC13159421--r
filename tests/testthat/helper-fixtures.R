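# shared fixtures, built in code at test time

# two (or more) well-separated Gaussian blobs in g dimensions
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  centers <- as.matrix(centers)
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    matrix(rnorm(n_per * ncol(centers), sd = sd),
      n_per, ncol(centers),
      byrow = TRUE
    ) + matrix(centers[k, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# the standard planted-domain fixture used across end-to-end tests
standard_fixture <- function(seed = 7) {
  generate_dataset(synthetic_spec(
    n_spots = 600, n_genes = 60, n_domains = 4,
    effect_size = 3, noise_sd = 1, seed = seed
  ))
}

# a light training configuration for test-scale runs
test_config <- function(...) {
  run_config(
    hidden_dims = 64L, d_h = 32L,
    N_way = 4L, M_shot = 5L, Q_query = 12L,
    episodes_per_epoch = 25L, n_epochs = 6L,
    ...
  )
}

# brute-force k-NN adjacency oracle: sort all pairwise distances per node,
# ties broken by lower index, union-symmetrised
knn_oracle <- function(coords, k) {
  C <- nrow(coords)
  D <- as.matrix(dist(coords))
  A <- matrix(0, C, C)
  if (C >= 2) {
    for (v in seq_len(C)) {
      ord <- order(D[v, -v], seq_len(C)[-v])
      nb <- (seq_len(C)[-v])[ord][seq_len(min(k, C - 1))]
      A[v, nb] <- 1
    }
  }
  pmax(A, t(A))
}

# BFS depth-2 oracle for two-hop node sets
bfs2_oracle <- function(A, v) {
  C <- nrow(A)
  dist <- rep(Inf, C)
  dist[v] <- 0
  frontier <- v
  for (hop in 1:2) {
    nxt <- integer(0)
    for (u in frontier) {
      nb <- which(A[u, ] > 0)
      new <- nb[dist[nb] == Inf]
      dist[new] <- hop
      nxt <- c(nxt, new)
    }
    frontier <- nxt
  }
  sort(which(dist <= 2))
}

# random small graph as a dense symmetric adjacency
random_graph <- function(C, p = 0.1) {
  A <- matrix(rbinom(C * C, 1, p), C, C)
  A[lower.tri(A, diag = TRUE)] <- 0
  pmax(A, t(A))
}

# hand-rolled finite-difference gradient of a scalar function of params
finite_diff_grad <- function(f, params, layer, i, j, eps = 1e-5) {
  p1 <- params
  p1$weights[[layer]][i, j] <- p1$weights[[layer]][i, j] + eps
  p2 <- params
  p2$weights[[layer]][i, j] <- p2$weights[[layer]][i, j] - eps
  (f(p1) - f(p2)) / (2 * eps)
}
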