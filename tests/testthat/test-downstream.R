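test_that("exact point-clusters are recovered with zero objective", {
  H <- rbind(
    matrix(rep(c(0, 0), 5), 5, 2, byrow = TRUE),
    matrix(rep(c(3, 3), 5), 5, 2, byrow = TRUE)
  )
  dom <- identify_domains(H, 2, seed = 1)
  expect_equal(dom$objective, 0)
  expect_length(unique(dom$assignments[1:5]), 1)
  expect_length(unique(dom$assignments[6:10]), 1)
  expect_false(dom$assignments[1] == dom$assignments[6])
})

test_that("K equal to the spot count gives one spot per domain", {
  set.seed(2)
  H <- matrix(rnorm(12), 6, 2)
  dom <- identify_domains(H, 6, seed = 1)
  expect_equal(sort(dom$assignments), 1:6)
  expect_equal(dom$objective, 0, tolerance = 1e-12)
})

test_that("K-means beats 1000 random assignments and restates its objective", {
  set.seed(3)
  H <- matrix(rnorm(60), 20, 3)
  dom <- identify_domains(H, 3, seed = 5)
  # invariant: reported objective equals direct recomputation
  direct <- sum((H - dom$centroids[dom$assignments, ])^2)
  expect_equal(dom$objective, direct, tolerance = 1e-6)
  # oracle bound: no random assignment does better
  rand_obj <- replicate(1000, {
    a <- sample(1:3, 20, replace = TRUE)
    cent <- t(sapply(1:3, function(k) {
      if (any(a == k)) colMeans(H[a == k, , drop = FALSE]) else rep(Inf, 3)
    }))
    sum((H - cent[a, ])^2)
  })
  expect_lte(dom$objective, min(rand_obj) + 1e-9)
})

test_that("the Lloyd objective never increases across iterations", {
  set.seed(4)
  for (trial in 1:10) {
    H <- matrix(rnorm(40 * 2), 40, 2)
    dom <- identify_domains(H, 4, seed = trial, n_restarts = 1)
    expect_true(all(diff(dom$objective_trace) <= 1e-9))
  }
})

test_that("identify_domains agrees with stats::kmeans on easy data", {
  blobs <- make_blobs(30, rbind(c(0, 0), c(8, 0), c(0, 8)), sd = 0.5, seed = 6)
  dom <- identify_domains(blobs$X, 3, seed = 1)
  km <- stats::kmeans(blobs$X, 3, nstart = 10)
  expect_equal(clustering_metrics(dom$assignments, km$cluster)[["ari"]], 1)
  expect_equal(dom$objective, km$tot.withinss, tolerance = 1e-8)
})

test_that("rejects more domains than spots", {
  expect_error(identify_domains(matrix(0, 3, 2), 4), "exceed")
})

test_that("a noiseless linear map is recovered exactly", {
  set.seed(7)
  H <- matrix(rnorm(50 * 4), 50, 4)
  W <- matrix(rnorm(4 * 6), 4, 6)
  b <- rnorm(6)
  X <- sweep(H %*% W, 2, b, "+")
  head <- fit_imputation_head(H, X, lambda = 0)
  xhat <- impute_expression(H, head)
  expect_equal(xhat, X, tolerance = 1e-8)
  expect_gte(imputation_metrics(xhat, X + rnorm(300, sd = 1e-9))[["pcc"]], 0.999)
})

test_that("a constant embedding column yields zero weights and mean biases", {
  H <- matrix(1, 20, 1)
  set.seed(8)
  X <- matrix(rnorm(40, mean = 5), 20, 2)
  head <- fit_imputation_head(H, X, lambda = 1e-3)
  expect_equal(max(abs(head$W_X)), 0, tolerance = 1e-8)
  expect_equal(head$b_X, colMeans(X), tolerance = 1e-8)
})

test_that("ridge solution matches the direct normal-equations oracle", {
  set.seed(9)
  H <- matrix(rnorm(30 * 3), 30, 3)
  X <- matrix(rnorm(30 * 5), 30, 5)
  lambda <- 1e-3
  head <- fit_imputation_head(H, X, lambda = lambda)
  Hc <- scale(H, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  W_oracle <- solve(t(Hc) %*% Hc + lambda * diag(3), t(Hc) %*% Xc)
  expect_equal(unname(head$W_X), unname(W_oracle), tolerance = 1e-8)
})

test_that("degenerate embeddings with lambda = 0 raise a singularity error", {
  H <- matrix(1, 10, 2)
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_imputation_head(H, X, lambda = 0), "singular")
})

test_that("zero embeddings with a zero head impute zero", {
  head <- structure(
    list(W_X = matrix(0, 3, 4), b_X = numeric(4), lambda = 0),
    class = "imputation_head"
  )
  expect_true(all(impute_expression(matrix(0, 5, 3), head) == 0))
  expect_error(impute_expression(matrix(0, 5, 2), head), "dimension")
})

test_that("masked-entry imputation beats the gene-mean baseline under dropout", {
  # strong domain structure so masked entries carry recoverable signal
  d <- generate_dataset(synthetic_spec(
    n_spots = 400, n_genes = 40, n_domains = 4,
    effect_size = 10, noise_sd = 0.5, seed = 5
  ))
  set.seed(10)
  mask <- matrix(runif(d$C * d$g) < 0.2, d$C, d$g)
  X_obs <- d$expression
  X_obs[mask] <- 0
  # embeddings from spatially smoothed observed data (untrained encoder)
  g <- build_knn_graph(d$coordinates, 6)
  ds_obs <- d
  ds_obs$expression <- X_obs
  params <- encoder_params(d$g, hidden_dims = 32L, d_h = 16L, seed = 1)
  H <- encode_all(ds_obs, g, params)
  # head refit excluding the masked entries
  head <- fit_imputation_head(H, X_obs, mask = mask)
  xhat <- impute_expression(H, head)
  l1_model <- imputation_metrics(xhat, d$expression, mask)[["l1"]]
  # gene means over each gene's unmasked spots
  gene_means <- sapply(seq_len(d$g), function(j) mean(X_obs[!mask[, j], j]))
  baseline <- matrix(gene_means, d$C, d$g, byrow = TRUE)
  l1_base <- imputation_metrics(baseline, d$expression, mask)[["l1"]]
  expect_lt(l1_model, l1_base)
})

test_that("ideally interleaved batches score LISI near 2", {
  set.seed(11)
  emb <- matrix(rnorm(400 * 2), 400, 2) # one homogeneous cloud
  labels <- rep(1:2, 200) # 50/50 interleaved
  lisi <- compute_lisi(emb, labels, perplexity = 30)
  expect_equal(attr(lisi, "mean"), 2, tolerance = 0.1)
})

test_that("far-separated batches score LISI near 1", {
  set.seed(12)
  emb <- rbind(
    matrix(rnorm(200 * 2), 200, 2),
    matrix(rnorm(200 * 2, mean = 100), 200, 2)
  )
  labels <- rep(1:2, each = 200)
  lisi <- compute_lisi(emb, labels, perplexity = 30)
  expect_equal(attr(lisi, "mean"), 1, tolerance = 0.05)
})

test_that("a single category yields LISI exactly 1 everywhere", {
  emb <- matrix(rnorm(50), 25, 2)
  lisi <- compute_lisi(emb, rep("a", 25))
  expect_equal(as.numeric(lisi), rep(1, 25))
})

test_that("LISI normalisation hits the printed corner cases", {
  expect_equal(
    normalize_lisi(1, 4, n_celltypes = 7, n_datasets = 4),
    c(ncLISI = 1, niLISI = 1)
  )
  expect_equal(
    normalize_lisi(7, 1, n_celltypes = 7, n_datasets = 4),
    c(ncLISI = 0, niLISI = 0)
  )
  expect_error(normalize_lisi(1, 1, 1, 4), "n_celltypes")
})

test_that("LISI normalisation is affine, order-reversing in cLISI", {
  cl <- seq(1, 5, by = 0.5)
  nc <- sapply(cl, function(x) normalize_lisi(x, 2, 5, 3)[["ncLISI"]])
  expect_true(all(diff(nc) < 0))
  expect_equal(diff(nc), rep(diff(nc)[1], length(nc) - 1), tolerance = 1e-12)
  il <- seq(1, 3, by = 0.25)
  ni <- sapply(il, function(x) normalize_lisi(2, x, 5, 3)[["niLISI"]])
  expect_true(all(diff(ni) > 0))
})

test_that("trajectory export round-trips embeddings and labels", {
  set.seed(13)
  H <- matrix(rnorm(40), 10, 4)
  rownames(H) <- paste0("s", 1:10)
  assignments <- rep(1:2, 5)
  path <- withr::local_tempfile(fileext = ".csv")
  export_for_trajectory(H, assignments, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 10)
  expect_equal(length(unique(back$domain)), 2)
  expect_equal(as.matrix(back[, -(1:2)]), H,
    tolerance = 1e-12, ignore_attr = TRUE
  )
})
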