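test_that("episode sampling exhausts small classes and keeps sets disjoint", {
  labels <- rep(1:2, each = 3)
  set.seed(1)
  ep <- sample_episode(labels, N = 2, M = 3, Q = 5)
  expect_setequal(ep$support$node, 1:6)
  expect_equal(nrow(ep$query), 0)
})

test_that("support and query never overlap and query labels stay in class_list", {
  set.seed(2)
  labels <- sample(1:6, 400, replace = TRUE)
  for (trial in 1:200) {
    ep <- sample_episode(labels, N = 4, M = 5, Q = 15)
    expect_length(intersect(ep$support$node, ep$query$node), 0)
    expect_true(all(ep$query$label %in% ep$class_list))
    expect_true(all(ep$support$label %in% ep$class_list))
    expect_length(unique(ep$support$label), 4)
    expect_lte(max(table(ep$support$label)), 5)
    expect_lte(nrow(ep$query), 15)
  }
})

test_that("episode sampling is deterministic per RNG state", {
  labels <- rep(1:5, each = 20)
  set.seed(123)
  e1 <- sample_episode(labels, 3, 4, 10)
  set.seed(123)
  e2 <- sample_episode(labels, 3, 4, 10)
  expect_identical(e1, e2)
})

test_that("episodes with too few classes are rejected", {
  expect_error(sample_episode(rep(1, 10), N = 2, M = 3, Q = 2), "classes")
})

test_that("prototypes are the class means of the support embeddings", {
  h <- rbind(c(0, 0), c(2, 2), c(5, 1))
  proto <- class_prototypes(h, c(1, 1, 2), c(1, 2))
  expect_equal(unname(proto[1, ]), c(1, 1))
  expect_equal(unname(proto[2, ]), c(5, 1)) # single-member class: its embedding
  set.seed(4)
  h2 <- matrix(rnorm(24), 6, 4)
  lab <- c(1, 1, 2, 2, 3, 3)
  p2 <- class_prototypes(h2, lab)
  for (k in 1:3) {
    expect_equal(unname(p2[k, ]), colMeans(h2[lab == k, ]), tolerance = 1e-12)
  }
})

test_that("contrastive loss approaches log(N - 1) as tau grows", {
  set.seed(5)
  for (N in c(2, 3, 5)) {
    h <- matrix(rnorm(N * 2 * 4), N * 2, 4)
    lab <- rep(1:N, each = 2)
    proto <- class_prototypes(h, lab)
    l <- contrastive_loss(h, lab, proto, 1:N, tau = 1e6)
    expect_equal(l, log(N - 1), tolerance = 1e-3)
  }
})

test_that("N = 2, M = 1 matches the hand expansion of the loss", {
  h <- rbind(c(1, 2), c(-0.5, 3))
  proto <- h # M = 1: prototypes are the embeddings themselves
  tau <- 0.7
  l <- contrastive_loss(h, 1:2, proto, 1:2, tau = tau)
  expected <- -0.5 * ((sum(h[1, ] * proto[1, ]) - sum(h[1, ] * proto[2, ])) +
    (sum(h[2, ] * proto[2, ]) - sum(h[2, ] * proto[1, ]))) / tau
  expect_equal(l, expected, tolerance = 1e-12)
})

test_that("contrastive loss matches a direct unstabilised evaluation", {
  set.seed(6)
  for (trial in 1:10) {
    N <- 3
    M <- 2
    h <- matrix(rnorm(N * M * 4), N * M, 4)
    lab <- rep(1:N, each = M)
    proto <- class_prototypes(h, lab)
    tau <- runif(1, 0.3, 2)
    direct <- 0
    for (r in seq_len(N * M)) {
      i <- lab[r]
      num <- exp(sum(h[r, ] * proto[i, ]) / tau)
      den <- sum(sapply(setdiff(1:N, i), function(k) {
        exp(sum(h[r, ] * proto[k, ]) / tau)
      }))
      direct <- direct - log(num / den)
    }
    direct <- direct / (N * M)
    expect_equal(
      contrastive_loss(h, lab, proto, 1:N, tau = tau),
      direct,
      tolerance = 1e-8
    )
  }
})

test_that("contrastive loss is invariant to class relabelling", {
  set.seed(7)
  h <- matrix(rnorm(6 * 3), 6, 3)
  lab <- rep(1:3, each = 2)
  proto <- class_prototypes(h, lab, 1:3)
  l1 <- contrastive_loss(h, lab, proto, 1:3, tau = 0.5)
  relab <- c(7, 5, 9)[lab] # arbitrary new ids, same partition
  proto2 <- class_prototypes(h, relab, c(5, 7, 9))
  l2 <- contrastive_loss(h, relab, proto2, c(5, 7, 9), tau = 0.5)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("a single class is rejected (empty denominator)", {
  h <- matrix(rnorm(4), 2, 2)
  expect_error(
    contrastive_loss(h, c(1, 1), class_prototypes(h, c(1, 1)), 1, tau = 1),
    "2 classes"
  )
})

test_that("query probabilities are a proper softmax over prototypes", {
  proto_same <- matrix(1, 4, 3)
  p <- query_class_probabilities(matrix(rnorm(6), 2, 3), proto_same, tau = 0.5)
  expect_equal(unname(p), matrix(0.25, 2, 4)) # identical prototypes -> uniform
  set.seed(8)
  for (trial in 1:100) {
    q <- matrix(rnorm(3 * 4), 3, 4)
    proto <- matrix(rnorm(5 * 4), 5, 4)
    p <- query_class_probabilities(q, proto, tau = runif(1, 0.2, 3))
    expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("query probabilities match the direct softmax oracle", {
  set.seed(9)
  q <- matrix(rnorm(8), 2, 4)
  proto <- matrix(rnorm(12), 3, 4)
  tau <- 0.9
  p <- query_class_probabilities(q, proto, tau)
  for (i in 1:2) {
    raw <- exp(sapply(1:3, function(k) sum(q[i, ] * proto[k, ]) / tau))
    expect_equal(unname(p[i, ]), raw / sum(raw), tolerance = 1e-10)
  }
})

test_that("classification loss has the right endpoints and oracle value", {
  onehot <- rbind(c(1, 0), c(0, 1))
  expect_equal(classification_loss(onehot, c(1, 2), 1:2), 0)
  uniform <- matrix(0.25, 3, 4)
  expect_equal(classification_loss(uniform, c(1, 2, 3), 1:4), log(4))
  set.seed(10)
  p <- matrix(runif(12), 3, 4)
  p <- p / rowSums(p)
  lab <- c(2, 4, 1)
  direct <- -mean(log(p[cbind(1:3, lab)]))
  expect_equal(classification_loss(p, lab, 1:4), direct, tolerance = 1e-10)
})

test_that("zero probabilities at the true class are clamped with a warning", {
  p <- rbind(c(1, 0), c(0, 1))
  expect_warning(l <- classification_loss(p, c(2, 1), 1:2), "clamp")
  expect_true(is.finite(l))
})

test_that("the combined loss is the stated convex combination", {
  expect_equal(combined_loss(2, 4, alpha = 1), 2)
  expect_equal(combined_loss(2, 4, alpha = 0), 4)
  expect_equal(combined_loss(2, 4, alpha = 0.5), 3)
  # linear in alpha: three-point collinearity check
  l <- sapply(c(0.2, 0.5, 0.8), function(a) combined_loss(1.3, 2.9, a))
  expect_equal(l[2] - l[1], l[3] - l[2], tolerance = 1e-12)
  expect_error(combined_loss(1, 1, alpha = 1.2), "alpha")
})

test_that("backprop gradients match finite differences on a small episode", {
  d <- generate_dataset(synthetic_spec(
    n_spots = 6, n_genes = 4,
    n_domains = 2, effect_size = 2, noise_sd = 0.5, seed = 2
  ))
  g <- build_knn_graph(d$coordinates, 2)
  cache <- spotmeta:::build_subgraph_cache(d, g)
  params <- encoder_params(4, hidden_dims = 5L, d_h = 3L, seed = 3)
  labels <- c(1, 1, 1, 2, 2, 2)
  episode <- list(
    support = tibble::tibble(node = c(1L, 2L, 4L, 5L), label = c(1, 1, 2, 2)),
    query = tibble::tibble(node = c(3L, 6L), label = c(1, 2)),
    class_list = c(1, 2)
  )
  tau <- 0.8
  alpha <- 0.6

  loss_at <- function(p) {
    h_sup <- t(sapply(episode$support$node, function(v) gcn_forward(cache[[v]], p)))
    h_qry <- t(sapply(episode$query$node, function(v) gcn_forward(cache[[v]], p)))
    proto <- class_prototypes(h_sup, episode$support$label, episode$class_list)
    l_ct <- contrastive_loss(h_sup, episode$support$label, proto,
      episode$class_list,
      tau = tau
    )
    probs <- query_class_probabilities(h_qry, proto, tau)
    l_ce <- classification_loss(probs, episode$query$label, episode$class_list)
    combined_loss(l_ct, l_ce, alpha)
  }

  # analytic gradients via the training-step internals
  h_sup <- t(sapply(episode$support$node, function(v) gcn_forward(cache[[v]], params)))
  h_qry <- t(sapply(episode$query$node, function(v) gcn_forward(cache[[v]], params)))
  lg <- spotmeta:::episode_loss_grads(
    h_sup, episode$support$label, h_qry,
    episode$query$label, episode$class_list, tau, alpha
  )
  expect_equal(lg$l_t, loss_at(params), tolerance = 1e-12)

  grads <- NULL
  for (i in seq_along(episode$support$node)) {
    v <- episode$support$node[i]
    fwd <- spotmeta:::gcn_forward_full(cache[[v]], params, keep = TRUE)
    gg <- spotmeta:::gcn_backward(fwd, cache[[v]], params, lg$grad_support[i, ])
    grads <- if (is.null(grads)) {
      gg
    } else {
      list(dW = Map(`+`, grads$dW, gg$dW), db = Map(`+`, grads$db, gg$db))
    }
  }
  for (i in seq_along(episode$query$node)) {
    v <- episode$query$node[i]
    fwd <- spotmeta:::gcn_forward_full(cache[[v]], params, keep = TRUE)
    gg <- spotmeta:::gcn_backward(fwd, cache[[v]], params, lg$grad_query[i, ])
    grads <- list(dW = Map(`+`, grads$dW, gg$dW), db = Map(`+`, grads$db, gg$db))
  }

  set.seed(11)
  for (layer in 1:2) {
    for (trial in 1:6) {
      i <- sample(nrow(params$weights[[layer]]), 1)
      j <- sample(ncol(params$weights[[layer]]), 1)
      fd <- finite_diff_grad(loss_at, params, layer, i, j)
      an <- grads$dW[[layer]][i, j]
      denom <- max(abs(fd), abs(an), 1e-8)
      expect_lt(abs(fd - an) / denom, 1e-4)
    }
  }
})

test_that("training reduces the episodic loss on separable synthetic data", {
  d <- generate_dataset(synthetic_spec(
    n_spots = 150, n_genes = 20,
    n_domains = 3, effect_size = 4, noise_sd = 0.5, seed = 8
  ))
  cfg <- run_config(
    hidden_dims = 16L, d_h = 8L, K_clusters = 4L, N_way = 3L,
    M_shot = 4L, Q_query = 8L, episodes_per_epoch = 20L, n_epochs = 3L,
    seed = 1L
  )
  fit <- train_encoder(d, config = cfg)
  first <- median(fit$log$l_t[1:10])
  last <- median(utils::tail(fit$log$l_t, 10))
  expect_lt(last, first)
})

test_that("training is deterministic given the config seed", {
  d <- generate_dataset(synthetic_spec(
    n_spots = 60, n_genes = 10,
    n_domains = 2, seed = 3
  ))
  cfg <- run_config(
    hidden_dims = 8L, d_h = 4L, K_clusters = 3L, N_way = 2L,
    M_shot = 3L, Q_query = 4L, episodes_per_epoch = 5L, n_epochs = 2L,
    seed = 9L
  )
  f1 <- train_encoder(d, config = cfg)
  f2 <- train_encoder(d, config = cfg)
  expect_identical(f1$embeddings, f2$embeddings)
  expect_identical(f1$log, f2$log)
})

test_that("trained embeddings separate pseudo-classes in cosine similarity", {
  d <- generate_dataset(synthetic_spec(
    n_spots = 150, n_genes = 20,
    n_domains = 3, effect_size = 4, noise_sd = 0.5, seed = 4
  ))
  cfg <- run_config(
    hidden_dims = 16L, d_h = 8L, K_clusters = 3L, N_way = 3L,
    M_shot = 4L, Q_query = 8L, episodes_per_epoch = 20L, n_epochs = 3L,
    seed = 2L
  )
  fit <- train_encoder(d, config = cfg)
  H <- fit$embeddings / sqrt(rowSums(fit$embeddings^2))
  S <- tcrossprod(H)
  lab <- fit$pseudo_labels$hard_labels
  same <- outer(lab, lab, "==") & upper.tri(S)
  diff <- outer(lab, lab, "!=") & upper.tri(S)
  expect_gt(mean(S[same]), mean(S[diff]))
})
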