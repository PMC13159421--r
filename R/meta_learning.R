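#' Sample one N-way, M-shot episode
#'
#' Draws `N` distinct pseudo-label classes, up to `M` support spots per
#' class, and up to `Q` query spots pooled over the same classes, with
#' support and query node sets disjoint. Sampling uses the current RNG
#' state, so seed the session (or use [with_seed()]-style wrappers) for
#' reproducible episode streams.
#'
#' @param labels Integer/factor vector of pseudo-labels per spot, or a
#'   `pseudo_labels` object (its `hard_labels` are used).
#' @param N Number of classes per episode (>= 2 for the contrastive loss).
#' @param M Maximum support spots per class.
#' @param Q Maximum total query spots.
#' @param spots Optional candidate spot indices (default: all labelled
#'   spots); use the training split here.
#' @return An object of class `episode`: tibbles `support` and `query`
#'   (columns `node`, `label`) and the integer `class_list`.
#' @export
sample_episode <- function(labels, N, M, Q, spots = NULL) {
  if (inherits(labels, "pseudo_labels")) labels <- labels$hard_labels
  labels <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  all_spots <- seq_along(labels)
  if (!is.null(spots)) all_spots <- intersect(all_spots, as.integer(spots))
  N <- check_count(N, "N")
  M <- check_count(M, "M")
  Q <- check_count(Q, "Q", min = 0L)

  classes <- sort(unique(labels[all_spots]))
  if (length(classes) < N) {
    stop(sprintf(
      "episode needs %d non-empty classes but only %d available", N,
      length(classes)
    ), call. = FALSE)
  }
  class_list <- sort(sample(classes, N))

  support_nodes <- integer(0)
  support_labels <- integer(0)
  for (cl in class_list) {
    members <- all_spots[labels[all_spots] == cl]
    take <- members[sample.int(length(members), min(M, length(members)))]
    support_nodes <- c(support_nodes, take)
    support_labels <- c(support_labels, rep.int(cl, length(take)))
  }

  pool <- setdiff(all_spots[labels[all_spots] %in% class_list], support_nodes)
  query_nodes <- if (length(pool) && Q > 0L) {
    pool[sample.int(length(pool), min(Q, length(pool)))]
  } else {
    integer(0)
  }

  structure(
    list(
      support = tibble::tibble(node = support_nodes, label = support_labels),
      query = tibble::tibble(node = query_nodes, label = labels[query_nodes]),
      class_list = class_list
    ),
    class = "episode"
  )
}

#' @export
print.episode <- function(x, ...) {
  cat(sprintf(
    "<episode> %d-way: %d support, %d query spots\n",
    length(x$class_list), nrow(x$support), nrow(x$query)
  ))
  invisible(x)
}

#' Class prototypes of an episode
#'
#' The prototype of class `i` is the arithmetic mean of the embeddings of
#' its support spots.
#'
#' @param support_embeddings Numeric matrix, one row per support spot.
#' @param support_labels Class label per row.
#' @param class_list Episode class ids (row order of the result).
#' @return `N x d_h` matrix, rownames = class ids.
#' @export
class_prototypes <- function(support_embeddings, support_labels,
                             class_list = sort(unique(support_labels))) {
  support_embeddings <- as.matrix(support_embeddings)
  proto <- matrix(0, length(class_list), ncol(support_embeddings))
  for (i in seq_along(class_list)) {
    rows <- which(support_labels == class_list[i])
    if (!length(rows)) {
      stop(sprintf("class %s has no support embeddings", class_list[i]),
        call. = FALSE
      )
    }
    proto[i, ] <- colMeans(support_embeddings[rows, , drop = FALSE])
  }
  rownames(proto) <- class_list
  proto
}

#' Prototype contrastive loss over the support set
#'
#' For support spot `j` of class `i` with embedding `h_ij` and prototypes
#' `hhat_1..hhat_N`,
#' `L_CT = -(1/NM) sum_ij log( exp(h_ij . hhat_i / tau) /
#'   sum_{k != i} exp(h_ij . hhat_k / tau) )`.
#' The denominator sums over the *other* classes only. Embeddings enter
#' unnormalised (dot-product similarity; no l2 normalisation, preserving
#' magnitude information). Evaluated with log-sum-exp stabilisation.
#'
#' @param support_embeddings Matrix of support embeddings (rows).
#' @param support_labels Class label per row.
#' @param prototypes `N x d_h` prototype matrix from [class_prototypes()].
#' @param class_list Class ids in prototype row order.
#' @param tau Positive temperature; smaller values sharpen the similarity
#'   distribution.
#' @return Scalar loss.
#' @export
contrastive_loss <- function(support_embeddings, support_labels, prototypes,
                             class_list = as.integer(rownames(prototypes)),
                             tau = 0.5) {
  parts <- contrastive_loss_parts(
    as.matrix(support_embeddings), support_labels,
    as.matrix(prototypes), class_list, tau
  )
  parts$loss
}

contrastive_loss_parts <- function(h, labels, proto, class_list, tau) {
  if (length(class_list) < 2L) {
    stop("contrastive loss needs at least 2 classes (empty denominator otherwise)",
      call. = FALSE
    )
  }
  tau <- check_number(tau, "tau", min = 1e-300)
  n <- nrow(h)
  sims <- tcrossprod(h, proto) / tau # n x N
  own <- match(labels, class_list)
  if (anyNA(own)) stop("support label outside class_list", call. = FALSE)
  neg <- sims
  neg[cbind(seq_len(n), own)] <- -Inf # exclude the positive class
  lse <- row_logsumexp(neg)
  loss <- -mean(sims[cbind(seq_len(n), own)] - lse)
  # gradients w.r.t. similarity logits, for backprop
  gsim <- exp(neg - lse) / n
  gsim[cbind(seq_len(n), own)] <- -1 / n
  list(loss = loss, sims = sims, grad_sims = gsim, own = own)
}

#' Query-class probabilities
#'
#' Softmax over prototype dot-product similarities at temperature `tau`:
#' `p_i(j) = softmax_j( h'_i . hhat_j / tau )`.
#'
#' @param query_embeddings Matrix of query embeddings (rows).
#' @param prototypes `N x d_h` prototype matrix.
#' @param tau Positive temperature.
#' @return `Q x N` row-stochastic matrix.
#' @export
query_class_probabilities <- function(query_embeddings, prototypes, tau = 0.5) {
  tau <- check_number(tau, "tau", min = 1e-300)
  sims <- tcrossprod(as.matrix(query_embeddings), as.matrix(prototypes)) / tau
  p <- exp(sims - row_logsumexp(sims))
  p / rowSums(p)
}

#' Query classification loss
#'
#' Mean cross-entropy of the query-class probabilities against the one-hot
#' pseudo-labels: `L_CE = -(1/Q) sum_i sum_j y_i(j) log p_i(j)`.
#'
#' @param probabilities `Q x N` row-stochastic matrix.
#' @param query_labels Class label per query row.
#' @param class_list Class ids in probability column order.
#' @return Scalar loss.
#' @export
classification_loss <- function(probabilities, query_labels,
                                class_list = seq_len(ncol(probabilities))) {
  probabilities <- as.matrix(probabilities)
  own <- match(query_labels, class_list)
  if (anyNA(own)) stop("query label outside class_list", call. = FALSE)
  p <- probabilities[cbind(seq_len(nrow(probabilities)), own)]
  if (any(p < 1e-12)) {
    warning("query probability underflow; clamped at 1e-12")
    p <- pmax(p, 1e-12)
  }
  -mean(log(p))
}

#' Combined episodic loss
#'
#' `L_T = alpha * L_CT + (1 - alpha) * L_CE`.
#'
#' @param l_ct Contrastive loss.
#' @param l_ce Classification loss.
#' @param alpha Mixing weight in \[0, 1\].
#' @return Scalar loss.
#' @export
combined_loss <- function(l_ct, l_ce, alpha = 0.5) {
  alpha <- check_number(alpha, "alpha", min = 0, max = 1)
  alpha * l_ct + (1 - alpha) * l_ce
}

# loss value and gradients w.r.t. support and query embeddings for one
# episode; gradients flow through the prototypes
episode_loss_grads <- function(h_sup, sup_labels, h_qry, qry_labels,
                               class_list, tau, alpha) {
  proto <- class_prototypes(h_sup, sup_labels, class_list)
  n_sup <- nrow(h_sup)
  counts <- vapply(class_list, function(cl) sum(sup_labels == cl), numeric(1))

  grad_sup <- matrix(0, n_sup, ncol(h_sup))
  grad_proto <- matrix(0, length(class_list), ncol(h_sup))

  ct <- contrastive_loss_parts(h_sup, sup_labels, proto, class_list, tau)
  if (alpha > 0) {
    grad_sup <- grad_sup + (alpha / tau) * (ct$grad_sims %*% proto)
    grad_proto <- grad_proto + (alpha / tau) * crossprod(ct$grad_sims, h_sup)
  }

  l_ce <- 0
  grad_qry <- NULL
  if (!is.null(h_qry) && nrow(h_qry) > 0L) {
    probs <- query_class_probabilities(h_qry, proto, tau)
    l_ce <- classification_loss(probs, qry_labels, class_list)
    own <- match(qry_labels, class_list)
    y <- matrix(0, nrow(probs), ncol(probs))
    y[cbind(seq_len(nrow(probs)), own)] <- 1
    gq <- (probs - y) / nrow(probs)
    if (alpha < 1) {
      grad_qry <- ((1 - alpha) / tau) * (gq %*% proto)
      grad_proto <- grad_proto + ((1 - alpha) / tau) * crossprod(gq, h_qry)
    }
  }
  if (is.null(grad_qry) && !is.null(h_qry)) {
    grad_qry <- matrix(0, nrow(h_qry), ncol(h_sup))
  }

  # prototypes are means of class support embeddings: push gradients down
  for (i in seq_along(class_list)) {
    rows <- which(sup_labels == class_list[i])
    grad_sup[rows, ] <- grad_sup[rows, ] +
      matrix(grad_proto[i, ] / counts[i], length(rows), ncol(h_sup), byrow = TRUE)
  }

  list(
    l_ct = ct$loss, l_ce = l_ce,
    l_t = combined_loss(ct$loss, l_ce, alpha),
    grad_support = grad_sup, grad_query = grad_qry
  )
}

adam_init <- function(params) {
  zeros <- function(x) lapply(x, function(m) array(0, dim = dim(m) %||% length(m)))
  list(
    mW = zeros(params$weights), vW = zeros(params$weights),
    mb = lapply(params$biases, function(b) numeric(length(b))),
    vb = lapply(params$biases, function(b) numeric(length(b))),
    t = 0L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(params$weights)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    params$weights[[l]] <- params$weights[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps) -
      lr * weight_decay * params$weights[[l]]
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    params$biases[[l]] <- params$biases[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the encoder with episodic contrastive meta-learning
#'
#' Pipeline: (1) soft K-means pseudo-labelling of the expression matrix;
#' (2) per epoch, sample `episodes_per_epoch` N-way M-shot episodes from
#' the pseudo-labelled spots, encode the support and query spots through
#' their two-hop subgraphs, evaluate
#' `L_T = alpha * L_CT + (1 - alpha) * L_CE`, and take one Adam step on the
#' encoder weights per episode (joint step on the combined loss; set
#' `sequential_updates = TRUE` in the config for one contrastive step
#' followed by one classification step instead); (3) return the final
#' parameters and the full embedding matrix `H`.
#'
#' When `config$scale_genes` is `TRUE` (default) each gene is standardised
#' (centred, unit variance) before pseudo-labelling and encoding, the usual
#' preprocessing for expression fed to graph encoders; disable it if the
#' input is already normalised that way.
#'
#' Everything is driven by `config$seed`, so identical configurations
#' reproduce identical embeddings bit for bit.
#'
#' @param dataset A [spot_dataset()].
#' @param graph A [build_knn_graph()] over the dataset (built internally if
#'   `NULL`).
#' @param config A [run_config()].
#' @param spots Optional indices episodes are sampled from (e.g. the
#'   training split); default all spots.
#' @return An object of class `spotmeta_fit`: `params`, `embeddings`
#'   (`C x d_h`), `pseudo_labels`, `log` (tibble: episode, l_ct, l_ce,
#'   l_t), `config`, `graph`.
#' @export
train_encoder <- function(dataset, graph = NULL, config = run_config(),
                          spots = NULL) {
  if (is.null(graph)) {
    graph <- build_knn_graph(dataset$coordinates,
      k = config$k_neighbors,
      similarity = config$similarity
    )
  }
  if (isTRUE(config$scale_genes)) {
    # per-gene standardisation: removes the shared baseline so the encoder
    # sees relative expression; constant genes are zeroed
    Xs <- scale(dataset$expression)
    Xs[, attr(Xs, "scaled:scale") == 0] <- 0
    attr(Xs, "scaled:center") <- NULL
    attr(Xs, "scaled:scale") <- NULL
    dataset$expression <- Xs
  }
  pl <- fit_soft_kmeans(dataset$expression,
    K = config$K_clusters,
    seed = config$seed, pca_dims = config$pca_dims
  )
  params <- encoder_params(
    n_genes = dataset$g, hidden_dims = config$hidden_dims,
    d_h = config$d_h, activation = config$activation,
    seed = config$seed
  )
  cache <- build_subgraph_cache(dataset, graph)
  state <- adam_init(params)
  n_episodes <- config$n_epochs * config$episodes_per_epoch
  log_ct <- log_ce <- log_t <- numeric(n_episodes)

  with_seed(config$seed + 1L, {
    for (ep in seq_len(n_episodes)) {
      episode <- sample_episode(pl$hard_labels,
        N = config$N_way,
        M = config$M_shot, Q = config$Q_query, spots = spots
      )
      res <- episode_step(episode, cache, params, state, config)
      params <- res$params
      state <- res$state
      log_ct[ep] <- res$l_ct
      log_ce[ep] <- res$l_ce
      log_t[ep] <- res$l_t
      if (!is.finite(res$l_t)) {
        stop(sprintf(
          "training diverged at episode %d (loss = %g); lower the learning rate",
          ep, res$l_t
        ), call. = FALSE)
      }
      if (config$refresh_pseudo_labels &&
        ep %% config$episodes_per_epoch == 0L && ep < n_episodes) {
        H_now <- encode_all(dataset, graph, params, cache)
        pl <- fit_soft_kmeans(H_now, K = config$K_clusters, seed = config$seed)
      }
    }
  })

  H <- encode_all(dataset, graph, params, cache)
  structure(
    list(
      params = params,
      embeddings = H,
      pseudo_labels = pl,
      log = tibble::tibble(
        episode = seq_len(n_episodes),
        epoch = rep(seq_len(config$n_epochs), each = config$episodes_per_epoch),
        l_ct = log_ct, l_ce = log_ce, l_t = log_t
      ),
      config = config,
      graph = graph
    ),
    class = "spotmeta_fit"
  )
}

# forward + backward + optimiser update for one episode
episode_step <- function(episode, cache, params, state, config) {
  sup <- episode$support$node
  qry <- episode$query$node
  fwd_sup <- lapply(cache[sup], gcn_forward_full, params = params, keep = TRUE)
  fwd_qry <- lapply(cache[qry], gcn_forward_full, params = params, keep = TRUE)
  h_sup <- t(vapply(
    seq_along(sup),
    function(i) fwd_sup[[i]]$H[cache[[sup[i]]]$center_pos, ],
    numeric(params$d_h)
  ))
  h_qry <- if (length(qry)) {
    t(vapply(
      seq_along(qry),
      function(i) fwd_qry[[i]]$H[cache[[qry[i]]]$center_pos, ],
      numeric(params$d_h)
    ))
  } else {
    NULL
  }

  take_step <- function(params, state, grad_sup, grad_qry) {
    grads <- NULL
    accumulate <- function(grads, g2) {
      if (is.null(grads)) {
        return(g2)
      }
      list(
        dW = Map(`+`, grads$dW, g2$dW),
        db = Map(`+`, grads$db, g2$db)
      )
    }
    for (i in seq_along(sup)) {
      g <- gcn_backward(fwd_sup[[i]], cache[[sup[i]]], params, grad_sup[i, ])
      grads <- accumulate(grads, g)
    }
    if (!is.null(grad_qry)) {
      for (i in seq_along(qry)) {
        g <- gcn_backward(fwd_qry[[i]], cache[[qry[i]]], params, grad_qry[i, ])
        grads <- accumulate(grads, g)
      }
    }
    adam_step(params, grads, state,
      lr = config$learning_rate,
      weight_decay = config$weight_decay %||% 0
    )
  }

  # ridge penalty on episode embeddings: keeps the norm runaway of the
  # positive-excluded contrastive objective in check without touching the
  # reported losses
  reg <- config$embed_reg %||% 0
  n_total <- length(sup) + length(qry)
  add_reg <- function(grad, h) {
    if (reg > 0 && !is.null(grad)) grad + (2 * reg / n_total) * h else grad
  }

  if (isTRUE(config$sequential_updates)) {
    # step 1: contrastive term alone; step 2: classification term alone
    lg1 <- episode_loss_grads(h_sup, episode$support$label, h_qry,
      episode$query$label, episode$class_list,
      tau = config$tau, alpha = 1
    )
    upd <- take_step(params, state, config$alpha * lg1$grad_support, NULL)
    params <- upd$params
    state <- upd$state
    lg2 <- episode_loss_grads(h_sup, episode$support$label, h_qry,
      episode$query$label, episode$class_list,
      tau = config$tau, alpha = 0
    )
    upd <- take_step(
      params, state,
      add_reg((1 - config$alpha) * lg2$grad_support, h_sup),
      if (is.null(lg2$grad_query)) NULL else
        add_reg((1 - config$alpha) * lg2$grad_query, h_qry)
    )
    l_ct <- lg1$l_ct
    l_ce <- lg2$l_ce
    l_t <- combined_loss(l_ct, l_ce, config$alpha)
  } else {
    lg <- episode_loss_grads(h_sup, episode$support$label, h_qry,
      episode$query$label, episode$class_list,
      tau = config$tau, alpha = config$alpha
    )
    upd <- take_step(
      params, state,
      add_reg(lg$grad_support, h_sup),
      if (is.null(lg$grad_query)) NULL else add_reg(lg$grad_query, h_qry)
    )
    l_ct <- lg$l_ct
    l_ce <- lg$l_ce
    l_t <- lg$l_t
  }
  list(
    params = upd$params, state = upd$state,
    l_ct = l_ct, l_ce = l_ce, l_t = l_t
  )
}

#' @export
print.spotmeta_fit <- function(x, ...) {
  cat(sprintf(
    "<spotmeta_fit> %d spots embedded in %d dimensions after %d episodes\n",
    nrow(x$embeddings), ncol(x$embeddings), nrow(x$log)
  ))
  last <- utils::tail(x$log, 10)
  cat(sprintf(
    "  final losses (last 10 episodes): L_CT %.4f, L_CE %.4f, L_T %.4f\n",
    mean(last$l_ct), mean(last$l_ce), mean(last$l_t)
  ))
  invisible(x)
}
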