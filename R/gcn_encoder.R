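#' Initialise graph convolutional encoder parameters
#'
#' A stack of graph convolution layers with Kipf-style symmetric
#' renormalisation. Layer weights are Glorot-uniform initialised from the
#' given seed; biases start at zero. ReLU (or ELU) is applied between
#' layers and the final layer is linear.
#'
#' @param n_genes Input feature dimensionality `g`.
#' @param hidden_dims Integer vector of hidden layer widths (default 128).
#'   Use `integer(0)` for a single-layer (linear) encoder.
#' @param d_h Output embedding dimensionality (default 64).
#' @param activation `"relu"` or `"elu"`, applied between layers.
#' @param seed Integer seed for the Glorot draw.
#' @return An object of class `encoder_params`: list with `weights` (list of
#'   matrices), `biases` (list of vectors), `dims`, `activation`, `d_h`.
#' @export
encoder_params <- function(n_genes, hidden_dims = 128L, d_h = 64L,
                           activation = c("relu", "elu"), seed = 1L) {
  activation <- match.arg(activation)
  dims <- c(
    check_count(n_genes, "n_genes"),
    vapply(hidden_dims, check_count, integer(1), field = "hidden_dims"),
    check_count(d_h, "d_h")
  )
  with_seed(seed, {
    weights <- list()
    biases <- list()
    for (l in seq_len(length(dims) - 1L)) {
      fan_in <- dims[l]
      fan_out <- dims[l + 1L]
      limit <- sqrt(6 / (fan_in + fan_out))
      weights[[l]] <- matrix(
        stats::runif(fan_in * fan_out, -limit, limit),
        fan_in, fan_out
      )
      biases[[l]] <- numeric(fan_out)
    }
    structure(
      list(
        weights = weights, biases = biases, dims = dims,
        n_layers = length(weights), activation = activation,
        d_h = dims[length(dims)]
      ),
      class = "encoder_params"
    )
  })
}

#' @export
print.encoder_params <- function(x, ...) {
  cat(sprintf(
    "<encoder_params> %d GCN layer(s): %s, %s activation\n",
    x$n_layers, paste(x$dims, collapse = " -> "), x$activation
  ))
  invisible(x)
}

activate <- function(z, activation) {
  switch(activation,
    relu = pmax(z, 0),
    elu = ifelse(z > 0, z, expm1(z))
  )
}

activate_grad <- function(z, activation) {
  switch(activation,
    relu = (z > 0) * 1,
    elu = ifelse(z > 0, 1, exp(z))
  )
}

# Kipf renormalisation: D^{-1/2} (A + I) D^{-1/2} on a dense 0/1 adjacency
normalized_adjacency <- function(A) {
  Ai <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Ai))
  Ai * outer(dinv, dinv)
}

# forward pass over one subgraph; optionally keep intermediates for backprop
gcn_forward_full <- function(subgraph, params, keep = FALSE) {
  X <- subgraph$features
  if (ncol(X) != params$dims[1]) {
    stop(sprintf(
      "feature dimension %d does not match encoder input dimension %d",
      ncol(X), params$dims[1]
    ), call. = FALSE)
  }
  Ahat <- subgraph$Ahat
  if (is.null(Ahat)) Ahat <- normalized_adjacency(subgraph$adjacency)
  H <- X
  pre <- vector("list", params$n_layers) # pre-activations Z_l
  agg <- vector("list", params$n_layers) # Ahat %*% H_{l-1}
  for (l in seq_len(params$n_layers)) {
    AH <- Ahat %*% H
    Z <- AH %*% params$weights[[l]]
    Z <- sweep(Z, 2L, params$biases[[l]], "+")
    if (keep) {
      agg[[l]] <- AH
      pre[[l]] <- Z
    }
    H <- if (l < params$n_layers) activate(Z, params$activation) else Z
  }
  if (keep) list(H = H, pre = pre, agg = agg, Ahat = Ahat) else H
}

#' Encode one spot from its two-hop subgraph
#'
#' Runs the graph convolutional encoder over the subgraph and returns the
#' output row of the centre node — the spot's embedding `h_v`. Using the
#' centre row (rather than pooling) keeps the embedding local: expression
#' changes at spots more than two hops away cannot affect it.
#'
#' @param subgraph A [extract_two_hop_subgraph()] result.
#' @param params An [encoder_params()] object.
#' @return Numeric vector of length `d_h`.
#' @export
gcn_forward <- function(subgraph, params) {
  H <- gcn_forward_full(subgraph, params)
  H[subgraph$center_pos, ]
}

# backprop through one subgraph given d(loss)/d(h_center); returns weight
# and bias gradients (same shapes as params)
gcn_backward <- function(fwd, subgraph, params, grad_center) {
  L <- params$n_layers
  dW <- vector("list", L)
  db <- vector("list", L)
  m <- nrow(fwd$pre[[L]])
  dZ <- matrix(0, m, ncol(fwd$pre[[L]]))
  dZ[subgraph$center_pos, ] <- grad_center
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fwd$agg[[l]], dZ)
    db[[l]] <- colSums(dZ)
    if (l > 1L) {
      dH <- fwd$Ahat %*% (dZ %*% t(params$weights[[l]]))
      dZ <- dH * activate_grad(fwd$pre[[l - 1L]], params$activation)
    }
  }
  list(dW = dW, db = db)
}

# precompute subgraphs (with normalised adjacency) for a set of spots
build_subgraph_cache <- function(dataset, graph, spots = seq_len(dataset$C)) {
  lapply(spots, function(v) {
    sg <- extract_two_hop_subgraph(graph, dataset$expression, v)
    sg$Ahat <- normalized_adjacency(sg$adjacency)
    sg
  })
}

#' Embed every spot
#'
#' Applies [gcn_forward()] to each spot's two-hop subgraph and stacks the
#' centre-node embeddings into the `C x d_h` matrix `H`. Spots are processed
#' independently, so batching cannot change the result.
#'
#' @param dataset A [spot_dataset()].
#' @param graph A [build_knn_graph()] over the dataset's coordinates.
#' @param params An [encoder_params()] object.
#' @param cache Optional precomputed subgraph list (internal use).
#' @return Numeric matrix `C x d_h` with spot ids as rownames.
#' @export
encode_all <- function(dataset, graph, params, cache = NULL) {
  if (graph$node_count != dataset$C) {
    stop("graph was not built over this dataset", call. = FALSE)
  }
  if (is.null(cache)) cache <- build_subgraph_cache(dataset, graph)
  H <- matrix(0, dataset$C, params$d_h)
  for (i in seq_along(cache)) {
    H[i, ] <- gcn_forward(cache[[i]], params)
  }
  rownames(H) <- dataset$spot_ids
  colnames(H) <- paste0("e", seq_len(params$d_h))
  H
}
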