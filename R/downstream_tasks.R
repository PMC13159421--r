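#' Spatial domain identification by K-means on the embeddings
#'
#' Lloyd's K-means with k-means++ seeding, best of `n_restarts` restarts,
#' minimising the clustering objective
#' `L_cluster = sum_i || h_i - mu_{z_i} ||^2`.
#'
#' @param H Numeric `C x d_h` embedding matrix.
#' @param K_domains Number of spatial domains (set this to the annotation
#'   count when ground-truth labels exist).
#' @param seed Integer seed.
#' @param n_restarts Independent k-means++ restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart.
#' @return An object of class `domain_result`: `assignments` (integers in
#'   `1..K_domains`), `centroids` (`K_domains x d_h`), `objective`
#'   (`L_cluster` at the returned solution), and `objective_trace` (per
#'   Lloyd iteration of the winning restart; non-increasing).
#' @export
identify_domains <- function(H, K_domains, seed = 1L, n_restarts = 10L,
                             max_iter = 100L) {
  H <- as.matrix(H)
  K_domains <- check_count(K_domains, "K_domains")
  if (K_domains > nrow(H)) {
    stop("K_domains must not exceed the number of spots", call. = FALSE)
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- lloyd_kmeans(H, kmeanspp_init(H, K_domains), max_iter)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    structure(
      c(best, list(K = K_domains)),
      class = "domain_result"
    )
  })
}

# plain Lloyd iterations from given starting centroids; empty clusters are
# re-seeded at the point farthest from its centroid
lloyd_kmeans <- function(X, centroids, max_iter = 100L) {
  n <- nrow(X)
  K <- nrow(centroids)
  assign_old <- rep(0L, n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- sqdist(X, centroids)
    assignment <- max.col(-d2, ties.method = "first")
    empties <- which(tabulate(assignment, K) == 0L)
    if (length(empties)) {
      # re-seed each empty cluster with a point far from its centroid
      ord <- order(d2[cbind(seq_len(n), assignment)], decreasing = TRUE)
      assignment[ord[seq_along(empties)]] <- empties
    }
    for (k in seq_len(K)) {
      centroids[k, ] <- colMeans(X[assignment == k, , drop = FALSE])
    }
    trace <- c(trace, sum((X - centroids[assignment, , drop = FALSE])^2))
    if (identical(assignment, assign_old)) break
    assign_old <- assignment
  }
  list(
    assignments = assignment,
    centroids = centroids,
    objective = trace[length(trace)],
    objective_trace = trace
  )
}

#' @export
print.domain_result <- function(x, ...) {
  cat(sprintf(
    "<domain_result> %d spots in %d domains, L_cluster = %.4f\n",
    length(x$assignments), x$K, x$objective
  ))
  invisible(x)
}

#' Fit the post hoc linear imputation head
#'
#' Finds the linear map back to expression space, `Xhat = H W_X + b_X`
#' (rows are spots), by per-gene ridge regression in closed form:
#' `W_X` minimises `||X - (H W_X + b_X)||^2 + lambda ||W_X||^2`. The head
#' is fitted after training, not jointly with the encoder.
#'
#' @param H_train Embeddings of the training spots (`n x d_h`).
#' @param X_train Matching expression (`n x g`).
#' @param lambda Ridge penalty (default `1e-3`); with `lambda = 0` a
#'   rank-deficient `H_train` raises a singularity error.
#' @param mask Optional logical `n x g` matrix marking entries to exclude
#'   from the fit (e.g. synthetically dropped-out entries under
#'   evaluation); the regression for each gene then uses only that gene's
#'   unmasked spots.
#' @return An object of class `imputation_head`: `W_X` (`d_h x g`), `b_X`
#'   (length `g`), `lambda`.
#' @export
fit_imputation_head <- function(H_train, X_train, lambda = 1e-3, mask = NULL) {
  H_train <- as.matrix(H_train)
  X_train <- as.matrix(X_train)
  if (nrow(H_train) != nrow(X_train)) {
    stop("H_train and X_train must have aligned rows", call. = FALSE)
  }
  lambda <- check_number(lambda, "lambda", min = 0)
  d_h <- ncol(H_train)
  g <- ncol(X_train)

  ridge_solve <- function(Hm, xm) {
    h_bar <- colMeans(Hm)
    x_bar <- mean(xm)
    Hc <- sweep(Hm, 2L, h_bar)
    G <- crossprod(Hc) + lambda * diag(d_h)
    if (rcond(G) < 1e-12) {
      stop("singular design: H_train has (near-)zero variance; use lambda > 0",
        call. = FALSE
      )
    }
    w <- solve(G, crossprod(Hc, xm - x_bar))
    list(w = w, b = x_bar - sum(h_bar * w))
  }

  if (is.null(mask)) {
    h_bar <- colMeans(H_train)
    x_bar <- colMeans(X_train)
    Hc <- sweep(H_train, 2L, h_bar)
    Xc <- sweep(X_train, 2L, x_bar)
    G <- crossprod(Hc) + lambda * diag(d_h)
    if (rcond(G) < 1e-12) {
      stop("singular design: H_train has (near-)zero variance; use lambda > 0",
        call. = FALSE
      )
    }
    W <- solve(G, crossprod(Hc, Xc))
    b <- as.numeric(x_bar - h_bar %*% W)
  } else {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(X_train))) {
      stop("mask must match the dimensions of X_train", call. = FALSE)
    }
    W <- matrix(0, d_h, g)
    b <- numeric(g)
    for (j in seq_len(g)) {
      keep <- !mask[, j]
      if (sum(keep) <= d_h) {
        stop(sprintf("gene %d has too few unmasked spots to fit", j),
          call. = FALSE
        )
      }
      fitj <- ridge_solve(H_train[keep, , drop = FALSE], X_train[keep, j])
      W[, j] <- fitj$w
      b[j] <- fitj$b
    }
    colnames(W) <- colnames(X_train)
  }
  structure(
    list(W_X = W, b_X = b, lambda = lambda),
    class = "imputation_head"
  )
}

#' Impute expression from embeddings
#'
#' `Xhat = H W_X + b_X` with the bias broadcast across rows.
#'
#' @param H Numeric `C x d_h` embedding matrix.
#' @param head A fitted [fit_imputation_head()].
#' @return `C x g` imputed expression matrix.
#' @export
impute_expression <- function(H, head) {
  H <- as.matrix(H)
  if (ncol(H) != nrow(head$W_X)) {
    stop(sprintf(
      "embedding dimension %d does not match the head (%d)",
      ncol(H), nrow(head$W_X)
    ), call. = FALSE)
  }
  sweep(H %*% head$W_X, 2L, head$b_X, "+")
}

#' Local inverse Simpson index (LISI) per spot
#'
#' For each spot, label proportions are computed over a Gaussian-kernel
#' neighbourhood whose bandwidth is tuned by binary search so the kernel's
#' perplexity matches `perplexity`; the score is the inverse Simpson index
#' `1 / sum_l p_l^2` of those proportions. A value near 1 means the
#' neighbourhood is pure; a value near the number of categories means
#' ideal mixing. Over cell-type labels this is cLISI (lower is better);
#' over batch labels it is iLISI (higher is better).
#'
#' @param embedding Numeric `C x d` matrix (e.g. learned or
#'   batch-corrected embeddings).
#' @param labels Per-spot category labels.
#' @param perplexity Effective neighbourhood size (default 30).
#' @return Numeric vector of per-spot LISI values, with the mean in
#'   attribute `"mean"`. A single label category yields all scores exactly 1.
#' @export
compute_lisi <- function(embedding, labels, perplexity = 30) {
  embedding <- as.matrix(embedding)
  labels <- factor(labels)
  C <- nrow(embedding)
  if (length(labels) != C) stop("labels length mismatch", call. = FALSE)
  if (nlevels(labels) < 2L) {
    return(structure(rep(1, C), mean = 1))
  }
  n_neighbors <- min(C - 1L, max(15L, ceiling(3 * perplexity)))
  perplexity <- min(perplexity, n_neighbors)
  d2_all <- sqdist(embedding, embedding)
  lab_int <- as.integer(labels)
  L <- nlevels(labels)
  out <- numeric(C)
  target <- log(perplexity)
  for (i in seq_len(C)) {
    d2 <- d2_all[i, -i]
    nb <- order(d2)[seq_len(n_neighbors)]
    d2 <- d2[nb]
    lab <- lab_int[-i][nb]
    # binary search the precision beta so that entropy(w) = log(perplexity)
    beta <- 1
    lo <- 0
    hi <- Inf
    for (iter in seq_len(60L)) {
      w <- exp(-beta * (d2 - min(d2)))
      sw <- sum(w)
      H_entropy <- log(sw) + beta * sum(w * (d2 - min(d2))) / sw
      if (abs(H_entropy - target) < 1e-7) break
      if (H_entropy > target) { # too flat -> increase beta
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (beta + lo) / 2
      }
    }
    w <- w / sum(w)
    p <- vapply(seq_len(L), function(l) sum(w[lab == l]), numeric(1))
    out[i] <- 1 / sum(p^2)
  }
  structure(out, mean = mean(out))
}

#' Normalise mean LISI scores to \[0, 1\]
#'
#' `ncLISI = (N_celltypes - cLISI) / (N_celltypes - 1)` (1 = perfect
#' biological preservation) and `niLISI = (iLISI - 1) / (N_datasets - 1)`
#' (1 = perfect batch mixing); both clipped to \[0, 1\].
#'
#' @param mean_clisi Mean cLISI over spots (in `[1, N_celltypes]`).
#' @param mean_ilisi Mean iLISI over spots (in `[1, N_datasets]`).
#' @param n_celltypes,n_datasets Category counts (>= 2).
#' @return Named numeric vector `c(ncLISI = ..., niLISI = ...)`.
#' @export
normalize_lisi <- function(mean_clisi, mean_ilisi, n_celltypes, n_datasets) {
  n_celltypes <- check_count(n_celltypes, "n_celltypes", min = 2L)
  n_datasets <- check_count(n_datasets, "n_datasets", min = 2L)
  nc <- (n_celltypes - mean_clisi) / (n_celltypes - 1)
  ni <- (mean_ilisi - 1) / (n_datasets - 1)
  c(
    ncLISI = min(max(nc, 0), 1),
    niLISI = min(max(ni, 0), 1)
  )
}

#' Export embeddings and domain labels for trajectory tools
#'
#' Writes a CSV with one row per spot — `spot_id`, `domain`, then the
#' embedding coordinates — consumable by external UMAP/PAGA tooling. No
#' trajectory computation happens here.
#'
#' @param H Numeric `C x d_h` embedding matrix.
#' @param assignments Domain label per spot.
#' @param out_path Output CSV path.
#' @param spot_ids Optional ids (default rownames of `H` or `spot_1...`).
#' @return The path, invisibly.
#' @export
export_for_trajectory <- function(H, assignments, out_path, spot_ids = NULL) {
  H <- as.matrix(H)
  if (length(assignments) != nrow(H)) {
    stop("assignments must have one entry per embedding row", call. = FALSE)
  }
  if (is.null(spot_ids)) spot_ids <- rownames(H)
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(nrow(H)))
  df <- data.frame(spot_id = spot_ids, domain = assignments)
  emb <- as.data.frame(H)
  colnames(emb) <- paste0("e", seq_len(ncol(H)))
  utils::write.csv(cbind(df, emb), out_path, row.names = FALSE, quote = FALSE)
  invisible(out_path)
}
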