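#' Soft cluster assignment
#'
#' Gaussian-kernel responsibilities with per-cluster isotropic variances:
#' `p[i,k]` is proportional to `exp(-0.5 * ||x_i - mu_k||^2 / sigma_k^2)`,
#' normalised so every row sums to one. Computed in log space with
#' log-sum-exp stabilisation so well-separated points never underflow to
#' all-zero rows.
#'
#' @param X Numeric `C x g` data matrix.
#' @param centroids Numeric `K x g` matrix of cluster centres.
#' @param variances Positive numeric vector of length `K` (isotropic
#'   per-cluster variances), or a single value recycled.
#' @return Row-stochastic `C x K` responsibility matrix.
#' @export
soft_assign <- function(X, centroids, variances) {
  X <- as.matrix(X)
  centroids <- as.matrix(centroids)
  K <- nrow(centroids)
  variances <- rep_len(as.numeric(variances), K)
  if (any(!is.finite(variances)) || any(variances <= 0)) {
    stop("variances must be positive", call. = FALSE)
  }
  if (ncol(X) != ncol(centroids)) {
    stop("X and centroids must have the same number of columns", call. = FALSE)
  }
  logits <- -0.5 * sweep(sqdist(X, centroids), 2L, variances, "/")
  resp <- exp(logits - row_logsumexp(logits))
  resp / rowSums(resp)
}

#' Responsibility-weighted centroid update
#'
#' `mu_k = sum_i p[i,k] x_i / sum_i p[i,k]`. Clusters whose total
#' responsibility falls below `1e-12` are flagged via the `"empty"`
#' attribute; the fitting loop re-seeds them.
#'
#' @param X Numeric `C x g` matrix.
#' @param responsibilities Row-stochastic `C x K` matrix.
#' @return `K x g` centroid matrix, with attribute `empty` (integer vector
#'   of starved cluster indices, possibly empty).
#' @export
update_centroids <- function(X, responsibilities) {
  X <- as.matrix(X)
  responsibilities <- as.matrix(responsibilities)
  if (nrow(X) != nrow(responsibilities)) {
    stop("X and responsibilities must have the same number of rows", call. = FALSE)
  }
  mass <- colSums(responsibilities)
  empty <- which(mass < 1e-12)
  safe_mass <- pmax(mass, 1e-12)
  centroids <- crossprod(responsibilities, X) / safe_mass
  attr(centroids, "empty") <- empty
  centroids
}

# responsibility-weighted isotropic variance per cluster, floored
update_variances <- function(X, responsibilities, centroids, floor = 1e-6) {
  d2 <- sqdist(X, centroids)
  mass <- pmax(colSums(responsibilities), 1e-12)
  pmax(colSums(responsibilities * d2) / (ncol(X) * mass), floor)
}

# k-means++ seeding: first centre uniform, then distance-proportional
kmeanspp_init <- function(X, K) {
  C <- nrow(X)
  centers <- integer(K)
  centers[1] <- sample.int(C, 1L)
  if (K > 1L) {
    d2 <- sqdist(X, X[centers[1], , drop = FALSE])[, 1]
    for (k in 2:K) {
      prob <- d2 / sum(d2)
      if (!all(is.finite(prob)) || sum(d2) <= 0) {
        centers[k] <- sample.int(C, 1L)
      } else {
        centers[k] <- sample.int(C, 1L, prob = prob)
      }
      d2 <- pmin(d2, sqdist(X, X[centers[k], , drop = FALSE])[, 1])
    }
  }
  X[centers, , drop = FALSE]
}

#' Variance-aware soft K-means pseudo-labelling
#'
#' Alternates soft assignment, centroid update, and isotropic variance
#' update until the largest responsibility change drops below `tol` (or
#' `max_iter` is reached), then hardens: the pseudo-label of spot `i` is
#' `argmax_k p[i,k]`. These hard labels act as the weak supervision signal
#' for episodic training.
#'
#' The per-cluster variance estimator
#' `sigma_k^2 = sum_i p[i,k] ||x_i - mu_k||^2 / (g * sum_i p[i,k])`
#' (floored at `1e-6`) is the natural isotropic completion of the soft
#' assignment rule. Initialisation is k-means++ under the given seed.
#' Setting `harden = TRUE` with `variance_mode = "fixed"` replaces the soft
#' assignment by its one-hot argmax each iteration, which reduces the
#' procedure exactly to Lloyd's K-means.
#'
#' @param X Numeric `C x g` matrix (expression, optionally PCA-reduced via
#'   `pca_dims`).
#' @param K Number of clusters (default 10, used for all datasets).
#' @param max_iter,tol Stopping rule: at most `max_iter` iterations or
#'   maximum absolute responsibility change below `tol`.
#' @param seed Integer seed (initialisation).
#' @param pca_dims If non-`NULL`, reduce `X` to this many principal
#'   components before clustering (speed on wide matrices).
#' @param variance_mode `"adaptive"` (re-estimated each iteration) or
#'   `"fixed"` (kept at `fixed_variance`).
#' @param fixed_variance Common variance used when `variance_mode = "fixed"`.
#' @param harden If `TRUE`, responsibilities are replaced by their one-hot
#'   argmax after each assignment step (Lloyd reduction).
#' @param init Optional `K x g` matrix of starting centroids (overrides
#'   k-means++).
#' @return An object of class `pseudo_labels`: `responsibilities` (`C x K`),
#'   `centroids` (`K x g`), `variances` (length `K`), `hard_labels`
#'   (integers in `1..K`), `K`, `n_iterations_run`, `converged`.
#' @export
fit_soft_kmeans <- function(X, K = 10L, max_iter = 300L, tol = 1e-5,
                            seed = 1L, pca_dims = NULL,
                            variance_mode = c("adaptive", "fixed"),
                            fixed_variance = 1, harden = FALSE, init = NULL) {
  variance_mode <- match.arg(variance_mode)
  X <- as.matrix(X)
  K <- check_count(K, "K")
  if (K > nrow(X)) stop("K must not exceed the number of rows of X", call. = FALSE)
  if (!is.null(pca_dims) && pca_dims < ncol(X)) {
    X <- stats::prcomp(X, center = TRUE, rank. = as.integer(pca_dims))$x
  }
  g <- ncol(X)

  with_seed(seed, {
    centroids <- if (is.null(init)) kmeanspp_init(X, K) else as.matrix(init)
    variances <- if (variance_mode == "fixed") {
      rep(fixed_variance, K)
    } else {
      rep(max(mean(apply(X, 2L, stats::var)), 1e-6), K)
    }

    resp_old <- NULL
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      resp <- soft_assign(X, centroids, variances)
      if (harden) {
        hard <- max.col(resp, ties.method = "first")
        resp <- matrix(0, nrow(X), K)
        resp[cbind(seq_len(nrow(X)), hard)] <- 1
      }
      centroids_new <- update_centroids(X, resp)
      empty <- attr(centroids_new, "empty")
      if (length(empty)) {
        # re-seed starved clusters at the least-committed points
        loners <- order(apply(resp, 1L, max))[seq_along(empty)]
        centroids_new[empty, ] <- X[loners, , drop = FALSE]
      }
      centroids <- centroids_new
      attr(centroids, "empty") <- NULL
      if (variance_mode == "adaptive") {
        variances <- update_variances(X, resp, centroids)
      }
      if (!is.null(resp_old) && max(abs(resp - resp_old)) < tol) {
        converged <- TRUE
        resp_old <- resp
        break
      }
      resp_old <- resp
    }
    resp <- soft_assign(X, centroids, variances)
    if (harden) {
      hard <- max.col(resp, ties.method = "first")
      resp <- matrix(0, nrow(X), K)
      resp[cbind(seq_len(nrow(X)), hard)] <- 1
    }

    structure(
      list(
        responsibilities = resp,
        centroids = centroids,
        variances = variances,
        hard_labels = max.col(resp, ties.method = "first"),
        K = K,
        n_iterations_run = iter,
        converged = converged
      ),
      class = "pseudo_labels"
    )
  })
}

#' @export
print.pseudo_labels <- function(x, ...) {
  cat(sprintf(
    "<pseudo_labels> %d spots, K = %d (%s after %d iteration(s))\n",
    nrow(x$responsibilities), x$K,
    if (x$converged) "converged" else "max_iter reached", x$n_iterations_run
  ))
  print(table(cluster = x$hard_labels))
  invisible(x)
}

#' Pseudo-labels as a tibble
#'
#' @param x A `pseudo_labels` object.
#' @param ... Unused.
#' @return Tibble with `spot`, `hard_label`, and `p_1 .. p_K` columns.
#' @method as_tibble pseudo_labels
#' @export
as_tibble.pseudo_labels <- function(x, ...) {
  out <- tibble::tibble(
    spot = seq_len(nrow(x$responsibilities)),
    hard_label = x$hard_labels
  )
  resp <- x$responsibilities
  colnames(resp) <- paste0("p_", seq_len(x$K))
  cbind(out, tibble::as_tibble(resp))
}
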