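#' Clustering agreement metrics
#'
#' Five external metrics of a predicted clustering against reference
#' labels, all invariant to relabelling of cluster ids:
#' \itemize{
#'   \item ARI: pair-counting adjusted Rand index (chance-corrected; <= 1,
#'     can be negative).
#'   \item NMI: mutual information normalised by the arithmetic mean of the
#'     two label entropies.
#'   \item ACC: accuracy after optimally matching clusters to classes
#'     one-to-one (Hungarian algorithm on the contingency table).
#'   \item purity: sum of per-cluster majority-class counts over `C`.
#'   \item homogeneity: `1 - H(class | cluster) / H(class)`.
#' }
#' Entropies use natural logarithms with the `0 * log 0 = 0` convention.
#'
#' @param predicted,truth Equal-length label vectors (>= 2 spots).
#' @return Named numeric vector
#'   `c(ari, nmi, acc, purity, homogeneity)`.
#' @export
#' @examples
#' clustering_metrics(c(1, 1, 2, 2), c("a", "a", "b", "b"))
clustering_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have the same length", call. = FALSE)
  }
  n <- length(truth)
  if (n < 2L) stop("need at least 2 spots", call. = FALSE)
  tab <- table(predicted, truth)

  c(
    ari = ari_from_table(tab),
    nmi = nmi_from_table(tab),
    acc = acc_from_table(tab, n),
    purity = sum(apply(tab, 1L, max)) / n,
    homogeneity = homogeneity_from_table(tab)
  )
}

# pair-counting ARI from a contingency table
ari_from_table <- function(tab) {
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(1) # both partitions trivial
  }
  (sum_ij - expected) / (max_index - expected)
}

entropy_nat <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

nmi_from_table <- function(tab) {
  n <- sum(tab)
  hu <- entropy_nat(rowSums(tab))
  hv <- entropy_nat(colSums(tab))
  if (hu == 0 && hv == 0) {
    return(1)
  }
  p <- tab / n
  pi_ <- rowSums(tab) / n
  pj_ <- colSums(tab) / n
  nz <- which(p > 0, arr.ind = TRUE)
  mi <- sum(p[nz] * log(p[nz] / (pi_[nz[, 1]] * pj_[nz[, 2]])))
  mi / ((hu + hv) / 2)
}

acc_from_table <- function(tab, n) {
  m <- max(dim(tab))
  padded <- matrix(0, m, m)
  padded[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  match_idx <- solve_assignment(-padded) # maximise matched counts
  sum(padded[cbind(seq_len(m), match_idx)]) / n
}

homogeneity_from_table <- function(tab) {
  h_class <- entropy_nat(colSums(tab))
  if (h_class == 0) {
    return(1)
  }
  n <- sum(tab)
  # H(class | cluster) = sum_k (n_k / n) * H(class within cluster k)
  h_cond <- sum(apply(tab, 1L, function(row) {
    if (sum(row) == 0) 0 else (sum(row) / n) * entropy_nat(row)
  }))
  1 - h_cond / h_class
}

# Hungarian algorithm (Jonker-Volgenant style shortest augmenting paths)
# for the square cost matrix `cost`; returns, for each row, the assigned
# column, minimising total cost. Deterministic: ties resolved by scan order.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L) # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        jj <- j + 1L
        if (!used[jj]) {
          cur <- cost[i0, j] - u[i0 + 0L] - v[jj]
          if (cur < minv[jj]) {
            minv[jj] <- cur
            way[jj] <- j0
          }
          if (minv[jj] < delta) {
            delta <- minv[jj]
            j1 <- jj
          }
        }
      }
      for (jj in seq_len(n + 1L)) {
        if (used[jj]) {
          u[p[jj]] <- u[p[jj]] + delta
          v[jj] <- v[jj] - delta
        } else {
          minv[jj] <- minv[jj] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (jj in 2L:(n + 1L)) {
    if (p[jj] > 0L) assignment[p[jj]] <- jj - 1L
  }
  assignment
}

#' Imputation error metrics
#'
#' Pearson correlation, mean absolute deviation (L1), and root mean square
#' error between imputed and true expression over the masked (evaluated)
#' entries.
#'
#' @param imputed,truth Aligned numeric matrices.
#' @param mask Logical matrix (or index vector) selecting evaluated
#'   entries; default all entries.
#' @return Named numeric vector `c(pcc, l1, rmse)`.
#' @export
imputation_metrics <- function(imputed, truth, mask = NULL) {
  imputed <- as.matrix(imputed)
  truth <- as.matrix(truth)
  if (!all(dim(imputed) == dim(truth))) {
    stop("imputed and truth must have the same dimensions", call. = FALSE)
  }
  if (is.null(mask)) mask <- rep(TRUE, length(truth))
  a <- imputed[mask]
  b <- truth[mask]
  if (!length(a)) stop("empty mask: no entries to evaluate", call. = FALSE)
  if (stats::var(b) == 0 || stats::var(a) == 0) {
    stop("PCC undefined: masked values have zero variance", call. = FALSE)
  }
  c(
    pcc = stats::cor(a, b),
    l1 = mean(abs(a - b)),
    rmse = sqrt(mean((a - b)^2))
  )
}

#' Multi-seed evaluation harness
#'
#' For each seed: split the spots 80/10/10 (or the configured fractions),
#' train the encoder with episodes drawn from the training split, identify
#' spatial domains on the full embedding matrix, score them against the
#' ground-truth labels, and (when `impute = TRUE`) fit the imputation head
#' on the training split and score imputation on the held-out test split.
#' The mean over seeds is the dataset-level summary statistic; the sd
#' captures run-to-run consistency.
#'
#' @param dataset A [spot_dataset()] with `true_labels`.
#' @param config A [run_config()]; its `seed` field is replaced per run.
#' @param seeds Integer vector of seeds (one run each).
#' @param K_domains Domains for [identify_domains()]; defaults to the
#'   number of distinct true labels.
#' @param impute Also evaluate held-out imputation (default `TRUE`).
#' @return An object of class `metric_report`: `per_seed` (tibble, one row
#'   per seed) and `summary` (tibble: metric, mean, sd).
#' @export
run_multi_seed <- function(dataset, config = run_config(), seeds = 1:10,
                           K_domains = NULL, impute = TRUE) {
  if (is.null(dataset$true_labels)) {
    stop("dataset must carry true_labels for evaluation", call. = FALSE)
  }
  if (is.null(K_domains)) K_domains <- nlevels(dataset$true_labels)
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    split <- split_spots(dataset$C, cfg$split_fractions, seed = cfg$seed)
    fit <- train_encoder(dataset, config = cfg, spots = split$train)
    dom <- identify_domains(fit$embeddings, K_domains, seed = cfg$seed)
    cm <- clustering_metrics(dom$assignments, dataset$true_labels)
    row <- tibble::tibble(
      seed = s, ari = cm[["ari"]], nmi = cm[["nmi"]], acc = cm[["acc"]],
      purity = cm[["purity"]], homogeneity = cm[["homogeneity"]]
    )
    if (impute) {
      head <- fit_imputation_head(
        fit$embeddings[split$train, , drop = FALSE],
        dataset$expression[split$train, , drop = FALSE]
      )
      xhat <- impute_expression(
        fit$embeddings[split$test, , drop = FALSE], head
      )
      im <- imputation_metrics(xhat, dataset$expression[split$test, , drop = FALSE])
      row$pcc <- im[["pcc"]]
      row$l1 <- im[["l1"]]
      row$rmse <- im[["rmse"]]
    }
    row
  })
  per_seed <- do.call(rbind, rows)
  metrics <- setdiff(colnames(per_seed), "seed")
  summary <- tibble::tibble(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_seed[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) {
      if (nrow(per_seed) > 1L) stats::sd(per_seed[[m]]) else 0
    }, numeric(1))
  )
  structure(
    list(per_seed = per_seed, summary = summary, seeds = seeds),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d seed(s)\n", nrow(x$per_seed)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Paired comparison of two methods across datasets
#'
#' Thin wrapper around the two-sided Wilcoxon signed-rank test on paired
#' per-dataset mean scores; repeated runs on one dataset must be averaged
#' first (one observation per dataset avoids pseudo-replication).
#'
#' @param scores_a,scores_b Equal-length numeric vectors of per-dataset
#'   mean scores for the two methods.
#' @return The `htest` object from [stats::wilcox.test()].
#' @export
compare_paired_scores <- function(scores_a, scores_b) {
  stats::wilcox.test(scores_a, scores_b, paired = TRUE, alternative = "two.sided")
}
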