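#' Specify a synthetic spatial transcriptomics dataset
#'
#' Describes a simulated tissue: spots laid out on a 2-D lattice or at
#' random, partitioned into spatial domains, each domain with its own mean
#' expression vector. Expression is the domain mean plus Gaussian noise,
#' clipped at zero, optionally sparsified by Bernoulli dropout and shifted
#' by additive per-batch gene-wise offsets.
#'
#' `effect_size` controls the Euclidean separation between domain mean
#' vectors in units of per-gene noise: domain deviations have per-gene scale
#' `effect_size / sqrt(n_genes)`, so the total separation between two domain
#' means is about `effect_size` regardless of the gene count. At the default
#' `noise_sd = 1` this places moderate effect sizes in the regime typical of
#' spatial data, where per-spot expression alone separates domains poorly
#' and spatial aggregation is required.
#'
#' @param n_spots,n_genes,n_domains Positive counts.
#' @param layout `"grid"` (near-square lattice, unit spacing) or
#'   `"random-uniform"` (uniform on the unit square).
#' @param domain_geometry `"horizontal-bands"` (domains are bands of equal
#'   height stacked along y, label increasing with y) or `"voronoi-blobs"`
#'   (nearest of `n_domains` random seed points).
#' @param effect_size Non-negative; separation of domain means (see Details).
#' @param noise_sd Non-negative; per-gene Gaussian noise standard deviation.
#' @param dropout_rate Probability in \[0, 1\] that an entry is zeroed after
#'   noise is added.
#' @param n_batches Positive count of batches (spots assigned uniformly at
#'   random).
#' @param batch_shift_sd Non-negative sd of the additive per-batch gene-wise
#'   shift.
#' @param seed Integer seed; identical specs generate identical datasets.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_spots = 600, n_genes = 60, n_domains = 4,
                           layout = c("grid", "random-uniform"),
                           domain_geometry = c("horizontal-bands", "voronoi-blobs"),
                           effect_size = 3, noise_sd = 1, dropout_rate = 0,
                           n_batches = 1, batch_shift_sd = 0, seed = 1L) {
  spec <- list(
    n_spots = check_count(n_spots, "n_spots"),
    n_genes = check_count(n_genes, "n_genes"),
    n_domains = check_count(n_domains, "n_domains"),
    layout = check_choice(match.arg(layout), "layout", c("grid", "random-uniform")),
    domain_geometry = check_choice(
      match.arg(domain_geometry), "domain_geometry",
      c("horizontal-bands", "voronoi-blobs")
    ),
    effect_size = check_number(effect_size, "effect_size", min = 0),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    dropout_rate = check_number(dropout_rate, "dropout_rate", min = 0, max = 1),
    n_batches = check_count(n_batches, "n_batches"),
    batch_shift_sd = check_number(batch_shift_sd, "batch_shift_sd", min = 0),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  if (spec$n_domains > spec$n_spots) {
    stop_field("n_domains", "must not exceed n_spots")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic spot dataset with known ground truth
#'
#' Draws a dataset according to a [synthetic_spec()]: spot coordinates,
#' planted domain labels, domain mean expression vectors (Gamma baseline
#' shared across domains plus folded-normal domain deviations scaled by the
#' effect size), Gaussian noise, zero-clipping, optional dropout and batch
#' shifts. The planted truth is attached for testing: the attribute
#' `domain_means` holds the `n_domains x n_genes` mean matrix (before batch
#' shift and dropout) and `batch_shifts` the `n_batches x n_genes` offsets.
#'
#' @param spec A [synthetic_spec()].
#' @return A [spot_dataset()] with `true_labels` (planted domains) and
#'   `batch_ids` set, and attributes `domain_means`, `batch_shifts`, `spec`.
#' @export
#' @examples
#' d <- generate_dataset(synthetic_spec(n_spots = 50, n_genes = 10, seed = 3))
#' table(d$true_labels)
generate_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    spec <- do.call(synthetic_spec, as.list(spec))
  }
  with_seed(spec$seed, {
    n <- spec$n_spots
    g <- spec$n_genes
    D <- spec$n_domains

    coords <- switch(spec$layout,
      "grid" = {
        side <- ceiling(sqrt(n))
        cbind(
          x = rep(seq_len(side), times = side)[seq_len(n)],
          y = rep(seq_len(side), each = side)[seq_len(n)]
        )
      },
      "random-uniform" = cbind(x = stats::runif(n), y = stats::runif(n))
    )

    domains <- switch(spec$domain_geometry,
      "horizontal-bands" = {
        y <- coords[, "y"]
        rng <- range(y)
        if (rng[1] == rng[2]) {
          rep(1L, n)
        } else {
          # equal-height bands; label is a monotone function of y
          pmin(D, 1L + floor((y - rng[1]) / (rng[2] - rng[1] + 1e-12) * D))
        }
      },
      "voronoi-blobs" = {
        seeds <- coords[sample.int(n, D), , drop = FALSE]
        max.col(-sqdist(coords, seeds), ties.method = "first")
      }
    )
    domains <- as.integer(domains)

    # baseline well above zero so zero-clipping of the Gaussian noise is rare
    # baseline well above zero so zero-clipping of the Gaussian noise is rare
    baseline <- stats::rgamma(g, shape = 4, scale = 1.5)
    # folded-normal domain deviations scaled so the expected Euclidean
    # separation between two domain mean vectors equals effect_size:
    # E||mu_a - mu_b||^2 = s^2 * g * 2(1 - 2/pi) with per-gene scale s
    s_dev <- spec$effect_size / sqrt(g * 2 * (1 - 2 / pi))
    deviation <- matrix(abs(stats::rnorm(D * g)), D, g) * s_dev
    domain_means <- sweep(deviation, 2L, baseline, "+")

    X <- domain_means[domains, , drop = FALSE]
    if (spec$noise_sd > 0) {
      X <- X + matrix(stats::rnorm(n * g, sd = spec$noise_sd), n, g)
    }

    batches <- if (spec$n_batches > 1L) {
      sample(rep_len(seq_len(spec$n_batches), n))
    } else {
      rep(1L, n)
    }
    batch_shifts <- matrix(0, spec$n_batches, g)
    if (spec$n_batches > 1L && spec$batch_shift_sd > 0) {
      batch_shifts <- matrix(
        stats::rnorm(spec$n_batches * g, sd = spec$batch_shift_sd),
        spec$n_batches, g
      )
      X <- X + batch_shifts[batches, , drop = FALSE]
    }

    X[X < 0] <- 0
    if (spec$dropout_rate > 0) {
      keep <- matrix(stats::rbinom(n * g, 1L, 1 - spec$dropout_rate), n, g)
      X <- X * keep
    }

    dimnames(X) <- list(
      paste0("spot_", seq_len(n)),
      paste0("gene_", seq_len(g))
    )
    out <- spot_dataset(
      expression = X, coordinates = coords,
      batch_ids = batches, true_labels = domains
    )
    attr(out, "domain_means") <- domain_means
    attr(out, "batch_shifts") <- batch_shifts
    attr(out, "spec") <- spec
    out
  })
}
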