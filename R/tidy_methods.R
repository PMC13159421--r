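#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a trained encoder fit
#'
#' One row per spot with its embedding coordinates and hard pseudo-label.
#'
#' @param x A `spotmeta_fit`.
#' @param ... Unused.
#' @return A tibble with columns `spot_id`, `pseudo_label`, `e1..e_dh`.
#' @method tidy spotmeta_fit
#' @export
tidy.spotmeta_fit <- function(x, ...) {
  emb <- tibble::as_tibble(x$embeddings, .name_repair = "minimal")
  out <- tibble::tibble(
    spot_id = rownames(x$embeddings),
    pseudo_label = x$pseudo_labels$hard_labels
  )
  cbind(out, emb)
}

#' One-row summary of a trained encoder fit
#'
#' @param x A `spotmeta_fit`.
#' @param ... Unused.
#' @return A tibble with spot/embedding dimensions, episode count, and the
#'   mean losses over the final ten episodes.
#' @method glance spotmeta_fit
#' @export
glance.spotmeta_fit <- function(x, ...) {
  last <- utils::tail(x$log, 10L)
  tibble::tibble(
    n_spots = nrow(x$embeddings),
    d_h = ncol(x$embeddings),
    n_episodes = nrow(x$log),
    final_l_ct = mean(last$l_ct),
    final_l_ce = mean(last$l_ce),
    final_l_t = mean(last$l_t)
  )
}

#' Tidy a domain-identification result
#'
#' @param x A `domain_result`.
#' @param ... Unused.
#' @return A tibble with `spot` and `domain` columns.
#' @method tidy domain_result
#' @export
tidy.domain_result <- function(x, ...) {
  tibble::tibble(spot = seq_along(x$assignments), domain = x$assignments)
}

#' One-row summary of a domain-identification result
#'
#' @param x A `domain_result`.
#' @param ... Unused.
#' @return A tibble with the domain count and the K-means objective.
#' @method glance domain_result
#' @export
glance.domain_result <- function(x, ...) {
  tibble::tibble(
    n_spots = length(x$assignments),
    n_domains = x$K,
    objective = x$objective
  )
}

#' Tidy a multi-seed metric report
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return The per-seed tibble.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) x$per_seed

#' Summary rows of a multi-seed metric report
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return The `metric, mean, sd` summary tibble.
#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) x$summary

#' Training-loss curves
#'
#' Per-episode contrastive, classification, and combined losses.
#'
#' @param object A `spotmeta_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spotmeta_fit
#' @export
autoplot.spotmeta_fit <- function(object, ...) {
  log <- object$log
  df <- rbind(
    data.frame(episode = log$episode, loss = log$l_ct, term = "L_CT"),
    data.frame(episode = log$episode, loss = log$l_ce, term = "L_CE"),
    data.frame(episode = log$episode, loss = log$l_t, term = "L_T")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$episode, y = .data$loss,
    colour = .data$term)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "episode", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Spatial map of identified domains
#'
#' @param domains A `domain_result` (or an assignment vector).
#' @param coordinates `C x 2` spot coordinates.
#' @return A ggplot object.
#' @export
plot_domains <- function(domains, coordinates) {
  assignments <- if (inherits(domains, "domain_result")) {
    domains$assignments
  } else {
    domains
  }
  df <- data.frame(
    x = coordinates[, 1], y = coordinates[, 2],
    domain = factor(assignments)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
    colour = .data$domain)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "domain") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
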