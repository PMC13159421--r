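#' Run the full pipeline and write its outputs
#'
#' Convenience wrapper used by the command-line interface: trains the
#' encoder, identifies spatial domains, fits the imputation head on the
#' training split, and writes domain labels, embeddings, and imputed
#' expression to `out_dir`.
#'
#' @param dataset A [spot_dataset()].
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param K_domains Number of domains; defaults to the number of distinct
#'   `true_labels` when present, else `config$K_clusters`.
#' @return Invisibly, a list with the `fit`, `domains`, `head`, and the
#'   file `manifest` tibble.
#' @export
run_pipeline <- function(dataset, config = run_config(), out_dir,
                         K_domains = NULL) {
  if (is.null(K_domains)) {
    K_domains <- if (!is.null(dataset$true_labels)) {
      nlevels(dataset$true_labels)
    } else {
      config$K_clusters
    }
  }
  split <- split_spots(dataset$C, config$split_fractions, seed = config$seed)
  fit <- train_encoder(dataset, config = config, spots = split$train)
  domains <- identify_domains(fit$embeddings, K_domains, seed = config$seed)
  head <- fit_imputation_head(
    fit$embeddings[split$train, , drop = FALSE],
    dataset$expression[split$train, , drop = FALSE]
  )
  imputed <- impute_expression(fit$embeddings, head)
  manifest <- write_outputs(
    labels = domains$assignments,
    embeddings = fit$embeddings,
    imputed = imputed,
    out_dir = out_dir,
    spot_ids = dataset$spot_ids
  )
  log_path <- file.path(out_dir, "training_log.csv")
  utils::write.csv(fit$log, log_path, row.names = FALSE)
  invisible(list(
    fit = fit, domains = domains, head = head,
    split = split, manifest = manifest
  ))
}
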