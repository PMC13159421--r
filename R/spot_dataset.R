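#' Assemble a spot dataset
#'
#' The universal input record for all downstream steps: a spots-by-genes
#' expression matrix paired with per-spot spatial coordinates, plus optional
#' batch identifiers and ground-truth domain labels used only for evaluation.
#'
#' @param expression Numeric matrix, spots in rows, genes in columns.
#'   Entries must be non-negative (expression after preprocessing).
#' @param coordinates Numeric matrix with one row per spot; typically two
#'   columns (x, y), three are accepted.
#' @param spot_ids Character vector of unique spot identifiers. Defaults to
#'   the rownames of `expression`, or `spot_1 ... spot_C`.
#' @param batch_ids Optional per-spot batch labels (coerced to factor).
#' @param true_labels Optional per-spot ground-truth domain labels
#'   (coerced to factor), used by the evaluation metrics only.
#'
#' @return An object of class `spot_dataset`: a list with elements
#'   `expression`, `coordinates`, `spot_ids`, `batch_ids`, `true_labels`,
#'   and counts `C` (spots) and `g` (genes).
#' @export
#' @examples
#' x <- matrix(rpois(12, 5), 4, 3)
#' d <- spot_dataset(x, cbind(x = 1:4, y = rep(1, 4)))
#' d$C
spot_dataset <- function(expression, coordinates, spot_ids = NULL,
                         batch_ids = NULL, true_labels = NULL) {
  expression <- as.matrix(expression)
  coordinates <- as.matrix(coordinates)
  if (!is.numeric(expression)) {
    stop("`expression` must be numeric", call. = FALSE)
  }
  if (!is.numeric(coordinates) || !all(is.finite(coordinates))) {
    stop("`coordinates` must be numeric and finite", call. = FALSE)
  }
  C <- nrow(expression)
  if (nrow(coordinates) != C) {
    stop(sprintf(
      "alignment error: expression has %d rows but coordinates has %d",
      C, nrow(coordinates)
    ), call. = FALSE)
  }
  if (is.null(spot_ids)) {
    spot_ids <- rownames(expression)
  }
  if (is.null(spot_ids)) {
    spot_ids <- paste0("spot_", seq_len(C))
  }
  spot_ids <- as.character(spot_ids)
  if (length(spot_ids) != C) {
    stop("`spot_ids` length must equal the number of spots", call. = FALSE)
  }
  if (anyDuplicated(spot_ids)) {
    stop("duplicate spot_ids are not allowed", call. = FALSE)
  }
  if (any(expression < 0, na.rm = TRUE)) {
    stop("`expression` must be non-negative", call. = FALSE)
  }
  if (anyNA(expression)) {
    stop("`expression` contains missing values", call. = FALSE)
  }
  if (!is.null(batch_ids)) {
    if (length(batch_ids) != C) stop("`batch_ids` length mismatch", call. = FALSE)
    batch_ids <- factor(batch_ids)
  }
  if (!is.null(true_labels)) {
    if (length(true_labels) != C) stop("`true_labels` length mismatch", call. = FALSE)
    true_labels <- factor(true_labels)
  }
  rownames(expression) <- spot_ids
  rownames(coordinates) <- spot_ids
  if (is.null(colnames(expression))) {
    colnames(expression) <- paste0("gene_", seq_len(ncol(expression)))
  }
  if (is.null(colnames(coordinates))) {
    colnames(coordinates) <- c("x", "y", "z")[seq_len(ncol(coordinates))]
  }
  structure(
    list(
      expression = expression,
      coordinates = coordinates,
      spot_ids = spot_ids,
      batch_ids = batch_ids,
      true_labels = true_labels,
      C = C,
      g = ncol(expression)
    ),
    class = "spot_dataset"
  )
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf(
    "<spot_dataset> %d spots x %d genes, %d-D coordinates\n",
    x$C, x$g, ncol(x$coordinates)
  ))
  if (!is.null(x$batch_ids)) {
    cat(sprintf("  batches: %d\n", nlevels(x$batch_ids)))
  }
  if (!is.null(x$true_labels)) {
    cat(sprintf("  true domains: %d\n", nlevels(x$true_labels)))
  }
  invisible(x)
}

#' Per-spot metadata as a tibble
#'
#' One row per spot with its identifier, coordinates, and (when present)
#' batch and true-domain labels. The expression matrix itself is not
#' flattened; use `dataset$expression` for it.
#'
#' @param x A `spot_dataset`.
#' @param ... Unused.
#' @return A tibble with `C` rows.
#' @method as_tibble spot_dataset
#' @export
as_tibble.spot_dataset <- function(x, ...) {
  out <- tibble::tibble(spot_id = x$spot_ids)
  for (j in seq_len(ncol(x$coordinates))) {
    out[[colnames(x$coordinates)[j]]] <- x$coordinates[, j]
  }
  if (!is.null(x$batch_ids)) out$batch <- x$batch_ids
  if (!is.null(x$true_labels)) out$true_domain <- x$true_labels
  out
}
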