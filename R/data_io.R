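#' Read a spot dataset from disk
#'
#' Supports dense expression tables (CSV or TSV, spots in rows, header row of
#' gene names, optional leading `spot_id` column) and sparse MatrixMarket
#' triplets (`.mtx`, spots in rows) with companion plain-text name files
#' (one id per line) for spots and genes. Coordinates are a CSV/TSV with one
#' row per spot (optional `spot_id` column, then 2 or 3 numeric columns).
#' Genes are kept exactly as stored: all-zero columns are retained and no
#' filtering is applied; duplicated gene names are disambiguated with an
#' ordinal suffix.
#'
#' @param expression_path Path to the dense table or `.mtx` file.
#' @param coordinates_path Path to the coordinates table.
#' @param labels_path,batches_path Optional CSV/TSV paths; either a single
#'   column, or two columns `(spot_id, value)`.
#' @param spot_ids_path,gene_ids_path Companion name files, required for MTX
#'   input (default: `<stem>_spots.txt` and `<stem>_genes.txt` next to the
#'   matrix).
#' @return A [spot_dataset()].
#' @export
read_dataset <- function(expression_path, coordinates_path,
                         labels_path = NULL, batches_path = NULL,
                         spot_ids_path = NULL, gene_ids_path = NULL) {
  for (p in c(expression_path, coordinates_path, labels_path, batches_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }

  if (grepl("\\.mtx$", expression_path, ignore.case = TRUE)) {
    stem <- sub("\\.mtx$", "", expression_path, ignore.case = TRUE)
    if (is.null(spot_ids_path)) spot_ids_path <- paste0(stem, "_spots.txt")
    if (is.null(gene_ids_path)) gene_ids_path <- paste0(stem, "_genes.txt")
    m <- as.matrix(Matrix::readMM(expression_path))
    spot_ids <- readLines(spot_ids_path)
    gene_ids <- readLines(gene_ids_path)
    if (length(spot_ids) != nrow(m) || length(gene_ids) != ncol(m)) {
      stop("MTX dimensions do not match the companion name files", call. = FALSE)
    }
    rownames(m) <- spot_ids
    colnames(m) <- disambiguate_names(gene_ids)
    expr <- m
  } else {
    tab <- read_delim_table(expression_path)
    ids <- extract_id_column(tab)
    expr <- numeric_matrix(ids$table, expression_path)
    rownames(expr) <- if (is.null(ids$ids)) paste0("spot_", seq_len(nrow(expr))) else ids$ids
    colnames(expr) <- disambiguate_names(colnames(ids$table))
  }

  ctab <- read_delim_table(coordinates_path)
  cids <- extract_id_column(ctab)
  coords <- numeric_matrix(cids$table, coordinates_path)

  if (nrow(coords) != nrow(expr)) {
    stop(sprintf(
      "alignment error: expression has %d spots but coordinates has %d rows",
      nrow(expr), nrow(coords)
    ), call. = FALSE)
  }
  # spots ordered as in the coordinates file
  if (!is.null(cids$ids)) {
    if (!setequal(cids$ids, rownames(expr))) {
      stop("alignment error: spot ids differ between expression and coordinates",
        call. = FALSE
      )
    }
    expr <- expr[match(cids$ids, rownames(expr)), , drop = FALSE]
  }

  spot_dataset(
    expression = expr,
    coordinates = coords,
    spot_ids = rownames(expr),
    batch_ids = read_label_file(batches_path, rownames(expr)),
    true_labels = read_label_file(labels_path, rownames(expr))
  )
}

read_delim_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path,
    sep = sep, header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, comment.char = ""
  )
}

# pull a non-numeric leading id column off a table, if present
extract_id_column <- function(tab) {
  if (ncol(tab) >= 2L &&
    (tolower(colnames(tab)[1]) %in% c("spot_id", "spot", "barcode", "id") ||
      is.character(tab[[1]]))) {
    list(ids = as.character(tab[[1]]), table = tab[, -1L, drop = FALSE])
  } else {
    list(ids = NULL, table = tab)
  }
}

numeric_matrix <- function(tab, path) {
  for (j in seq_along(tab)) {
    col <- tab[[j]]
    if (!is.numeric(col)) {
      converted <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(converted) & !is.na(col))
      if (length(bad)) {
        stop(sprintf(
          "parse error in %s: non-numeric value '%s' at row %d, column '%s'",
          path, col[bad[1]], bad[1], colnames(tab)[j]
        ), call. = FALSE)
      }
      tab[[j]] <- converted
    }
  }
  as.matrix(tab)
}

disambiguate_names <- function(x) {
  if (!anyDuplicated(x)) {
    return(x)
  }
  ave(x, x, FUN = function(v) {
    if (length(v) == 1L) v else paste0(v, "_", seq_along(v))
  })
}

read_label_file <- function(path, spot_ids) {
  if (is.null(path)) {
    return(NULL)
  }
  tab <- read_delim_table(path)
  if (ncol(tab) >= 2L) {
    vals <- tab[[2L]]
    names(vals) <- as.character(tab[[1L]])
    if (all(spot_ids %in% names(vals))) vals <- vals[spot_ids]
  } else {
    vals <- tab[[1L]]
  }
  if (length(vals) != length(spot_ids)) {
    stop(sprintf("label file %s has %d rows; expected %d", path, length(vals),
      length(spot_ids)), call. = FALSE)
  }
  unname(vals)
}

#' Write a spot dataset to disk
#'
#' Writes the formats [read_dataset()] reads, so generated fixtures double
#' as round-trip tests.
#'
#' @param dataset A [spot_dataset()].
#' @param dir Output directory (created if missing).
#' @param format `"csv"` (dense) or `"mtx"` (MatrixMarket triplet plus
#'   companion name files).
#' @return Invisibly, a tibble manifest of the written files.
#' @export
write_dataset <- function(dataset, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  if (format == "csv") {
    p <- file.path(dir, "expression.csv")
    write_matrix_csv(dataset$expression, p, id_col = "spot_id")
    paths <- c(expression = p)
  } else {
    p <- file.path(dir, "expression.mtx")
    Matrix::writeMM(Matrix::Matrix(dataset$expression, sparse = TRUE), p)
    writeLines(dataset$spot_ids, file.path(dir, "expression_spots.txt"))
    writeLines(colnames(dataset$expression), file.path(dir, "expression_genes.txt"))
    paths <- c(
      expression = p,
      spots = file.path(dir, "expression_spots.txt"),
      genes = file.path(dir, "expression_genes.txt")
    )
  }

  cp <- file.path(dir, "coordinates.csv")
  write_matrix_csv(dataset$coordinates, cp, id_col = "spot_id")
  paths <- c(paths, coordinates = cp)

  if (!is.null(dataset$true_labels)) {
    lp <- file.path(dir, "labels.csv")
    utils::write.csv(
      data.frame(spot_id = dataset$spot_ids, domain = dataset$true_labels),
      lp,
      row.names = FALSE, quote = FALSE
    )
    paths <- c(paths, labels = lp)
  }
  if (!is.null(dataset$batch_ids)) {
    bp <- file.path(dir, "batches.csv")
    utils::write.csv(
      data.frame(spot_id = dataset$spot_ids, batch = dataset$batch_ids),
      bp,
      row.names = FALSE, quote = FALSE
    )
    paths <- c(paths, batches = bp)
  }
  invisible(tibble::tibble(what = names(paths), path = unname(paths)))
}

write_matrix_csv <- function(m, path, id_col = NULL) {
  df <- as.data.frame(m)
  if (!is.null(id_col)) {
    df <- cbind(stats::setNames(data.frame(rownames(m)), id_col), df)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write analysis outputs
#'
#' Writes domain labels (two-column CSV `spot_id, domain`), the embedding
#' matrix, and the imputed expression matrix, each with full numeric
#' precision so a read-back reproduces values to within 1e-12.
#'
#' @param labels Integer/factor vector of domain assignments (or `NULL`).
#' @param embeddings Numeric matrix `C x d_h` (or `NULL`).
#' @param imputed Numeric matrix `C x g` (or `NULL`).
#' @param out_dir Output directory.
#' @param spot_ids Spot identifiers; defaults to rownames of the first
#'   non-`NULL` matrix or `spot_1...`.
#' @return A tibble manifest listing the written files.
#' @export
write_outputs <- function(labels = NULL, embeddings = NULL, imputed = NULL,
                          out_dir, spot_ids = NULL) {
  pieces <- list(labels = labels, embeddings = embeddings, imputed = imputed)
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) stop("nothing to write", call. = FALSE)
  sizes <- vapply(pieces, NROW, numeric(1))
  if (any(sizes == 0)) {
    stop(sprintf("`%s` is empty; nothing written", names(pieces)[sizes == 0][1]),
      call. = FALSE
    )
  }
  if (length(unique(sizes)) != 1L) {
    stop("outputs must share the same number of rows (spots)", call. = FALSE)
  }
  C <- sizes[[1]]
  if (is.null(spot_ids)) {
    for (p in pieces) {
      if (!is.null(rownames(p))) {
        spot_ids <- rownames(p)
        break
      }
    }
  }
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(C))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- file.access(out_dir, mode = 2) == 0
  if (!ok) stop(sprintf("output directory not writable: %s", out_dir), call. = FALSE)

  manifest <- list()
  if (!is.null(labels)) {
    p <- file.path(out_dir, "domains.csv")
    utils::write.csv(data.frame(spot_id = spot_ids, domain = labels), p,
      row.names = FALSE, quote = FALSE
    )
    manifest$domains <- p
  }
  if (!is.null(embeddings)) {
    p <- file.path(out_dir, "embeddings.csv")
    m <- embeddings
    rownames(m) <- spot_ids
    if (is.null(colnames(m))) colnames(m) <- paste0("e", seq_len(ncol(m)))
    write_matrix_csv(m, p, id_col = "spot_id")
    manifest$embeddings <- p
  }
  if (!is.null(imputed)) {
    p <- file.path(out_dir, "imputed.csv")
    m <- imputed
    rownames(m) <- spot_ids
    if (is.null(colnames(m))) colnames(m) <- paste0("gene_", seq_len(ncol(m)))
    write_matrix_csv(m, p, id_col = "spot_id")
    manifest$imputed <- p
  }
  tibble::tibble(
    what = names(manifest),
    path = unname(unlist(manifest)),
    rows = C
  )
}

#' Split spots into train/validation/test indices
#'
#' Deterministic random partition with largest-remainder rounding of the
#' requested fractions (so a 10-spot dataset under 80/10/10 yields sizes
#' 8/1/1).
#'
#' @param C Number of spots (>= 3).
#' @param fractions Length-3 non-negative numeric summing to 1.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train`, `val`, `test`;
#'   disjoint and jointly exhaustive over `1:C`.
#' @export
split_spots <- function(C, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  C <- check_count(C, "C")
  if (C < 3L) stop("C must be at least 3 to split three ways", call. = FALSE)
  if (length(fractions) != 3L || any(fractions < 0) ||
    abs(sum(fractions) - 1) > 1e-9) {
    stop_field("fractions", "must be three non-negative numbers summing to 1")
  }
  exact <- C * fractions
  sizes <- floor(exact)
  short <- C - sum(sizes)
  if (short > 0) {
    order_rem <- order(exact - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(short)]] <- sizes[order_rem[seq_len(short)]] + 1L
  }
  perm <- with_seed(seed, sample.int(C))
  list(
    train = sort(perm[seq_len(sizes[1])]),
    val = sort(perm[sizes[1] + seq_len(sizes[2])]),
    test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  )
}

#' Default run configuration
#'
#' Collects every tunable of the pipeline in one validated list. Defaults:
#' `k_neighbors = 6` (hexagonal Visium neighbourhoods), `K_clusters = 10`
#' (fixed across datasets), temperature `tau = 0.5` (moderate values 0.5-1
#' perform best), `alpha = 0.5` (equal weighting of the contrastive and
#' classification losses), 5-way 5-shot episodes with 15 queries, batch
#' size 32 (intermediate sizes 20-50), Adam at `learning_rate = 1e-3`,
#' 80/10/10 split fractions.
#'
#' @param ... Named overrides of any field.
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    k_neighbors = 6L, K_clusters = 10L,
    hidden_dims = 128L, d_h = 64L, activation = "elu",
    tau = 0.5, alpha = 0.5,
    N_way = 5L, M_shot = 5L, Q_query = 15L,
    episodes_per_epoch = 30L, n_epochs = 10L,
    learning_rate = 3e-4, weight_decay = 0, embed_reg = 0,
    batch_size = 32L,
    seed = 1L, split_fractions = c(0.8, 0.1, 0.1),
    similarity = "negative_distance",
    scale_genes = TRUE,
    refresh_pseudo_labels = TRUE, sequential_updates = FALSE,
    pca_dims = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
      call. = FALSE
    )
  }
  cfg[names(dots)] <- dots
  cfg$k_neighbors <- check_count(cfg$k_neighbors, "k_neighbors")
  cfg$K_clusters <- check_count(cfg$K_clusters, "K_clusters")
  cfg$d_h <- check_count(cfg$d_h, "d_h")
  cfg$tau <- check_number(cfg$tau, "tau", min = 1e-12)
  cfg$alpha <- check_number(cfg$alpha, "alpha", min = 0, max = 1)
  cfg$N_way <- check_count(cfg$N_way, "N_way")
  cfg$M_shot <- check_count(cfg$M_shot, "M_shot")
  cfg$Q_query <- check_count(cfg$Q_query, "Q_query", min = 0L)
  cfg$episodes_per_epoch <- check_count(cfg$episodes_per_epoch, "episodes_per_epoch")
  cfg$n_epochs <- check_count(cfg$n_epochs, "n_epochs")
  cfg$learning_rate <- check_number(cfg$learning_rate, "learning_rate", min = 1e-12)
  cfg$weight_decay <- check_number(cfg$weight_decay, "weight_decay", min = 0)
  cfg$embed_reg <- check_number(cfg$embed_reg, "embed_reg", min = 0)
  cfg$batch_size <- check_count(cfg$batch_size, "batch_size")
  cfg$seed <- check_count(cfg$seed, "seed", min = -.Machine$integer.max)
  if (cfg$N_way > cfg$K_clusters) {
    stop_field("N_way", "must not exceed K_clusters")
  }
  if (length(cfg$split_fractions) != 3L ||
    abs(sum(cfg$split_fractions) - 1) > 1e-9) {
    stop_field("split_fractions", "must be three fractions summing to 1")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys are [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}
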