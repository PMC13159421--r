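#' Build the spot-spot k-nearest-neighbour graph
#'
#' Each spot selects its `min(k, C-1)` most similar spots by spatial
#' location and the edge set is symmetrised by union (an edge exists when
#' either endpoint selects the other), giving a binary symmetric adjacency
#' with zero diagonal. Similarity defaults to negative Euclidean distance
#' between coordinate vectors, i.e. spatial proximity; the raw coordinate
#' inner product is available for comparison but is not a proximity measure
#' (it favours spots far from the origin) and is not recommended.
#'
#' Ties at equal similarity are broken by lower spot index, so lattice data
#' (where ties are common) yields a deterministic graph.
#'
#' @param coordinates Numeric `C x z` matrix of finite spot locations.
#' @param k Number of neighbours each spot selects (default 6, matching the
#'   hexagonal neighbourhood of Visium arrays).
#' @param similarity `"negative_distance"` (default) or `"inner_product"`.
#' @return An object of class `spot_graph`: list with the sparse `adjacency`
#'   (`Matrix::dgCMatrix`, 0/1, symmetric, zero diagonal), `k`, `node_count`,
#'   and `neighbors` (adjacency list of integer vectors).
#' @export
#' @examples
#' g <- build_knn_graph(cbind(x = c(0, 1, 2), y = 0), k = 1)
#' as.matrix(g$adjacency)
build_knn_graph <- function(coordinates, k = 6L,
                            similarity = c("negative_distance", "inner_product")) {
  similarity <- match.arg(similarity)
  coordinates <- as.matrix(coordinates)
  if (!is.numeric(coordinates) || !all(is.finite(coordinates))) {
    stop("coordinates must be finite numeric", call. = FALSE)
  }
  k <- check_count(k, "k")
  C <- nrow(coordinates)

  sim <- if (similarity == "negative_distance") {
    -sqdist(coordinates, coordinates) # monotone in -distance; ranks identical
  } else {
    tcrossprod(coordinates)
  }

  ii <- integer(0)
  jj <- integer(0)
  if (C >= 2L) {
    kk <- min(k, C - 1L)
    for (v in seq_len(C)) {
      s <- sim[v, ]
      s[v] <- -Inf
      # highest similarity first; ties broken by lower index
      nb <- order(-s, seq_len(C))[seq_len(kk)]
      ii <- c(ii, rep.int(v, kk))
      jj <- c(jj, nb)
    }
  }
  A <- Matrix::sparseMatrix(
    i = c(ii, jj), j = c(jj, ii),
    x = 1, dims = c(C, C), use.last.ij = FALSE
  )
  A@x[] <- 1 # union symmetrisation: duplicates collapse to 1
  A <- methods::as(A, "CsparseMatrix")
  structure(
    list(
      adjacency = A,
      k = k,
      node_count = C,
      neighbors = adjacency_list(A)
    ),
    class = "spot_graph"
  )
}

adjacency_list <- function(A) {
  C <- nrow(A)
  At <- methods::as(A, "TsparseMatrix")
  nb <- split(At@i + 1L, factor(At@j + 1L, levels = seq_len(C)))
  lapply(nb, sort)
}

#' @export
print.spot_graph <- function(x, ...) {
  cat(sprintf(
    "<spot_graph> %d nodes, %d undirected edges (k = %d)\n",
    x$node_count, Matrix::nnzero(x$adjacency) / 2, x$k
  ))
  invisible(x)
}

#' Extract the two-hop induced subgraph of a spot
#'
#' The subgraph on `{v} U N(v)` where `N(v) = {u : 1 <= d(v, u) <= 2}` is
#' the set of nodes within breadth-first-search distance two of the centre,
#' with every graph edge whose endpoints both lie in that node set, and the
#' expression rows of those nodes.
#'
#' @param graph A [build_knn_graph()] result.
#' @param features Numeric `C x g` matrix of node features (expression).
#' @param v Centre spot index in `1:C`.
#' @return An object of class `spot_subgraph`: list with `center` (original
#'   index), `node_set` (sorted original indices, centre included),
#'   `center_pos` (position of the centre within `node_set`), `adjacency`
#'   (dense induced 0/1 matrix), `features` (rows of `features` for
#'   `node_set`), and `hop_distance` (0/1/2 per node).
#' @export
extract_two_hop_subgraph <- function(graph, features, v) {
  C <- graph$node_count
  if (length(v) != 1L || !is.numeric(v) || is.na(v) || v < 1 || v > C ||
    v != floor(v)) {
    stop(sprintf("centre node v must be an index in 1..%d", C), call. = FALSE)
  }
  v <- as.integer(v)
  features <- as.matrix(features)
  if (nrow(features) != C) {
    stop("features must have one row per graph node", call. = FALSE)
  }

  hop1 <- graph$neighbors[[v]]
  hop2 <- setdiff(unique(unlist(graph$neighbors[hop1], use.names = FALSE)),
    c(v, hop1))
  node_set <- sort(c(v, hop1, hop2))
  hops <- integer(length(node_set))
  hops[match(hop1, node_set)] <- 1L
  hops[match(hop2, node_set)] <- 2L
  hops[match(v, node_set)] <- 0L

  A_sub <- as.matrix(graph$adjacency[node_set, node_set, drop = FALSE])
  structure(
    list(
      center = v,
      node_set = node_set,
      center_pos = match(v, node_set),
      adjacency = A_sub,
      features = features[node_set, , drop = FALSE],
      hop_distance = stats::setNames(hops, node_set)
    ),
    class = "spot_subgraph"
  )
}

#' @export
print.spot_subgraph <- function(x, ...) {
  cat(sprintf(
    "<spot_subgraph> centre %d: %d nodes, %d edges\n",
    x$center, length(x$node_set), sum(x$adjacency) / 2
  ))
  invisible(x)
}

#' Export the adjacency as an edge-list tibble
#'
#' Three columns `(i, j, weight)` with `i < j`, one row per undirected edge;
#' handy for debugging or external graph tools.
#'
#' @param graph A `spot_graph`.
#' @return A tibble.
#' @export
edge_list <- function(graph) {
  At <- methods::as(graph$adjacency, "TsparseMatrix")
  i <- At@i + 1L
  j <- At@j + 1L
  keep <- i < j
  tibble::tibble(i = i[keep], j = j[keep], weight = 1)
}
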