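#' Build the exact kNN graph over raw-feature coordinates
#'
#' For every target cell, finds the \code{k0} nearest other cells under
#' Euclidean distance in the supplied low-dimensional representation of the
#' raw chromatin-accessibility features. The graph is directed (each cell's
#' own neighbor list), the cell itself is excluded, and distance ties are
#' broken by ascending cell index so the graph is deterministic. This graph
#' is built once before training and held fixed; the
#' neighborhood-contrastive loss preserves it in the embedding space.
#'
#' @param rep a \code{\link{lowdim_rep}} (or a bare numeric matrix of
#'   coordinates).
#' @param k0 neighborhood size; must satisfy \code{k0 < n_cells}.
#' @return An object of class \code{"knn_graph"}: list with
#'   \code{neighbor_indices} (n_cells x k0 integer matrix of 1-based row
#'   indices, column r = rank-r neighbor), \code{k0}, \code{n_cells}.
#' @export
build_knn_graph <- function(rep, k0) {
  coords <- if (inherits(rep, "lowdim_rep")) rep$coords else as.matrix(rep)
  if (any(!is.finite(coords))) stop("coordinates contain non-finite values")
  n <- nrow(coords)
  k0 <- as.integer(k0)
  if (k0 < 1L) stop("k0 must be positive")
  if (k0 >= n) stop(sprintf("k0 = %d requires more than %d cells", k0, n))
  # squared Euclidean distances via the Gram matrix; exact search is fine at
  # the scales this graph is used for (tens of thousands of cells)
  sq <- rowSums(coords^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(coords)
  diag(d2) <- Inf
  nb <- matrix(0L, n, k0)
  for (i in seq_len(n)) {
    # order() is stable and the secondary key is the index, so equidistant
    # neighbors come out in ascending-index order
    o <- order(d2[i, ], seq_len(n))[seq_len(k0)]
    nb[i, ] <- o
  }
  structure(list(neighbor_indices = nb, k0 = k0, n_cells = n),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("<knn_graph> %d cells, k0=%d\n", x$n_cells, x$k0))
  invisible(x)
}

#' Sample one positive partner per batch cell
#'
#' For each cell in the minibatch, draws one of its \code{k0} graph
#' neighbors uniformly at random (with replacement across training steps),
#' forming the positive pairs consumed by the neighborhood-contrastive
#' loss. Uses the current R random number stream; seed it for
#' reproducibility.
#'
#' @param graph a \code{"knn_graph"}.
#' @param batch_indices 1-based cell indices of the minibatch.
#' @return integer vector of partner cell indices, one per batch cell.
#' @export
sample_positive_partners <- function(graph, batch_indices) {
  batch_indices <- as.integer(batch_indices)
  if (any(batch_indices < 1L | batch_indices > graph$n_cells))
    stop("batch index out of range 1..", graph$n_cells)
  picks <- sample.int(graph$k0, length(batch_indices), replace = TRUE)
  graph$neighbor_indices[cbind(batch_indices, picks)]
}

#' Export a kNN graph as a TSV edge list
#'
#' @param graph a \code{"knn_graph"}.
#' @param path output file path; columns source_index, target_index, rank
#'   (1-based indices, rank 1 = nearest).
#' @return invisibly, \code{path}.
#' @export
write_knn_edges <- function(graph, path) {
  nb <- graph$neighbor_indices
  df <- data.frame(
    source_index = rep(seq_len(graph$n_cells), times = graph$k0),
    target_index = as.vector(nb),
    rank = rep(seq_len(graph$k0), each = graph$n_cells))
  df <- df[order(df$source_index, df$rank), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fraction of raw-space neighbor pairs preserved in another space
#'
#' Measures neighborhood-structure preservation: the mean, over cells, of
#' the fraction of each cell's k nearest neighbors in \code{ref_coords}
#' that are also among its k nearest neighbors in \code{other_coords}.
#'
#' @param ref_coords,other_coords matrices with one row per cell (same
#'   cells, same order).
#' @param k neighborhood size (default 10).
#' @return A number in [0, 1].
#' @export
knn_preservation <- function(ref_coords, other_coords, k = 10) {
  g1 <- build_knn_graph(as.matrix(ref_coords), k)
  g2 <- build_knn_graph(as.matrix(other_coords), k)
  mean(vapply(seq_len(g1$n_cells), function(i) {
    length(intersect(g1$neighbor_indices[i, ], g2$neighbor_indices[i, ])) / k
  }, 0))
}
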