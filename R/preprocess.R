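#' Restrict two datasets to their shared genes
#'
#' Cross-modal transfer needs the reference expression matrix and the target
#' gene activity matrix to live in the same gene space. Gene names are
#' compared by exact string match after whitespace trimming (no ortholog or
#' alias resolution); both datasets are restricted to the intersection, in
#' the reference's column order.
#'
#' @param reference,target \code{\link{expr_dataset}} objects.
#' @return A list with elements \code{reference} and \code{target}, both
#'   restricted to the M shared genes in identical column order.
#' @export
align_genes <- function(reference, target) {
  shared <- reference$gene_names[reference$gene_names %in% target$gene_names]
  if (length(shared) == 0L)
    stop("no genes are shared between the two datasets; check that both ",
         "use the same gene naming convention (case-sensitive exact match)")
  take <- function(ds) {
    if (identical(ds$gene_names, shared)) return(ds)
    j <- match(shared, ds$gene_names)
    expr_dataset(ds$matrix[, j, drop = FALSE], ds$cell_ids, shared, ds$labels)
  }
  list(reference = take(reference), target = take(target))
}

#' Library-size normalize and log-transform
#'
#' Rescales each cell's profile to sum to \code{scale} (counts per
#' \code{scale}), then applies \code{log(1+x)}. All-zero cells are left as
#' zeros. Applied identically to both modalities so their profiles are
#' comparable in the shared gene space.
#'
#' @param ds an \code{\link{expr_dataset}} with non-negative values.
#' @param scale positive target row sum before the log transform
#'   (default 1e4).
#' @return A normalized \code{\link{expr_dataset}}.
#' @export
normalize_log_cpm <- function(ds, scale = 1e4) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  m <- ds$matrix
  rs <- if (methods::is(m, "Matrix")) Matrix::rowSums(m) else rowSums(m)
  fac <- ifelse(rs > 0, scale / rs, 0)
  if (methods::is(m, "sparseMatrix")) {
    m <- Matrix::Diagonal(x = fac) %*% m
    m@x <- log1p(m@x)
    m <- methods::as(m, "CsparseMatrix")
  } else {
    m <- log1p(m * fac)
  }
  expr_dataset(m, ds$cell_ids, ds$gene_names, ds$labels)
}
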