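#' Construct an expression dataset
#'
#' The basic container used throughout the package: a cells x genes
#' non-negative numeric matrix (dense or \pkg{Matrix} sparse) together with
#' unique cell identifiers, unique gene names, and optional per-cell type
#' labels. The labeled scRNA-seq reference (gene expression matrix, GEM) and
#' the unlabeled scATAC-seq target (gene activity matrix, GAM) are both
#' stored this way.
#'
#' @param matrix cells x genes numeric matrix (base matrix or a
#'   \code{\link[Matrix]{Matrix}} sparse matrix); all values must be finite
#'   and non-negative.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#' @param gene_names character vector of unique gene names, one per column.
#' @param labels optional character vector of cell-type labels, one per cell;
#'   empty strings are rejected.
#' @return An object of class \code{"expr_dataset"}: a list with elements
#'   \code{matrix}, \code{cell_ids}, \code{gene_names}, \code{labels}.
#' @export
expr_dataset <- function(matrix, cell_ids, gene_names, labels = NULL) {
  if (!(is.matrix(matrix) || methods::is(matrix, "Matrix")))
    stop("`matrix` must be a base matrix or a Matrix sparse matrix")
  cell_ids <- as.character(cell_ids)
  gene_names <- trimws(as.character(gene_names))
  if (nrow(matrix) != length(cell_ids))
    stop(sprintf("matrix has %d rows but %d cell ids were given",
                 nrow(matrix), length(cell_ids)))
  if (ncol(matrix) != length(gene_names))
    stop(sprintf("matrix has %d columns but %d gene names were given",
                 ncol(matrix), length(gene_names)))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ",
         paste(utils::head(unique(cell_ids[duplicated(cell_ids)]), 3),
               collapse = ", "))
  if (anyDuplicated(gene_names))
    stop("duplicate gene names: ",
         paste(utils::head(unique(gene_names[duplicated(gene_names)]), 3),
               collapse = ", "))
  vals <- if (methods::is(matrix, "sparseMatrix")) matrix@x else matrix
  if (length(vals) && any(!is.finite(vals)))
    stop("matrix contains non-finite values")
  if (length(vals) && any(vals < 0))
    stop("matrix contains negative values")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(cell_ids))
      stop("labels must have one entry per cell")
    if (any(is.na(labels) | !nzchar(labels)))
      stop("labels must be non-empty strings")
  }
  structure(list(matrix = matrix, cell_ids = cell_ids,
                 gene_names = gene_names, labels = labels),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset> %d cells x %d genes%s\n",
              length(x$cell_ids), length(x$gene_names),
              if (is.null(x$labels)) "" else
                sprintf(", %d label classes", length(unique(x$labels)))))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$matrix)

#' Construct a low-dimensional representation of raw target features
#'
#' Holds per-cell coordinates in a low-dimensional space computed from the
#' target modality's raw chromatin-accessibility features (e.g. principal
#' components or tSNE coordinates). The kNN graph that the
#' neighborhood-contrastive loss preserves is built on these coordinates,
#' never on the gene activity matrix.
#'
#' @param coords cells x dims numeric matrix of finite coordinates.
#' @param cell_ids character vector of cell identifiers; must be identical,
#'   in the same order, to the target dataset's \code{cell_ids}.
#' @return An object of class \code{"lowdim_rep"}.
#' @export
lowdim_rep <- function(coords, cell_ids) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  cell_ids <- as.character(cell_ids)
  if (nrow(coords) != length(cell_ids))
    stop("coords must have one row per cell id")
  if (ncol(coords) < 1L) stop("coords needs at least one dimension")
  if (any(!is.finite(coords))) stop("coords contain non-finite values")
  structure(list(coords = coords, cell_ids = cell_ids),
            class = "lowdim_rep")
}

#' @export
print.lowdim_rep <- function(x, ...) {
  cat(sprintf("<lowdim_rep> %d cells x %d dims\n",
              nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

check_rep_aligned <- function(rep, ds) {
  if (!identical(rep$cell_ids, ds$cell_ids))
    stop("low-dimensional representation cell ids do not match the target ",
         "dataset's cell ids (same cells, same order, required)")
  invisible(TRUE)
}

#' Encode cell-type labels into a reproducible vocabulary
#'
#' Builds the label vocabulary (ordered lexicographically so runs are
#' reproducible) and maps each label to an integer code in \code{0..K-1}.
#' The vocabulary is always built from the reference labels only; target
#' labels outside it are treated as novel ground truth during evaluation.
#'
#' @param labels character vector of non-empty class labels.
#' @return A list with \code{vocab} (an object of class
#'   \code{"label_vocab"}: character vector \code{classes} of length K) and
#'   \code{codes} (integer vector in 0..K-1, one per input label).
#' @export
encode_labels <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("labels must be non-empty")
  if (any(is.na(labels) | !nzchar(labels)))
    stop("labels must be non-empty strings")
  classes <- sort(unique(labels), method = "radix")
  vocab <- structure(list(classes = classes), class = "label_vocab")
  list(vocab = vocab, codes = label_codes(vocab, labels))
}

#' Map labels to integer codes under an existing vocabulary
#'
#' @param vocab a \code{"label_vocab"} object.
#' @param labels character labels; labels not in the vocabulary map to
#'   \code{NA} (novel ground truth).
#' @return integer codes in 0..K-1, \code{NA} for out-of-vocabulary labels.
#' @export
label_codes <- function(vocab, labels) {
  match(as.character(labels), vocab$classes) - 1L
}

#' @export
print.label_vocab <- function(x, ...) {
  cat(sprintf("<label_vocab> K=%d: %s\n", length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}
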