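#' Read a Matrix Market dataset with cell/gene sidecar files
#'
#' Loads a sparse matrix in Matrix Market coordinate format together with
#' plain-text sidecars listing one cell id and one gene name per line.
#' Orientation (cells x genes vs genes x cells) is resolved from the sidecar
#' lengths; the matrix is transposed if it is stored genes x cells. If both
#' orientations are consistent (square matrix with equally long sidecars)
#' the reader refuses to guess.
#'
#' @param matrix_path path to the .mtx file.
#' @param cells_path path to the cell id sidecar (one id per line).
#' @param genes_path path to the gene name sidecar (one name per line).
#' @param labels_path optional path to per-cell labels: either one label per
#'   line (aligned to the cells sidecar) or two tab-separated columns
#'   \code{cell_id<TAB>label}.
#' @return An \code{\link{expr_dataset}}, oriented cells x genes.
#' @export
read_mtx_dataset <- function(matrix_path, cells_path, genes_path,
                             labels_path = NULL) {
  for (p in c(matrix_path, cells_path, genes_path, labels_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrix_path)
  cells <- read_id_lines(cells_path)
  genes <- read_id_lines(genes_path)
  nc <- length(cells); ng <- length(genes)
  direct <- nrow(m) == nc && ncol(m) == ng
  transposed <- nrow(m) == ng && ncol(m) == nc
  if (direct && transposed && nc == ng) {
    stop("ambiguous orientation: matrix in ", matrix_path, " is square and ",
         "both sidecars have ", nc, " lines; cannot tell cells from genes")
  } else if (direct) {
    # keep as is
  } else if (transposed) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(paste0(
      "dimension mismatch: matrix %s is %d x %d but %s has %d lines and ",
      "%s has %d lines"), matrix_path, nrow(m), ncol(m),
      cells_path, nc, genes_path, ng))
  }
  labels <- if (!is.null(labels_path)) read_labels_file(labels_path, cells)
  expr_dataset(methods::as(m, "CsparseMatrix"), cells, genes, labels)
}

read_id_lines <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

read_labels_file <- function(path, cells) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (any(grepl("\t", lines, fixed = TRUE))) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- trimws(vapply(parts, `[`, "", 1L))
    labs <- trimws(vapply(parts, `[`, "", 2L))
    if (identical(ids[1L], "cell_id")) { ids <- ids[-1L]; labs <- labs[-1L] }
    idx <- match(cells, ids)
    if (anyNA(idx))
      stop("labels file ", path, " is missing cells: ",
           paste(utils::head(cells[is.na(idx)], 3), collapse = ", "))
    labs[idx]
  } else {
    labs <- trimws(lines)
    if (length(labs) != length(cells))
      stop(sprintf("labels file %s has %d lines but there are %d cells",
                   path, length(labs), length(cells)))
    labs
  }
}

#' Write a dataset as Matrix Market plus sidecars
#'
#' Inverse of \code{\link{read_mtx_dataset}}: writes \code{<prefix>.mtx},
#' \code{<prefix>_cells.txt}, \code{<prefix>_genes.txt} and, when labels are
#' present, \code{<prefix>_labels.tsv} (cell_id, label).
#'
#' @param ds an \code{\link{expr_dataset}}.
#' @param prefix output path prefix (directories are created).
#' @return invisibly, the named character vector of written paths.
#' @export
write_mtx_dataset <- function(ds, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = paste0(prefix, ".mtx"),
             cells = paste0(prefix, "_cells.txt"),
             genes = paste0(prefix, "_genes.txt"))
  m <- ds$matrix
  if (!methods::is(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, paths[["matrix"]])
  writeLines(ds$cell_ids, paths[["cells"]])
  writeLines(ds$gene_names, paths[["genes"]])
  if (!is.null(ds$labels)) {
    paths <- c(paths, labels = paste0(prefix, "_labels.tsv"))
    utils::write.table(
      data.frame(cell_id = ds$cell_ids, label = ds$labels),
      paths[["labels"]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Read a dense CSV/TSV expression dataset
#'
#' Expects the first row to hold gene names (plus, optionally, a label
#' column) and the first column to hold cell ids. The separator is inferred
#' from the file extension (.tsv/.txt gives tab) unless given.
#'
#' @param path path to the delimited file.
#' @param labels_column optional name of a column to be interpreted as the
#'   per-cell label rather than a gene.
#' @param sep field separator; default inferred from the extension.
#' @return An \code{\link{expr_dataset}}.
#' @export
read_csv_dataset <- function(path, labels_column = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("need at least a cell id column and one gene")
  cells <- trimws(df[[1L]])
  if (anyDuplicated(cells))
    stop("duplicate cell ids in ", path, ": ",
         paste(utils::head(unique(cells[duplicated(cells)]), 3),
               collapse = ", "))
  df <- df[, -1L, drop = FALSE]
  labels <- NULL
  if (!is.null(labels_column)) {
    j <- match(labels_column, colnames(df))
    if (is.na(j)) stop("labels column '", labels_column, "' not found")
    labels <- trimws(df[[j]])
    df <- df[, -j, drop = FALSE]
  }
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(NULL, colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                   df[[j]][i], i, colnames(df)[j], path))
    }
    m[, j] <- v
  }
  expr_dataset(m, cells, colnames(df), labels)
}

#' Write per-cell predictions as TSV
#'
#' One row per cell: \code{cell_id}, \code{predicted_type},
#' \code{confidence} (max softmax probability e), \code{novel_confidence}
#' (1 - e), then one probability column per class. Numbers are printed with
#' at least six significant digits so the file round-trips to 1e-6.
#'
#' @param result a \code{"nclt_prediction"} from \code{\link{predict.nclt}}
#'   (or any list with \code{cell_ids}, \code{probabilities},
#'   \code{predicted_code}, \code{confidence}, \code{novel_confidence}).
#' @param vocab the \code{"label_vocab"} naming the K classes.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_predictions <- function(result, vocab, path) {
  K <- length(vocab$classes)
  header <- c("cell_id", "predicted_type", "confidence", "novel_confidence",
              paste0("prob_", vocab$classes))
  n <- length(result$cell_ids)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (n > 0L) {
    num <- function(x) formatC(x, digits = 8, format = "g")
    probs <- result$probabilities
    rows <- vapply(seq_len(n), function(i) {
      paste(c(result$cell_ids[i],
              vocab$classes[result$predicted_code[i] + 1L],
              num(result$confidence[i]),
              num(result$novel_confidence[i]),
              num(probs[i, ])), collapse = "\t")
    }, "")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a predictions TSV written by \code{\link{write_predictions}}
#'
#' @param path path to the TSV.
#' @return A list with \code{cell_ids}, \code{predicted_type},
#'   \code{confidence}, \code{novel_confidence}, \code{probabilities}
#'   (cells x K matrix with class names), \code{classes}.
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  pcols <- grep("^prob_", colnames(df), value = TRUE)
  probs <- as.matrix(df[, pcols, drop = FALSE])
  storage.mode(probs) <- "double"
  colnames(probs) <- sub("^prob_", "", pcols)
  list(cell_ids = df$cell_id, predicted_type = df$predicted_type,
       confidence = as.numeric(df$confidence),
       novel_confidence = as.numeric(df$novel_confidence),
       probabilities = probs, classes = colnames(probs))
}

#' Write per-cell embeddings as CSV
#'
#' @param embedding cells x d matrix.
#' @param cell_ids character vector, one id per row.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_embeddings <- function(embedding, cell_ids, path) {
  df <- data.frame(cell_id = cell_ids,
                   as.data.frame(embedding, optional = TRUE))
  colnames(df) <- c("cell_id", paste0("dim_", seq_len(ncol(embedding))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
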