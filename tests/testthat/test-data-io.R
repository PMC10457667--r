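test_that("expr_dataset enforces its invariants", {
  m <- matrix(1:6, 2, 3)
  ds <- expr_dataset(m, c("c1", "c2"), c("g1", "g2", "g3"))
  expect_s3_class(ds, "expr_dataset")
  expect_identical(dim(ds), c(2L, 3L))
  expect_error(expr_dataset(m, c("c1", "c1"), c("g1", "g2", "g3")),
               "duplicate cell ids")
  expect_error(expr_dataset(m, c("c1", "c2"), c("g1", "g1", "g3")),
               "duplicate gene names")
  expect_error(expr_dataset(m, "c1", c("g1", "g2", "g3")), "rows")
  expect_error(expr_dataset(-m, c("c1", "c2"), c("g1", "g2", "g3")),
               "negative")
  expect_error(expr_dataset(m, c("c1", "c2"), c("g1", "g2", "g3"),
                            labels = c("T", "")), "non-empty")
  expect_error(expr_dataset(m * NA, c("c1", "c2"), c("g1", "g2", "g3")),
               "non-finite")
})

test_that("MTX reader handles orientation, labels and errors", {
  dir <- withr::local_tempdir()
  m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(5, 1),
                            dims = c(3, 2))
  Matrix::writeMM(m, file.path(dir, "m.mtx"))
  writeLines(c("c1", "c2", "c3"), file.path(dir, "cells.txt"))
  writeLines(c("gA", "gB"), file.path(dir, "genes.txt"))
  ds <- read_mtx_dataset(file.path(dir, "m.mtx"), file.path(dir, "cells.txt"),
                         file.path(dir, "genes.txt"))
  expect_equal(as.matrix(ds$matrix),
               matrix(c(5, 0, 0, 0, 0, 1), 3, 2), ignore_attr = TRUE)

  # genes x cells storage is transposed back using the sidecar lengths
  Matrix::writeMM(Matrix::t(m), file.path(dir, "mt.mtx"))
  ds_t <- read_mtx_dataset(file.path(dir, "mt.mtx"),
                           file.path(dir, "cells.txt"),
                           file.path(dir, "genes.txt"))
  expect_equal(as.matrix(ds_t$matrix), as.matrix(ds$matrix))

  # sidecar/matrix mismatch names the offending files
  writeLines(c("c1", "c2", "c3", "c4"), file.path(dir, "cells4.txt"))
  expect_error(read_mtx_dataset(file.path(dir, "m.mtx"),
                                file.path(dir, "cells4.txt"),
                                file.path(dir, "genes.txt")),
               "dimension mismatch")

  # square matrix with equal sidecars is ambiguous
  sq <- Matrix::sparseMatrix(i = 1, j = 2, x = 3, dims = c(2, 2))
  Matrix::writeMM(sq, file.path(dir, "sq.mtx"))
  writeLines(c("a", "b"), file.path(dir, "two.txt"))
  expect_error(read_mtx_dataset(file.path(dir, "sq.mtx"),
                                file.path(dir, "two.txt"),
                                file.path(dir, "two.txt")),
               "ambiguous")

  # labels: positional and id-keyed
  writeLines(c("T", "B", "T"), file.path(dir, "labs.txt"))
  dsl <- read_mtx_dataset(file.path(dir, "m.mtx"), file.path(dir, "cells.txt"),
                          file.path(dir, "genes.txt"),
                          labels_path = file.path(dir, "labs.txt"))
  expect_identical(dsl$labels, c("T", "B", "T"))
  writeLines(c("c3\tNK", "c1\tT", "c2\tB"), file.path(dir, "labs.tsv"))
  dsl2 <- read_mtx_dataset(file.path(dir, "m.mtx"),
                           file.path(dir, "cells.txt"),
                           file.path(dir, "genes.txt"),
                           labels_path = file.path(dir, "labs.tsv"))
  expect_identical(dsl2$labels, c("T", "B", "NK"))
})

test_that("MTX round-trip is element-wise identical", {
  dir <- withr::local_tempdir()
  set.seed(1)
  m <- matrix(rpois(30, 1), 5, 6)
  ds <- expr_dataset(m, paste0("c", 1:5), paste0("g", 1:6),
                     labels = sample(c("T", "B"), 5, TRUE))
  paths <- write_mtx_dataset(ds, file.path(dir, "rt"))
  back <- read_mtx_dataset(paths[["matrix"]], paths[["cells"]],
                           paths[["genes"]], paths[["labels"]])
  expect_equal(as.matrix(back$matrix), m, ignore_attr = TRUE)
  expect_identical(back$cell_ids, ds$cell_ids)
  expect_identical(back$gene_names, ds$gene_names)
  expect_identical(back$labels, ds$labels)
})

test_that("CSV reader parses labels, rejects bad input", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "d.csv")
  writeLines(c("cell,g1,g2,type", "c1,1,2,T", "c2,3,4,B"), p)
  ds <- read_csv_dataset(p, labels_column = "type")
  expect_identical(ds$labels, c("T", "B"))
  expect_identical(ds$gene_names, c("g1", "g2"))
  expect_equal(as.matrix(ds$matrix), rbind(c(1, 2), c(3, 4)),
               ignore_attr = TRUE)
  expect_error(read_csv_dataset(p, labels_column = "absent"), "not found")
})

test_that("CSV reader flags non-numeric cells and duplicate ids", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "d.csv")
  writeLines(c("cell,g1,g2", "c1,1,x", "c2,3,4"), p)
  expect_error(read_csv_dataset(p), "non-numeric value 'x'")
  p2 <- file.path(dir, "dup.csv")
  writeLines(c("cell,g1", "c1,1", "c1,2"), p2)
  expect_error(read_csv_dataset(p2), "duplicate cell ids")
  p3 <- file.path(dir, "nolab.csv")
  writeLines(c("cell,g1,g2", "c1,1,2", "c2,3,4"), p3)
  expect_null(read_csv_dataset(p3)$labels)
})

test_that("align_genes intersects, preserves reference order, is idempotent", {
  ref <- expr_dataset(matrix(1:6, 2, 3), c("r1", "r2"), c("A", "B", "C"))
  tgt <- expr_dataset(matrix(1:6, 2, 3), c("t1", "t2"), c("B", "C", "D"))
  al <- align_genes(ref, tgt)
  expect_identical(al$reference$gene_names, c("B", "C"))
  expect_identical(al$target$gene_names, c("B", "C"))
  expect_equal(as.matrix(al$target$matrix),
               as.matrix(tgt$matrix[, 1:2]), ignore_attr = TRUE)
  # idempotent
  al2 <- align_genes(al$reference, al$target)
  expect_identical(al2, al)
  # identical vocabularies unchanged
  same <- align_genes(ref, expr_dataset(matrix(1:6, 2, 3), c("t1", "t2"),
                                        c("A", "B", "C")))
  expect_identical(same$reference$gene_names, c("A", "B", "C"))
  # disjoint errors
  expect_error(align_genes(ref, expr_dataset(matrix(1:2, 2, 1),
                                             c("t1", "t2"), "Z")),
               "no genes are shared")
})

test_that("normalize_log_cpm matches the closed form and guards zero rows", {
  ds <- expr_dataset(rbind(c(1, 1), c(0, 0)), c("c1", "c2"), c("g1", "g2"))
  norm <- normalize_log_cpm(ds, scale = 2)
  expect_equal(as.matrix(norm$matrix)[1, ], c(log(2), log(2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.matrix(norm$matrix)[2, ], c(0, 0), ignore_attr = TRUE)
  one <- expr_dataset(matrix(4), "c", "g")
  expect_equal(as.matrix(normalize_log_cpm(one, 4)$matrix)[1, 1], log(5),
               tolerance = 1e-12)
})

test_that("normalization round-trips row sums for dense and sparse input", {
  set.seed(3)
  m <- matrix(rpois(60, 2), 6, 10)
  m[2, ] <- 0
  for (mat in list(m, methods::as(Matrix::Matrix(m, sparse = TRUE),
                                  "CsparseMatrix"))) {
    ds <- expr_dataset(mat, paste0("c", 1:6), paste0("g", 1:10))
    out <- as.matrix(normalize_log_cpm(ds, 1e4)$matrix)
    back <- rowSums(expm1(out))
    expect_equal(back[-2], rep(1e4, 5), tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(back[2], 0)
  }
})

test_that("label encoding is lexicographic and stable", {
  enc <- encode_labels(c("T", "B", "T"))
  expect_identical(enc$vocab$classes, c("B", "T"))
  expect_identical(enc$codes, c(1L, 0L, 1L))
  expect_identical(encode_labels("x")$codes, 0L)
  expect_identical(encode_labels(c("a", "b", "c"))$codes, 0:2)
  expect_error(encode_labels(character()), "non-empty")
  expect_error(encode_labels(c("a", "")), "non-empty")
  vocab <- enc$vocab
  expect_identical(label_codes(vocab, c("T", "novel", "B")),
                   c(1L, NA_integer_, 0L))
})

test_that("prediction TSV writes and round-trips to 1e-6", {
  dir <- withr::local_tempdir()
  vocab <- encode_labels(c("B", "T"))$vocab
  res <- list(cell_ids = "c1", probabilities = rbind(c(0.7, 0.3)),
              predicted_code = 0L, confidence = 0.7, novel_confidence = 0.3)
  p <- file.path(dir, "pred.tsv")
  write_predictions(res, vocab, p)
  back <- read_predictions(p)
  expect_identical(back$predicted_type, "B")
  expect_equal(back$confidence, 0.7, tolerance = 1e-6)
  expect_equal(back$novel_confidence, 0.3, tolerance = 1e-6)
  expect_equal(unname(back$probabilities[1, ]), c(0.7, 0.3),
               tolerance = 1e-6)

  # empty result: header only
  empty <- list(cell_ids = character(), probabilities = matrix(0, 0, 2),
                predicted_code = integer(), confidence = numeric(),
                novel_confidence = numeric())
  p2 <- file.path(dir, "empty.tsv")
  write_predictions(empty, vocab, p2)
  expect_length(readLines(p2), 1L)

  # random probabilities survive the round trip
  set.seed(9)
  P <- matrix(runif(20), 10, 2); P <- P / rowSums(P)
  res3 <- list(cell_ids = paste0("c", 1:10), probabilities = P,
               predicted_code = max.col(P, "first") - 1L,
               confidence = apply(P, 1, max),
               novel_confidence = 1 - apply(P, 1, max))
  p3 <- file.path(dir, "many.tsv")
  write_predictions(res3, vocab, p3)
  expect_equal(unname(read_predictions(p3)$probabilities), unname(P),
               tolerance = 1e-6)
})
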