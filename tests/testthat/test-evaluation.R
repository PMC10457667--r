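test_that("prediction definitions follow the softmax-confidence contract", {
  bench <- make_benchmark(tiny_config())
  fit <- nclt(bench$reference, bench$target, bench$target_rep,
              train = tiny_train())
  pred <- predict(fit, bench$target)
  expect_equal(rowSums(pred$probabilities), rep(1, length(pred$cell_ids)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(pred$confidence,
               apply(pred$probabilities, 1, max), ignore_attr = TRUE)
  expect_equal(pred$novel_confidence, 1 - pred$confidence)
  expect_true(all(pred$confidence >= 1 / length(pred$classes) - 1e-9))
  idx <- cbind(seq_along(pred$cell_ids), pred$predicted_code + 1L)
  expect_equal(pred$probabilities[idx], pred$confidence, ignore_attr = TRUE)
  # gene mismatch errors with the expected count
  small <- expr_dataset(bench$target$matrix[, 1:10],
                        bench$target$cell_ids,
                        bench$target$gene_names[1:10])
  expect_error(predict(fit, small), "lacks")
})

test_that("softmax ties resolve to the lowest class and shift-invariance holds", {
  R <- nclt:::softmax_rows(rbind(c(0, 0), c(3, 1)))
  expect_equal(R[1, ], c(0.5, 0.5))
  expect_equal(max.col(R, ties.method = "first")[1], 1L)
  R2 <- nclt:::softmax_rows(rbind(c(0, 0), c(3, 1)) + 100)
  expect_equal(R, R2, tolerance = 1e-12)
})

test_that("novel calls use a strict threshold", {
  res <- list(confidence = c(0.9, 0.3, 0.5))
  expect_identical(call_novel(res, 0.5), c(FALSE, TRUE, FALSE))
})

test_that("common-type accuracy excludes novel ground truth", {
  vocab <- encode_labels(c("B", "T"))$vocab
  expect_equal(common_type_accuracy(c("T", "T", "B"), c(1L, 0L, 0L), vocab),
               2 / 3)
  expect_equal(common_type_accuracy(c("T", "novelX"), c(1L, 0L), vocab), 1)
  expect_equal(common_type_accuracy(c("T", "B"), c(1L, 0L), vocab), 1)
  expect_true(is.na(common_type_accuracy(c("x", "y"), c(0L, 1L), vocab)))
})

test_that("per-type F1 handles worked, perfect, degenerate and absent cases", {
  vocab <- encode_labels(c("A", "B"))$vocab
  # class A: TP=2, FP=1, FN=1 -> F1 = 2/3
  truth <- c("A", "A", "A", "B", "B")
  pred <- c(0L, 0L, 1L, 0L, 1L)
  f1 <- per_type_f1(truth, pred, vocab)
  expect_equal(f1$f1[f1$class == "A"], 2 / 3, tolerance = 1e-12)
  # perfect class
  f1p <- per_type_f1(c("A", "B"), c(0L, 1L), vocab)
  expect_equal(f1p$f1, c(1, 1))
  # class never predicted and never true: absent (NA), not 0
  vocab3 <- encode_labels(c("A", "B", "C"))$vocab
  f13 <- per_type_f1(c("A", "B"), c(0L, 1L), vocab3)
  expect_true(is.na(f13$f1[f13$class == "C"]))
  # class true but never predicted: 0 with the degenerate flag
  f1d <- per_type_f1(c("A", "A"), c(1L, 1L), vocab)
  expect_equal(f1d$f1[f1d$class == "A"], 0)
  expect_true(f1d$degenerate[f1d$class == "A"])
})

test_that("novel-type AUROC matches examples and the pairwise oracle", {
  expect_equal(novel_auroc(c(0.9, 0.8, 0.1), c(TRUE, TRUE, FALSE)), 1)
  expect_equal(novel_auroc(rep(0.4, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE,
                                          FALSE)), 0.5)
  expect_equal(novel_auroc(c(0.9, 0.4, 0.6, 0.1),
                           c(TRUE, FALSE, FALSE, TRUE)), 0.5)
  expect_true(is.na(novel_auroc(c(0.3, 0.4), c(TRUE, TRUE))))
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(10:500, 1)
    scores <- round(runif(n), 2)   # rounding forces ties
    truth <- runif(n) < 0.4
    if (!any(truth) || all(truth)) next
    expect_equal(novel_auroc(scores, truth), oracle_auroc(scores, truth),
                 tolerance = 1e-9)
  }
})

test_that("OSCR matches examples and the threshold-sweep oracle", {
  vocab <- encode_labels(c("A", "B"))$vocab
  # one correct common cell above the only novel cell
  expect_equal(oscr(c(0.9, 0.1), c(0L, 0L), c("A", "zz"),
                    c(FALSE, TRUE), vocab), 1)
  # the only common cell misclassified
  expect_equal(oscr(c(0.9, 0.1), c(1L, 0L), c("A", "zz"),
                    c(FALSE, TRUE), vocab), 0)
  # interleaved confidences: CCR at the novel cell's threshold is 1/2
  expect_equal(oscr(c(0.9, 0.7, 0.8), c(0L, 0L, 0L), c("A", "A", "zz"),
                    c(FALSE, FALSE, TRUE), vocab), 0.5)
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(20:500, 1)
    e <- round(runif(n), 2)
    is_novel <- runif(n) < 0.3
    if (!any(is_novel) || all(is_novel)) next
    truth_codes <- sample(0:1, n, TRUE)
    truth <- ifelse(is_novel, "zz", c("A", "B")[truth_codes + 1])
    pred <- sample(0:1, n, TRUE)
    expect_equal(oscr(e, pred, truth, is_novel, vocab),
                 oracle_oscr(e, pred, truth_codes, is_novel),
                 tolerance = 1e-9)
  }
})

test_that("rank statistics are invariant to increasing transforms", {
  set.seed(12)
  n <- 120
  e <- runif(n)
  is_novel <- runif(n) < 0.3
  is_novel[1:2] <- c(TRUE, FALSE)
  vocab <- encode_labels(c("A", "B"))$vocab
  truth <- ifelse(is_novel, "zz", sample(c("A", "B"), n, TRUE))
  pred <- sample(0:1, n, TRUE)
  g <- function(x) plogis(5 * x - 1)   # strictly increasing
  expect_equal(novel_auroc(1 - e, is_novel), novel_auroc(g(1 - e), is_novel))
  expect_equal(oscr(e, pred, truth, is_novel, vocab),
               oscr(g(e), pred, truth, is_novel, vocab), tolerance = 1e-12)
})

test_that("perfect separation makes OSCR equal zero-threshold accuracy", {
  vocab <- encode_labels(c("A", "B"))$vocab
  e <- c(0.9, 0.95, 0.85, 0.2, 0.1)
  is_novel <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  truth <- c("A", "B", "A", "zz", "zz")
  pred <- c(0L, 1L, 1L, 0L, 0L)   # 2 of 3 common correct
  expect_equal(oscr(e, pred, truth, is_novel, vocab), 2 / 3,
               tolerance = 1e-12)
})

test_that("evaluate_transfer assembles a coherent report and serializes it", {
  bench <- make_benchmark(tiny_config())
  fit <- nclt(bench$reference, bench$target, bench$target_rep,
              train = tiny_train())
  pred <- predict(fit, bench$target)
  ev <- evaluate_transfer(pred, bench$truth_labels, fit$vocab)
  expect_equal(ev$n_common + ev$n_novel, length(bench$truth_labels))
  expect_true(ev$common_accuracy >= 0 && ev$common_accuracy <= 1)
  expect_true(ev$novel_auroc >= 0 && ev$novel_auroc <= 1)
  expect_true(ev$oscr >= 0 && ev$oscr <= 1)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "eval.json")
  write_eval_report(ev, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$common_accuracy, ev$common_accuracy, tolerance = 1e-12)
  expect_true("novel_auroc" %in% names(back))

  # without novel cells the open-set metrics are absent
  common_only <- bench$truth_labels[!grepl("^novel", bench$truth_labels)]
  keep <- !grepl("^novel", bench$truth_labels)
  pred_sub <- list(cell_ids = pred$cell_ids[keep],
                   probabilities = pred$probabilities[keep, ],
                   predicted_code = pred$predicted_code[keep],
                   predicted_type = pred$predicted_type[keep],
                   confidence = pred$confidence[keep],
                   novel_confidence = pred$novel_confidence[keep],
                   classes = pred$classes)
  ev2 <- evaluate_transfer(pred_sub, common_only, fit$vocab)
  expect_true(is.na(ev2$novel_auroc) && is.na(ev2$oscr))
  p2 <- file.path(dir, "eval2.json")
  write_eval_report(ev2, p2)
  expect_false("novel_auroc" %in% names(jsonlite::read_json(p2)))
})

test_that("confidence histogram counts every cell once per truth group", {
  set.seed(13)
  e <- runif(50)
  nv <- runif(50) < 0.3
  h <- confidence_histogram(e, nv, n_bins = 10)
  expect_equal(sum(h$count_common), sum(!nv))
  expect_equal(sum(h$count_novel), sum(nv))
  expect_equal(nrow(h), 10L)
})
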