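#' Plan the minibatches of one training epoch
#'
#' Each step consumes equal-sized index sets from both modalities. An epoch
#' is one shuffled pass over the larger modality; the smaller modality is
#' cycled through freshly reshuffled permutations as needed, and the final
#' partial batch is dropped so every batch holds exactly \code{batch_size}
#' cells from each stream. Uses the current R random number stream.
#'
#' @param n_ref,n_target cell counts of the two modalities.
#' @param batch_size cells per modality per batch.
#' @param cycle logical; allow the smaller modality to be resampled. When
#'   \code{FALSE} and \code{batch_size} exceeds the smaller modality, an
#'   error is raised.
#' @return A list of batches, each a list with integer index vectors
#'   \code{ref} and \code{target}.
#' @export
minibatch_schedule <- function(n_ref, n_target, batch_size, cycle = TRUE) {
  stopifnot(n_ref >= 1L, n_target >= 1L)
  N <- as.integer(batch_size)
  n_big <- max(n_ref, n_target)
  if (!cycle && N > min(n_ref, n_target))
    stop("batch_size exceeds the smaller modality and cycling is disabled")
  n_batches <- n_big %/% N
  if (n_batches < 1L)
    stop("batch_size ", N, " exceeds the larger modality (", n_big,
         " cells); no full batch can be formed")
  stream <- function(n) {
    idx <- sample.int(n)
    while (length(idx) < n_batches * N) idx <- c(idx, sample.int(n))
    idx[seq_len(n_batches * N)]
  }
  ref_idx <- stream(n_ref)
  tgt_idx <- stream(n_target)
  lapply(seq_len(n_batches), function(b) {
    sl <- ((b - 1L) * N + 1L):(b * N)
    list(ref = ref_idx[sl], target = tgt_idx[sl])
  })
}

#' Fit a neighborhood-contrastive label-transfer model
#'
#' Trains a shared encoder f (genes -> d-dimensional embeddings) and a
#' classifier g (embeddings -> K cell-type logits) that transfer cell-type
#' labels from a labeled scRNA-seq reference to unlabeled scATAC-seq cells
#' represented as a gene activity matrix. The objective combines
#' cross-entropy on the reference, a projection regularizer on both
#' modalities, a cosine feature-alignment loss over best-matched cross-modal
#' pairs, and a neighborhood-contrastive loss that preserves the target
#' cells' kNN graph computed on a low-dimensional representation of their
#' raw chromatin-accessibility features (the graph is built once, before
#' training). See \code{\link{loss_weights}} for the loss hyperparameters.
#'
#' @param reference labeled \code{\link{expr_dataset}} (gene expression
#'   matrix with per-cell type labels).
#' @param target unlabeled \code{\link{expr_dataset}} (gene activity
#'   matrix); genes are intersected with the reference's.
#' @param target_rep \code{\link{lowdim_rep}} of the target's raw features
#'   (e.g. principal components of the peak matrix), aligned to
#'   \code{target}.
#' @param model a \code{\link{model_config}}; \code{input_dim} and
#'   \code{n_classes} are filled in from the data when missing.
#' @param train a \code{\link{train_config}}.
#' @param weights a \code{\link{loss_weights}}.
#' @param normalize logical; library-size normalize + log1p both modalities
#'   (default \code{TRUE}).
#' @param norm_scale target row sum for normalization (default 1e4).
#' @param verbose print per-epoch loss summaries.
#' @return An object of class \code{"nclt"}: the trained parameters, the
#'   label vocabulary, the aligned gene set, configs, and the per-step /
#'   per-epoch training history. Use \code{\link{predict.nclt}} to annotate
#'   cells.
#' @examples
#' bench <- make_benchmark(synthetic_config(cells_per_type_ref = 40,
#'   cells_per_type_target = 40, n_genes = 60, n_raw_features = 300,
#'   seed = 7))
#' fit <- nclt(bench$reference, bench$target, bench$target_rep,
#'             train = train_config(epochs = 2, batch_size = 32, seed = 7))
#' pred <- predict(fit, bench$target)
#' table(pred$predicted_type)
#' @export
nclt <- function(reference, target, target_rep,
                 model = NULL, train = train_config(),
                 weights = loss_weights(), normalize = TRUE,
                 norm_scale = 1e4, verbose = FALSE) {
  stopifnot(inherits(reference, "expr_dataset"),
            inherits(target, "expr_dataset"),
            inherits(train, "nclt_train_config"),
            inherits(weights, "loss_weights"))
  if (is.null(reference$labels))
    stop("the reference dataset must carry cell-type labels")
  if (!inherits(target_rep, "lowdim_rep"))
    target_rep <- lowdim_rep(as.matrix(target_rep), target$cell_ids)
  check_rep_aligned(target_rep, target)

  aligned <- align_genes(reference, target)
  reference <- aligned$reference; target <- aligned$target
  if (normalize) {
    reference <- normalize_log_cpm(reference, norm_scale)
    target <- normalize_log_cpm(target, norm_scale)
  }
  enc <- encode_labels(reference$labels)
  vocab <- enc$vocab
  K <- length(vocab$classes)
  M <- length(reference$gene_names)
  if (is.null(model)) {
    model <- model_config(input_dim = M, n_classes = K)
  } else {
    stopifnot(inherits(model, "nclt_model_config"))
    if (model$input_dim != M)
      stop("model input_dim (", model$input_dim, ") != shared genes (", M, ")")
    if (model$n_classes != K)
      stop("model n_classes (", model$n_classes, ") != label classes (",
           K, ")")
  }

  graph <- build_knn_graph(target_rep, train$k0)

  Xl <- as.matrix(reference$matrix)
  Xu <- as.matrix(target$matrix)
  yl <- enc$codes

  set.seed(train$seed)
  params <- init_networks_seeded(model)
  opt_state <- opt_state_init(params, train$optimizer)

  step_log <- list()
  epoch_log <- matrix(NA_real_, train$epochs, 5,
                      dimnames = list(NULL,
                        c("ce", "pr", "fa", "ncl", "total")))
  step <- 0L
  for (ep in seq_len(train$epochs)) {
    batches <- minibatch_schedule(nrow(Xl), nrow(Xu), train$batch_size)
    ep_rec <- matrix(0, length(batches), 5)
    for (b in seq_along(batches)) {
      ri <- batches[[b]]$ref; ti <- batches[[b]]$target
      pi <- sample_positive_partners(graph, ti)
      res <- train_step(params, opt_state,
                        rna_X = Xl[ri, , drop = FALSE],
                        rna_labels = yl[ri],
                        atac_X = Xu[ti, , drop = FALSE],
                        partner_X = Xu[pi, , drop = FALSE],
                        weights = weights, config = train)
      params <- res$params; opt_state <- res$opt_state
      step <- step + 1L
      step_log[[step]] <- c(epoch = ep, step = step, res$record)
      ep_rec[b, ] <- res$record
    }
    epoch_log[ep, ] <- colMeans(ep_rec)
    if (verbose)
      message(sprintf(
        "epoch %d/%d  ce %.4f  pr %.4f  fa %.4f  ncl %.4f  total %.4f",
        ep, train$epochs, epoch_log[ep, 1], epoch_log[ep, 2],
        epoch_log[ep, 3], epoch_log[ep, 4], epoch_log[ep, 5]))
  }

  history <- list(
    steps = as.data.frame(do.call(rbind, step_log)),
    epochs = as.data.frame(cbind(epoch = seq_len(train$epochs), epoch_log)))

  structure(list(
    params = params, vocab = vocab, gene_names = reference$gene_names,
    model_config = model, train_config = train, weights = weights,
    normalize = normalize, norm_scale = norm_scale,
    history = history, k0 = train$k0, seed = train$seed,
    n_reference = nrow(Xl), n_target = nrow(Xu)),
    class = "nclt")
}

## like init_networks() but drawing from the already-seeded run stream
init_networks_seeded <- function(config) {
  sizes <- c(config$input_dim, config$hidden, config$embed_dim)
  encoder <- lapply(seq_len(length(sizes) - 1L), function(l)
    init_layer(sizes[l], sizes[l + 1L]))
  list(encoder = encoder, classifier = init_layer(config$embed_dim,
                                                  config$n_classes))
}

#' Predict cell types for new cells
#'
#' Embeds the cells with the trained encoder, applies the classifier and a
#' softmax, and reports for each cell the full K-class probability vector r,
#' the predicted class (argmax, ties to the lowest class code), the
#' prediction confidence e = max_k r(k), and the novel-type confidence
#' 1 - e.
#'
#' @param object a fitted \code{"nclt"} model.
#' @param newdata an \code{\link{expr_dataset}} containing (at least) the
#'   model's genes; columns are reordered to the training gene order and
#'   the same normalization is applied.
#' @param ... unused.
#' @return An object of class \code{"nclt_prediction"}: list with
#'   \code{cell_ids}, \code{probabilities} (cells x K),
#'   \code{predicted_code} (0-based), \code{predicted_type},
#'   \code{confidence}, \code{novel_confidence}, \code{embedding}
#'   (cells x d), \code{classes}.
#' @export
predict.nclt <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "expr_dataset"))
  miss <- setdiff(object$gene_names, newdata$gene_names)
  if (length(miss))
    stop("newdata lacks ", length(miss), " of the model's ",
         length(object$gene_names), " genes (e.g. ",
         paste(utils::head(miss, 3), collapse = ", "), ")")
  j <- match(object$gene_names, newdata$gene_names)
  ds <- expr_dataset(newdata$matrix[, j, drop = FALSE], newdata$cell_ids,
                     object$gene_names, newdata$labels)
  if (object$normalize) ds <- normalize_log_cpm(ds, object$norm_scale)
  X <- as.matrix(ds$matrix)
  H <- encoder_forward(object$params$encoder, X)$H
  logits <- classifier_forward(object$params$classifier, H)
  R <- softmax_rows(logits)
  pred <- max.col(R, ties.method = "first") - 1L
  e <- R[cbind(seq_len(nrow(R)), pred + 1L)]
  colnames(R) <- object$vocab$classes
  structure(list(
    cell_ids = ds$cell_ids, probabilities = R, predicted_code = pred,
    predicted_type = object$vocab$classes[pred + 1L],
    confidence = e, novel_confidence = 1 - e, embedding = H,
    classes = object$vocab$classes),
    class = "nclt_prediction")
}

#' @export
print.nclt_prediction <- function(x, ...) {
  cat(sprintf("<nclt_prediction> %d cells, K=%d classes\n",
              length(x$cell_ids), length(x$classes)))
  tab <- table(x$predicted_type)
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  cat(sprintf("  mean confidence %.3f\n", mean(x$confidence)))
  invisible(x)
}

#' @export
print.nclt <- function(x, ...) {
  mc <- x$model_config
  cat("Neighborhood-contrastive label-transfer model\n")
  cat(sprintf("  encoder: %s -> %d genes -> %d dims%s\n", "",
              mc$input_dim, mc$embed_dim,
              if (length(mc$hidden))
                paste0(" (hidden: ", paste(mc$hidden, collapse = ","), ")")
              else " (linear)"))
  cat(sprintf("  classes (K=%d): %s\n", length(x$vocab$classes),
              paste(x$vocab$classes, collapse = ", ")))
  cat(sprintf("  trained %d epochs on %d reference / %d target cells\n",
              x$train_config$epochs, x$n_reference, x$n_target))
  fin <- x$history$epochs[nrow(x$history$epochs), ]
  cat(sprintf("  final epoch loss: total %.4f (ce %.4f, pr %.4f, fa %.4f, ncl %.4f)\n",
              fin$total, fin$ce, fin$pr, fin$fa, fin$ncl))
  invisible(x)
}

#' @export
summary.nclt <- function(object, ...) {
  structure(list(model = object,
                 epochs = object$history$epochs),
            class = "summary.nclt")
}

#' @export
print.summary.nclt <- function(x, ...) {
  print(x$model)
  cat("\nPer-epoch mean loss components:\n")
  print(utils::head(x$epochs, 3), row.names = FALSE)
  if (nrow(x$epochs) > 6) cat("  ...\n")
  print(utils::tail(x$epochs, 3), row.names = FALSE)
  invisible(x)
}

#' Extract model parameters
#'
#' @param object a fitted \code{"nclt"} model.
#' @param ... unused.
#' @return A named list of encoder layer weights/biases and the classifier
#'   weights/bias.
#' @export
coef.nclt <- function(object, ...) {
  out <- list()
  for (l in seq_along(object$params$encoder)) {
    out[[paste0("encoder", l, ".W")]] <- object$params$encoder[[l]]$W
    out[[paste0("encoder", l, ".b")]] <- object$params$encoder[[l]]$b
  }
  out[["classifier.W"]] <- object$params$classifier$W
  out[["classifier.b"]] <- object$params$classifier$b
  out
}

#' Plot training history
#'
#' Draws the per-epoch mean of each loss component and the total.
#'
#' @param x a fitted \code{"nclt"} model.
#' @param ... passed to \code{matplot}.
#' @export
plot.nclt <- function(x, ...) {
  ep <- x$history$epochs
  graphics::matplot(ep$epoch, ep[, c("ce", "pr", "fa", "ncl", "total")],
                    type = "l", lty = 1, lwd = 2,
                    col = c("#1b9e77", "#d95f02", "#7570b3", "#e7298a",
                            "black"),
                    xlab = "epoch", ylab = "mean loss", ...)
  graphics::legend("topright", c("CE", "PR", "FA", "NCL", "total"),
                   lty = 1, lwd = 2,
                   col = c("#1b9e77", "#d95f02", "#7570b3", "#e7298a",
                           "black"), bty = "n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the parameters, configs,
#' label vocabulary, gene set and run seed; \code{load_checkpoint} restores
#' a model usable with \code{\link{predict.nclt}}.
#'
#' @param model a fitted \code{"nclt"} model.
#' @param path checkpoint file path.
#' @return \code{save_checkpoint}: invisibly, \code{path};
#'   \code{load_checkpoint}: the restored \code{"nclt"} object.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "nclt"))
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "nclt")) stop(path, " is not an nclt checkpoint")
  model
}
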