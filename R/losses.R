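## Training losses, as pure functions of embedding / probability batches.
## Each has an independent looped oracle in the test suite; the vectorized
## forms here are the ones the training loop differentiates.

#' Projection regularization: full embedding-dispersion loss
#'
#' Three terms over a batch of embeddings H (|B| x d): the reciprocal of the
#' mean absolute deviation around the batch mean (rewards dispersion), the
#' mean absolute off-diagonal entry of the batch's Pearson correlation
#' matrix (rewards orthogonal dimensions), and the mean absolute coordinate
#' of the batch mean (anchors the cloud at the origin).
#'
#' @param H batch x d numeric matrix of embeddings, batch >= 2, d >= 2.
#' @return A non-negative number. When every embedding is identical the mean
#'   absolute deviation is 0; the reciprocal is then guarded as
#'   \code{1/(mad + 1e-8)} and a warning is raised.
#' @seealso \code{\link{nndr_reduced_loss}}, \code{\link{pr_loss}}
#' @export
nndr_loss <- function(H) {
  H <- check_embedding_batch(H)
  terms <- nndr_terms(H)
  terms[["dispersion"]] + terms[["orthogonality"]] + terms[["centering"]]
}

#' Projection regularization: reduced loss (dispersion term removed)
#'
#' The variant applied to the labeled reference batch: only the
#' orthogonality and centering terms. The dispersion term is dropped there
#' because cross-entropy already spreads the labeled embeddings; keeping it
#' on both modalities lets their spread grow at different rates and worsens
#' misalignment.
#'
#' @inheritParams nndr_loss
#' @return A non-negative number.
#' @export
nndr_reduced_loss <- function(H) {
  H <- check_embedding_batch(H)
  terms <- nndr_terms(H)
  terms[["orthogonality"]] + terms[["centering"]]
}

check_embedding_batch <- function(H) {
  H <- as.matrix(H)
  storage.mode(H) <- "double"
  if (nrow(H) < 2L) stop("embedding batch needs at least 2 cells")
  if (ncol(H) < 2L) stop("embedding dimension must be at least 2")
  if (any(!is.finite(H))) stop("embeddings contain non-finite values")
  H
}

## the three scalar terms of the dispersion regularizer
nndr_terms <- function(H, eps = 1e-8) {
  n <- nrow(H); d <- ncol(H)
  mu <- colMeans(H)
  Hc <- sweep(H, 2L, mu)
  mad <- sum(abs(Hc)) / (n * d)
  if (mad == 0)
    warning("degenerate embedding batch: all embeddings identical")
  A <- batch_correlation(Hc)
  c(dispersion = 1 / (mad + eps),
    orthogonality = (sum(abs(A)) - sum(abs(diag(A)))) / d^2,
    centering = sum(abs(mu)) / d)
}

## Pearson correlation of embedding dimensions over the batch, from the
## centered matrix; zero-variance dimensions get correlation 0
batch_correlation <- function(Hc) {
  s <- sqrt(colSums(Hc^2))
  ok <- s > 0
  Hn <- Hc
  Hn[, ok] <- sweep(Hc[, ok, drop = FALSE], 2L, s[ok], "/")
  Hn[, !ok] <- 0
  A <- crossprod(Hn)
  diag(A)[!ok] <- 0
  A
}

#' Projection regularization loss over both modality batches
#'
#' The full dispersion loss on the unlabeled target (scATAC) batch plus the
#' reduced loss on the labeled reference (scRNA) batch. The asymmetry is
#' deliberate: see \code{\link{nndr_reduced_loss}}.
#'
#' @param rna_H reference-batch embeddings (batch x d).
#' @param atac_H target-batch embeddings (batch x d).
#' @return A non-negative number.
#' @export
pr_loss <- function(rna_H, atac_H) {
  nndr_loss(atac_H) + nndr_reduced_loss(rna_H)
}

#' Feature alignment loss over best-matched cross-modal pairs
#'
#' For each target (scATAC) cell, finds the reference (scRNA) cell with the
#' highest cosine similarity in the embedding space, keeps the top-p
#' fraction of target cells by best-match similarity, and returns minus the
#' mean of those similarities. High-similarity cross-modal pairs likely
#' share a cell type; pulling them together aligns the modalities without
#' requiring paired cells.
#'
#' @param atac_H target-batch embeddings (Nu x d).
#' @param rna_H reference-batch embeddings (Nl x d).
#' @param top_p fraction in (0, 1] of target cells kept; the selected set
#'   has \code{ceiling(top_p * Nu)} cells (never empty). Ties in both the
#'   best-match search and the top-p cut are broken by lowest index.
#' @return A number in [-1, 1].
#' @export
fa_loss <- function(atac_H, rna_H, top_p = 0.8) {
  atac_H <- as.matrix(atac_H); rna_H <- as.matrix(rna_H)
  stopifnot(ncol(atac_H) == ncol(rna_H))
  if (nrow(atac_H) < 1L || nrow(rna_H) < 1L) stop("batches must be non-empty")
  if (!(top_p > 0 && top_p <= 1)) stop("top_p must be in (0, 1]")
  S <- cosine_cross(atac_H, rna_H)   # Nu x Nl
  best <- max.col(S, ties.method = "first")
  best_sim <- S[cbind(seq_len(nrow(S)), best)]
  m <- ceiling(top_p * nrow(S))
  keep <- order(-best_sim, seq_along(best_sim))[seq_len(m)]
  -mean(best_sim[keep])
}

## cosine similarity matrix between rows of A and rows of B;
## zero-norm rows yield similarity 0 with a warning
cosine_cross <- function(A, B) {
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0))
    warning("zero-norm embedding encountered; cosine set to 0 for its pairs")
  na[na == 0] <- Inf; nb[nb == 0] <- Inf
  tcrossprod(A / na, B / nb)
}

#' Cross-entropy loss on the labeled reference batch
#'
#' Mean over the batch of \code{-log r_b(y_b)} where r_b is the softmax
#' class-probability row of cell b and y_b its true class code. When
#' \code{logits} is supplied the loss is computed from the logits with the
#' log-sum-exp trick instead of from \code{probabilities}.
#'
#' @param probabilities batch x K matrix of softmax rows (each summing to 1
#'   within 1e-6); ignored when \code{logits} is given.
#' @param labels integer class codes in 0..K-1, one per row.
#' @param logits optional batch x K matrix of pre-softmax scores.
#' @return A non-negative number.
#' @export
ce_loss <- function(probabilities = NULL, labels, logits = NULL) {
  if (is.null(logits)) {
    P <- as.matrix(probabilities)
    if (any(abs(rowSums(P) - 1) > 1e-6))
      stop("probability rows must sum to 1")
    logP <- log(pmax(P, 1e-300))
  } else {
    Z <- as.matrix(logits)
    logP <- Z - apply(Z, 1L, logsumexp)
  }
  K <- ncol(logP)
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= K))
    stop("label codes must lie in 0..", K - 1L)
  if (length(labels) != nrow(logP)) stop("one label per row required")
  -mean(logP[cbind(seq_len(nrow(logP)), labels + 1L)])
}

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' Neighborhood-contrastive loss
#'
#' Two-sided normalized-temperature contrastive loss over N positive pairs
#' (h_b, hhat_b), where hhat_b is the embedding of a neighbor of cell b
#' sampled from the raw-feature kNN graph. With
#' \code{sigma(a, b) = exp(cos(a, b) / tau)}, each anchor's similarity to
#' its partner is contrasted against its similarities to all partners and
#' all other anchors; the roles of anchors and partners are then swapped and
#' the two sides averaged. Minimizing it pulls graph neighbors together in
#' the embedding and pushes other batch members apart.
#'
#' @param atac_H N x d matrix of anchor embeddings.
#' @param partner_H N x d matrix; row b is the embedding of cell b's sampled
#'   neighbor.
#' @param tau positive temperature.
#' @return A non-negative number (each contrasted fraction is at most 1);
#'   exactly 0 when N = 1.
#' @export
ncl_loss <- function(atac_H, partner_H, tau = 0.1) {
  ncl_forward(atac_H, partner_H, tau)$loss
}

## forward pass shared with the gradient code: returns loss plus the
## intermediates backprop needs
ncl_forward <- function(atac_H, partner_H, tau) {
  H <- as.matrix(atac_H); P <- as.matrix(partner_H)
  if (!identical(dim(H), dim(P)))
    stop("anchor and partner batches must have identical shape")
  if (!(is.numeric(tau) && length(tau) == 1L && tau > 0))
    stop("tau must be a positive number")
  N <- nrow(H)
  nh <- sqrt(rowSums(H^2)); np <- sqrt(rowSums(P^2))
  if (any(nh == 0) || any(np == 0))
    stop("zero-norm embedding in contrastive batch")
  Hn <- H / nh; Pn <- P / np
  Shp <- tcrossprod(Hn, Pn)        # cos(h_b, hhat_r)
  Shh <- tcrossprod(Hn)            # cos(h_b, h_r)
  Spp <- tcrossprod(Pn)            # cos(hhat_b, hhat_r)
  Ehp <- exp(Shp / tau); Ehh <- exp(Shh / tau); Epp <- exp(Spp / tau)
  off <- 1 - diag(N)
  D1 <- rowSums(Ehp) + rowSums(Ehh * off)        # anchor-side denominators
  D2 <- colSums(Ehp) + rowSums(Epp * off)        # partner-side denominators
  pos <- diag(Ehp)
  loss <- -(sum(log(pos / D1)) + sum(log(pos / D2))) / (2 * N)
  list(loss = loss, Hn = Hn, Pn = Pn, nh = nh, np = np,
       Ehp = Ehp, Ehh = Ehh, Epp = Epp, D1 = D1, D2 = D2, N = N, tau = tau)
}

#' Combine the four loss components into the training objective
#'
#' \code{ce + pr_weight * pr + lambda1 * fa + lambda2 * ncl}. The
#' projection-regularization coefficient is fixed at 0.1 by default.
#'
#' @param ce,pr,fa,ncl the four component values.
#' @param weights a \code{\link{loss_weights}} object.
#' @return The weighted total.
#' @export
total_loss <- function(ce, pr, fa, ncl, weights = loss_weights()) {
  ce + weights$pr_weight * pr + weights$lambda1 * fa + weights$lambda2 * ncl
}

#' Loss weights and contrastive hyperparameters
#'
#' @param pr_weight coefficient on the projection regularizer (default 0.1).
#' @param lambda1 coefficient on the feature alignment loss (default 1).
#' @param lambda2 coefficient on the neighborhood-contrastive loss
#'   (default 1).
#' @param tau contrastive temperature (default 0.1).
#' @param top_p fraction of target cells kept by the alignment loss
#'   (default 0.8).
#' @return An object of class \code{"loss_weights"}.
#' @export
loss_weights <- function(pr_weight = 0.1, lambda1 = 1, lambda2 = 1,
                         tau = 0.1, top_p = 0.8) {
  stopifnot(tau > 0, top_p > 0, top_p <= 1, lambda1 >= 0, lambda2 >= 0,
            pr_weight >= 0)
  structure(list(pr_weight = pr_weight, lambda1 = lambda1,
                 lambda2 = lambda2, tau = tau, top_p = top_p),
            class = "loss_weights")
}
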