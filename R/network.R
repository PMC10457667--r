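## Encoder/classifier networks and analytic gradients of the four losses.
##
## There is no autodiff here: every gradient is derived by hand and checked
## against finite differences in the test suite. All abs() and selection
## operations (best-match, top-p) use subgradients / piecewise-constant
## selections, which is exact almost everywhere.

#' Model architecture configuration
#'
#' @param input_dim number of (shared) genes M fed to the encoder.
#' @param embed_dim embedding dimensionality d (default 64, must be >= 2).
#' @param n_classes number of reference cell types K (>= 2).
#' @param hidden integer vector of hidden-layer widths for the encoder;
#'   empty (the default) gives a purely linear encoder M -> d.
#' @param activation hidden-layer nonlinearity; only \code{"relu"} is
#'   implemented.
#' @return An object of class \code{"nclt_model_config"}.
#' @export
model_config <- function(input_dim, embed_dim = 64, n_classes,
                         hidden = integer(), activation = "relu") {
  input_dim <- as.integer(input_dim); embed_dim <- as.integer(embed_dim)
  n_classes <- as.integer(n_classes); hidden <- as.integer(hidden)
  if (input_dim < 1L) stop("input_dim must be >= 1")
  if (embed_dim < 2L) stop("embed_dim must be >= 2")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (any(hidden < 1L)) stop("hidden widths must be positive")
  activation <- match.arg(activation, "relu")
  structure(list(input_dim = input_dim, embed_dim = embed_dim,
                 n_classes = n_classes, hidden = hidden,
                 activation = activation),
            class = "nclt_model_config")
}

#' Training configuration
#'
#' @param batch_size cells sampled from each modality per step (>= 2;
#'   default 256).
#' @param epochs number of passes over the larger modality (default 30).
#' @param learning_rate optimizer step size (default 0.01).
#' @param momentum momentum coefficient for SGD (default 0.9).
#' @param optimizer \code{"sgd"} (momentum SGD, the default) or
#'   \code{"adam"}.
#' @param k0 kNN-graph neighborhood size (default 15).
#' @param seed integer seed governing every source of randomness in a run.
#' @return An object of class \code{"nclt_train_config"}.
#' @export
train_config <- function(batch_size = 256, epochs = 30,
                         learning_rate = 0.01, momentum = 0.9,
                         optimizer = c("sgd", "adam"), k0 = 15, seed = 1) {
  optimizer <- match.arg(optimizer)
  batch_size <- as.integer(batch_size); epochs <- as.integer(epochs)
  if (batch_size < 2L) stop("batch_size must be >= 2")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(batch_size = batch_size, epochs = epochs,
                 learning_rate = learning_rate, momentum = momentum,
                 optimizer = optimizer, k0 = as.integer(k0),
                 seed = as.integer(seed)),
            class = "nclt_train_config")
}

#' Initialize encoder and classifier parameters
#'
#' The encoder maps M -> d (through any configured hidden layers with
#' rectifier activations); the classifier is a single affine map d -> K.
#' Weights are Glorot-scaled Gaussian, biases zero; initialization is
#' deterministic under \code{seed}.
#'
#' @param config a \code{\link{model_config}}.
#' @param seed integer seed.
#' @return A list with \code{encoder} (list of layers, each \code{W},
#'   \code{b}) and \code{classifier} (one such layer).
#' @export
init_networks <- function(config, seed = 1) {
  stopifnot(inherits(config, "nclt_model_config"))
  set.seed(as.integer(seed))
  sizes <- c(config$input_dim, config$hidden, config$embed_dim)
  encoder <- lapply(seq_len(length(sizes) - 1L), function(l) {
    init_layer(sizes[l], sizes[l + 1L])
  })
  classifier <- init_layer(config$embed_dim, config$n_classes)
  list(encoder = encoder, classifier = classifier)
}

init_layer <- function(n_in, n_out) {
  sd <- sqrt(2 / (n_in + n_out))
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out),
       b = numeric(n_out))
}

## ---- forward passes -------------------------------------------------------

## encoder forward; keeps pre- and post-activation matrices for backprop
encoder_forward <- function(encoder, X) {
  acts <- vector("list", length(encoder))
  A <- X
  nl <- length(encoder)
  for (l in seq_len(nl)) {
    Z <- A %*% encoder[[l]]$W
    Z <- sweep(Z, 2L, encoder[[l]]$b, "+")
    A_out <- if (l < nl) pmax(Z, 0) else Z   # hidden relu, linear output
    acts[[l]] <- list(input = A, Z = Z)
    A <- A_out
  }
  list(H = A, acts = acts)
}

## backprop dL/dH through the encoder; returns per-layer gradients
encoder_backward <- function(encoder, acts, dH) {
  nl <- length(encoder)
  grads <- vector("list", nl)
  delta <- dH
  for (l in rev(seq_len(nl))) {
    if (l < nl) delta <- delta * (acts[[l]]$Z > 0)
    grads[[l]] <- list(W = crossprod(acts[[l]]$input, delta),
                       b = colSums(delta))
    if (l > 1L) delta <- delta %*% t(encoder[[l]]$W)
  }
  grads
}

classifier_forward <- function(classifier, H) {
  sweep(H %*% classifier$W, 2L, classifier$b, "+")
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

## ---- gradients of the losses w.r.t. embeddings ---------------------------

## cross-entropy: returns loss, dLogits, softmax rows
ce_grad <- function(logits, labels) {
  n <- nrow(logits)
  R <- softmax_rows(logits)
  Y <- matrix(0, n, ncol(logits))
  Y[cbind(seq_len(n), as.integer(labels) + 1L)] <- 1
  loss <- ce_loss(labels = labels, logits = logits)
  list(loss = loss, dLogits = (R - Y) / n, probs = R)
}

## dispersion regularizer: loss value and dL/dH for the full or reduced form
nndr_grad <- function(H, reduced = FALSE, eps = 1e-8) {
  n <- nrow(H); d <- ncol(H)
  mu <- colMeans(H)
  Hc <- sweep(H, 2L, mu)
  s <- sqrt(colSums(Hc^2))
  ok <- s > 0
  Hn <- Hc
  Hn[, ok] <- sweep(Hc[, ok, drop = FALSE], 2L, s[ok], "/")
  Hn[, !ok] <- 0
  A <- crossprod(Hn); diag(A)[!ok] <- 0
  G <- sign(A) / d^2; diag(G) <- 0; G[!ok, ] <- 0; G[, !ok] <- 0
  term2 <- sum(abs(A)) / d^2 - sum(abs(diag(A))) / d^2
  term3 <- sum(abs(mu)) / d
  # term2 gradient: 2 * (Hn G - Hn * colSums(G*A)) / s per column
  cvec <- colSums(G * A)
  g2 <- 2 * (Hn %*% G - sweep(Hn, 2L, cvec, "*"))
  sdiv <- ifelse(ok, s, Inf)
  g2 <- sweep(g2, 2L, sdiv, "/")
  # term3 gradient: sign(mu_j) / (n d)
  g3 <- matrix(sign(mu) / (n * d), n, d, byrow = TRUE)
  grad <- g2 + g3
  if (reduced) return(list(loss = term2 + term3, grad = grad))
  mad <- sum(abs(Hc)) / (n * d)
  term1 <- 1 / (mad + eps)
  S <- sign(Hc)
  dmad <- (S - matrix(colMeans(S), n, d, byrow = TRUE)) / (n * d)
  g1 <- -dmad / (mad + eps)^2
  list(loss = term1 + term2 + term3, grad = grad + g1)
}

## feature alignment: loss value plus gradients for both modality batches
fa_grad <- function(atac_H, rna_H, top_p) {
  Nu <- nrow(atac_H)
  na <- sqrt(rowSums(atac_H^2)); nb <- sqrt(rowSums(rna_H^2))
  na0 <- ifelse(na == 0, Inf, na); nb0 <- ifelse(nb == 0, Inf, nb)
  S <- tcrossprod(atac_H / na0, rna_H / nb0)
  best <- max.col(S, ties.method = "first")
  best_sim <- S[cbind(seq_len(Nu), best)]
  m <- ceiling(top_p * Nu)
  keep <- order(-best_sim, seq_len(Nu))[seq_len(m)]
  loss <- -mean(best_sim[keep])
  dA <- matrix(0, Nu, ncol(atac_H))
  dB <- matrix(0, nrow(rna_H), ncol(rna_H))
  for (b in keep) {
    i <- best[b]
    if (!is.finite(na0[b]) || !is.finite(nb0[i])) next  # zero-norm: cos == 0
    a <- atac_H[b, ]; r <- rna_H[i, ]
    cs <- S[b, i]
    dA[b, ] <- dA[b, ] - (r / (na[b] * nb[i]) - cs * a / na[b]^2) / m
    dB[i, ] <- dB[i, ] - (a / (na[b] * nb[i]) - cs * r / nb[i]^2) / m
  }
  list(loss = loss, dAtac = dA, dRna = dB)
}

## neighborhood-contrastive loss: value plus gradients for anchors/partners
ncl_grad <- function(atac_H, partner_H, tau) {
  fw <- ncl_forward(atac_H, partner_H, tau)
  N <- fw$N
  off <- 1 - diag(N)
  # gradients w.r.t. the cosine matrices
  Ghp <- (fw$Ehp / fw$D1 + sweep(fw$Ehp, 2L, fw$D2, "/")) / (2 * N * fw$tau)
  diag(Ghp) <- diag(Ghp) - 1 / (N * fw$tau)
  Ghh <- (fw$Ehh * off / fw$D1) / (2 * N * fw$tau)
  Gpp <- (fw$Epp * off / fw$D2) / (2 * N * fw$tau)
  # chain to the row-normalized embeddings
  dHn <- Ghp %*% fw$Pn + (Ghh + t(Ghh)) %*% fw$Hn
  dPn <- t(Ghp) %*% fw$Hn + (Gpp + t(Gpp)) %*% fw$Pn
  # chain through row normalization h -> h / ||h||
  unnorm <- function(dXn, Xn, nrm) (dXn - Xn * rowSums(dXn * Xn)) / nrm
  list(loss = fw$loss,
       dAtac = unnorm(dHn, fw$Hn, fw$nh),
       dPartner = unnorm(dPn, fw$Pn, fw$np))
}

## ---- full objective: forward + backward over all four streams ------------

## One evaluation of the training objective and its gradients w.r.t. every
## parameter. Gradient routing: CE reaches encoder and classifier; PR, FA
## and NCL reach the encoder only (they never consume classifier outputs).
objective_grads <- function(params, rna_X, rna_labels, atac_X, partner_X,
                            weights) {
  fl <- encoder_forward(params$encoder, rna_X)
  fu <- encoder_forward(params$encoder, atac_X)
  fp <- encoder_forward(params$encoder, partner_X)
  logits <- classifier_forward(params$classifier, fl$H)

  ce <- ce_grad(logits, rna_labels)
  pr_u <- nndr_grad(fu$H, reduced = FALSE)
  pr_l <- nndr_grad(fl$H, reduced = TRUE)
  fa <- fa_grad(fu$H, fl$H, weights$top_p)
  ncl <- ncl_grad(fu$H, fp$H, weights$tau)

  w <- weights
  comp <- c(ce = ce$loss, pr = pr_u$loss + pr_l$loss, fa = fa$loss,
            ncl = ncl$loss)
  total <- total_loss(comp[["ce"]], comp[["pr"]], comp[["fa"]],
                      comp[["ncl"]], w)

  # classifier gradients (CE only)
  dLogits <- ce$dLogits
  g_cls <- list(W = crossprod(fl$H, dLogits), b = colSums(dLogits))

  # embedding gradients per stream
  dHl <- dLogits %*% t(params$classifier$W) +
    w$pr_weight * pr_l$grad + w$lambda1 * fa$dRna
  dHu <- w$pr_weight * pr_u$grad + w$lambda1 * fa$dAtac +
    w$lambda2 * ncl$dAtac
  dHp <- w$lambda2 * ncl$dPartner

  g_enc <- encoder_backward(params$encoder, fl$acts, dHl)
  for (g in list(encoder_backward(params$encoder, fu$acts, dHu),
                 encoder_backward(params$encoder, fp$acts, dHp))) {
    for (l in seq_along(g_enc)) {
      g_enc[[l]]$W <- g_enc[[l]]$W + g[[l]]$W
      g_enc[[l]]$b <- g_enc[[l]]$b + g[[l]]$b
    }
  }

  list(total = total, components = comp,
       grads = list(encoder = g_enc, classifier = g_cls))
}

## ---- optimizers -----------------------------------------------------------

opt_state_init <- function(params, optimizer) {
  zeros_like <- function(layer) list(W = layer$W * 0, b = layer$b * 0)
  st <- list(encoder = lapply(params$encoder, zeros_like),
             classifier = zeros_like(params$classifier))
  if (optimizer == "adam")
    list(m = st, v = st, t = 0L)
  else
    list(v = st)
}

apply_update <- function(params, grads, state, config) {
  lr <- config$learning_rate
  if (config$optimizer == "sgd") {
    mom <- config$momentum
    upd_layer <- function(p, g, v) {
      v$W <- mom * v$W + g$W; v$b <- mom * v$b + g$b
      p$W <- p$W - lr * v$W; p$b <- p$b - lr * v$b
      list(p = p, v = v)
    }
    for (l in seq_along(params$encoder)) {
      r <- upd_layer(params$encoder[[l]], grads$encoder[[l]],
                     state$v$encoder[[l]])
      params$encoder[[l]] <- r$p; state$v$encoder[[l]] <- r$v
    }
    r <- upd_layer(params$classifier, grads$classifier, state$v$classifier)
    params$classifier <- r$p; state$v$classifier <- r$v
  } else {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1L
    corr <- lr * sqrt(1 - b2^state$t) / (1 - b1^state$t)
    upd_layer <- function(p, g, m, v) {
      m$W <- b1 * m$W + (1 - b1) * g$W; m$b <- b1 * m$b + (1 - b1) * g$b
      v$W <- b2 * v$W + (1 - b2) * g$W^2; v$b <- b2 * v$b + (1 - b2) * g$b^2
      p$W <- p$W - corr * m$W / (sqrt(v$W) + eps)
      p$b <- p$b - corr * m$b / (sqrt(v$b) + eps)
      list(p = p, m = m, v = v)
    }
    for (l in seq_along(params$encoder)) {
      r <- upd_layer(params$encoder[[l]], grads$encoder[[l]],
                     state$m$encoder[[l]], state$v$encoder[[l]])
      params$encoder[[l]] <- r$p
      state$m$encoder[[l]] <- r$m; state$v$encoder[[l]] <- r$v
    }
    r <- upd_layer(params$classifier, grads$classifier,
                   state$m$classifier, state$v$classifier)
    params$classifier <- r$p
    state$m$classifier <- r$m; state$v$classifier <- r$v
  }
  list(params = params, state = state)
}

#' One gradient step on the joint objective
#'
#' Computes embeddings for the reference batch, the target batch and the
#' target partner batch with the single shared encoder, evaluates the four
#' losses, combines them, and applies one optimizer update. Cross-entropy
#' gradients reach both encoder and classifier; the projection, alignment
#' and contrastive gradients reach the encoder only.
#'
#' @param params list with \code{encoder}/\code{classifier} (see
#'   \code{\link{init_networks}}).
#' @param opt_state optimizer state from a previous call, or \code{NULL} to
#'   initialize.
#' @param rna_X,atac_X,partner_X input batches (rows = cells, columns = the
#'   shared genes); \code{partner_X} row b is the sampled graph neighbor of
#'   \code{atac_X} row b.
#' @param rna_labels integer class codes for \code{rna_X}.
#' @param weights a \code{\link{loss_weights}}.
#' @param config a \code{\link{train_config}} (learning rate / optimizer).
#' @return A list: updated \code{params}, \code{opt_state}, and
#'   \code{record} with the four components and the total.
#' @export
train_step <- function(params, opt_state = NULL, rna_X, rna_labels, atac_X,
                       partner_X, weights = loss_weights(),
                       config = train_config()) {
  if (is.null(opt_state)) opt_state <- opt_state_init(params, config$optimizer)
  ob <- objective_grads(params, rna_X, rna_labels, atac_X, partner_X, weights)
  if (!is.finite(ob$total)) {
    bad <- names(ob$components)[!is.finite(ob$components)]
    stop("non-finite loss component(s): ",
         paste(if (length(bad)) bad else "total", collapse = ", "))
  }
  upd <- apply_update(params, ob$grads, opt_state, config)
  list(params = upd$params, opt_state = upd$state,
       record = c(ob$components, total = ob$total))
}
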