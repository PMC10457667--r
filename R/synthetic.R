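#' Configuration for the synthetic two-modality benchmark
#'
#' The generator emulates the data model the method assumes: shared latent
#' cell populations render into (i) a labeled reference expression matrix
#' and (ii) a target modality whose raw feature space (binary
#' accessibility-like peaks) is informative, but whose gene-level view (the
#' gene activity matrix) is an information-lossy transform of that raw
#' space. The \code{distortion} knob interpolates the gene-level projection
#' between a faithful per-gene aggregation of peaks (0: raw-space
#' neighborhoods preserved) and a rank-deficient random mixing (near 1:
#' neighborhoods scrambled), so the benefit of neighborhood-contrastive
#' training can be demonstrated as a function of information loss.
#'
#' @param n_common_types cell types present in both modalities (>= 2).
#' @param n_novel_types extra types present only in the target (>= 0).
#' @param cells_per_type_ref reference cells per common type.
#' @param cells_per_type_target target cells per type (common and novel).
#' @param n_genes shared gene vocabulary size M.
#' @param n_raw_features raw peak-like feature count (> n_genes).
#' @param latent_dim latent space dimensionality; default
#'   \code{max(4, number of types)}. Low values keep the raw binary
#'   encoding's neighborhood geometry faithful to the latent space.
#' @param noise_sd isotropic latent within-type standard deviation.
#' @param distortion gene-view information loss, in [0, 1].
#' @param dropout_rate probability of zeroing entries, in [0, 1); applied
#'   to the raw peak matrix and to the gene activity matrix (default 0:
#'   no technical zeros beyond binarization itself).
#' @param seed integer seed.
#' @return An object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_common_types = 3, n_novel_types = 1,
                             cells_per_type_ref = 200,
                             cells_per_type_target = 300,
                             n_genes = 200, n_raw_features = 2000,
                             latent_dim = NULL, noise_sd = 0.8,
                             distortion = 0.3, dropout_rate = 0,
                             seed = 1) {
  if (is.null(latent_dim))
    latent_dim <- max(4L, as.integer(n_common_types) +
                        as.integer(n_novel_types))
  cfg <- list(n_common_types = as.integer(n_common_types),
              n_novel_types = as.integer(n_novel_types),
              cells_per_type_ref = as.integer(cells_per_type_ref),
              cells_per_type_target = as.integer(cells_per_type_target),
              n_genes = as.integer(n_genes),
              n_raw_features = as.integer(n_raw_features),
              latent_dim = as.integer(latent_dim),
              noise_sd = as.numeric(noise_sd),
              distortion = as.numeric(distortion),
              dropout_rate = as.numeric(dropout_rate),
              seed = as.integer(seed))
  with(cfg, {
    if (n_common_types < 2L) stop("need at least 2 common types")
    if (n_novel_types < 0L) stop("n_novel_types must be >= 0")
    if (cells_per_type_ref < 1L || cells_per_type_target < 1L)
      stop("cells per type must be positive")
    if (n_raw_features <= n_genes)
      stop("n_raw_features must exceed n_genes")
    if (latent_dim < n_common_types + n_novel_types)
      stop("latent_dim must be at least the number of types")
    if (noise_sd < 0) stop("noise_sd must be non-negative")
    if (distortion < 0 || distortion > 1)
      stop("distortion must be in [0, 1]")
    if (dropout_rate < 0 || dropout_rate >= 1)
      stop("dropout_rate must be in [0, 1)")
  })
  structure(cfg, class = "synthetic_config")
}

## type means: orthogonal latent directions at fixed separation, so
## inter-type distances are controlled (separation / sqrt(2) per pair apart)
type_means <- function(latent_dim, n_types, separation = 4) {
  M <- matrix(stats::rnorm(latent_dim * n_types), latent_dim, n_types)
  Q <- qr.Q(qr(M))[, seq_len(n_types), drop = FALSE]
  separation * t(Q)
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Draw latent cells for every type
#'
#' Each cell type is an isotropic Gaussian cluster around a distinct mean;
#' means are placed along random orthogonal latent directions at a fixed
#' separation. Uses the current R random number stream (seed it, or call
#' through \code{\link{make_benchmark}} which does).
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param cells_per_type cells to draw per type.
#' @param types which type indices to include (default: all, common types
#'   first, then novel).
#' @param means optional precomputed type-means matrix (types x latent_dim);
#'   drawn fresh when \code{NULL}.
#' @return A list with \code{latent} (cells x latent_dim), \code{labels}
#'   (character: \code{type_<i>} for common, \code{novel_<j>} for novel
#'   types), and \code{means}.
#' @export
simulate_latent_cells <- function(config, cells_per_type, types = NULL,
                                  means = NULL) {
  n_types <- config$n_common_types + config$n_novel_types
  if (is.null(means))
    means <- type_means(config$latent_dim, n_types)
  if (is.null(types)) types <- seq_len(n_types)
  type_names <- c(sprintf("type_%d", seq_len(config$n_common_types)),
                  if (config$n_novel_types > 0)
                    sprintf("novel_%d", seq_len(config$n_novel_types)))
  n <- length(types) * cells_per_type
  lat <- matrix(0, n, config$latent_dim)
  labels <- character(n)
  row <- 0L
  for (t in types) {
    idx <- row + seq_len(cells_per_type)
    lat[idx, ] <- matrix(means[t, ], cells_per_type, config$latent_dim,
                         byrow = TRUE) +
      matrix(stats::rnorm(cells_per_type * config$latent_dim,
                          sd = config$noise_sd),
             cells_per_type, config$latent_dim)
    labels[idx] <- type_names[t]
    row <- row + cells_per_type
  }
  list(latent = lat, labels = labels, means = means)
}

## shared gene loading matrix (latent_dim x n_genes)
gene_loadings <- function(config) {
  matrix(stats::rnorm(config$latent_dim * config$n_genes),
         config$latent_dim, config$n_genes)
}

#' Render the labeled reference modality (expression matrix)
#'
#' Expression = softplus(latent x gene loadings), scaled by a lognormal
#' per-cell library-size factor, plus small Gaussian measurement noise
#' (clamped at zero). Only common types appear in the reference; novel
#' types exist in the target alone.
#'
#' @param latent output of \code{\link{simulate_latent_cells}} restricted
#'   to common types.
#' @param config a \code{\link{synthetic_config}}.
#' @param loadings gene loading matrix (latent_dim x n_genes).
#' @param prefix cell-id prefix.
#' @return A labeled \code{\link{expr_dataset}}.
#' @export
render_reference_modality <- function(latent, config,
                                      loadings = NULL, prefix = "ref") {
  if (is.null(loadings)) loadings <- gene_loadings(config)
  n <- nrow(latent$latent)
  expr <- softplus(latent$latent %*% loadings)
  lib <- exp(stats::rnorm(n, 0, 0.3))
  expr <- expr * lib
  expr <- pmax(expr + matrix(stats::rnorm(n * ncol(expr), sd = 0.05),
                             n, ncol(expr)), 0)
  expr_dataset(expr, sprintf("%s_cell_%05d", prefix, seq_len(n)),
               sprintf("gene_%04d", seq_len(config$n_genes)),
               latent$labels)
}

#' Render the target modality: raw peaks, low-dim coordinates, gene view
#'
#' Raw features: each gene spawns \code{n_raw_features / n_genes} peak-like
#' features whose latent loadings are jittered copies of the gene's
#' loading. Peak activity softplus(latent x peak loadings) is binarized at
#' per-peak thresholds staggered across the activity quantiles of the
#' gene's peaks (rank r of g gets the (r - 1/2)/g quantile), so a gene's
#' peaks form a graded ladder of accessibility cutoffs and the binary
#' matrix is a fine quantization of the latent geometry; dropout (if any)
#' then zeroes random entries. The low-dimensional representation is the
#' top \code{min(50, n_raw_features)} principal components of the binary
#' raw matrix. The gene activity matrix is the raw matrix pushed through a
#' projection mixing the faithful per-gene peak average (weight
#' 1 - distortion) with a non-negative rank-deficient random mixing
#' (weight distortion), followed by dropout — at distortion 0 raw-space
#' neighborhoods survive in the gene view; near 1 they are scrambled.
#'
#' @param latent output of \code{\link{simulate_latent_cells}} with common
#'   and novel types.
#' @param config a \code{\link{synthetic_config}}.
#' @param loadings the same gene loading matrix used for the reference.
#' @param prefix cell-id prefix.
#' @return A list: \code{gam} (unlabeled \code{\link{expr_dataset}}),
#'   \code{rep} (\code{\link{lowdim_rep}}), \code{truth} (character labels,
#'   for evaluation only), \code{raw} (binary peak matrix).
#' @export
render_target_modality <- function(latent, config, loadings = NULL,
                                   prefix = "tgt") {
  if (is.null(loadings)) loadings <- gene_loadings(config)
  n <- nrow(latent$latent)
  M <- config$n_genes; n_raw <- config$n_raw_features
  gene_of_peak <- rep(seq_len(M), length.out = n_raw)
  peaks_per_gene <- ceiling(n_raw / M)
  rank_in_gene <- (seq_len(n_raw) - 1L) %/% M + 1L
  peak_load <- loadings[, gene_of_peak, drop = FALSE] +
    matrix(stats::rnorm(config$latent_dim * n_raw, sd = 0.05),
           config$latent_dim, n_raw)
  act <- softplus(latent$latent %*% peak_load)
  # deterministic binarization: peak rank r of a gene opens above the
  # (r - 1/2)/peaks_per_gene activity quantile, a graded cutoff ladder
  u <- (rank_in_gene - 0.5) / peaks_per_gene
  theta <- vapply(seq_len(n_raw),
                  function(j) stats::quantile(act[, j], u[j], names = FALSE),
                  0)
  raw <- 1 * sweep(act, 2L, theta, ">")
  if (config$dropout_rate > 0)
    raw <- raw * matrix(stats::rbinom(n * n_raw, 1L,
                                      1 - config$dropout_rate), n, n_raw)

  coords <- pca_coords(raw, min(50L, n_raw))

  # faithful projection: average of each gene's peaks
  counts <- tabulate(gene_of_peak, nbins = M)
  P_f <- matrix(0, n_raw, M)
  P_f[cbind(seq_len(n_raw), gene_of_peak)] <- 1 / counts[gene_of_peak]
  gam_f <- raw %*% P_f
  if (config$distortion > 0) {
    r_def <- 5L  # rank of the scrambling component
    Cm <- matrix(abs(stats::rnorm(n_raw * r_def)), n_raw, r_def)
    Dm <- matrix(abs(stats::rnorm(r_def * M)), r_def, M)
    gam_d <- raw %*% (Cm %*% Dm)
    s <- mean(gam_f) / mean(gam_d)
    gam <- (1 - config$distortion) * gam_f + config$distortion * s * gam_d
  } else gam <- gam_f
  if (config$dropout_rate > 0) {
    keep <- matrix(stats::rbinom(n * M, 1L, 1 - config$dropout_rate), n, M)
    gam <- gam * keep
  }
  ids <- sprintf("%s_cell_%05d", prefix, seq_len(n))
  list(gam = expr_dataset(gam, ids, sprintf("gene_%04d", seq_len(M))),
       rep = lowdim_rep(coords, ids),
       truth = latent$labels,
       raw = raw)
}

## PCA coordinates via the Gram-matrix eigendecomposition (cells << features)
pca_coords <- function(X, k) {
  Xc <- sweep(X, 2L, colMeans(X))
  G <- tcrossprod(Xc)
  eig <- eigen(G, symmetric = TRUE)
  k <- min(k, sum(eig$values > 1e-8))
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  coords <- U * rep(sqrt(pmax(eig$values[seq_len(k)], 0)), each = nrow(U))
  # sign convention: largest-magnitude coordinate positive
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- sprintf("PC%d", seq_len(k))
  coords
}

#' Generate a complete linked two-modality benchmark
#'
#' One seeded call producing the labeled reference, the unlabeled target
#' gene activity matrix, the target's low-dimensional raw-feature
#' representation, the held-out truth labels, and a manifest recording the
#' configuration.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return A list with \code{reference}, \code{target} (gene view),
#'   \code{target_rep}, \code{truth_labels}, \code{target_raw} (binary peak
#'   matrix), \code{latent} (list for reference and target), and
#'   \code{manifest}.
#' @export
make_benchmark <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_types <- config$n_common_types + config$n_novel_types
  means <- type_means(config$latent_dim, n_types)
  loadings <- gene_loadings(config)
  lat_ref <- simulate_latent_cells(config, config$cells_per_type_ref,
                                   types = seq_len(config$n_common_types),
                                   means = means)
  lat_tgt <- simulate_latent_cells(config, config$cells_per_type_target,
                                   types = seq_len(n_types), means = means)
  reference <- render_reference_modality(lat_ref, config, loadings)
  tgt <- render_target_modality(lat_tgt, config, loadings)
  manifest <- list(generator = "nclt synthetic benchmark",
                   config = unclass(config),
                   n_reference_cells = length(reference$cell_ids),
                   n_target_cells = length(tgt$gam$cell_ids))
  list(reference = reference, target = tgt$gam, target_rep = tgt$rep,
       truth_labels = tgt$truth, target_raw = tgt$raw,
       latent = list(reference = lat_ref, target = lat_tgt),
       manifest = manifest)
}

#' Write a benchmark to disk in the package's exchange formats
#'
#' Writes reference and target as Matrix Market + sidecars (reference
#' labels as TSV), the low-dimensional representation as CSV, the truth
#' labels as TSV, and the manifest as JSON.
#'
#' @param bench output of \code{\link{make_benchmark}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_mtx_dataset(bench$reference, file.path(dir, "reference")),
    write_mtx_dataset(bench$target, file.path(dir, "target")))
  rep_path <- file.path(dir, "target_lowdim.csv")
  df <- data.frame(cell_id = bench$target_rep$cell_ids,
                   bench$target_rep$coords, check.names = FALSE)
  utils::write.csv(df, rep_path, row.names = FALSE, quote = FALSE)
  truth_path <- file.path(dir, "target_truth.tsv")
  utils::write.table(
    data.frame(cell_id = bench$target$cell_ids, label = bench$truth_labels),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(bench$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, lowdim = rep_path, truth = truth_path,
              manifest = manifest_path))
}

#' Read a low-dimensional representation from CSV
#'
#' Expects a \code{cell_id} column followed by numeric coordinate columns,
#' as written by \code{\link{write_benchmark}}.
#'
#' @param path CSV path.
#' @return A \code{\link{lowdim_rep}}.
#' @export
read_lowdim_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"cell_id" %in% colnames(df)) stop("expected a cell_id column in ", path)
  ids <- as.character(df$cell_id)
  coords <- as.matrix(df[, setdiff(colnames(df), "cell_id"), drop = FALSE])
  storage.mode(coords) <- "double"
  lowdim_rep(coords, ids)
}
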