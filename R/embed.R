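#' Embedding configuration
#'
#' @param method One of \code{"umap"}, \code{"tsne"}, \code{"pca"}.
#'   UMAP is the default; PCA is a fully deterministic linear baseline.
#' @param seed Integer seed controlling every stochastic step.
#' @param compress Logical or \code{NULL}: compress profiles with PCA before
#'   embedding. \code{NULL} (default) enables compression only above 5000
#'   sequences.
#' @param compress_dims Number of components kept when compressing (default 50).
#' @param n_neighbors UMAP neighborhood size (default 15, capped at n - 1).
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param perplexity t-SNE perplexity (default 30, capped at floor((n-1)/3)).
#' @param ... Ignored; reserved.
#' @return A list of class \code{embed_config}.
#' @export
embed_config <- function(method = "umap", seed = 42L, compress = NULL,
                         compress_dims = 50L, n_neighbors = 15L,
                         min_dist = 0.1, perplexity = 30, ...) {
  method <- match.arg(method, c("umap", "tsne", "pca"))
  cfg <- list(method = method, seed = as.integer(seed), compress = compress,
              compress_dims = as.integer(compress_dims),
              n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
              perplexity = perplexity)
  class(cfg) <- "embed_config"
  cfg
}

#' Compress profiles by principal components
#'
#' Linear variance-maximizing projection of the mean-centered profile rows
#' onto the leading \code{dims} principal components. Used to compress the
#' feature space before a (more expensive) nonlinear embedding, and as the
#' deterministic \code{"pca"} embedding backend (\code{dims = 2}).
#'
#' @param matrix A \code{profile_matrix} or a plain numeric matrix.
#' @param dims Number of components, \code{2 <= dims < n_features}.
#' @param seed Unused by the exact SVD path; accepted and recorded so the
#'   call signature matches the stochastic backends.
#' @return A list: \code{scores} (n x dims matrix), \code{explained_variance}
#'   (fraction per component), \code{center}, \code{rotation}.
#' @export
compress_profiles <- function(matrix, dims, seed = 42L) {
  x <- if (inherits(matrix, "profile_matrix")) matrix$values else matrix
  stopifnot(is.matrix(x))
  if (dims < 2L || dims >= ncol(x)) {
    stop("dims must satisfy 2 <= dims < n_features (n_features = ", ncol(x), ")")
  }
  if (nrow(x) < dims) stop("need at least as many sequences as components")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  sv <- svd(xc, nu = dims, nv = dims)
  # fix component signs (largest-|loading| positive) for run-to-run stability
  for (j in seq_len(dims)) {
    s <- sign(sv$v[which.max(abs(sv$v[, j])), j])
    if (s < 0) { sv$v[, j] <- -sv$v[, j]; sv$u[, j] <- -sv$u[, j] }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(dims)], dims, dims)
  tot <- sum(xc^2)
  list(
    scores = scores,
    explained_variance = if (tot > 0) sv$d[seq_len(dims)]^2 / tot else rep(0, dims),
    center = ctr,
    rotation = sv$v
  )
}

#' Embed profiles in two dimensions
#'
#' Reduces the (optionally PCA-compressed) k-mer profile matrix to 2D with
#' the configured backend. All backends are deterministic under a fixed seed
#' (UMAP runs single-threaded SGD for exact reproducibility).
#'
#' @param matrix A \code{profile_matrix}, or a plain numeric matrix plus
#'   \code{ids}.
#' @param config An [embed_config()].
#' @param ids Row ids when \code{matrix} is a plain matrix.
#' @return A list of class \code{embedding_2d}: \code{ids}, \code{coords}
#'   (n x 2), \code{config}.
#' @export
embed_2d <- function(matrix, config = embed_config(), ids = NULL) {
  if (inherits(matrix, "profile_matrix")) {
    ids <- matrix$ids
    x <- matrix$values
  } else {
    x <- matrix
    if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  }
  stopifnot(is.matrix(x), length(ids) == nrow(x))
  if (!config$method %in% c("umap", "tsne", "pca")) {
    stop("unknown embedding method '", config$method,
         "'; supported: umap, tsne, pca")
  }
  if (any(!is.finite(x))) stop("non-finite values in embedding input")
  n <- nrow(x)
  if (n < 10L) stop("need at least 10 sequences to embed (got ", n, ")")

  compress <- config$compress
  if (is.null(compress)) compress <- n > 5000L
  if (isTRUE(compress) && config$compress_dims < ncol(x)) {
    x <- compress_profiles(x, dims = min(config$compress_dims, n - 1L),
                           seed = config$seed)$scores
  }

  coords <- switch(config$method,
    pca = compress_profiles(x, dims = 2L, seed = config$seed)$scores,
    umap = {
      nb <- min(config$n_neighbors, n - 1L)
      set.seed(config$seed)
      uwot::umap(x, n_neighbors = nb, min_dist = config$min_dist,
                 n_components = 2L, n_threads = 1L, n_sgd_threads = 0L,
                 verbose = FALSE)
    },
    tsne = {
      perp <- min(config$perplexity, floor((n - 1) / 3))
      set.seed(config$seed)
      Rtsne::Rtsne(x, dims = 2L, perplexity = perp, check_duplicates = FALSE,
                   pca = FALSE, num_threads = 1L, verbose = FALSE)$Y
    }
  )
  coords <- unname(as.matrix(coords))
  if (any(!is.finite(coords))) stop("embedding produced non-finite coordinates")
  emb <- list(ids = ids, coords = coords, config = config)
  class(emb) <- "embedding_2d"
  emb
}

#' Export an embedding as TSV (sequence_id, x, y)
#'
#' @param embedding An \code{embedding_2d}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_embedding_tsv <- function(embedding, path) {
  df <- data.frame(sequence_id = embedding$ids,
                   x = embedding$coords[, 1], y = embedding$coords[, 2],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.embedding_2d <- function(x, ...) {
  cat("<embedding_2d> ", length(x$ids), " points, method=",
      x$config$method, ", seed=", x$config$seed, "\n", sep = "")
  invisible(x)
}
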