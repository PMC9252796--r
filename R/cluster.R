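#' Cluster a 2D embedding into candidate bins
#'
#' Dispatches to one of four clustering backends on the embedding
#' coordinates. Density-based methods (dbscan, hdbscan) may leave points
#' unclustered (noise, label 0); partitioning methods label every point.
#' Cluster labels are renumbered 1..n_clusters by decreasing cluster size,
#' ties broken by the lexicographically smallest member sequence id, so
#' output is stable across runs.
#'
#' @param embedding An \code{embedding_2d}.
#' @param method One of \code{"dbscan"}, \code{"hdbscan"} (default),
#'   \code{"kmeans"}, \code{"spectral"}.
#' @param params Named list of method parameters: \code{eps} and
#'   \code{min_samples} for dbscan (defaults 0.5, 5);
#'   \code{min_cluster_size} and optional \code{min_samples} for hdbscan
#'   (default 10); \code{k} (required) for kmeans and spectral.
#' @param seed Integer seed for the stochastic backends.
#' @return A list of class \code{cluster_labels}: \code{ids}, \code{labels}
#'   (integer, 0 = noise), \code{method}, \code{params}, \code{seed}.
#' @export
cluster_embedding <- function(embedding, method = "hdbscan", params = list(),
                              seed = 42L) {
  stopifnot(inherits(embedding, "embedding_2d"))
  method <- match.arg(method, c("dbscan", "hdbscan", "kmeans", "spectral"))
  x <- embedding$coords
  n <- nrow(x)
  labels <- switch(method,
    dbscan = {
      eps <- params$eps %||% 0.5
      ms <- params$min_samples %||% 5L
      dbscan_labels(x, eps = eps, min_samples = ms)
    },
    hdbscan = {
      mcs <- params$min_cluster_size %||% 10L
      ms <- params$min_samples %||% mcs
      hdbscan_labels(x, min_cluster_size = mcs, min_samples = ms)
    },
    kmeans = {
      k <- params$k
      if (is.null(k)) stop("kmeans requires params$k (number of clusters)")
      set.seed(seed)
      stats::kmeans(x, centers = k, nstart = 10L, iter.max = 100L)$cluster
    },
    spectral = {
      k <- params$k
      if (is.null(k)) stop("spectral clustering requires params$k")
      # median-distance RBF width; kernlab's automatic estimate is unstable
      # on well-separated embeddings
      set.seed(seed)
      sigma <- params$sigma %||% {
        rows <- if (n > 2000L) sample.int(n, 2000L) else seq_len(n)
        med <- stats::median(stats::dist(x[rows, , drop = FALSE]))
        1 / (2 * med^2)
      }
      as.integer(kernlab::specc(x, centers = k,
                                kpar = list(sigma = sigma)))
    }
  )
  if (all(labels == 0L)) {
    stop("clustering produced no clusters (all points noise); ",
         "adjust method parameters")
  }
  labels <- renumber_labels(labels, embedding$ids)
  res <- list(ids = embedding$ids, labels = labels, method = method,
              params = params, seed = as.integer(seed))
  class(res) <- "cluster_labels"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Renumber nonzero labels to 1..n_clusters by decreasing size; ties broken by
# the lexicographically smallest member id. Noise (0) is preserved.
renumber_labels <- function(labels, ids) {
  nz <- labels != 0L
  if (!any(nz)) return(labels)
  sizes <- table(labels[nz])
  min_id <- tapply(ids[nz], labels[nz], min)
  old <- names(sizes)
  ord <- order(-as.integer(sizes), min_id[old])
  map <- stats::setNames(seq_along(old), old[ord])
  out <- labels
  out[nz] <- as.integer(map[as.character(labels[nz])])
  out
}

#' Density-based clustering (DBSCAN)
#'
#' Classic radius/min-samples region-growing algorithm. A point is a core
#' point if its eps-neighborhood (itself included) holds at least
#' \code{min_samples} points; clusters are the connected components of core
#' points under eps-reachability, plus their border points; the rest is
#' noise (label 0).
#'
#' @param x Numeric matrix of coordinates (n x d).
#' @param eps Neighborhood radius.
#' @param min_samples Minimum neighborhood size for a core point.
#' @return Integer label vector; 0 = noise. Labels are arbitrary positive
#'   integers (renumbering happens in [cluster_embedding()]).
#' @export
dbscan_labels <- function(x, eps, min_samples) {
  stopifnot(eps > 0, min_samples >= 1)
  n <- nrow(x)
  xt <- t(x)
  eps2 <- eps^2
  nbr <- function(i) which(colSums((xt - x[i, ])^2) <= eps2)
  labels <- integer(n)
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- nbr(i)
    if (length(nb) < min_samples) next  # noise for now; may become border later
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[nb != i]
    head <- 1L
    while (head <= length(queue)) {
      j <- queue[head]; head <- head + 1L
      if (labels[j] == 0L) labels[j] <- cl
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- nbr(j)
        if (length(nbj) >= min_samples) {
          # duplicates in the queue are harmless: visited/label checks skip them
          queue <- c(queue, nbj[!visited[nbj] | labels[nbj] == 0L])
        }
      }
    }
  }
  labels
}

#' Export cluster labels as TSV (sequence_id, cluster)
#'
#' @param labels A \code{cluster_labels}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_cluster_tsv <- function(labels, path) {
  df <- data.frame(sequence_id = labels$ids, cluster = labels$labels,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cluster_labels <- function(x, ...) {
  k <- max(x$labels)
  cat("<cluster_labels> ", length(x$ids), " points, ", k, " cluster(s), ",
      sum(x$labels == 0L), " noise point(s), method=", x$method, "\n", sep = "")
  invisible(x)
}
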