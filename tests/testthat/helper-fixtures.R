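# Shared fixtures: all built in code, no files on disk.

random_dna <- function(len, seed, alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Independent brute-force canonical k-mer profile: explicit window list,
# dictionary counting, reverse-complement collapsing by string comparison.
# Deliberately shares no code with the package implementation.
oracle_profile <- function(seq, k) {
  rc1 <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  n <- nchar(seq)
  counts <- new.env()
  valid <- 0L
  for (i in seq_len(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("N", w, fixed = TRUE)) next
    canon <- min(w, rc1(w))
    counts[[canon]] <- (if (is.null(counts[[canon]])) 0L else counts[[canon]]) + 1L
    valid <- valid + 1L
  }
  lst <- as.list(counts)
  list(counts = unlist(lst)[order(names(lst))], valid = valid)
}

write_test_fasta <- function(lines) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(lines, fa)
  fa
}

# seq_records table straight from id/sequence vectors
records_from_seqs <- function(ids, seqs) {
  fa <- write_test_fasta(as.vector(rbind(paste0(">", ids), seqs)))
  read_fasta(fa)
}

# Profile-like matrix with rows scattered tightly around g distinct
# compositional centroids; rows renormalized to sum to 1.
centroid_profiles <- function(n_per, n_features = 136, n_groups = 2,
                              noise = 0.005, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rgamma(n_groups * n_features, shape = 0.5),
                    nrow = n_groups)
  centers <- centers / rowSums(centers)
  rows <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    r <- matrix(rep(centers[g, ], n_per), nrow = n_per, byrow = TRUE) +
      matrix(abs(stats::rnorm(n_per * n_features, sd = noise)), nrow = n_per)
    r / rowSums(r)
  }))
  list(values = rows, groups = rep(seq_len(n_groups), each = n_per))
}

# Well-separated 2D point blobs with ground-truth membership.
make_blobs <- function(n_per, centers, spread = 0.5, seed = 1) {
  set.seed(seed)
  coords <- do.call(rbind, lapply(seq_len(nrow(centers)), function(g) {
    cbind(stats::rnorm(n_per, centers[g, 1], spread),
          stats::rnorm(n_per, centers[g, 2], spread))
  }))
  list(coords = coords, groups = rep(seq_len(nrow(centers)), each = n_per))
}

fake_embedding <- function(coords, ids = as.character(seq_len(nrow(coords)))) {
  structure(list(ids = ids, coords = coords,
                 config = embed_config(method = "pca", seed = 1L)),
            class = "embedding_2d")
}

fake_cluster_labels <- function(ids, labels, method = "kmeans") {
  structure(list(ids = ids, labels = as.integer(labels), method = method,
                 params = list(), seed = 1L),
            class = "cluster_labels")
}

# Brute-force connected components of points at radius eps restricted to
# core points (neighborhood >= min_samples), the reference answer for
# DBSCAN cluster count on clean blob data.
brute_components <- function(coords, eps, min_samples) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords)) <= eps
  core <- rowSums(d) >= min_samples
  comp <- rep(0L, n)
  cur <- 0L
  for (i in which(core)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(d[v, ] & core & comp == 0L))
    }
  }
  # border points join any adjacent core component
  for (i in which(!core)) {
    nb <- which(d[i, ] & core)
    if (length(nb)) comp[i] <- comp[nb[1]]
  }
  comp
}

# Naive double-loop KDE oracle: cells x points, closed form per pair.
oracle_kde <- function(points, bandwidth, x_centers, y_centers) {
  hx <- bandwidth[1]; hy <- bandwidth[2]
  n <- nrow(points)
  out <- matrix(0, length(x_centers), length(y_centers))
  for (ix in seq_along(x_centers)) {
    for (iy in seq_along(y_centers)) {
      s <- 0
      for (p in seq_len(n)) {
        s <- s + exp(-((x_centers[ix] - points[p, 1])^2 / (2 * hx^2) +
                       (y_centers[iy] - points[p, 2])^2 / (2 * hy^2)))
      }
      out[ix, iy] <- s / (n * 2 * pi * hx * hy)
    }
  }
  out
}

# small ready-made community (cached per session to keep tests fast)
small_community <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- community_spec(n_genomes = 3L, genome_length = 60000L,
                             fragments_per_genome = 60L, seed = 101L)
      cache <<- c(generate_community(spec), list(spec = spec))
    }
    cache
  }
})
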