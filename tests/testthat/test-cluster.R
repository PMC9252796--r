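test_that("dbscan matches brute-force components on separated blobs", {
  blobs <- make_blobs(100, centers = rbind(c(0, 0), c(10, 10)), spread = 0.5,
                      seed = 21)
  emb <- fake_embedding(blobs$coords)
  cl <- cluster_embedding(emb, "dbscan",
                          params = list(eps = 1, min_samples = 5))
  expect_equal(max(cl$labels), 2L)
  expect_equal(sum(cl$labels == 0L), 0L)
  ref <- brute_components(blobs$coords, eps = 1, min_samples = 5)
  # same partition up to label permutation
  expect_equal(length(unique(paste(cl$labels, ref))), 2L)
})

test_that("kmeans recovers blob membership up to permutation", {
  blobs <- make_blobs(100, centers = rbind(c(0, 0), c(10, 10)), spread = 0.5,
                      seed = 22)
  emb <- fake_embedding(blobs$coords)
  cl <- cluster_embedding(emb, "kmeans", params = list(k = 2), seed = 5)
  expect_equal(length(unique(paste(cl$labels, blobs$groups))), 2L)
})

test_that("hdbscan and spectral find the blob structure", {
  blobs <- make_blobs(80, centers = rbind(c(0, 0), c(10, 10), c(-10, 8)),
                      spread = 0.5, seed = 23)
  emb <- fake_embedding(blobs$coords)
  h <- cluster_embedding(emb, "hdbscan", params = list(min_cluster_size = 10))
  expect_equal(max(h$labels), 3L)
  agree <- table(h$labels[h$labels > 0], blobs$groups[h$labels > 0])
  expect_equal(sum(apply(agree, 1, max)), sum(agree))  # pure clusters
  s <- cluster_embedding(emb, "spectral", params = list(k = 3), seed = 5)
  expect_equal(length(unique(paste(s$labels, blobs$groups))), 3L)
})

test_that("identical repeated points form a single dbscan cluster", {
  coords <- matrix(c(rep(1, 50), rep(2, 50)), ncol = 2)
  emb <- fake_embedding(coords)
  cl <- cluster_embedding(emb, "dbscan",
                          params = list(eps = 0.1, min_samples = 5))
  expect_equal(unique(cl$labels), 1L)
})

test_that("labels are renumbered by decreasing size with stable ties", {
  blobs <- make_blobs(50, centers = rbind(c(0, 0), c(10, 10)), spread = 0.3,
                      seed = 24)
  # make group 2 bigger by dropping some of group 1
  keep <- c(1:30, 51:100)
  emb <- fake_embedding(blobs$coords[keep, , drop = FALSE])
  cl <- cluster_embedding(emb, "dbscan",
                          params = list(eps = 1, min_samples = 5))
  sizes <- as.integer(table(cl$labels[cl$labels > 0]))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(which.max(tabulate(cl$labels[cl$labels > 0])), 1L)
})

test_that("clustering is invariant to input row order", {
  blobs <- make_blobs(60, centers = rbind(c(0, 0), c(8, 8)), spread = 0.4,
                      seed = 25)
  ids <- sprintf("p%03d", seq_len(nrow(blobs$coords)))
  set.seed(99)
  perm <- sample(length(ids))
  for (m in c("dbscan", "hdbscan", "kmeans", "spectral")) {
    params <- switch(m, dbscan = list(eps = 1, min_samples = 5),
                     hdbscan = list(min_cluster_size = 10),
                     list(k = 2))
    a <- cluster_embedding(fake_embedding(blobs$coords, ids), m, params,
                           seed = 3)
    b <- cluster_embedding(
      fake_embedding(blobs$coords[perm, , drop = FALSE], ids[perm]),
      m, params, seed = 3)
    map_a <- stats::setNames(a$labels, a$ids)
    map_b <- stats::setNames(b$labels, b$ids)
    expect_identical(map_a[sort(ids)], map_b[sort(ids)])
  }
})

test_that("parameter errors are informative", {
  blobs <- make_blobs(30, centers = rbind(c(0, 0), c(5, 5)), seed = 26)
  emb <- fake_embedding(blobs$coords)
  expect_error(cluster_embedding(emb, "kmeans"), "requires params\\$k")
  expect_error(cluster_embedding(emb, "spectral"), "requires params\\$k")
  # eps far too small: everything noise
  expect_error(cluster_embedding(emb, "dbscan",
                                 params = list(eps = 1e-6, min_samples = 5)),
               "no clusters")
})
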