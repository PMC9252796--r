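test_that("default bandwidth follows Scott's rule", {
  set.seed(61)
  # exact closed form: sd = 1 on both axes, n = 64 -> h = 64^(-1/6) = 0.5
  z <- matrix(rnorm(128), 64, 2)
  z <- scale(z)  # unit sd exactly
  h <- default_bandwidth(z)
  expect_equal(unname(h), c(0.5, 0.5), tolerance = 1e-12)

  # scale equivariance
  h3 <- default_bandwidth(z * 3)
  expect_equal(unname(h3), unname(h) * 3, tolerance = 1e-12)

  same <- matrix(1, 10, 2)
  expect_error(default_bandwidth(same), "zero variance")
})

test_that("kde_2d evaluates the closed-form Gaussian mixture", {
  # single point at a cell center, h = 1 -> density 1/(2*pi) at that center
  g <- kde_2d(matrix(0, 1, 2), bandwidth = 1, grid_size = 101,
              bounds = list(xlim = c(-5.05, 5.05), ylim = c(-5.05, 5.05)))
  expect_equal(g$values[51, 51], 1 / (2 * pi), tolerance = 1e-12)
  expect_equal(grid_mass(g), 1, tolerance = 1e-2)

  expect_error(kde_2d(matrix(0, 1, 2), bandwidth = 1, grid_size = 10), "grid_size")
  expect_error(kde_2d(matrix(0, 1, 2), bandwidth = 1, grid_size = 2000), "grid_size")
  expect_error(kde_2d(matrix(0, 1, 2), bandwidth = -1), "positive")
})

test_that("grid values match the naive double loop", {
  set.seed(62)
  pts <- matrix(rnorm(100), 50, 2)
  h <- default_bandwidth(pts)
  g <- kde_2d(pts, h, grid_size = 100)
  ref <- oracle_kde(pts, h, g$x_centers, g$y_centers)
  expect_equal(max(abs(g$values - ref)), 0, tolerance = 1e-10)
  expect_true(all(g$values >= 0))
  expect_gte(grid_mass(g), 0.99)
  expect_lte(grid_mass(g), 1.0)
})

test_that("grid maximum sits near the mode of a standard normal sample", {
  set.seed(63)
  pts <- matrix(rnorm(2000), 1000, 2)
  g <- kde_2d(pts, grid_size = 100)
  peak <- which(g$values == max(g$values), arr.ind = TRUE)[1, ]
  cell <- diff(g$x_edges[1:2])
  expect_lte(abs(g$x_centers[peak[1]]), 3 * cell + 1e-9)
  expect_lte(abs(g$y_centers[peak[2]]), 3 * cell + 1e-9)
})

diff_fixture <- function(seed = 64) {
  set.seed(seed)
  coords <- rbind(matrix(rnorm(80, 0, 0.5), 40, 2),
                  matrix(rnorm(80, 5, 0.5), 40, 2))
  ids <- sprintf("d%03d", 1:80)
  emb <- fake_embedding(coords, ids)
  labels <- fake_cluster_labels(ids, rep(c(1L, 2L), each = 40))
  list(emb = emb, labels = labels, ids = ids)
}

test_that("identical class point sets give a zero difference", {
  fx <- diff_fixture()
  # both classes hold the same points (two labeled copies not possible with
  # unique ids, so split evens/odds of an interleaved identical layout)
  coords <- fx$emb$coords[rep(1:40, each = 2), , drop = FALSE]
  ids <- sprintf("e%03d", 1:80)
  emb <- fake_embedding(coords, ids)
  labels <- fake_cluster_labels(ids, rep(1:2, 40))
  classes <- data.frame(sequence_id = ids,
                        class = rep(c("A", "B"), 40),
                        stringsAsFactors = FALSE)
  d <- density_difference(emb, classes, labels, grid_size = 50)
  expect_lt(max(abs(d$diff)), 1e-12)
  expect_equal(d$per_cluster$mean_diff, c(0, 0), tolerance = 1e-15)
})

test_that("swapping class labels negates the result exactly", {
  fx <- diff_fixture()
  classes <- data.frame(sequence_id = fx$ids,
                        class = rep(c("A", "B"), 40),
                        stringsAsFactors = FALSE)
  flipped <- classes
  flipped$class <- ifelse(classes$class == "A", "B", "A")
  d1 <- density_difference(fx$emb, classes, fx$labels, grid_size = 60)
  d2 <- density_difference(fx$emb, flipped, fx$labels, grid_size = 60)
  expect_identical(d1$diff, -d2$diff)
  expect_identical(d1$per_cluster$mean_diff, -d2$per_cluster$mean_diff)
  expect_identical(d1$per_cluster$sum_diff, -d2$per_cluster$sum_diff)
})

test_that("degenerate single-point classes match the closed form", {
  coords <- rbind(c(0, 0), c(10, 10))
  ids <- c("a1", "b1")
  emb <- fake_embedding(coords, ids)
  labels <- fake_cluster_labels(ids, c(1L, 1L))
  classes <- data.frame(sequence_id = ids, class = c("A", "B"),
                        stringsAsFactors = FALSE)
  d <- density_difference(emb, classes, labels, bandwidth = 1, grid_size = 25)
  fa <- kde_eval_points(matrix(coords[1, ], 1, 2), c(1, 1),
                        matrix(coords[1, ], 1, 2))
  expect_equal(fa, 1 / (2 * pi), tolerance = 1e-12)
  # diff evaluated at (0,0): f_A ~ 1/(2*pi), f_B ~ 0
  at_origin <- kde_eval_points(matrix(coords[1, ], 1, 2), c(1, 1),
                               matrix(c(0, 0), 1, 2)) -
    kde_eval_points(matrix(coords[2, ], 1, 2), c(1, 1), matrix(c(0, 0), 1, 2))
  expect_equal(at_origin, 1 / (2 * pi), tolerance = 1e-6)
})

test_that("per-cluster table covers every cluster and validates inputs", {
  fx <- diff_fixture()
  classes <- data.frame(sequence_id = fx$ids,
                        class = rep(c("A", "B"), 40),
                        stringsAsFactors = FALSE)
  d <- density_difference(fx$emb, classes, fx$labels, grid_size = 50)
  expect_equal(d$per_cluster$cluster, c(1L, 2L))
  expect_equal(d$per_cluster$n_A + d$per_cluster$n_B, c(40L, 40L))

  bad <- rbind(classes, data.frame(sequence_id = "ghost", class = "A"))
  expect_error(density_difference(fx$emb, bad, fx$labels), "ghost")
  one_class <- classes
  one_class$class <- "A"
  expect_error(density_difference(fx$emb, one_class, fx$labels), "two classes")
})
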