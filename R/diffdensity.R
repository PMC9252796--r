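# Two-class differential kernel density on the embedding: per-class 2D
# Gaussian KDE on a shared grid, their difference surface, and per-cluster
# signed density scores.

GRID_SIZE_RANGE <- c(25L, 1000L)

#' Default KDE bandwidth (Scott's rule, 2D)
#'
#' Per-axis bandwidth \code{h_i = sd_i * n^(-1/6)} — Scott's rule for a
#' two-dimensional sample.
#'
#' @param points n x 2 numeric matrix of embedding coordinates.
#' @return Numeric length-2 vector \code{(h_x, h_y)}.
#' @export
default_bandwidth <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 2L)
  n <- nrow(points)
  if (n < 2L) stop("need >= 2 points for a default bandwidth")
  s <- apply(points, 2L, stats::sd)
  if (any(s == 0)) {
    stop("zero variance on an axis; supply an explicit bandwidth")
  }
  s * n^(-1 / 6)
}

#' 2D Gaussian kernel density estimate on a grid
#'
#' Density at each cell center (x, y) is
#' \deqn{\frac{1}{n}\sum_i \frac{1}{2\pi h_x h_y}
#'   \exp\!\left(-\frac{(x-x_i)^2}{2h_x^2}-\frac{(y-y_i)^2}{2h_y^2}\right),}
#' the product of independent axis-wise Gaussian kernels, normalized per
#' point, so the grid integrates to ~1 when the bounds pad the data
#' sufficiently. Default bounds are the data bounding box padded by
#' \code{4 * max(h_x, h_y)}.
#'
#' @param points n x 2 numeric matrix (n >= 1).
#' @param bandwidth Length-1 (isotropic) or length-2 positive numeric;
#'   default from [default_bandwidth()].
#' @param grid_size Number of cells per axis, within \[25, 1000\]
#'   (default 250).
#' @param bounds Optional list with \code{xlim}, \code{ylim}; must contain
#'   all points.
#' @return A list of class \code{density_grid}: \code{grid_size},
#'   \code{x_edges}, \code{y_edges} (length grid_size + 1), \code{x_centers},
#'   \code{y_centers}, \code{values} (grid_size x grid_size, x by row),
#'   \code{bandwidth}, \code{n_points}.
#' @export
kde_2d <- function(points, bandwidth = NULL, grid_size = 250L, bounds = NULL) {
  stopifnot(is.matrix(points), ncol(points) == 2L, nrow(points) >= 1L)
  grid_size <- as.integer(grid_size)
  if (grid_size < GRID_SIZE_RANGE[1L] || grid_size > GRID_SIZE_RANGE[2L]) {
    stop("grid_size must be within [", GRID_SIZE_RANGE[1L], ", ",
         GRID_SIZE_RANGE[2L], "]")
  }
  if (is.null(bandwidth)) bandwidth <- default_bandwidth(points)
  bandwidth <- rep(as.numeric(bandwidth), length.out = 2L)
  if (any(bandwidth <= 0)) stop("bandwidth must be positive")
  if (is.null(bounds)) {
    pad <- 4 * max(bandwidth)
    bounds <- list(xlim = range(points[, 1L]) + c(-pad, pad),
                   ylim = range(points[, 2L]) + c(-pad, pad))
  } else {
    if (any(points[, 1L] < bounds$xlim[1L] | points[, 1L] > bounds$xlim[2L] |
            points[, 2L] < bounds$ylim[1L] | points[, 2L] > bounds$ylim[2L])) {
      stop("bounds must contain all points")
    }
  }
  x_edges <- seq(bounds$xlim[1L], bounds$xlim[2L], length.out = grid_size + 1L)
  y_edges <- seq(bounds$ylim[1L], bounds$ylim[2L], length.out = grid_size + 1L)
  x_centers <- (x_edges[-1L] + x_edges[-length(x_edges)]) / 2
  y_centers <- (y_edges[-1L] + y_edges[-length(y_edges)]) / 2
  values <- kde_eval_grid(points, bandwidth, x_centers, y_centers)
  grid <- list(grid_size = grid_size, x_edges = x_edges, y_edges = y_edges,
               x_centers = x_centers, y_centers = y_centers, values = values,
               bandwidth = bandwidth, n_points = nrow(points))
  class(grid) <- "density_grid"
  grid
}

# Separable evaluation: values[ix, iy] = sum_i gx[ix, i] * gy[iy, i] / n,
# with gx, gy the axis-wise normalized Gaussian kernels.
kde_eval_grid <- function(points, bandwidth, x_centers, y_centers) {
  n <- nrow(points)
  gx <- exp(-outer(x_centers, points[, 1L], "-")^2 / (2 * bandwidth[1L]^2))
  gy <- exp(-outer(y_centers, points[, 2L], "-")^2 / (2 * bandwidth[2L]^2))
  (gx %*% t(gy)) / (n * 2 * pi * bandwidth[1L] * bandwidth[2L])
}

#' Evaluate the KDE closed form at arbitrary points
#'
#' @param points n x 2 matrix the density was built from.
#' @param bandwidth Length-2 positive numeric.
#' @param at m x 2 matrix of evaluation points.
#' @return Numeric vector of length m.
#' @export
kde_eval_points <- function(points, bandwidth, at) {
  bandwidth <- rep(as.numeric(bandwidth), length.out = 2L)
  n <- nrow(points)
  dx <- outer(at[, 1L], points[, 1L], "-")^2 / (2 * bandwidth[1L]^2)
  dy <- outer(at[, 2L], points[, 2L], "-")^2 / (2 * bandwidth[2L]^2)
  rowSums(exp(-(dx + dy))) / (n * 2 * pi * bandwidth[1L] * bandwidth[2L])
}

#' Total probability mass on a density grid
#'
#' \code{sum(values) * cell_area}; close to 1 when the grid pads the data.
#'
#' @param grid A \code{density_grid}.
#' @return Scalar mass.
#' @export
grid_mass <- function(grid) {
  cell <- diff(grid$x_edges[1:2]) * diff(grid$y_edges[1:2])
  sum(grid$values) * cell
}

#' Read a two-class label table
#'
#' @param path TSV with header columns \code{sequence_id}, \code{class}.
#' @return data.frame \code{sequence_id}, \code{class}; exactly two
#'   distinct classes required.
#' @export
read_class_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sequence_id", "class") %in% names(df))) {
    stop("class table must have columns 'sequence_id' and 'class'")
  }
  if (length(unique(df$class)) != 2L) {
    stop("class table must define exactly two classes (found ",
         length(unique(df$class)), ")")
  }
  df
}

#' Differential density between two classes on the embedding
#'
#' Applies a Gaussian 2D kernel to the embedded sequences of each class
#' separately, on a shared grid and bandwidth, and reports the difference
#' surface (class A minus class B) plus per-cluster signed scores. Each
#' class density is normalized by its own point count, so the difference
#' reflects distributional shift rather than absolute abundance; per-class
#' member counts are reported alongside. Per-cluster scores evaluate both
#' densities exactly (closed form, no grid interpolation) at each member
#' point and aggregate the mean and sum of (f_A - f_B).
#'
#' @param embedding An \code{embedding_2d}.
#' @param classes data.frame \code{sequence_id}, \code{class} (two classes;
#'   class names sorted — first is "A").
#' @param labels A \code{cluster_labels} over the same embedding.
#' @param bandwidth Optional scalar or pair; default Scott's rule on the
#'   pooled labeled points.
#' @param grid_size Cells per axis (default 250).
#' @return A list of class \code{density_diff_result}: \code{grid_A},
#'   \code{grid_B}, \code{diff} (values_A - values_B), \code{per_cluster}
#'   (data.frame cluster, n_A, n_B, mean_diff, sum_diff), \code{class_names}.
#' @export
density_difference <- function(embedding, classes, labels, bandwidth = NULL,
                               grid_size = 250L) {
  stopifnot(inherits(embedding, "embedding_2d"),
            inherits(labels, "cluster_labels"))
  miss <- setdiff(classes$sequence_id, embedding$ids)
  if (length(miss)) {
    stop("class table id(s) not in the embedding: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  cls <- sort(unique(classes$class))
  if (length(cls) != 2L) stop("exactly two classes required")
  ia <- match(classes$sequence_id[classes$class == cls[1L]], embedding$ids)
  ib <- match(classes$sequence_id[classes$class == cls[2L]], embedding$ids)
  pa <- embedding$coords[ia, , drop = FALSE]
  pb <- embedding$coords[ib, , drop = FALSE]
  if (is.null(bandwidth) && (nrow(pa) < 2L || nrow(pb) < 2L)) {
    stop("each class needs >= 2 points (or supply an explicit bandwidth)")
  }
  pooled <- rbind(pa, pb)
  if (is.null(bandwidth)) bandwidth <- default_bandwidth(pooled)
  bandwidth <- rep(as.numeric(bandwidth), length.out = 2L)
  pad <- 4 * max(bandwidth)
  bounds <- list(xlim = range(pooled[, 1L]) + c(-pad, pad),
                 ylim = range(pooled[, 2L]) + c(-pad, pad))
  ga <- kde_2d(pa, bandwidth, grid_size, bounds)
  gb <- kde_2d(pb, bandwidth, grid_size, bounds)

  nz <- sort(unique(labels$labels[labels$labels != 0L]))
  per <- do.call(rbind, lapply(nz, function(cl) {
    mem_ids <- labels$ids[labels$labels == cl]
    at <- embedding$coords[match(mem_ids, embedding$ids), , drop = FALSE]
    fa <- kde_eval_points(pa, bandwidth, at)
    fb <- kde_eval_points(pb, bandwidth, at)
    data.frame(cluster = cl,
               n_A = sum(mem_ids %in% classes$sequence_id[classes$class == cls[1L]]),
               n_B = sum(mem_ids %in% classes$sequence_id[classes$class == cls[2L]]),
               mean_diff = mean(fa - fb),
               sum_diff = sum(fa - fb))
  }))
  res <- list(grid_A = ga, grid_B = gb, diff = ga$values - gb$values,
              per_cluster = per, class_names = cls, bandwidth = bandwidth,
              grid_size = grid_size)
  class(res) <- "density_diff_result"
  res
}

#' Write differential-density outputs
#'
#' The difference grid as a TSV matrix, grid edges/bandwidth in a JSON
#' sidecar, and the per-cluster score table as TSV.
#'
#' @param result A \code{density_diff_result}.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_diff_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid_path <- file.path(dir, "density_diff_grid.tsv")
  utils::write.table(result$diff, grid_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side_path <- file.path(dir, "density_diff_grid.json")
  jsonlite::write_json(list(
    x_edges = result$grid_A$x_edges, y_edges = result$grid_A$y_edges,
    bandwidth = result$bandwidth, grid_size = result$grid_size,
    class_A = result$class_names[1L], class_B = result$class_names[2L],
    n_A = result$grid_A$n_points, n_B = result$grid_B$n_points
  ), side_path, auto_unbox = TRUE, digits = NA)
  per_path <- file.path(dir, "density_diff_per_cluster.tsv")
  utils::write.table(result$per_cluster, per_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(grid_path, side_path, per_path))
}

#' @export
print.density_diff_result <- function(x, ...) {
  cat("<density_diff_result> classes ", x$class_names[1L], " (n=",
      x$grid_A$n_points, ") vs ", x$class_names[2L], " (n=",
      x$grid_B$n_points, "), grid ", x$grid_size, "x", x$grid_size,
      "\n", sep = "")
  print(x$per_cluster)
  invisible(x)
}
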