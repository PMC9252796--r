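# Hierarchical density-based clustering (HDBSCAN), implemented from the
# algorithm definition: mutual-reachability distances, minimum spanning tree,
# single-linkage hierarchy, condensed tree at min_cluster_size, and
# excess-of-mass cluster selection. O(n^2) distance/MST stage — adequate for
# the embedding sizes this package targets (thousands of points).

#' Hierarchical density-based clustering (HDBSCAN)
#'
#' Clusters points by density without a radius parameter. The
#' mutual-reachability distance between two points is
#' \code{max(core(a), core(b), d(a, b))}, where \code{core(p)} is the
#' distance from p to its \code{min_samples}-th nearest neighbor (p counts
#' as its own first neighbor). A single-linkage hierarchy over these
#' distances is condensed so that only splits into two sides of at least
#' \code{min_cluster_size} points create new clusters; clusters are then
#' selected by maximal stability (excess of mass), and points outside every
#' selected cluster are noise.
#'
#' @param x Numeric matrix of coordinates (n x d).
#' @param min_cluster_size Smallest cluster size considered real (>= 2).
#' @param min_samples Neighborhood size for core distances
#'   (default \code{min_cluster_size}).
#' @return Integer label vector; 0 = noise. Labels are arbitrary positive
#'   integers (renumbering happens in [cluster_embedding()]).
#' @export
hdbscan_labels <- function(x, min_cluster_size = 10L,
                           min_samples = min_cluster_size) {
  n <- nrow(x)
  min_cluster_size <- as.integer(min_cluster_size)
  min_samples <- as.integer(min_samples)
  stopifnot(min_cluster_size >= 2L, min_samples >= 1L)
  if (n < 2L * min_cluster_size || min_samples > n) return(integer(n))

  d <- as.matrix(stats::dist(x))
  core <- apply(d, 1L, function(r) sort(r, partial = min_samples)[min_samples])
  m <- pmax(d, matrix(core, n, n), matrix(core, n, n, byrow = TRUE))

  edges <- prim_mst(m)
  hier <- single_linkage(edges, n)
  ct <- condense_tree(hier, n, min_cluster_size)
  eom_labels(ct, n)
}

# Prim's MST on a dense symmetric weight matrix; returns (n-1) x 3 matrix
# of (a, b, weight) edges.
prim_mst <- function(m) {
  n <- nrow(m)
  inmst <- logical(n)
  inmst[1L] <- TRUE
  mind <- m[1L, ]
  from <- rep(1L, n)
  mind[1L] <- Inf
  edges <- matrix(0, n - 1L, 3L)
  for (e in seq_len(n - 1L)) {
    j <- which.min(mind)
    edges[e, ] <- c(from[j], j, mind[j])
    inmst[j] <- TRUE
    upd <- which(!inmst & m[j, ] < mind)
    mind[upd] <- m[j, upd]
    from[upd] <- j
    mind[j] <- Inf
  }
  edges
}

# Single-linkage dendrogram from MST edges via union-find. Nodes 1..n are
# points; node n+e is the merge created by the e-th smallest edge.
single_linkage <- function(edges, n) {
  edges <- edges[order(edges[, 3L]), , drop = FALSE]
  nnode <- 2L * n - 1L
  up <- seq_len(nnode)
  sizes <- c(rep(1L, n), integer(n - 1L))
  childL <- integer(nnode)
  childR <- integer(nnode)
  height <- numeric(nnode)
  findroot <- function(i) {
    while (up[i] != i) {
      up[i] <<- up[up[i]]
      i <- up[i]
    }
    i
  }
  for (e in seq_len(n - 1L)) {
    u <- findroot(as.integer(edges[e, 1L]))
    v <- findroot(as.integer(edges[e, 2L]))
    nid <- n + e
    childL[nid] <- u
    childR[nid] <- v
    height[nid] <- edges[e, 3L]
    sizes[nid] <- sizes[u] + sizes[v]
    up[u] <- nid
    up[v] <- nid
  }
  list(childL = childL, childR = childR, height = height, sizes = sizes,
       root = nnode)
}

# Leaves (point indices) under a dendrogram node, iteratively.
leaves_under <- function(hier, node, n) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (nd <= n) out <- c(out, nd)
    else stack <- c(stack, hier$childL[nd], hier$childR[nd])
  }
  out
}

# Condense the single-linkage hierarchy: descending from the root, a split
# creates two new clusters only when both sides hold >= min_cluster_size
# points; otherwise the smaller side's points fall out of the current
# cluster at that level. lambda = 1 / distance (capped for zero heights).
# Returns per-cluster parent/birth/stability and per-point exit cluster.
condense_tree <- function(hier, n, min_cluster_size) {
  lam <- function(h) 1 / max(h, 1e-12)
  cl_parent <- 0L          # parent cluster of cluster i (0 for root)
  cl_birth <- 0
  cl_stab <- 0
  pt_cluster <- integer(n) # condensed cluster each point fell out of
  kcl <- 1L
  stack_node <- hier$root
  stack_cl <- 1L
  while (length(stack_node)) {
    i <- length(stack_node)
    nd <- stack_node[i]; cl <- stack_cl[i]
    stack_node <- stack_node[-i]; stack_cl <- stack_cl[-i]
    if (nd <= n) { # singleton root only possible for n = 1; handled upstream
      pt_cluster[nd] <- cl
      next
    }
    l <- lam(hier$height[nd])
    u <- hier$childL[nd]; v <- hier$childR[nd]
    su <- hier$sizes[u]; sv <- hier$sizes[v]
    if (su >= min_cluster_size && sv >= min_cluster_size) {
      # true split: current cluster ends here, two children are born
      cl_stab[cl] <- cl_stab[cl] + (l - cl_birth[cl]) * (su + sv)
      for (ch in c(u, v)) {
        kcl <- kcl + 1L
        cl_parent[kcl] <- cl
        cl_birth[kcl] <- l
        cl_stab[kcl] <- 0
        stack_node <- c(stack_node, ch)
        stack_cl <- c(stack_cl, kcl)
      }
    } else {
      for (ch in c(u, v)) {
        if (hier$sizes[ch] >= min_cluster_size) {
          stack_node <- c(stack_node, ch)
          stack_cl <- c(stack_cl, cl)
        } else {
          pts <- leaves_under(hier, ch, n)
          cl_stab[cl] <- cl_stab[cl] + (l - cl_birth[cl]) * length(pts)
          pt_cluster[pts] <- cl
        }
      }
    }
  }
  list(parent = cl_parent, birth = cl_birth, stability = cl_stab,
       pt_cluster = pt_cluster, n_clusters = kcl)
}

# Excess-of-mass selection over the condensed tree: bottom-up, a cluster is
# a candidate when its own stability exceeds the best total stability of its
# descendants; the root is never selected. Each point is labeled by the
# topmost candidate on its root path, or 0 (noise) if there is none.
eom_labels <- function(ct, n) {
  k <- ct$n_clusters
  if (k < 2L) return(integer(n))
  score <- numeric(k)
  cand <- logical(k)
  for (c in k:1L) {
    ch <- which(ct$parent == c)
    if (!length(ch)) {
      score[c] <- ct$stability[c]
      cand[c] <- TRUE
    } else if (ct$stability[c] > sum(score[ch]) && c != 1L) {
      score[c] <- ct$stability[c]
      cand[c] <- TRUE
    } else {
      score[c] <- sum(score[ch])
    }
  }
  cand[1L] <- FALSE
  # path from each cluster to root, topmost candidate wins
  top_candidate <- integer(k)
  for (c in seq_len(k)) {
    path <- integer(0)
    cc <- c
    while (cc != 0L) {
      path <- c(path, cc)
      cc <- ct$parent[cc]
    }
    hits <- path[cand[path]]
    top_candidate[c] <- if (length(hits)) hits[length(hits)] else 0L
  }
  sel <- top_candidate[ct$pt_cluster]
  # compact selected cluster ids to 1..K
  used <- sort(unique(sel[sel != 0L]))
  out <- integer(n)
  out[sel != 0L] <- match(sel[sel != 0L], used)
  out
}
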