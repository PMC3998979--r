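# Profile distances ----------------------------------------------------------

# distance of each row of X to vector v. pearson: 1 - r, with the documented
# tie-break for constant profiles (0 to another constant, 1 to anything else)
.profile_dist <- function(X, v, distance) {
  if (distance == "euclidean")
    return(sqrt(rowSums(sweep(X, 2, v)^2)))
  vc <- v - mean(v)
  sv <- sqrt(sum(vc^2))
  Xc <- X - rowMeans(X)
  sx <- sqrt(rowSums(Xc^2))
  d <- rep(1, nrow(X))
  if (sv == 0) {
    d[sx == 0] <- 0
  } else {
    ok <- sx > 0
    d[ok] <- 1 - (Xc[ok, , drop = FALSE] %*% vc) / (sx[ok] * sv)
  }
  # clamp float noise so identical profiles are at distance exactly 0 and a
  # homogeneous leaf never triggers a spurious split
  d[abs(d) < 1e-12] <- 0
  pmax(d, 0)
}

# distance of a single profile xi to each row of centroid matrix C
.dist_to_centroids <- function(xi, C, distance) {
  if (distance == "euclidean")
    return(sqrt(rowSums(sweep(C, 2, xi)^2)))
  xic <- xi - mean(xi)
  sxi <- sqrt(sum(xic^2))
  Cc <- C - rowMeans(C)
  sC <- sqrt(rowSums(Cc^2))
  d <- rep(1, nrow(C))
  if (sxi == 0) {
    d[sC == 0] <- 0
  } else {
    ok <- sC > 0
    d[ok] <- 1 - (Cc[ok, , drop = FALSE] %*% xic) / (sC[ok] * sxi)
  }
  d[abs(d) < 1e-12] <- 0
  pmax(d, 0)
}

# Self-organizing tree algorithm ---------------------------------------------

#' SOTA clustering of expression profiles
#'
#' A from-scratch implementation of the self-organizing tree algorithm: a
#' divisive, growing binary tree of "cells". The tree starts as a single
#' cell holding all genes. Each growth cycle adapts the leaf centroids by
#' repeatedly presenting every gene to the tree (the closest leaf wins and
#' is moved toward the gene; when the winner's sister is also a leaf, the
#' parent and sister are moved too, with smaller learning rates), then
#' splits the leaf with the largest resource (mean member-to-centroid
#' distance) into two daughters. Growth stops when every leaf's resource is
#' at or below `resource_threshold`, or the leaf count reaches
#' `max_clusters`, or `max_cycles` is exhausted. Leaves become the clusters.
#'
#' Defaults follow the original algorithm description: learning rates 0.01
#' (winner), 0.005 (parent), 0.001 (sister); resource is the mean distance
#' of a leaf's members to its centroid. Initialization is deterministic
#' given `seed`: daughter centroids are copies of the parent plus a tiny
#' seeded jitter, and winner ties break toward the lowest node id.
#'
#' @param x numeric matrix, genes x conditions (log2 TPM profiles).
#' @param distance `"pearson"` (1 - correlation, the expression-profile
#'   convention) or `"euclidean"`.
#' @param max_cycles maximum number of growth cycles (splits).
#' @param resource_threshold stop splitting once all leaf resources are at
#'   or below this value.
#' @param max_clusters maximum number of leaves (>= 1).
#' @param learning numeric vector `c(winner, parent, sister)` learning rates.
#' @param n_epochs adaptation passes through the data per cycle.
#' @param seed RNG seed for the centroid jitter.
#' @return a `sota_fit`: list with `assignment` (named integer labels
#'   1..k), `k`, `centroids` (k x conditions), `resources`, `nodes` (the
#'   grown tree: data.frame id/parent/left/right), `method = "sota"`.
#' @export
sota_cluster <- function(x, distance = c("pearson", "euclidean"),
                         max_cycles = 100, resource_threshold = 0,
                         max_clusters = 6,
                         learning = c(0.01, 0.005, 0.001),
                         n_epochs = 20, seed = 1L) {
  distance <- match.arg(distance)
  x <- as.matrix(x)
  if (nrow(x) < 1) .stopf("need at least one gene")
  if (!all(is.finite(x))) .stopf("profiles must be finite")
  if (max_clusters < 1) .stopf("max_clusters must be >= 1")
  set.seed(seed)
  n <- nrow(x)

  centroids <- matrix(colMeans(x), 1)           # node 1 = root, initially leaf
  parent <- NA_integer_
  children <- matrix(NA_integer_, 1, 2)
  is_leaf <- TRUE

  assign_leaves <- function() {
    leaves <- which(is_leaf)
    d <- vapply(leaves, function(l) .profile_dist(x, centroids[l, ], distance),
                numeric(n))
    if (is.null(dim(d))) d <- matrix(d, nrow = n)
    # ties break toward the lowest node id: leaves are in increasing id
    # order and max.col("first") keeps the earliest minimum
    win <- leaves[max.col(-d, ties.method = "first")]
    list(winner = win, dist = d[cbind(seq_len(n), match(win, leaves))])
  }

  adapt <- function() {
    for (epoch in seq_len(n_epochs)) {
      leaves <- which(is_leaf)
      if (length(leaves) == 1) {  # single cell: batch update to the mean
        centroids[leaves, ] <<- centroids[leaves, ] +
          learning[1] * (colMeans(x) - centroids[leaves, ])
        next
      }
      for (i in seq_len(n)) {
        d <- .dist_to_centroids(x[i, ], centroids[leaves, , drop = FALSE],
                                distance)
        w <- leaves[which.min(d)]
        centroids[w, ] <<- centroids[w, ] + learning[1] * (x[i, ] - centroids[w, ])
        pa <- parent[w]
        if (!is.na(pa)) {
          sis <- setdiff(children[pa, ], w)
          if (length(sis) == 1 && is_leaf[sis]) {
            centroids[pa, ] <<- centroids[pa, ] +
              learning[2] * (x[i, ] - centroids[pa, ])
            centroids[sis, ] <<- centroids[sis, ] +
              learning[3] * (x[i, ] - centroids[sis, ])
          }
        }
      }
    }
  }

  split_node <- function(node) {
    for (side in 1:2) {
      id <- nrow(centroids) + 1L
      jitter <- stats::rnorm(ncol(x), sd = 1e-3)
      centroids <<- rbind(centroids, centroids[node, ] + jitter)
      parent <<- c(parent, node)
      children <<- rbind(children, c(NA_integer_, NA_integer_))
      children[node, side] <<- id
      is_leaf <<- c(is_leaf, TRUE)
    }
    is_leaf[node] <<- FALSE
  }

  for (cycle in seq_len(max_cycles)) {
    adapt()
    a <- assign_leaves()
    res <- vapply(which(is_leaf), function(l) {
      m <- a$winner == l
      if (any(m)) mean(a$dist[m]) else 0
    }, numeric(1))
    leaves <- which(is_leaf)
    # count clusters as occupied leaves so empty daughters from degenerate
    # splits do not use up the cluster budget
    if (max(res) <= resource_threshold ||
        length(unique(a$winner)) >= max_clusters)
      break
    split_node(leaves[which.max(res)])  # which.max -> lowest id on ties
  }

  a <- assign_leaves()
  # clusters are the occupied leaves; a degenerate split can leave an empty
  # daughter, which is kept in the tree but not given a cluster label
  occupied <- sort(unique(a$winner))
  labels <- match(a$winner, occupied)
  resources <- vapply(seq_along(occupied), function(j) {
    m <- labels == j
    mean(a$dist[m])
  }, numeric(1))

  structure(list(
    assignment = stats::setNames(labels, rownames(x)),
    k = length(occupied),
    centroids = centroids[occupied, , drop = FALSE],
    resources = resources,
    nodes = data.frame(id = seq_len(nrow(centroids)), parent = parent,
                       left = children[, 1], right = children[, 2],
                       is_leaf = is_leaf),
    method = "sota"
  ), class = "sota_fit")
}

# Hierarchical clustering -----------------------------------------------------

#' Agglomerative hierarchical clustering with a k-group cut
#'
#' Standard agglomeration (via `stats::hclust`) on correlation or euclidean
#' distances with average or complete linkage, cut into `k` groups. Cluster
#' labels are numbered by order of first appearance in the input, as
#' `stats::cutree` does, so results are deterministic given input order.
#'
#' @param x numeric matrix, genes x conditions.
#' @param distance `"pearson"` or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @param k number of clusters, between 1 and `nrow(x)`.
#' @return list with `assignment` (named integer labels 1..k), `k`,
#'   `tree` (the `hclust` object), `method = "hierarchical"`.
#' @export
hier_cluster <- function(x, distance = c("pearson", "euclidean"),
                         linkage = c("average", "complete"), k) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  x <- as.matrix(x)
  if (k < 1 || k > nrow(x)) .stopf("k must be between 1 and the gene count")
  d <- if (distance == "euclidean") stats::dist(x)
       else stats::as.dist(1 - stats::cor(t(x)))
  tree <- stats::hclust(d, method = linkage)
  list(assignment = stats::cutree(tree, k), k = k, tree = tree,
       method = "hierarchical")
}

#' Per-cluster mean profiles and sizes
#'
#' Summarizes a cluster assignment over a profile matrix: each cluster's
#' mean profile, its size, and a direction tag per condition saying whether
#' the cluster mean lies above or below the gene-wise grand mean of the
#' whole matrix.
#'
#' @param assignment named integer labels (gene -> cluster), e.g. the
#'   `assignment` of [sota_cluster()] or [hier_cluster()].
#' @param x numeric matrix, genes x conditions, covering all assigned genes.
#' @return list with `profiles` (k x conditions mean matrix), `sizes`,
#'   `direction` (k x conditions character matrix of "above"/"below").
#' @export
cluster_profile_summary <- function(assignment, x) {
  x <- as.matrix(x)
  genes <- names(assignment)
  if (!all(genes %in% rownames(x)))
    .stopf("assignment contains genes absent from the matrix")
  x <- x[genes, , drop = FALSE]
  ks <- sort(unique(assignment))
  profiles <- t(vapply(ks, function(k)
    colMeans(x[assignment == k, , drop = FALSE]), numeric(ncol(x))))
  rownames(profiles) <- ks
  grand <- mean(x)
  list(profiles = profiles,
       sizes = vapply(ks, function(k) sum(assignment == k), integer(1)),
       direction = ifelse(profiles > grand, "above", "below"))
}

#' Newick string of a clustering tree
#'
#' For `hier_cluster` fits the merge tree is converted through
#' `ape::as.phylo`; for `sota_fit` objects the grown binary tree is
#' serialized recursively with leaves named by cluster label.
#'
#' @param fit a `sota_fit` or the list returned by [hier_cluster()].
#' @return a single Newick string (terminated by `;`).
#' @export
as_newick <- function(fit) {
  if (inherits(fit, "sota_fit")) {
    nodes <- fit$nodes
    leaves <- which(nodes$is_leaf)
    lab <- stats::setNames(paste0("C", seq_along(leaves)), leaves)
    rec <- function(id) {
      if (nodes$is_leaf[id]) return(lab[[as.character(id)]])
      paste0("(", rec(nodes$left[id]), ",", rec(nodes$right[id]), ")")
    }
    return(paste0(rec(1L), ";"))
  }
  if (!is.null(fit$tree) && inherits(fit$tree, "hclust"))
    return(ape::write.tree(ape::as.phylo(fit$tree)))
  .stopf("unsupported tree object")
}

#' Write a cluster assignment as TSV (gene_id, cluster)
#' @param assignment named integer vector of labels.
#' @param path output file.
#' @export
write_assignment_tsv <- function(assignment, path) {
  write_tsv(data.frame(gene_id = names(assignment),
                       cluster = unname(assignment)), path)
}
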