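#' Hierarchical clustering of profile rows (UPGMA)
#'
#' Agglomerative clustering of the gene rows of a profile using Euclidean
#' distance on the 0/1 vectors and unweighted average linkage (UPGMA).
#' When two candidate merges are at exactly equal distance, the pair whose
#' lexicographically smallest gene label is lowest is merged first (then
#' the smaller second label), and dendrogram children are ordered by their
#' smallest leaf label, which makes the result deterministic and invariant
#' to input row order.
#'
#' @param profile a `phylo_profile`, or a numeric matrix of row vectors.
#' @return An `hclust`-compatible object (components `merge`, `height`,
#'   `order`, `labels`, `method`, `dist.method`) plus `gene_order`, the
#'   dendrogram leaf ordering as gene names. A single-gene input returns
#'   the identity ordering with an empty merge tree.
#' @export
cluster_genes <- function(profile) {
  mat <- if (inherits(profile, "phylo_profile")) profile$matrix else profile
  stopifnot(is.matrix(mat))
  n <- nrow(mat)
  labels <- rownames(mat)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 1L) {
    return(structure(list(merge = matrix(integer(), 0, 2), height = numeric(),
                          order = 1L, labels = labels, method = "average",
                          dist.method = "euclidean", gene_order = labels),
                     class = c("gene_clustering", "hclust")))
  }
  d <- as.matrix(stats::dist(mat, method = "euclidean"))
  # active clusters: id (negative = singleton row, positive = merge index),
  # size, and smallest member label (for the order-stable tie-break)
  id <- -seq_len(n)
  size <- rep(1L, n)
  minlab <- labels
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  D <- d
  diag(D) <- Inf
  alive <- rep(TRUE, n)
  for (step in seq_len(n - 1L)) {
    live <- which(alive)
    best <- NULL
    bestd <- Inf
    bestkey <- NULL
    for (ii in seq_along(live)) {
      i <- live[ii]
      for (jj in seq_along(live)) {
        if (jj <= ii) next
        j <- live[jj]
        dij <- D[i, j]
        key <- sort(c(minlab[i], minlab[j]))
        take <- if (dij < bestd - 1e-12) TRUE
                else if (dij <= bestd + 1e-12)
                  key[1] < bestkey[1] ||
                    (key[1] == bestkey[1] && key[2] < bestkey[2])
                else FALSE
        if (take) {
          bestd <- dij; best <- c(i, j); bestkey <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- bestd
    # UPGMA update: unweighted average over original members
    for (k in which(alive)) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    minlab[i] <- min(minlab[i], minlab[j])
    id[i] <- step
    alive[j] <- FALSE
  }
  ord <- .dendrogram_order(merge, n, labels)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "average",
                 dist.method = "euclidean", gene_order = labels[ord]),
            class = c("gene_clustering", "hclust"))
}

# canonical leaf order: children of each merge expanded smaller-label first
.dendrogram_order <- function(merge, n, labels) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    a <- expand(merge[node, 1L])
    b <- expand(merge[node, 2L])
    if (min(labels[a]) <= min(labels[b])) c(a, b) else c(b, a)
  }
  if (n == 1L) return(1L)
  expand(nrow(merge))
}

#' Cut a gene clustering into k groups
#'
#' @param clustering result of [cluster_genes()].
#' @param k number of clusters.
#' @return named integer vector of cluster memberships.
#' @export
cut_gene_clusters <- function(clustering, k) {
  stats::cutree(clustering, k = k)
}
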