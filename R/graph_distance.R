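# Labeled maximal-common-subgraph distance between subnetworks, pairwise
# distance matrices, hierarchical clustering and cophenetic stability.

#' Label-constrained maximal common subgraph
#'
#' The maximal common subgraph of two uniquely-labeled graphs under the
#' constraint that matched nodes share the same label. With unique labels
#' the label-preserving node matching is forced to be the identity, so the
#' maximum-node-size common subgraph is exactly the intersection of the node
#' sets together with the intersection of the edge sets. The result may be
#' disconnected and need not be an induced subgraph of either input.
#'
#' @param g1,g2 [LabeledGraph-class] objects (or anything
#'   [asLabeledGraph()] accepts)
#' @return a [LabeledGraph-class]; empty when the label sets are disjoint
#' @seealso [mcsDistance()]
#' @export
labeledMCS <- function(g1, g2) {
  g1 <- asLabeledGraph(g1); g2 <- asLabeledGraph(g2)
  nodes <- intersect(g1@nodes, g2@nodes)
  if (nrow(g1@edges) == 0 || nrow(g2@edges) == 0) {
    return(labeledGraph(nodes))
  }
  k1 <- .edgeKey(g1@edges[, 1], g1@edges[, 2])
  k2 <- .edgeKey(g2@edges[, 1], g2@edges[, 2])
  keep <- k1 %in% k2
  lg <- labeledGraph(nodes, g1@edges[keep, , drop = FALSE])
  lg
}

#' Maximal-common-subgraph distance between two labeled graphs
#'
#' \deqn{d(G_1, G_2) = 1 - |MCS(G_1, G_2)| / \max(|G_1|, |G_2|)} where
#' \eqn{|\cdot|} counts nodes (isolated nodes included). Identical graphs
#' give 0, label-disjoint graphs give 1. Symmetric and bounded in [0, 1];
#' the triangle inequality is not asserted.
#'
#' @param g1,g2 graphs coercible via [asLabeledGraph()]
#' @return number in [0, 1]; two empty graphs give 0 with a warning
#' @export
mcsDistance <- function(g1, g2) {
  g1 <- asLabeledGraph(g1); g2 <- asLabeledGraph(g2)
  mx <- max(length(g1@nodes), length(g2@nodes))
  if (mx == 0) {
    warning("both graphs are empty; distance defined as 0")
    return(0)
  }
  1 - length(intersect(g1@nodes, g2@nodes)) / mx
}

#' Pairwise MCS-distance matrix over a collection of graphs
#'
#' @param items named list of graphs coercible via [asLabeledGraph()]
#'   (at least 2, unique names)
#' @return symmetric numeric matrix with zero diagonal and entries in
#'   [0, 1], dimnames = item names
#' @seealso [hierarchicalCluster()], [copheneticCorrelation()]
#' @export
pairwiseDistances <- function(items) {
  if (length(items) < 2) stop("need at least 2 items")
  nm <- names(items)
  if (is.null(nm) || any(!nzchar(nm))) stop("items must be named")
  if (anyDuplicated(nm)) stop("duplicate item names")
  items <- lapply(items, asLabeledGraph)
  n <- length(items)
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- mcsDistance(items[[i]], items[[j]])
    }
  }
  d
}

#' Hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering on a precomputed distance matrix. The linkage
#' defaults to average (UPGMA).
#'
#' @param distances symmetric distance matrix with dimnames (or a
#'   \code{dist})
#' @param linkage one of \code{"average"}, \code{"complete"},
#'   \code{"single"}
#' @return an \code{hclust} merge tree (leaf order gives a heatmap ordering)
#' @export
hierarchicalCluster <- function(distances,
                                linkage = c("average", "complete",
                                            "single")) {
  linkage <- match.arg(linkage)
  d <- if (inherits(distances, "dist")) distances else {
    stopifnot(is.matrix(distances), nrow(distances) == ncol(distances))
    stats::as.dist(distances)
  }
  if (attr(d, "Size") < 2) stop("need at least 2 items to cluster")
  stats::hclust(d, method = linkage)
}

#' Write a dendrogram in Newick format
#'
#' @param tree an \code{hclust} object
#' @param path output file path
#' @return invisibly, the path
#' @export
writeDendrogramNewick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Cophenetic correlation between two distance matrices' clusterings
#'
#' Clusters each matrix hierarchically, extracts the cophenetic
#' (dendrogram-implied ultrametric) distances and returns the Pearson
#' correlation of the two vectorized cophenetic matrices. Used as a
#' stability measure of clustering across parameter settings.
#'
#' @param m1,m2 symmetric distance matrices over the same item names
#' @param linkage linkage method, see [hierarchicalCluster()]
#' @return number in [-1, 1]; \code{NA} with a warning when a cophenetic
#'   vector has zero variance
#' @export
copheneticCorrelation <- function(m1, m2, linkage = "average") {
  n1 <- rownames(m1); n2 <- rownames(m2)
  if (is.null(n1) || is.null(n2) || !setequal(n1, n2))
    stop("matrices must share the same item names")
  m2 <- m2[n1, n1, drop = FALSE]
  c1 <- stats::cophenetic(hierarchicalCluster(m1, linkage))
  c2 <- stats::cophenetic(hierarchicalCluster(m2, linkage))
  # align pair order
  v1 <- as.matrix(c1)[n1, n1][lower.tri(m1)]
  v2 <- as.matrix(c2)[n1, n1][lower.tri(m1)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("cophenetic distances have zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(v1, v2)
}
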