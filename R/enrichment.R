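# Mapping subnetwork edges back to pathways and hypergeometric enrichment.

#' Map subnetwork edges to the pathways they belong to
#'
#' One entry per pathway with at least one subnetwork edge; an edge carrying
#' several pathway annotations appears under each of them. Edges are labeled
#' \code{"A|B"} with endpoints in sorted order.
#'
#' @param subnetwork a [Subnetwork-class] (or annotated
#'   [PathwayNetwork-class])
#' @return named list mapping pathway name to a character vector of edge
#'   labels
#' @export
annotateSubnetworkPathways <- function(subnetwork) {
  net <- if (is(subnetwork, "Subnetwork")) subnetwork@network else subnetwork
  stopifnot(is(net, "PathwayNetwork"))
  g <- net@graph
  if (igraph::ecount(g) == 0) return(list())
  el <- igraph::as_edgelist(g)
  lab <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
  pw <- igraph::edge_attr(g, "pathways")
  n <- lengths(pw)
  if (sum(n) == 0) return(list())
  long <- data.frame(pathway = unlist(pw, use.names = FALSE),
                     edge = rep(lab, n), stringsAsFactors = FALSE)
  out <- lapply(split(long$edge, long$pathway), unique)
  out[order(names(out))]
}

# upper-tail hypergeometric probability P[X >= k],
# X ~ Hypergeometric(N total, K annotated, n drawn)
.hyperTail <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric pathway enrichment of a subnetwork
#'
#' For every pathway with at least one subnetwork edge, tests whether the
#' subnetwork over-represents that pathway's interactions: with N parent
#' edges of which K carry the pathway, and n subnetwork edges of which k
#' carry it, \eqn{p = P[X \ge k]} for \eqn{X \sim} Hypergeometric(N, K, n).
#' The universe is edge-based (interactions); \code{unit = "gene"} switches
#' to the gene-based variant (sample = subnetwork genes, universe = parent
#' genes, category = pathway members). BH adjustment is applied across the
#' pathways tested; rows are sorted by q then p.
#'
#' @param subnetwork a [Subnetwork-class]
#' @param network the parent [PathwayNetwork-class] (default: the
#'   subnetwork's parent)
#' @param unit \code{"edge"} (default) or \code{"gene"}
#' @return data.frame with columns \code{pathway}, \code{k}, \code{n},
#'   \code{K}, \code{N}, \code{p}, \code{q}; empty (with a warning) when the
#'   subnetwork has no edges (or genes)
#' @export
pathwayEnrichment <- function(subnetwork,
                              network = parentNetwork(subnetwork),
                              unit = c("edge", "gene")) {
  unit <- match.arg(unit)
  stopifnot(is(network, "PathwayNetwork"))
  empty <- data.frame(pathway = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE)
  if (unit == "edge") {
    subAnn <- annotateSubnetworkPathways(subnetwork)
    subNet <- if (is(subnetwork, "Subnetwork")) subnetwork@network else subnetwork
    n <- numEdges(subNet)
    N <- numEdges(network)
    if (n == 0) {
      warning("subnetwork has no edges; nothing to test")
      return(empty)
    }
    parAnn <- annotateSubnetworkPathways(network)
    k <- lengths(subAnn)
    K <- lengths(parAnn)[names(subAnn)]
  } else {
    subGenes <- if (is(subnetwork, "Subnetwork")) geneNames(subnetwork)
                else geneNames(subnetwork)
    n <- length(subGenes)
    N <- numNodes(network)
    if (n == 0) {
      warning("subnetwork has no genes; nothing to test")
      return(empty)
    }
    members <- pathwayMembers(network)
    k <- vapply(members, function(mm) length(intersect(mm, subGenes)), 0L)
    k <- k[k >= 1]
    K <- lengths(members)[names(k)]
  }
  if (length(k) == 0) return(empty)
  p <- .hyperTail(as.numeric(k), as.numeric(K), n, N)
  out <- data.frame(pathway = names(k), k = as.integer(k), n = as.integer(n),
                    K = as.integer(K), N = as.integer(N), p = p,
                    q = bhAdjust(p), stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}
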