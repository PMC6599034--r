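# Degree-preserving null networks (full and partial edge switching),
# empirical per-node p-values against the null ensemble, Benjamini-Hochberg
# adjustment and extraction of the significant subnetwork.

#' Fully randomize a network by degree-preserving edge switching
#'
#' Performs \code{swapsPerEdge * |E|} attempted Maslov-Sneppen double-edge
#' swaps: a swap replacing (a,b),(c,d) with (a,d),(c,b) is applied only when
#' it creates no self-loop and no duplicate edge. The degree multiset is
#' preserved exactly. Pathway annotations are dropped: null networks exist
#' only to be propagated over.
#'
#' @param network a [PathwayNetwork-class] with at least 2 edges (fewer:
#'   returns an unchanged copy with a warning)
#' @param swapsPerEdge attempted swaps per edge (default 10)
#' @param seed optional RNG seed
#' @return a randomized [PathwayNetwork-class] without annotations
#' @seealso [perturbNetwork()], [empiricalPvalues()]
#' @export
edgeSwitchRandomize <- function(network, swapsPerEdge = 10, seed = NULL) {
  stopifnot(is(network, "PathwayNetwork"))
  g <- network@graph
  m <- igraph::ecount(g)
  if (m < 2) {
    warning("network has fewer than 2 edges; no valid swap exists, ",
            "returning an unchanged copy")
    gr <- g
  } else {
    gr <- .withSeed(seed,
      igraph::rewire(g, igraph::keeping_degseq(
        loops = FALSE, niter = ceiling(swapsPerEdge * m))))
  }
  for (at in igraph::edge_attr_names(gr))
    gr <- igraph::delete_edge_attr(gr, at)
  ne <- igraph::ecount(gr)
  if (ne > 0) {
    gr <- igraph::set_edge_attr(gr, "interaction",
                                value = rep("interacts-with", ne))
    gr <- igraph::set_edge_attr(gr, "pathways",
                                value = rep(list(character(0)), ne))
  }
  new("PathwayNetwork", graph = gr)
}

#' Partially rewire a network to a target fraction of replaced edges
#'
#' Applies legal degree-preserving double-edge swaps one at a time until the
#' fraction of original edges that have been replaced reaches
#' \code{targetFraction}, then stops. Because one swap replaces at most two
#' original edges, the achieved fraction lies in
#' \code{[target, target + 2/|E|]}. Annotations survive on edges that are
#' still original; rewired edges are unannotated.
#'
#' @param network a [PathwayNetwork-class]
#' @param targetFraction number in (0, 1)
#' @param seed optional RNG seed
#' @param maxAttempts attempt cap, default \code{100 * |E|}; exceeding it is
#'   an error that reports the achieved fraction
#' @return a perturbed [PathwayNetwork-class]
#' @seealso [rewiredFraction()], [perturbationSweep()]
#' @export
perturbNetwork <- function(network, targetFraction, seed = NULL,
                           maxAttempts = NULL) {
  stopifnot(is(network, "PathwayNetwork"))
  if (length(targetFraction) != 1 || targetFraction <= 0 ||
      targetFraction >= 1)
    stop("targetFraction must be a single number in (0, 1)")
  g <- network@graph
  genes <- geneNames(network)
  m <- igraph::ecount(g)
  if (m < 2) stop("network must have at least 2 edges to perturb")
  if (is.null(maxAttempts)) maxAttempts <- 100L * m

  el <- igraph::as_edgelist(g, names = FALSE)
  origKey <- .edgeKey(el[, 1], el[, 2])
  cur <- new.env(parent = emptyenv(), hash = TRUE)
  for (k in origKey) assign(k, TRUE, envir = cur)
  origSet <- origKey
  nOrig <- m                      # current edges that are still original

  .withSeed(seed, {
    attempts <- 0L
    while (1 - nOrig / m < targetFraction) {
      if (attempts >= maxAttempts)
        stop(sprintf(
          "could not reach target rewired fraction %.4g after %d attempts; achieved %.4g",
          targetFraction, attempts, 1 - nOrig / m))
      attempts <- attempts + 1L
      ij <- sample.int(m, 2)
      a <- el[ij[1], 1]; b <- el[ij[1], 2]
      c <- el[ij[2], 1]; d <- el[ij[2], 2]
      if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      if (length(unique(c(a, b, c, d))) < 4) next
      k1 <- .edgeKey(a, d); k2 <- .edgeKey(c, b)
      if (exists(k1, envir = cur, inherits = FALSE) ||
          exists(k2, envir = cur, inherits = FALSE)) next
      o1 <- .edgeKey(a, b); o2 <- .edgeKey(c, d)
      rm(list = c(o1, o2), envir = cur)
      assign(k1, TRUE, envir = cur); assign(k2, TRUE, envir = cur)
      nOrig <- nOrig - (o1 %in% origSet) - (o2 %in% origSet) +
        (k1 %in% origSet) + (k2 %in% origSet)
      el[ij[1], ] <- c(min(a, d), max(a, d))
      el[ij[2], ] <- c(min(c, b), max(c, b))
    }
  })

  # carry annotations over for edges that are still original
  oldInt <- igraph::edge_attr(g, "interaction")
  oldPw <- igraph::edge_attr(g, "pathways")
  key <- .edgeKey(el[, 1], el[, 2])
  hit <- match(key, origKey)
  int <- ifelse(is.na(hit), "rewired", oldInt[ifelse(is.na(hit), 1, hit)])
  pw <- vector("list", m)
  for (i in seq_len(m))
    pw[[i]] <- if (is.na(hit[i])) character(0) else oldPw[[hit[i]]]
  gn <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  igraph::V(gn)$name <- genes
  gn <- igraph::add_edges(gn, t(el))
  igraph::E(gn)$interaction <- int
  gn <- igraph::set_edge_attr(gn, "pathways", value = pw)
  new("PathwayNetwork", graph = gn)
}

#' Fraction of original edges replaced in a perturbed network
#'
#' \code{|E_original \\ E_perturbed| / |E_original|}; both networks must be
#' defined over the same node set.
#'
#' @param original,perturbed [PathwayNetwork-class] objects with identical
#'   node sets
#' @return number in [0, 1]
#' @export
rewiredFraction <- function(original, perturbed) {
  stopifnot(is(original, "PathwayNetwork"), is(perturbed, "PathwayNetwork"))
  if (!setequal(geneNames(original), geneNames(perturbed)))
    stop("networks must share the same node set")
  e1 <- igraph::as_edgelist(original@graph)
  e2 <- igraph::as_edgelist(perturbed@graph)
  if (nrow(e1) == 0) stop("original network has no edges")
  k1 <- .edgeKey(e1[, 1], e1[, 2])
  k2 <- .edgeKey(e2[, 1], e2[, 2])
  sum(!(k1 %in% k2)) / length(k1)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (via \code{stats::p.adjust}) with input
#' validation: every p must lie in (0, 1], as produced by the add-one
#' empirical estimator. Output preserves input order and is capped at 1.
#'
#' @param pvals numeric vector of p-values in (0, 1]
#' @return numeric vector of q-values, same length and order
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (length(pvals) == 0) return(numeric(0))
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1))
    stop("all p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# adjacency matrices of an edge-switched ensemble (shared across all nodes
# and all t values of one run)
.makeEnsemble <- function(network, spec) {
  g <- network@graph
  m <- igraph::ecount(g)
  niter <- ceiling(spec@swapsPerEdge * m)
  lapply(seq_len(spec@nRandom), function(r) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                   niter = niter))
    .adjacency(gr)
  })
}

# empirical significance for several iteration counts sharing one ensemble
.empiricalMulti <- function(network, seeds, tValues, spec) {
  seeds <- .asSeedSet(network, seeds)
  genes <- geneNames(network)
  seedIdx <- match(seeds@mapped, genes)
  unl <- setdiff(seq_along(genes), seedIdx)
  ad <- .adjacency(network@graph)
  tValues <- as.integer(tValues)
  fobs <- .propagateCore(ad$A, ad$deg, seedIdx, tValues)
  .withSeed(if (length(spec@seed)) spec@seed else NULL, {
    ensemble <- .makeEnsemble(network, spec)
    counts <- matrix(0L, length(unl), length(tValues))
    for (ar in ensemble) {
      fr <- .propagateCore(ar$A, ar$deg, seedIdx, tValues)
      counts <- counts + (fr[unl, , drop = FALSE] >=
                            fobs[unl, , drop = FALSE] - 1e-12)
    }
  })
  lapply(seq_along(tValues), function(h) {
    p <- (1 + counts[, h]) / (1 + spec@nRandom)
    new("SignificanceTable",
        table = data.frame(gene = genes[unl], f = fobs[unl, h], p = p,
                           q = bhAdjust(p), stringsAsFactors = FALSE),
        nRandom = spec@nRandom, iterations = tValues[h])
  })
}

#' Empirical per-node p-values against a degree-preserving null ensemble
#'
#' Runs label propagation with identical settings on \code{nRandom}
#' edge-switched random networks (one shared ensemble for all nodes) and,
#' for each unlabeled node, computes the add-one empirical p-value
#' \eqn{p(v) = (1 + \#\{r: f_r(v) \ge f_{obs}(v)\}) / (1 + n_{random})},
#' ties counting as extreme. Benjamini-Hochberg q-values are computed across
#' all unlabeled nodes. Fully deterministic when \code{spec} carries a seed.
#'
#' @param network a [PathwayNetwork-class]
#' @param seeds a [SeedSet-class] or character vector
#' @param t propagation iterations (default 10)
#' @param spec a [RandomizationSpec-class] (default: 1000 networks, 10
#'   swaps/edge)
#' @return a [SignificanceTable-class]
#' @seealso [extractSubnetwork()], [randomizationSpec()]
#' @export
empiricalPvalues <- function(network, seeds, t = 10L,
                             spec = randomizationSpec()) {
  stopifnot(is(spec, "RandomizationSpec"))
  .empiricalMulti(network, seeds, t, spec)[[1]]
}

#' Extract the significant subnetwork
#'
#' Nodes are the mapped seeds plus every unlabeled node with adjusted
#' q-value (or raw p with \code{useAdjusted = FALSE}) strictly below
#' \code{alpha}; edges are induced from the parent network and keep their
#' pathway annotations. No connected-component filtering.
#'
#' @param network the parent [PathwayNetwork-class]
#' @param seeds the [SeedSet-class] (or character vector) used for the run
#' @param table the [SignificanceTable-class] from [empiricalPvalues()]
#' @param alpha significance threshold in (0, 1), default 0.05
#' @param useAdjusted threshold BH q (default TRUE) or raw p
#' @return a [Subnetwork-class]
#' @export
extractSubnetwork <- function(network, seeds, table, alpha = 0.05,
                              useAdjusted = TRUE) {
  stopifnot(is(network, "PathwayNetwork"), is(table, "SignificanceTable"))
  if (length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  seeds <- .asSeedSet(network, seeds)
  tb <- table@table
  crit <- if (useAdjusted) tb$q else tb$p
  keep <- union(seeds@mapped, tb$gene[crit < alpha])
  sg <- igraph::induced_subgraph(network@graph,
                                 match(keep, geneNames(network)))
  new("Subnetwork", network = new("PathwayNetwork", graph = sg),
      parent = network, seeds = seeds, significance = table,
      alpha = alpha, useAdjusted = useAdjusted)
}
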