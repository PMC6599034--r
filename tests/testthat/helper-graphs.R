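# Shared fixtures: small networks built in code.

# PathwayNetwork from an edge data.frame (a, b, pathways ';'-collapsed)
makeNet <- function(edges, extraNodes = character(0)) {
  pw <- lapply(edges$pathways %||% rep("", nrow(edges)), function(s)
    if (nzchar(s)) strsplit(s, ";", fixed = TRUE)[[1]] else character(0))
  pathprop:::.buildNetwork(edges$a, edges$b,
                           interaction = rep("i", nrow(edges)),
                           pathways = pw, extraNodes = extraNodes,
                           warnSelfLoops = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# path A-B-C
pathABC <- function() makeNet(data.frame(a = c("A", "B"), b = c("B", "C")))

# random connected unannotated network
randomConnectedNet <- function(n, p) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("g%03d", seq_len(n))
  igraph::E(g)$interaction <- "i"
  g <- igraph::set_edge_attr(g, "pathways",
                             value = rep(list(character(0)),
                                         igraph::ecount(g)))
  new("PathwayNetwork", graph = g)
}

# random (possibly disconnected) unannotated network
randomNet <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("g%03d", seq_len(n))
  igraph::E(g)$interaction <- "i"
  if (igraph::ecount(g) > 0)
    g <- igraph::set_edge_attr(g, "pathways",
                               value = rep(list(character(0)),
                                           igraph::ecount(g)))
  new("PathwayNetwork", graph = g)
}

seedsOf <- function(net, genes) {
  new("SeedSet", requested = genes, mapped = genes, dropped = character(0))
}

# SignificanceTable built directly (for recovery-rate arithmetic tests)
sigTable <- function(genes, p, nRandom = 9999L, t = 10L) {
  new("SignificanceTable",
      table = data.frame(gene = genes, f = rep(0.5, length(genes)), p = p,
                         q = bhAdjust(p), stringsAsFactors = FALSE),
      nRandom = nRandom, iterations = t)
}

# the scaled-down planted benchmark network shared by slower tests
plantedFixture <- function(seed = 42) {
  generatePlantedPathwayNetwork(plantedNetworkSpec(seed = seed))
}
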