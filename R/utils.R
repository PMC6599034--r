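# Internal helpers shared across modules.

# canonical undirected edge key; "\1" cannot occur in gene symbols read from
# tab-delimited input
.edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\1")

# run code under a fixed seed when one is given, without touching the
# caller's RNG stream otherwise
.withSeed <- function(seed, code) {
  if (is.null(seed) || length(seed) == 0) code
  else withr::with_seed(as.integer(seed), code)
}

# coerce seeds argument (SeedSet or character) for a given network
.asSeedSet <- function(network, seeds) {
  if (is(seeds, "SeedSet")) {
    if (!all(seeds@mapped %in% geneNames(network)))
      stop("seed set was mapped against a different network")
    return(seeds)
  }
  mapSeeds(network, seeds)
}

# build a PathwayNetwork from parallel edge vectors plus optional isolated
# nodes; merges duplicate rows (pathway-set union), drops self-loops
.buildNetwork <- function(a, b, interaction = NULL, pathways = NULL,
                          extraNodes = character(0), warnSelfLoops = TRUE) {
  stopifnot(length(a) == length(b))
  if (is.null(interaction)) interaction <- rep("interacts-with", length(a))
  if (is.null(pathways)) pathways <- rep(list(character(0)), length(a))
  loops <- a == b
  if (any(loops)) {
    if (warnSelfLoops)
      warning(sprintf("dropped %d self-loop row(s)", sum(loops)))
    a <- a[!loops]; b <- b[!loops]
    interaction <- interaction[!loops]; pathways <- pathways[!loops]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- .edgeKey(lo, hi)
  first <- !duplicated(key)
  idx <- split(seq_along(key), factor(key, levels = key[first]))
  mpw <- lapply(idx, function(i)
    sort(unique(unlist(pathways[i], use.names = FALSE))))
  mint <- vapply(idx, function(i) interaction[i[1]], "")
  lo <- lo[first]; hi <- hi[first]
  nodes <- sort(unique(c(lo, hi, extraNodes)))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (length(lo) > 0) {
    g <- igraph::add_edges(g, rbind(match(lo, nodes), match(hi, nodes)))
    igraph::E(g)$interaction <- unname(mint)
    g <- igraph::set_edge_attr(g, "pathways", value = unname(mpw))
  }
  new("PathwayNetwork", graph = g)
}

# sparse symmetric adjacency + degrees, vertex order = geneNames(network)
.adjacency <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  list(A = A, deg = Matrix::rowSums(A))
}
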