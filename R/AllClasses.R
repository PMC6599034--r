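#' @import methods
#' @importFrom stats phyper p.adjust hclust as.dist cophenetic cor aggregate
#'   binom.test approx sd setNames runif rbinom
#' @importFrom utils read.delim write.table head combn
NULL

# ---------------------------------------------------------------------------
# PathwayNetwork
# ---------------------------------------------------------------------------

#' PathwayNetwork: an undirected gene interaction graph with per-edge pathway
#' annotations
#'
#' A simple (no self-loops, no multi-edges) undirected graph whose vertices
#' are uniquely named gene symbols. Each edge carries an interaction-type
#' string and a (possibly empty) set of pathway names, mirroring the
#' Pathway Commons extended-SIF representation of curated pathway databases
#' such as PID. All computation treats the graph as unweighted and
#' undirected (a symmetric 0/1 weight matrix); interaction types are kept
#' only for output.
#'
#' @slot graph an \pkg{igraph} object holding the structure; vertex attribute
#'   \code{name}, edge attributes \code{interaction} (character) and
#'   \code{pathways} (list of character vectors).
#'
#' @seealso [readExtendedSIF()], [generatePlantedPathwayNetwork()],
#'   [pathwayMembers()]
#' @export
setClass("PathwayNetwork", slots = c(graph = "ANY"))

setValidity("PathwayNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("'graph' must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (!igraph::is_simple(g)) return("graph must be simple (no loops/multi-edges)")
  nm <- igraph::V(g)$name
  if (is.null(nm) || anyNA(nm) || any(nm == "")) return("all nodes must be named")
  if (anyDuplicated(nm)) return("node names must be unique")
  if (igraph::ecount(g) > 0) {
    pw <- igraph::edge_attr(g, "pathways")
    if (is.null(pw) || !is.list(pw)) return("edge attribute 'pathways' must be a list")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# SeedSet
# ---------------------------------------------------------------------------

#' SeedSet: a seed gene list mapped onto a network
#'
#' Records the genes the user asked for (\code{requested}), the subset that
#' is present in the network (\code{mapped}, the labeled nodes of the
#' propagation), and the symbols that could not be mapped (\code{dropped}).
#' Matching is exact and case-sensitive.
#'
#' @slot requested character, the requested symbols in input order
#' @slot mapped character, requested symbols present in the network
#' @slot dropped character, requested symbols absent from the network
#' @seealso [mapSeeds()], [readSeedList()]
#' @export
setClass("SeedSet",
  slots = c(requested = "character", mapped = "character", dropped = "character"))

setValidity("SeedSet", function(object) {
  if (!setequal(union(object@mapped, object@dropped), object@requested))
    return("mapped and dropped must partition requested")
  if (length(intersect(object@mapped, object@dropped)) > 0)
    return("mapped and dropped must be disjoint")
  TRUE
})

# ---------------------------------------------------------------------------
# PropagationResult
# ---------------------------------------------------------------------------

#' PropagationResult: per-node diffusion scores after label propagation
#'
#' Holds the harmonic-function value f for every node of the network after a
#' fixed number of synchronous iterations with seed values clamped to 1.
#' Scores are dimensionless, in [0, 1]; nodes in components containing no
#' seed stay at 0.
#'
#' @slot scores named numeric, f value per node
#' @slot iterations integer, the number of iterations run
#' @slot seeds the [SeedSet-class] used
#' @seealso [propagate()], [harmonicFixedPoint()]
#' @export
setClass("PropagationResult",
  slots = c(scores = "numeric", iterations = "integer", seeds = "SeedSet"))

setValidity("PropagationResult", function(object) {
  if (is.null(names(object@scores))) return("scores must be named")
  if (any(object@scores < -1e-12 | object@scores > 1 + 1e-12))
    return("scores must lie in [0, 1]")
  TRUE
})

# ---------------------------------------------------------------------------
# RandomizationSpec
# ---------------------------------------------------------------------------

#' RandomizationSpec: settings for the degree-preserving null ensemble
#'
#' @slot nRandom integer, number of random networks in the ensemble
#'   (default 1000)
#' @slot swapsPerEdge numeric Q, attempted double-edge swaps per edge used to
#'   fully randomize each null network (default 10)
#' @slot seed numeric of length 0 or 1; when set, the ensemble and hence all
#'   downstream empirical p-values are fully reproducible
#' @seealso [randomizationSpec()], [empiricalPvalues()]
#' @export
setClass("RandomizationSpec",
  slots = c(nRandom = "integer", swapsPerEdge = "numeric", seed = "numeric"))

setValidity("RandomizationSpec", function(object) {
  if (length(object@nRandom) != 1 || object@nRandom < 1L)
    return("nRandom must be a single integer >= 1")
  if (length(object@swapsPerEdge) != 1 || object@swapsPerEdge <= 0)
    return("swapsPerEdge must be a single positive number")
  if (length(object@seed) > 1) return("seed must have length 0 or 1")
  TRUE
})

#' Construct a RandomizationSpec
#'
#' @param nRandom number of degree-preserving random networks (default 1000,
#'   the ensemble size used for the empirical null)
#' @param swapsPerEdge attempted edge switches per edge for full
#'   randomization (default 10)
#' @param seed optional RNG seed making the ensemble reproducible
#' @return a [RandomizationSpec-class]
#' @examples
#' randomizationSpec(nRandom = 200, seed = 1)
#' @export
randomizationSpec <- function(nRandom = 1000L, swapsPerEdge = 10, seed = NULL) {
  new("RandomizationSpec", nRandom = as.integer(nRandom),
      swapsPerEdge = as.numeric(swapsPerEdge),
      seed = if (is.null(seed)) numeric(0) else as.numeric(seed))
}

# ---------------------------------------------------------------------------
# SignificanceTable
# ---------------------------------------------------------------------------

#' SignificanceTable: empirical significance of propagation scores
#'
#' One row per unlabeled node: the observed diffusion score \code{f}, the
#' empirical p-value against the edge-switched ensemble (add-one estimator,
#' ties counted as extreme) and the Benjamini-Hochberg adjusted q-value.
#'
#' @slot table data.frame with columns \code{gene}, \code{f}, \code{p},
#'   \code{q}
#' @slot nRandom integer, ensemble size used
#' @slot iterations integer, propagation iteration count t
#' @seealso [empiricalPvalues()], [extractSubnetwork()]
#' @export
setClass("SignificanceTable",
  slots = c(table = "data.frame", nRandom = "integer", iterations = "integer"))

setValidity("SignificanceTable", function(object) {
  tb <- object@table
  need <- c("gene", "f", "p", "q")
  if (!all(need %in% names(tb)))
    return("table must have columns gene, f, p, q")
  if (nrow(tb) > 0) {
    if (any(tb$p < 1 / (object@nRandom + 1) - 1e-12 | tb$p > 1))
      return("p-values out of range for the add-one estimator")
    if (any(tb$q < tb$p - 1e-12)) return("q must be >= p")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# Subnetwork
# ---------------------------------------------------------------------------

#' Subnetwork: seeds plus significant nodes with induced edges
#'
#' The unit of output of the propagation workflow: the mapped seed genes
#' together with every unlabeled node passing the significance threshold,
#' plus all parent-network edges between them (with their pathway
#' annotations). No connected-component filtering is applied.
#'
#' @slot network induced [PathwayNetwork-class]
#' @slot parent the full parent [PathwayNetwork-class]
#' @slot seeds the [SeedSet-class]
#' @slot significance the [SignificanceTable-class] used for extraction
#' @slot alpha significance threshold applied
#' @slot useAdjusted logical; threshold applied to BH q (TRUE) or raw p
#' @seealso [extractSubnetwork()], [pathwayEnrichment()], [mcsDistance()]
#' @export
setClass("Subnetwork",
  slots = c(network = "PathwayNetwork", parent = "PathwayNetwork",
            seeds = "SeedSet", significance = "SignificanceTable",
            alpha = "numeric", useAdjusted = "logical"))

setValidity("Subnetwork", function(object) {
  sub <- igraph::V(object@network@graph)$name
  par <- igraph::V(object@parent@graph)$name
  if (!all(sub %in% par)) return("subnetwork nodes must be parent nodes")
  if (!all(object@seeds@mapped %in% sub))
    return("all mapped seeds must be in the subnetwork")
  TRUE
})

# ---------------------------------------------------------------------------
# LabeledGraph
# ---------------------------------------------------------------------------

#' LabeledGraph: a uniquely-labeled graph for MCS comparison
#'
#' Minimal representation used by the maximal-common-subgraph distance:
#' a set of unique node labels and a set of unordered label pairs. Because
#' labels are unique, the label-constrained maximal common subgraph of two
#' such graphs is their node- and edge-set intersection.
#'
#' @slot nodes character vector of unique labels
#' @slot edges character matrix with 2 columns (possibly 0 rows)
#' @seealso [labeledMCS()], [mcsDistance()], [asLabeledGraph()]
#' @export
setClass("LabeledGraph", slots = c(nodes = "character", edges = "matrix"))

setValidity("LabeledGraph", function(object) {
  if (anyDuplicated(object@nodes)) return("node labels must be unique")
  e <- object@edges
  if (ncol(e) != 2) return("edges must have 2 columns")
  if (nrow(e) > 0) {
    if (!is.character(e)) return("edges must be a character matrix")
    if (!all(e %in% object@nodes)) return("edge endpoints must be nodes")
    if (any(e[, 1] == e[, 2])) return("self-loops are not allowed")
    if (anyDuplicated(.edgeKey(e[, 1], e[, 2]))) return("duplicate edges")
  }
  TRUE
})

#' Construct a LabeledGraph
#'
#' @param nodes character vector of unique labels
#' @param edges optional two-column character matrix (or data.frame) of
#'   unordered label pairs; endpoints not listed in \code{nodes} are added
#' @return a [LabeledGraph-class]
#' @examples
#' labeledGraph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' @export
labeledGraph <- function(nodes = character(0), edges = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    em <- matrix(character(0), ncol = 2)
  } else {
    em <- as.matrix(edges)
    storage.mode(em) <- "character"
    # canonical orientation + dedupe
    a <- pmin(em[, 1], em[, 2]); b <- pmax(em[, 1], em[, 2])
    keep <- !duplicated(.edgeKey(a, b))
    em <- cbind(a[keep], b[keep])
    nodes <- union(nodes, c(a, b))
  }
  dimnames(em) <- NULL
  new("LabeledGraph", nodes = as.character(nodes), edges = em)
}

# ---------------------------------------------------------------------------
# PlantedNetworkSpec
# ---------------------------------------------------------------------------

#' PlantedNetworkSpec: parameters of the synthetic planted-pathway generator
#'
#' Describes a network made of annotated pathway communities (each a
#' connected random graph whose edges carry the pathway's name), unannotated
#' linker edges modelling cross-talk, and a sparse unannotated background.
#'
#' @slot nPathways integer number of planted pathways
#' @slot pathwaySize integer genes per pathway (>= 3)
#' @slot intraEdgeProb probability of each non-tree within-pathway edge
#' @slot nLinkerEdges integer count of unannotated cross-pathway edges
#' @slot nBackgroundNodes integer count of background genes
#' @slot backgroundEdgeProb probability of each background attachment edge
#' @slot seed numeric of length 0 or 1, RNG seed
#' @seealso [plantedNetworkSpec()], [generatePlantedPathwayNetwork()]
#' @export
setClass("PlantedNetworkSpec",
  slots = c(nPathways = "integer", pathwaySize = "integer",
            intraEdgeProb = "numeric", nLinkerEdges = "integer",
            nBackgroundNodes = "integer", backgroundEdgeProb = "numeric",
            seed = "numeric"))

setValidity("PlantedNetworkSpec", function(object) {
  if (object@nPathways < 1L) return("nPathways must be >= 1")
  if (object@pathwaySize < 3L) return("pathwaySize must be >= 3")
  for (p in c(object@intraEdgeProb, object@backgroundEdgeProb))
    if (p <= 0 || p > 1) return("probabilities must be in (0, 1]")
  if (object@nLinkerEdges < 0L || object@nBackgroundNodes < 0L)
    return("counts must be non-negative")
  if (length(object@seed) > 1) return("seed must have length 0 or 1")
  TRUE
})

# ---------------------------------------------------------------------------
# DrugScreenTable
# ---------------------------------------------------------------------------

#' DrugScreenTable: IC50s, maximum screening concentrations and mutations
#'
#' Container for the drug-response screen: an IC50 matrix (cell line x drug,
#' concentration units consistent within a drug), the per-drug maximum
#' screening concentration used as the responder decision boundary, and a
#' binary mutation-call matrix (cell line x gene).
#'
#' @slot ic50 numeric matrix, rows = cell lines, columns = drugs (NAs allowed)
#' @slot maxConc named numeric, one maximum screening concentration per drug
#' @slot mutations binary numeric matrix, rows = cell lines, columns = genes
#' @seealso [generateDrugScreen()], [findSeparatingDrugs()]
#' @export
setClass("DrugScreenTable",
  slots = c(ic50 = "matrix", maxConc = "numeric", mutations = "matrix"))

setValidity("DrugScreenTable", function(object) {
  if (any(object@ic50 <= 0, na.rm = TRUE)) return("ic50 values must be > 0")
  if (any(object@maxConc <= 0)) return("maxConc values must be > 0")
  if (!all(colnames(object@ic50) %in% names(object@maxConc)))
    return("every drug needs a maximum screening concentration")
  if (!all(object@mutations %in% c(0, 1))) return("mutations must be 0/1")
  if (!identical(rownames(object@ic50), rownames(object@mutations)))
    return("ic50 and mutations must share cell-line rows")
  TRUE
})
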