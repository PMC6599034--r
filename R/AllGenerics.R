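# Accessor generics and show methods.

#' @rdname accessors
#' @param x an object
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("pathwayMembers", function(x) standardGeneric("pathwayMembers"))

#' @rdname accessors
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))

#' @rdname accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname accessors
#' @export
setGeneric("seedGenes", function(x) standardGeneric("seedGenes"))

#' @rdname accessors
#' @export
setGeneric("droppedGenes", function(x) standardGeneric("droppedGenes"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("significanceTable", function(x) standardGeneric("significanceTable"))

#' @rdname accessors
#' @export
setGeneric("parentNetwork", function(x) standardGeneric("parentNetwork"))

#' Coerce an object to a LabeledGraph
#'
#' @param x a [LabeledGraph-class], [PathwayNetwork-class] or
#'   [Subnetwork-class]
#' @return a [LabeledGraph-class]
#' @export
setGeneric("asLabeledGraph", function(x) standardGeneric("asLabeledGraph"))

# --- PathwayNetwork ---------------------------------------------------------

#' Accessors
#'
#' Small accessor family: \code{geneNames}/\code{numNodes}/\code{numEdges}
#' for graph-like objects, \code{edgeTable} for a data.frame view of edges
#' (pathways collapsed with \code{";"}), \code{pathwayMembers} for the map
#' pathway -> genes incident to at least one edge annotated with it,
#' \code{seedGenes}/\code{droppedGenes} for seed sets, \code{scores} for
#' propagation results, \code{significanceTable} for significance results
#' and \code{parentNetwork} for a subnetwork's parent.
#'
#' @param x an object of the matching class
#' @name accessors
#' @return the extracted component
NULL

#' @rdname accessors
#' @export
setMethod("geneNames", "PathwayNetwork", function(x) igraph::V(x@graph)$name)

#' @rdname accessors
#' @export
setMethod("numNodes", "PathwayNetwork", function(x) igraph::vcount(x@graph))

#' @rdname accessors
#' @export
setMethod("numEdges", "PathwayNetwork", function(x) igraph::ecount(x@graph))

#' @rdname accessors
#' @export
setMethod("edgeTable", "PathwayNetwork", function(x) {
  g <- x@graph
  if (igraph::ecount(g) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      interaction = character(0), pathways = character(0),
                      stringsAsFactors = FALSE))
  }
  el <- igraph::as_edgelist(g)
  pw <- igraph::edge_attr(g, "pathways")
  data.frame(from = el[, 1], to = el[, 2],
             interaction = igraph::edge_attr(g, "interaction"),
             pathways = vapply(pw, paste, "", collapse = ";"),
             stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("pathwayMembers", "PathwayNetwork", function(x) {
  g <- x@graph
  if (igraph::ecount(g) == 0) return(list())
  el <- igraph::as_edgelist(g)
  pw <- igraph::edge_attr(g, "pathways")
  n <- lengths(pw)
  if (sum(n) == 0) return(list())
  long <- data.frame(pathway = unlist(pw, use.names = FALSE),
                     from = rep(el[, 1], n), to = rep(el[, 2], n),
                     stringsAsFactors = FALSE)
  out <- lapply(split(seq_len(nrow(long)), long$pathway),
                function(i) sort(unique(c(long$from[i], long$to[i]))))
  out[order(names(out))]
})

#' @rdname accessors
#' @export
setMethod("pathwayNames", "PathwayNetwork", function(x) {
  g <- x@graph
  if (igraph::ecount(g) == 0) return(character(0))
  sort(unique(unlist(igraph::edge_attr(g, "pathways"), use.names = FALSE)))
})

#' @rdname accessors
#' @export
setMethod("asIgraph", "PathwayNetwork", function(x) x@graph)

setMethod("show", "PathwayNetwork", function(object) {
  cat(sprintf("PathwayNetwork: %d genes, %d interactions, %d pathways\n",
              numNodes(object), numEdges(object),
              length(pathwayNames(object))))
})

# --- SeedSet ----------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("seedGenes", "SeedSet", function(x) x@mapped)

#' @rdname accessors
#' @export
setMethod("droppedGenes", "SeedSet", function(x) x@dropped)

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("SeedSet: %d requested, %d mapped, %d dropped\n",
              length(object@requested), length(object@mapped),
              length(object@dropped)))
})

# --- PropagationResult ------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("scores", "PropagationResult", function(x) x@scores)

setMethod("show", "PropagationResult", function(object) {
  cat(sprintf("PropagationResult: %d nodes, t = %d, %d seeds\n",
              length(object@scores), object@iterations,
              length(object@seeds@mapped)))
})

# --- SignificanceTable ------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("significanceTable", "SignificanceTable", function(x) x@table)

setMethod("show", "SignificanceTable", function(object) {
  cat(sprintf(
    "SignificanceTable: %d unlabeled nodes, ensemble of %d, t = %d\n",
    nrow(object@table), object@nRandom, object@iterations))
  cat(sprintf("  nodes with q < 0.05: %d\n", sum(object@table$q < 0.05)))
})

# --- Subnetwork -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("geneNames", "Subnetwork", function(x) geneNames(x@network))

#' @rdname accessors
#' @export
setMethod("numNodes", "Subnetwork", function(x) numNodes(x@network))

#' @rdname accessors
#' @export
setMethod("numEdges", "Subnetwork", function(x) numEdges(x@network))

#' @rdname accessors
#' @export
setMethod("edgeTable", "Subnetwork", function(x) edgeTable(x@network))

#' @rdname accessors
#' @export
setMethod("seedGenes", "Subnetwork", function(x) x@seeds@mapped)

#' @rdname accessors
#' @export
setMethod("parentNetwork", "Subnetwork", function(x) x@parent)

#' @rdname accessors
#' @export
setMethod("significanceTable", "Subnetwork", function(x) x@significance@table)

setMethod("show", "Subnetwork", function(object) {
  cat(sprintf(
    "Subnetwork: %d genes (%d seeds + %d significant), %d edges, %s < %g\n",
    numNodes(object), length(object@seeds@mapped),
    numNodes(object) - length(object@seeds@mapped), numEdges(object),
    if (object@useAdjusted) "q" else "p", object@alpha))
})

# --- LabeledGraph -----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("geneNames", "LabeledGraph", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("numNodes", "LabeledGraph", function(x) length(x@nodes))

#' @rdname accessors
#' @export
setMethod("numEdges", "LabeledGraph", function(x) nrow(x@edges))

setMethod("show", "LabeledGraph", function(object) {
  cat(sprintf("LabeledGraph: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
})

#' @rdname asLabeledGraph
#' @export
setMethod("asLabeledGraph", "LabeledGraph", function(x) x)

#' @rdname asLabeledGraph
#' @export
setMethod("asLabeledGraph", "PathwayNetwork", function(x) {
  el <- if (numEdges(x) > 0) igraph::as_edgelist(x@graph) else NULL
  labeledGraph(geneNames(x), el)
})

#' @rdname asLabeledGraph
#' @export
setMethod("asLabeledGraph", "Subnetwork", function(x) asLabeledGraph(x@network))

# --- DrugScreenTable --------------------------------------------------------

setMethod("show", "DrugScreenTable", function(object) {
  cat(sprintf("DrugScreenTable: %d cell lines, %d drugs, %d genes\n",
              nrow(object@ic50), ncol(object@ic50), ncol(object@mutations)))
})
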