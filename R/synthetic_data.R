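# Synthetic planted-pathway networks, null seed sets and toy drug screens.
# These generators emulate the structure the workflow assumes (annotated
# pathway communities inside a larger sparse interactome; mutant-responsive
# drug profiles) so every stage is testable without external downloads.

#' Construct a PlantedNetworkSpec
#'
#' Defaults describe the scaled-down benchmark used throughout the package:
#' 4 planted pathways of 20 genes each (each a connected random community
#' whose edges carry the pathway's name), 30 unannotated cross-pathway
#' linker edges, and 150 sparsely attached unannotated background genes.
#'
#' @param nPathways number of pathways (default 4)
#' @param pathwaySize genes per pathway, >= 3 (default 20)
#' @param intraEdgeProb probability of each non-tree within-pathway edge
#'   (default 0.3, making pathway communities clearly denser than the
#'   background)
#' @param nLinkerEdges cross-pathway edges (default 30)
#' @param nBackgroundNodes background genes (default 150)
#' @param backgroundEdgeProb probability of each background attachment edge
#'   (default 0.02)
#' @param seed optional RNG seed
#' @return a [PlantedNetworkSpec-class]
#' @export
plantedNetworkSpec <- function(nPathways = 4L, pathwaySize = 20L,
                               intraEdgeProb = 0.3, nLinkerEdges = 30L,
                               nBackgroundNodes = 150L,
                               backgroundEdgeProb = 0.02, seed = NULL) {
  new("PlantedNetworkSpec", nPathways = as.integer(nPathways),
      pathwaySize = as.integer(pathwaySize),
      intraEdgeProb = as.numeric(intraEdgeProb),
      nLinkerEdges = as.integer(nLinkerEdges),
      nBackgroundNodes = as.integer(nBackgroundNodes),
      backgroundEdgeProb = as.numeric(backgroundEdgeProb),
      seed = if (is.null(seed)) numeric(0) else as.numeric(seed))
}

#' Generate a planted-pathway network
#'
#' Each pathway is a connected random graph on its members: a uniform random
#' recursive spanning tree guarantees connectivity and every remaining pair
#' is added with probability \code{intraEdgeProb}; all these edges are
#' annotated with the pathway's name. Linker edges join random cross-pathway
#' pairs and are unannotated (modelling cross-talk outside curated
#' pathways), as are the sparse background attachments. The resulting graph
#' is simple; pathway membership is defined by annotated edges, exactly as
#' in extended-SIF input.
#'
#' @param spec a [PlantedNetworkSpec-class]
#' @return a [PathwayNetwork-class] with pathways named \code{"PW1"},
#'   \code{"PW2"}, ... and genes \code{"PW1_G01"}, ..., \code{"BG_G001"},
#'   ...
#' @examples
#' net <- generatePlantedPathwayNetwork(plantedNetworkSpec(seed = 1))
#' net
#' @export
generatePlantedPathwayNetwork <- function(spec) {
  stopifnot(is(spec, "PlantedNetworkSpec"))
  .withSeed(if (length(spec@seed)) spec@seed else NULL, {
    a <- character(0); b <- character(0); pw <- list()
    have <- new.env(parent = emptyenv())
    addEdge <- function(x, y, ann) {
      a <<- c(a, x); b <<- c(b, y); pw <<- c(pw, list(ann))
      assign(.edgeKey(x, y), TRUE, envir = have)
    }
    pwGenes <- lapply(seq_len(spec@nPathways), function(i)
      sprintf("PW%d_G%02d", i, seq_len(spec@pathwaySize)))
    for (i in seq_len(spec@nPathways)) {
      gs <- pwGenes[[i]]
      nm <- sprintf("PW%d", i)
      sz <- length(gs)
      # random recursive spanning tree guarantees connectivity
      for (j in 2:sz) {
        k <- if (j == 2) 1L else sample.int(j - 1L, 1L)
        addEdge(gs[k], gs[j], nm)
      }
      # Bernoulli extras over the pairs not already in the tree
      pairs <- combn(sz, 2)
      for (c2 in seq_len(ncol(pairs))) {
        u <- gs[pairs[1, c2]]; v <- gs[pairs[2, c2]]
        if (exists(.edgeKey(u, v), envir = have, inherits = FALSE)) next
        if (stats::runif(1) < spec@intraEdgeProb) addEdge(u, v, nm)
      }
    }
    # cross-pathway linkers, unannotated
    if (spec@nPathways >= 2 && spec@nLinkerEdges > 0) {
      added <- 0L; tries <- 0L
      while (added < spec@nLinkerEdges && tries < 100L * spec@nLinkerEdges) {
        tries <- tries + 1L
        ij <- sample.int(spec@nPathways, 2)
        x <- sample(pwGenes[[ij[1]]], 1); y <- sample(pwGenes[[ij[2]]], 1)
        if (exists(.edgeKey(x, y), envir = have, inherits = FALSE)) next
        addEdge(x, y, character(0))
        added <- added + 1L
      }
      if (added < spec@nLinkerEdges)
        stop("could not place the requested number of linker edges")
    }
    # background genes attach sparsely; one guaranteed attachment keeps
    # every gene in the interactome (edge-list formats carry no isolated
    # nodes), the rest are Bernoulli
    bgGenes <- if (spec@nBackgroundNodes > 0)
      sprintf("BG_G%03d", seq_len(spec@nBackgroundNodes)) else character(0)
    allPrev <- unlist(pwGenes, use.names = FALSE)
    for (bg in bgGenes) {
      hit <- allPrev[stats::runif(length(allPrev)) < spec@backgroundEdgeProb]
      if (length(hit) == 0) hit <- sample(allPrev, 1)
      for (x in hit) addEdge(x, bg, character(0))
      allPrev <- c(allPrev, bg)
    }
    net <- .buildNetwork(a, b,
                         interaction = rep("interacts-with", length(a)),
                         pathways = pw, extraNodes = bgGenes,
                         warnSelfLoops = FALSE)
    net
  })
}

#' Draw a null seed set uniformly from a network's genes
#'
#' Used for p-value calibration: seeds chosen without regard to network
#' structure.
#'
#' @param network a [PathwayNetwork-class]
#' @param size number of seeds (<= number of genes)
#' @param seed optional RNG seed
#' @return a [SeedSet-class]
#' @export
generateNullSeedSet <- function(network, size, seed = NULL) {
  genes <- geneNames(network)
  if (size > length(genes)) stop("size exceeds the number of genes")
  s <- .withSeed(seed, sample(genes, size))
  new("SeedSet", requested = s, mapped = s, dropped = character(0))
}

#' Generate a toy drug-response screen with a planted separating pair
#'
#' Emulates the structure of a cell-line sensitivity screen: a log-uniform
#' IC50 matrix, per-drug maximum screening concentrations and binary
#' mutation calls. For the planted drugs, every cell line carrying a
#' mutation in either gene of \code{plantedPair} receives an IC50 strictly
#' below the drug's maximum screening concentration and every wild-type
#' line strictly above it (perfect separation, mutants responsive); all
#' other drugs are drawn from one shared distribution regardless of
#' mutation status. Decoy mutation columns are included so pair
#' stratification is exercised on more than the planted genes.
#'
#' @param nCellLines number of cell lines (>= 4; default 20)
#' @param nDrugs number of drugs (default 10)
#' @param plantedPair two gene names (default \code{c("GENE_A", "GENE_B")})
#' @param plantedDrugs drug names to separate (default the first two drugs)
#' @param seed optional RNG seed
#' @return a [DrugScreenTable-class]
#' @export
generateDrugScreen <- function(nCellLines = 20L, nDrugs = 10L,
                               plantedPair = c("GENE_A", "GENE_B"),
                               plantedDrugs = NULL, seed = NULL) {
  if (nCellLines < 4) stop("need at least 4 cell lines")
  if (length(plantedPair) != 2) stop("plantedPair must name two genes")
  drugs <- sprintf("drug%02d", seq_len(nDrugs))
  if (is.null(plantedDrugs)) plantedDrugs <- drugs[seq_len(min(2, nDrugs))]
  if (!all(plantedDrugs %in% drugs))
    stop("plantedDrugs must be a subset of the drug names")
  lines <- sprintf("CL%02d", seq_len(nCellLines))
  .withSeed(seed, {
    # mutation calls for the pair: both groups guaranteed non-empty
    repeat {
      mutA <- stats::rbinom(nCellLines, 1, 0.2)
      mutB <- stats::rbinom(nCellLines, 1, 0.2)
      nm <- sum(mutA | mutB)
      if (nm >= 2 && nm <= nCellLines - 2) break
    }
    decoys <- matrix(stats::rbinom(nCellLines * 4L, 1, 0.25), nCellLines, 4,
                     dimnames = list(lines, sprintf("DECOY_%d", 1:4)))
    mutations <- cbind(matrix(c(mutA, mutB), nCellLines, 2,
                              dimnames = list(lines, plantedPair)), decoys)
    mutant <- (mutA | mutB) == 1
    maxConc <- stats::setNames(10^stats::runif(nDrugs, -0.5, 1), drugs)
    ic50 <- matrix(NA_real_, nCellLines, nDrugs,
                   dimnames = list(lines, drugs))
    for (d in drugs) {
      if (d %in% plantedDrugs) {
        ic50[mutant, d] <- maxConc[d] * stats::runif(sum(mutant), 0.05, 0.8)
        ic50[!mutant, d] <- maxConc[d] * stats::runif(sum(!mutant), 1.25, 8)
      } else {
        ic50[, d] <- maxConc[d] * 10^stats::runif(nCellLines, -1, 1)
      }
    }
    new("DrugScreenTable", ic50 = ic50, maxConc = maxConc,
        mutations = mutations)
  })
}
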