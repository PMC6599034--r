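# Benchmarking machinery: pathway seed sampling, in-/out-pathway recovery
# curves, the iteration-count sweep, the network-perturbation sweep and
# cophenetic stability across iteration counts.

#' Default significance-threshold grid for recovery curves
#' @return numeric vector of thresholds on q (or p)
#' @export
defaultThresholdGrid <- function() c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2,
                                     0.5, 1.0)

#' Sample seed genes from a pathway
#'
#' Uniform sampling without replacement from the pathway's member genes
#' (genes incident to at least one edge annotated with the pathway).
#'
#' @param network a [PathwayNetwork-class]
#' @param pathway pathway name present in the network
#' @param size number of genes to draw (<= pathway size)
#' @param seed optional RNG seed
#' @return a [SeedSet-class]
#' @export
sampleSeedGenes <- function(network, pathway, size, seed = NULL) {
  members <- pathwayMembers(network)[[pathway]]
  if (is.null(members)) stop("unknown pathway: ", pathway)
  if (size > length(members))
    stop("pathway ", pathway, " has only ", length(members), " members")
  s <- .withSeed(seed, sample(members, size))
  new("SeedSet", requested = s, mapped = s, dropped = character(0))
}

#' In- and out-pathway recovery rates at a significance threshold
#'
#' With S the unlabeled nodes significant at the threshold (q, or p, at most
#' the threshold), P the pathway members and V the network genes:
#' \code{in_rate = |S ∩ P \\ seeds| / |P \\ seeds|} (the fraction of
#' non-seed pathway genes recovered) and
#' \code{out_rate = |S \\ P| / |V \\ P|} (the fraction of all non-pathway
#' genes pulled in) — the workflow's sensitivity/specificity surrogates.
#'
#' @param table a [SignificanceTable-class]
#' @param seeds the [SeedSet-class] used for the run
#' @param pathwayGenes character vector of pathway member genes
#' @param network the [PathwayNetwork-class]
#' @param threshold significance threshold in (0, 1]
#' @param useAdjusted use q (default) or raw p
#' @return named numeric \code{c(in_rate = , out_rate = )}; \code{in_rate}
#'   is \code{NA} (with a warning) when every pathway gene is a seed
#' @export
recoveryRates <- function(table, seeds, pathwayGenes, network, threshold,
                          useAdjusted = TRUE) {
  stopifnot(is(table, "SignificanceTable"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  tb <- table@table
  crit <- if (useAdjusted) tb$q else tb$p
  S <- tb$gene[crit <= threshold]
  P <- unique(pathwayGenes)
  sd <- seeds@mapped
  V <- geneNames(network)
  inDen <- length(setdiff(P, sd))
  inRate <- if (inDen == 0) {
    warning("all pathway genes are seeds; in_rate undefined")
    NA_real_
  } else length(setdiff(intersect(S, P), sd)) / inDen
  outDen <- length(setdiff(V, P))
  outRate <- if (outDen == 0) NA_real_ else length(setdiff(S, P)) / outDen
  c(in_rate = inRate, out_rate = outRate)
}

# recovery curve over a threshold grid -> data.frame
.recoveryCurve <- function(table, seeds, pathwayGenes, network,
                           thresholds = defaultThresholdGrid(),
                           useAdjusted = TRUE) {
  rows <- t(vapply(thresholds, function(th)
    recoveryRates(table, seeds, pathwayGenes, network, th, useAdjusted),
    c(in_rate = 0, out_rate = 0)))
  data.frame(threshold = thresholds, in_rate = rows[, "in_rate"],
             out_rate = rows[, "out_rate"])
}

#' Recovery curve across a grid of significance thresholds
#'
#' @inheritParams recoveryRates
#' @param thresholds threshold grid (default [defaultThresholdGrid()])
#' @return data.frame with columns \code{threshold}, \code{in_rate},
#'   \code{out_rate}; both rates are non-decreasing as the threshold
#'   loosens
#' @export
recoveryCurve <- function(table, seeds, pathwayGenes, network,
                          thresholds = defaultThresholdGrid(),
                          useAdjusted = TRUE) {
  .recoveryCurve(table, seeds, pathwayGenes, network, thresholds,
                 useAdjusted)
}

#' Area under a recovery curve
#'
#' Summarizes a recovery curve as the area under the piecewise-linear
#' in-rate-versus-out-rate curve over out_rate in [0, 1] (anchored at
#' (0, 0); constant beyond the last observed point). Used to compare
#' "in_rate at matched out_rate" between settings.
#'
#' @param curve data.frame with columns \code{in_rate}, \code{out_rate}
#' @return number in [0, 1]
#' @export
recoveryArea <- function(curve) {
  ok <- is.finite(curve$in_rate) & is.finite(curve$out_rate)
  x <- c(0, curve$out_rate[ok]); y <- c(0, curve$in_rate[ok])
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  # collapse duplicate x (keep max in_rate at that out_rate)
  keep <- !duplicated(x, fromLast = TRUE)
  x <- x[keep]; y <- y[keep]
  if (x[length(x)] < 1) { x <- c(x, 1); y <- c(y, y[length(y)]) }
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Iteration-count sweep of recovery performance
#'
#' Full factorial over pathways x seed sizes x replicates: each cell draws a
#' seed set, computes significance tables for every \code{t} in
#' \code{tValues} against one shared random-network ensemble, and records
#' the recovery curve. The headline summary is the mean curve per
#' (t, threshold) across pathways, sizes and replicates.
#'
#' @param network a [PathwayNetwork-class]
#' @param pathways pathway names to sample from
#' @param sizes seed-set sizes (every pathway must support every size)
#' @param tValues iteration counts (default \code{c(5, 10, 15, 20, 25)})
#' @param reps replicates per pathway x size
#' @param spec a [RandomizationSpec-class]
#' @param seed optional RNG seed for the whole sweep
#' @param thresholds threshold grid
#' @param useAdjusted threshold q (default) or p
#' @return list with \code{runs} (one row per pathway, size, rep, t,
#'   threshold) and \code{means} (mean rates per t, threshold)
#' @export
iterationSweep <- function(network, pathways, sizes,
                           tValues = c(5L, 10L, 15L, 20L, 25L), reps = 5L,
                           spec = randomizationSpec(nRandom = 150L),
                           seed = NULL,
                           thresholds = defaultThresholdGrid(),
                           useAdjusted = TRUE) {
  members <- pathwayMembers(network)
  for (pwn in pathways) {
    if (is.null(members[[pwn]])) stop("unknown pathway: ", pwn)
    if (max(sizes) > length(members[[pwn]]))
      stop("pathway ", pwn, " cannot support seed size ", max(sizes))
  }
  runs <- list()
  .withSeed(seed, {
    for (pwn in pathways) for (sz in sizes) for (r in seq_len(reps)) {
      seeds <- sampleSeedGenes(network, pwn, sz)
      tabs <- .empiricalMulti(network, seeds, tValues,
                              .freshSpec(spec))
      for (h in seq_along(tValues)) {
        cv <- .recoveryCurve(tabs[[h]], seeds, members[[pwn]], network,
                             thresholds, useAdjusted)
        cv$pathway <- pwn; cv$size <- sz; cv$rep <- r
        cv$t <- tValues[h]
        runs[[length(runs) + 1]] <- cv
      }
    }
  })
  runs <- do.call(rbind, runs)
  means <- aggregate(cbind(in_rate, out_rate) ~ t + threshold, data = runs,
                     FUN = mean)
  list(runs = runs, means = means[order(means$t, means$threshold), ])
}

# strip the seed from a spec: sweeps draw their randomness from the sweep
# seed so that ensembles differ across cells
.freshSpec <- function(spec) {
  new("RandomizationSpec", nRandom = spec@nRandom,
      swapsPerEdge = spec@swapsPerEdge, seed = numeric(0))
}

#' Network-perturbation sweep of recovery performance
#'
#' For each rewired-edge fraction and replicate, the network is partially
#' rewired by [perturbNetwork()], the workflow is run on the perturbed
#' network (t fixed, default 10), and the recovery curve against the
#' original pathway annotation is recorded. Curves with the same
#' perturbation level are averaged.
#'
#' @param network a [PathwayNetwork-class]
#' @param pathway pathway to sample seeds from
#' @param fractions rewired-edge fractions in (0, 1)
#' @param reps replicates per fraction (seed sets are drawn per replicate
#'   and shared across fractions, pairing the comparison)
#' @param t propagation iterations (default 10)
#' @param seedSize seeds per replicate (default 5)
#' @param spec a [RandomizationSpec-class]
#' @param seed optional RNG seed
#' @param thresholds threshold grid
#' @param useAdjusted threshold q (default) or p
#' @return list with \code{runs} and \code{means} (per fraction, threshold)
#' @export
perturbationSweep <- function(network, pathway, fractions, reps = 5L,
                              t = 10L, seedSize = 5L,
                              spec = randomizationSpec(nRandom = 150L),
                              seed = NULL,
                              thresholds = defaultThresholdGrid(),
                              useAdjusted = TRUE) {
  if (any(fractions <= 0 | fractions >= 1))
    stop("fractions must lie in (0, 1)")
  members <- pathwayMembers(network)[[pathway]]
  if (is.null(members)) stop("unknown pathway: ", pathway)
  runs <- list()
  .withSeed(seed, {
    for (r in seq_len(reps)) {
      seeds <- sampleSeedGenes(network, pathway, seedSize)
      for (fr in fractions) {
        pnet <- perturbNetwork(network, fr)
        tab <- .empiricalMulti(pnet, seeds, t, .freshSpec(spec))[[1]]
        cv <- .recoveryCurve(tab, seeds, members, pnet, thresholds,
                             useAdjusted)
        cv$fraction <- fr; cv$rep <- r
        runs[[length(runs) + 1]] <- cv
      }
    }
  })
  runs <- do.call(rbind, runs)
  means <- aggregate(cbind(in_rate, out_rate) ~ fraction + threshold,
                     data = runs, FUN = mean)
  list(runs = runs,
       means = means[order(means$fraction, means$threshold), ])
}

#' Cophenetic stability of subnetwork clustering across iteration counts
#'
#' For each \code{t}, one subnetwork is built per seed set (all t values
#' share one random-network ensemble per seed set) and the pairwise
#' MCS-distance matrix over the subnetworks is clustered. The result is the
#' matrix of cophenetic correlations between the clusterings obtained at
#' each pair of t values: high values mean the similarity structure of the
#' result networks is robust to the iteration parameter.
#'
#' @param network a [PathwayNetwork-class]
#' @param seedSets named list of at least 3 [SeedSet-class] objects (or
#'   character vectors)
#' @param tValues iteration counts to compare
#' @param spec a [RandomizationSpec-class]
#' @param alpha subnetwork significance threshold (default 0.05)
#' @param useAdjusted threshold BH q (TRUE) or raw p (default FALSE: at
#'   benchmark scale the granular empirical-p floor makes BH q
#'   uninformative, so stability is assessed on raw-p subnetworks)
#' @param linkage linkage for clustering (default average)
#' @param seed optional RNG seed
#' @return symmetric matrix of cophenetic correlations with unit diagonal,
#'   dimnames = t values
#' @export
stabilityAcrossT <- function(network, seedSets,
                             tValues = c(5L, 10L, 25L),
                             spec = randomizationSpec(nRandom = 100L),
                             alpha = 0.05, useAdjusted = FALSE,
                             linkage = "average", seed = NULL) {
  if (length(seedSets) < 3) stop("need at least 3 seed sets")
  nm <- names(seedSets)
  if (is.null(nm)) nm <- paste0("set", seq_along(seedSets))
  tValues <- as.integer(tValues)
  subsByT <- replicate(length(tValues), list(), simplify = FALSE)
  .withSeed(seed, {
    for (i in seq_along(seedSets)) {
      seeds <- .asSeedSet(network, seedSets[[i]])
      tabs <- .empiricalMulti(network, seeds, tValues, .freshSpec(spec))
      for (h in seq_along(tValues)) {
        sub <- extractSubnetwork(network, seeds, tabs[[h]], alpha,
                                 useAdjusted = useAdjusted)
        subsByT[[h]][[nm[i]]] <- asLabeledGraph(sub)
      }
    }
  })
  mats <- lapply(subsByT, pairwiseDistances)
  k <- length(tValues)
  out <- matrix(1, k, k, dimnames = list(tValues, tValues))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    out[i, j] <- out[j, i] <-
      copheneticCorrelation(mats[[i]], mats[[j]], linkage)
  }
  out
}
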