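# Harmonic-function label propagation: synchronous degree-normalized
# averaging from a clamped seed set, plus the exact fixed point solved as a
# sparse linear system (the t -> infinity limit, used as a test oracle).

# core iteration on a sparse adjacency matrix; returns an n x length(tValues)
# matrix of snapshots of f at the requested iteration counts
.propagateCore <- function(A, deg, seedIdx, tValues) {
  n <- nrow(A)
  tValues <- as.integer(tValues)
  stopifnot(all(tValues >= 1))
  f <- numeric(n)
  f[seedIdx] <- 1
  unl <- setdiff(seq_len(n), seedIdx)
  active <- unl[deg[unl] > 0]          # degree-0 unlabeled nodes stay 0
  out <- matrix(0, n, length(tValues))
  ord <- order(tValues)
  tMax <- max(tValues)
  for (t in seq_len(tMax)) {
    if (length(active) > 0) {
      fnew <- as.numeric(A %*% f)      # synchronous: uses previous f only
      f[active] <- fnew[active] / deg[active]
    }
    hit <- which(tValues == t)
    for (h in hit) out[, h] <- f
  }
  out
}

#' Run label propagation from a seed set
#'
#' Implements the iterative harmonic-function update: at every iteration,
#' each unlabeled node's score is replaced by the degree-normalized sum of
#' its neighbors' previous scores, \eqn{f(x_j) = \sum_k w_{jk} f(x_k) /
#' \sum_k w_{jk}}, with all updates applied synchronously. Seed (labeled)
#' nodes are initialized to 1 and clamped there; unlabeled nodes start at 0.
#' Exactly \code{t} iterations are run (default 10); no convergence check is
#' applied. Scores are monotone non-decreasing in \code{t} and bounded by 1;
#' nodes in components without a seed, and isolated unlabeled nodes, stay
#' at 0.
#'
#' @param network a [PathwayNetwork-class]
#' @param seeds a [SeedSet-class] or character vector of gene symbols
#' @param t number of iterations (integer >= 1, default 10)
#' @return a [PropagationResult-class]
#' @examples
#' f <- tempfile()
#' writeLines(c("A\ti\tB", "B\ti\tC"), f)
#' net <- readExtendedSIF(f)
#' scores(propagate(net, "A", t = 1))  # B averages its neighbors: 0.5
#' @seealso [harmonicFixedPoint()], [empiricalPvalues()]
#' @export
propagate <- function(network, seeds, t = 10L) {
  stopifnot(is(network, "PathwayNetwork"))
  if (length(t) != 1 || is.na(t) || t < 1) stop("t must be an integer >= 1")
  seeds <- .asSeedSet(network, seeds)
  ad <- .adjacency(network@graph)
  seedIdx <- match(seeds@mapped, geneNames(network))
  f <- .propagateCore(ad$A, ad$deg, seedIdx, as.integer(t))[, 1]
  names(f) <- geneNames(network)
  new("PropagationResult", scores = f, iterations = as.integer(t),
      seeds = seeds)
}

#' Exact harmonic fixed point of label propagation
#'
#' Solves the stationary condition \eqn{f(j) = \sum_k w_{jk} f(k) / \sum_k
#' w_{jk}} for all unlabeled nodes as a sparse linear system, one
#' seed-containing connected component at a time. This is the limit of
#' [propagate()] as \code{t} grows; components without any boundary node get
#' 0. Besides seeds clamped at 1, additional boundary values can be pinned
#' via \code{pinned} (e.g. a node held at 0), which is useful for checking
#' the solver against closed-form harmonic interpolation.
#'
#' @param network a [PathwayNetwork-class]
#' @param seeds a [SeedSet-class] or character vector (clamped to 1)
#' @param pinned optional named numeric of extra clamped boundary values
#' @return a [PropagationResult-class]; the \code{iterations} slot holds
#'   \code{.Machine$integer.max} to mark the infinite-iteration limit
#' @export
harmonicFixedPoint <- function(network, seeds, pinned = NULL) {
  stopifnot(is(network, "PathwayNetwork"))
  seeds <- .asSeedSet(network, seeds)
  genes <- geneNames(network)
  bvals <- stats::setNames(rep(1, length(seeds@mapped)), seeds@mapped)
  if (!is.null(pinned)) {
    if (is.null(names(pinned)) || !all(names(pinned) %in% genes))
      stop("pinned values must be named after network genes")
    bvals[names(pinned)] <- pinned
  }
  bIdx <- match(names(bvals), genes)
  ad <- .adjacency(network@graph)
  A <- ad$A; deg <- ad$deg
  n <- length(genes)
  f <- numeric(n)
  f[bIdx] <- unname(bvals)
  comp <- igraph::components(network@graph)$membership
  for (cc in unique(comp[bIdx])) {
    U <- which(comp == cc & !(seq_len(n) %in% bIdx))
    U <- U[deg[U] > 0]
    if (length(U) == 0) next
    L <- Matrix::Diagonal(x = deg[U]) - A[U, U, drop = FALSE]
    rhs <- A[U, bIdx, drop = FALSE] %*% f[bIdx]
    f[U] <- as.numeric(Matrix::solve(L, rhs))
  }
  f <- pmin(pmax(f, 0), 1)
  names(f) <- genes
  new("PropagationResult", scores = f,
      iterations = .Machine$integer.max, seeds = seeds)
}
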