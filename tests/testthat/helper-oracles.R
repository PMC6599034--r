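# Independent oracles, kept deliberately naive: brute-force BH step-up,
# exhaustive hypergeometric tail enumeration and exhaustive labeled-MCS
# search. They never call the implementation paths they certify.

# Benjamini-Hochberg step-up by the definition: q_(i) = min_{j >= i} m p_(j)/j
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# P[X >= k] for X = |draw of n from N with K marked| by full enumeration
enumHyperTail <- function(k, K, n, N) {
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d %in% marked)) >= k)
}

# exhaustive label-constrained MCS: search all subset pairs and all
# label-preserving bijections (forced by unique labels to the identity on
# equal label sets), maximizing node count then edge count
bruteForceMCS <- function(g1, g2) {
  n1 <- g1@nodes; n2 <- g2@nodes
  e1 <- if (nrow(g1@edges)) pathprop:::.edgeKey(g1@edges[, 1], g1@edges[, 2])
        else character(0)
  e2 <- if (nrow(g2@edges)) pathprop:::.edgeKey(g2@edges[, 1], g2@edges[, 2])
        else character(0)
  best <- list(nodes = character(0), edges = character(0))
  subsets <- function(x) {
    if (length(x) == 0) return(list(character(0)))
    unlist(lapply(0:length(x), function(k)
      if (k == 0) list(character(0))
      else apply(utils::combn(x, k), 2, identity, simplify = FALSE)),
      recursive = FALSE)
  }
  for (s1 in subsets(n1)) {
    # a label-preserving bijection onto some subset of g2 exists iff the
    # same label set occurs in g2
    if (!all(s1 %in% n2)) next
    ee1 <- e1[g1@edges[, 1] %in% s1 & g1@edges[, 2] %in% s1]
    common <- intersect(ee1, e2)
    if (length(s1) > length(best$nodes) ||
        (length(s1) == length(best$nodes) &&
         length(common) > length(best$edges))) {
      best <- list(nodes = s1, edges = common)
    }
  }
  best
}

# small random labeled graph over a fixed label alphabet
randomLabeledGraph <- function(maxNodes = 6, alphabet = LETTERS[1:8]) {
  n <- sample(0:maxNodes, 1)
  nodes <- sample(alphabet, n)
  if (n >= 2) {
    pairs <- utils::combn(nodes, 2)
    keep <- stats::runif(ncol(pairs)) < 0.4
    labeledGraph(nodes, t(pairs[, keep, drop = FALSE]))
  } else {
    labeledGraph(nodes)
  }
}
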