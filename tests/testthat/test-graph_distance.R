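test_that("labeled MCS is the node/edge intersection on worked examples", {
  g1 <- labeledGraph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  g2 <- labeledGraph(c("B", "C", "D"), rbind(c("B", "C"), c("C", "D")))
  m <- labeledMCS(g1, g2)
  expect_setequal(m@nodes, c("B", "C"))
  expect_equal(nrow(m@edges), 1)
  expect_setequal(as.vector(m@edges), c("B", "C"))

  # a common subgraph need not be induced: shared nodes, no shared edge
  g3 <- labeledGraph(c("A", "B"), rbind(c("A", "B")))
  g4 <- labeledGraph(c("A", "B"))
  m2 <- labeledMCS(g3, g4)
  expect_setequal(m2@nodes, c("A", "B"))
  expect_equal(nrow(m2@edges), 0)

  empty <- labeledMCS(labeledGraph("X"), labeledGraph("Y"))
  expect_length(empty@nodes, 0)
})

test_that("labeled MCS agrees with exhaustive search on small graph pairs", {
  set.seed(91)
  graphs <- replicate(10, randomLabeledGraph(), simplify = FALSE)
  for (i in seq_along(graphs)) {
    for (j in i:length(graphs)) {
      m <- labeledMCS(graphs[[i]], graphs[[j]])
      bf <- bruteForceMCS(graphs[[i]], graphs[[j]])
      expect_setequal(m@nodes, bf$nodes)
      mEdges <- if (nrow(m@edges))
        pathprop:::.edgeKey(m@edges[, 1], m@edges[, 2]) else character(0)
      expect_setequal(mEdges, bf$edges)
    }
  }
})

test_that("MCS distance follows the 1 - |MCS|/max formula", {
  g <- labeledGraph(c("A", "B", "C"), rbind(c("A", "B")))
  expect_equal(mcsDistance(g, g), 0)
  h <- labeledGraph(c("X", "Y"), rbind(c("X", "Y")))
  expect_equal(mcsDistance(g, h), 1)
  g1 <- labeledGraph(c("A", "B", "C"))
  g2 <- labeledGraph(c("B", "C", "D"), rbind(c("B", "D")))
  expect_equal(mcsDistance(g1, g2), 1 / 3)
  expect_equal(mcsDistance(g2, g1), 1 / 3)  # symmetric
  expect_warning(d0 <- mcsDistance(labeledGraph(), labeledGraph()), "empty")
  expect_equal(d0, 0)
  # bounded on random pairs
  set.seed(92)
  for (r in 1:10) {
    a <- randomLabeledGraph(); b <- randomLabeledGraph()
    if (numNodes(a) + numNodes(b) == 0) next
    d <- mcsDistance(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, mcsDistance(b, a))
  }
})

test_that("pairwise distance matrices are symmetric, zero-diagonal and consistent", {
  i1 <- labeledGraph(c("A", "B"), rbind(c("A", "B")))
  expect_equal(pairwiseDistances(list(x = i1, y = i1)),
               matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y"))))
  dj <- list(a = labeledGraph(c("A", "B")), b = labeledGraph(c("C", "D")),
             c = labeledGraph(c("E", "F")))
  m <- pairwiseDistances(dj)
  expect_equal(m[upper.tri(m)], rep(1, 3))
  set.seed(93)
  items <- list(u = randomLabeledGraph(), v = randomLabeledGraph(),
                w = randomLabeledGraph())
  m2 <- pairwiseDistances(items)
  expect_equal(m2, t(m2))
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_equal(m2[i, j], mcsDistance(items[[i]], items[[j]]))
  }
  expect_error(pairwiseDistances(list(a = i1)), "at least 2")
  expect_error(pairwiseDistances(stats::setNames(dj, c("a", "a", "b"))),
               "duplicate")
})

test_that("hierarchical clustering merges the nearest pair first", {
  m <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  hc <- hierarchicalCluster(m)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("x", "y"))
  expect_equal(hc$height[1], 0.1)
  two <- m[1:2, 1:2]
  hc2 <- hierarchicalCluster(two)
  expect_equal(hc2$height, 0.1)
  expect_error(hierarchicalCluster(m[1, 1, drop = FALSE]), "at least 2")
})

test_that("cophenetic correlation detects identity, scaling and block reversal", {
  set.seed(94)
  n <- 6
  m <- matrix(stats::runif(n * n, 0.2, 1), n, n)
  m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(letters[1:n], letters[1:n])
  expect_equal(copheneticCorrelation(m, m), 1.0)
  expect_equal(copheneticCorrelation(m, 3 * m), 1.0)

  # two tight blocks vs the reversed block structure
  blockA <- matrix(0.9, n, n); blockA[1:3, 1:3] <- 0.1
  blockA[4:6, 4:6] <- 0.1; diag(blockA) <- 0
  dimnames(blockA) <- dimnames(m)
  blockB <- matrix(0.9, n, n)
  blockB[c(1, 4, 5), c(1, 4, 5)] <- 0.1
  blockB[c(2, 3, 6), c(2, 3, 6)] <- 0.1; diag(blockB) <- 0
  dimnames(blockB) <- dimnames(m)
  expect_lt(copheneticCorrelation(blockA, blockB), 0.5)

  expect_error(copheneticCorrelation(m, m[c(2:n, 1), c(2:n, 1)]), NA)
  bad <- m; dimnames(bad) <- list(LETTERS[1:n], LETTERS[1:n])
  expect_error(copheneticCorrelation(m, bad), "same item names")
  flat <- matrix(0.5, n, n); diag(flat) <- 0
  dimnames(flat) <- dimnames(m)
  expect_warning(cc <- copheneticCorrelation(flat, m), "zero variance")
  expect_true(is.na(cc))
})

test_that("cophenetic distances agree with an independent ultrametric fit", {
  # reference route: ape's cophenetic on the phylo version of the same tree
  set.seed(95)
  for (r in 1:5) {
    n <- 6
    m <- matrix(stats::runif(n * n, 0.1, 1), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
    hc <- hierarchicalCluster(m, "average")
    ours <- as.matrix(stats::cophenetic(hc))
    ref <- ape::cophenetic.phylo(ape::as.phylo(hc))
    expect_equal(ref[rownames(ours), colnames(ours)], ours,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("dendrograms round-trip through Newick export", {
  m <- matrix(c(0, 0.2, 0.8, 0.2, 0, 0.8, 0.8, 0.8, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  f <- withr::local_tempfile()
  writeDendrogramNewick(hierarchicalCluster(m), f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, c("x", "y", "z"))
})
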