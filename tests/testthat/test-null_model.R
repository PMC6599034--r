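test_that("full edge switching preserves the degree multiset and mixes edges", {
  set.seed(81)
  for (r in 1:5) {
    net <- randomNet(60, 0.08)
    rnd <- edgeSwitchRandomize(net, swapsPerEdge = 10)
    expect_equal(sort(igraph::degree(rnd@graph)[geneNames(net)]),
                 sort(igraph::degree(net@graph)[geneNames(net)]),
                 ignore_attr = TRUE)
    expect_equal(sort(igraph::degree(rnd@graph)),
                 sort(igraph::degree(net@graph)), ignore_attr = TRUE)
  }
  # retained original-edge fraction is low after 10 swaps/edge
  set.seed(82)
  retained <- replicate(20, {
    net <- randomNet(200, 0.03)
    rnd <- edgeSwitchRandomize(net, swapsPerEdge = 10)
    1 - rewiredFraction(net, rnd)
  })
  expect_lt(mean(retained), 0.3)
})

test_that("degenerate graphs are handled: K3 unchanged, single edge warns", {
  k3 <- makeNet(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
  rnd <- edgeSwitchRandomize(k3, swapsPerEdge = 50, seed = 1)
  e <- igraph::as_edgelist(rnd@graph)
  expect_setequal(pathprop:::.edgeKey(e[, 1], e[, 2]),
                  c("A\1B", "B\1C", "A\1C"))
  one <- makeNet(data.frame(a = "A", b = "B"))
  expect_warning(rnd1 <- edgeSwitchRandomize(one), "fewer than 2 edges")
  expect_equal(numEdges(rnd1), 1)
})

test_that("partial rewiring stops at the target and keeps surviving annotations", {
  # first applied swap on |E| = 100 replaces exactly 2 original edges
  set.seed(83)
  net100 <- randomNet(60, 0.057)
  while (numEdges(net100) != 100) net100 <- randomNet(60, 0.057)
  p1 <- perturbNetwork(net100, 0.001, seed = 4)
  expect_equal(rewiredFraction(net100, p1), 0.02)

  # achieved fraction within one-swap granularity of the target
  net <- plantedFixture(10)
  m <- numEdges(net)
  for (fr in c(0.01, 0.1, 0.4)) {
    pp <- perturbNetwork(net, fr, seed = 5)
    ach <- rewiredFraction(net, pp)
    expect_gte(ach, fr)
    expect_lte(ach, fr + 2 / m)
    expect_equal(sort(igraph::degree(pp@graph)[geneNames(net)]),
                 sort(igraph::degree(net@graph)[geneNames(net)]),
                 ignore_attr = TRUE)
    # annotations survive exactly on edges that are still original
    eo <- edgeTable(net); ep <- edgeTable(pp)
    ko <- paste(eo$from, eo$to); kp <- paste(ep$from, ep$to)
    shared <- intersect(ko, kp)
    expect_equal(ep$pathways[match(shared, kp)],
                 eo$pathways[match(shared, ko)])
    expect_true(all(ep$pathways[!kp %in% ko] == ""))
  }
})

test_that("rewired fraction follows its set-difference definition", {
  net <- pathABC()
  expect_equal(rewiredFraction(net, net), 0)
  # 4-cycle with one legal double swap applied: 2 of 4 edges replaced
  cyc <- makeNet(data.frame(a = c("A", "B", "C", "D"),
                            b = c("B", "C", "D", "A")))
  swp <- makeNet(data.frame(a = c("A", "C", "B", "D"),
                            b = c("C", "B", "D", "A")))
  expect_equal(sort(igraph::degree(swp@graph)),
               sort(igraph::degree(cyc@graph)), ignore_attr = TRUE)
  expect_equal(rewiredFraction(cyc, swp), 0.5)
  # edge-disjoint same-degree graphs: fraction 1
  p1 <- makeNet(data.frame(a = c("A", "C"), b = c("B", "D")))
  p2 <- makeNet(data.frame(a = c("A", "B"), b = c("C", "D")))
  expect_equal(rewiredFraction(p1, p2), 1)
  bad <- makeNet(data.frame(a = "A", b = "E"))
  expect_error(rewiredFraction(net, bad), "same node set")
})

test_that("BH adjustment matches the step-up definition and validates input", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(c(0.5, 1.0)), c(1.0, 1.0))
  expect_error(bhAdjust(c(0.1, 0)), "0, 1")
  expect_error(bhAdjust(c(0.1, 1.1)), "0, 1")
  set.seed(84)
  for (r in 1:25) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), bruteForceBH(p))
  }
})

test_that("empirical p-values obey the add-one formula, ties and determinism", {
  # star: every degree-preserving rewiring is the star itself, so every
  # leaf ties with all ensemble values and gets p = 1 (ties are extreme)
  star <- makeNet(data.frame(a = rep("HUB", 5), b = paste0("L", 1:5)))
  st <- empiricalPvalues(star, "HUB", t = 3,
                         spec = randomizationSpec(nRandom = 19L, seed = 1))
  expect_equal(significanceTable(st)$p, rep(1, 5))

  # unreachable nodes have f = 0 and p = 1
  two <- makeNet(data.frame(a = c("A", "B", "X"), b = c("B", "C", "Y")))
  st2 <- empiricalPvalues(two, "A", t = 5,
                          spec = randomizationSpec(nRandom = 19L, seed = 2))
  tb2 <- significanceTable(st2)
  expect_equal(tb2$p[tb2$gene %in% c("X", "Y")], c(1, 1))

  # p bounded below by 1/(n+1), q = BH(p), reproducible under the spec seed
  net <- plantedFixture(11)
  seeds <- sampleSeedGenes(net, "PW2", 5, seed = 3)
  spec <- randomizationSpec(nRandom = 49L, seed = 99)
  stA <- empiricalPvalues(net, seeds, t = 5, spec = spec)
  stB <- empiricalPvalues(net, seeds, t = 5, spec = spec)
  tb <- significanceTable(stA)
  expect_identical(tb, significanceTable(stB))
  expect_gte(min(tb$p), 1 / 50)
  expect_equal(tb$q, bhAdjust(tb$p))
})

test_that("subnetwork extraction applies the threshold to seeds plus q", {
  net <- plantedFixture(12)
  seeds <- sampleSeedGenes(net, "PW1", 5, seed = 4)
  st <- empiricalPvalues(net, seeds, t = 5,
                         spec = randomizationSpec(nRandom = 39L, seed = 5))
  tb <- significanceTable(st)

  tiny <- extractSubnetwork(net, seeds, st, alpha = 1e-6)
  expect_setequal(geneNames(tiny), seedGenes(seeds))

  wide <- extractSubnetwork(net, seeds, st, alpha = 0.999)
  expect_setequal(geneNames(wide),
                  union(seedGenes(seeds), tb$gene[tb$q < 0.999]))

  # induced edges: every subnetwork edge exists in the parent with the
  # same annotation, and no parent edge between kept nodes is missing
  sn <- extractSubnetwork(net, seeds, st, alpha = 0.3, useAdjusted = FALSE)
  ep <- edgeTable(net); es <- edgeTable(sn)
  kp <- paste(ep$from, ep$to); ks <- paste(es$from, es$to)
  expect_true(all(ks %in% kp))
  expect_equal(es$pathways, ep$pathways[match(ks, kp)])
  inside <- ep$from %in% geneNames(sn) & ep$to %in% geneNames(sn)
  expect_setequal(ks, kp[inside])
})

test_that("planted pathway genes are recovered at the raw-p threshold", {
  net <- plantedFixture(42)
  seeds <- sampleSeedGenes(net, "PW1", 5, seed = 6)
  st <- empiricalPvalues(net, seeds, t = 10,
                         spec = randomizationSpec(nRandom = 200L, seed = 7))
  tb <- significanceTable(st)
  rest <- setdiff(pathwayMembers(net)$PW1, seedGenes(seeds))
  expect_gte(sum(tb$p[tb$gene %in% rest] < 0.05), length(rest) / 2)
})
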